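# Exact rational linear programming.
#
# A two-phase primal simplex with Bland's rule over rq rationals. Bland's
# rule guarantees termination; exact arithmetic makes every feasibility and
# optimality verdict tolerance-free, which the combinatorial claims of the
# package (vertex counts, module verification, rank tests) depend on.

# outer product of two rq vectors -> rq matrix
rq_outer <- function(u, v) {
  rq_norm(outer(u$num, v$num), outer(u$den, v$den))
}

# min cmin' y  s.t.  A y = b, y >= 0   (standard form)
# returns list(status, y, obj, ray)
rq_simplex <- function(A, b, cmin) {
  m <- rq_nrow(A); n <- rq_ncol(A)
  stopifnot(length(b) == m, length(cmin) == n)
  # b >= 0 by row negation
  for (i in seq_len(m)) {
    if (b$num[i] < 0) {
      A[i, ] <- -A[i, , drop = FALSE]
      b[i] <- -b[i]
    }
  }
  bm <- b; dim(bm) <- c(m, 1)
  art <- rq_matrix(rq(0), m, m)
  for (i in seq_len(m)) art[i, i] <- rq(1)
  Tab <- rq_cbind(A, art, bm)
  last <- n + m + 1L
  basis <- n + seq_len(m)

  c1 <- rq_c(rq(numeric(n)), rq(rep(1, m)), rq(0))
  c2 <- rq_c(cmin, rq(numeric(m)), rq(0))
  # canonicalize phase-1 costs against the artificial basis
  for (i in seq_len(m)) c1 <- c1 - Tab[i, , drop = TRUE]

  env <- environment()
  do_pivot <- function(r, e) {
    piv <- Tab[r, e, drop = TRUE]
    Tab[r, ] <- Tab[r, , drop = FALSE] / piv
    colv <- Tab[, e, drop = TRUE]
    colv[r] <- rq(0)
    Tab <- Tab - rq_outer(colv, Tab[r, , drop = TRUE])
    f1 <- c1[e]; if (f1$num != 0) c1 <- c1 - Tab[r, , drop = TRUE] * f1
    f2 <- c2[e]; if (f2$num != 0) c2 <- c2 - Tab[r, , drop = TRUE] * f2
    basis[r] <- e
    assign("Tab", Tab, envir = env); assign("c1", c1, envir = env)
    assign("c2", c2, envir = env); assign("basis", basis, envir = env)
  }

  run_phase <- function(cost_name) {
    repeat {
      crow <- get(cost_name, envir = env)
      ecand <- which(crow$num[seq_len(n)] < 0)
      if (length(ecand) == 0) return("optimal")
      e <- ecand[1]  # Bland
      rows <- which(Tab$num[, e] > 0)
      if (length(rows) == 0) return(e)  # unbounded along col e
      best <- NULL; bestr <- NULL
      for (i in rows) {
        th <- Tab[i, last, drop = TRUE] / Tab[i, e, drop = TRUE]
        if (is.null(best) || isTRUE(th < best) ||
            (isTRUE(th == best) && basis[i] < basis[bestr])) {
          best <- th; bestr <- i
        }
      }
      do_pivot(bestr, e)
      Tab <- get("Tab", envir = env); basis <- get("basis", envir = env)
    }
  }

  # phase 1
  r1 <- run_phase("c1")
  stopifnot(identical(r1, "optimal"))  # phase-1 objective bounded below by 0
  val1 <- -c1[last]
  if (val1$num != 0) return(list(status = "infeasible"))

  # drive artificials out of the basis; drop redundant rows
  drop_rows <- integer(0)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      e <- which(Tab$num[i, seq_len(n)] != 0)
      if (length(e)) {
        do_pivot(i, e[1])
        Tab <- get("Tab", envir = env); basis <- get("basis", envir = env)
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
  }
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(rq_nrow(Tab)), drop_rows)
    Tab <- Tab[keep, , drop = FALSE]
    basis <- basis[keep]
    assign("Tab", Tab, envir = env); assign("basis", basis, envir = env)
  }

  # phase 2
  r2 <- run_phase("c2")
  Tab <- get("Tab", envir = env); basis <- get("basis", envir = env)
  c2 <- get("c2", envir = env)
  y <- rq(numeric(n))
  for (i in seq_along(basis)) if (basis[i] <= n) y[basis[i]] <- Tab[i, last, drop = TRUE]
  if (!identical(r2, "optimal")) {
    e <- r2
    ray <- rq(numeric(n))
    ray[e] <- rq(1)
    for (i in seq_along(basis)) {
      if (basis[i] <= n) ray[basis[i]] <- -Tab[i, e, drop = TRUE]
    }
    return(list(status = "unbounded", y = y, ray = ray))
  }
  list(status = "optimal", y = y, obj = -c2[last])
}

# ---- generic bounded LP layer ---------------------------------------------

# An rlp is a linear problem over named variables with bounds and rows.
rlp_new <- function(var_names) {
  nv <- length(var_names)
  list(names = var_names, nv = nv,
       lb = rep(list(rq(0)), nv), ub = rep(list(Inf), nv),
       rows = list())
}

rlp_set_bounds <- function(lp, i, lb, ub) {
  lp$lb[[i]] <- as_bound(lb); lp$ub[[i]] <- as_bound(ub)
  lp
}

# idx: integer var indices; coef: rq vector; rel in "=", "<=", ">="
rlp_add_row <- function(lp, idx, coef, rel, rhs) {
  if (!inherits(coef, "rq")) coef <- rq_from_decimal(coef)
  if (!inherits(rhs, "rq")) rhs <- rq_from_decimal(rhs)
  lp$rows[[length(lp$rows) + 1L]] <- list(idx = as.integer(idx), coef = coef,
                                          rel = rel, rhs = rhs)
  lp
}

# minimize/maximize obj (rq vector over the lp's variables)
# returns list(status, x = rq vector over variables, obj, ray)
rlp_solve <- function(lp, obj, sense = c("min", "max")) {
  sense <- match.arg(sense)
  nv <- lp$nv
  # variable transform: map each var to standard-form columns
  kind <- character(nv); colix <- vector("list", nv)
  fixed_val <- vector("list", nv)
  ncols <- 0L
  extra_ub <- list()  # rows y_k <= u for doubly-bounded vars
  for (v in seq_len(nv)) {
    l <- lp$lb[[v]]; u <- lp$ub[[v]]
    lf <- bound_finite(l); uf <- bound_finite(u)
    if (lf && uf && isTRUE(l == u)) {
      kind[v] <- "fixed"; fixed_val[[v]] <- l
    } else if (lf) {
      kind[v] <- "shift"; ncols <- ncols + 1L; colix[[v]] <- ncols
      if (uf) extra_ub[[length(extra_ub) + 1L]] <- list(col = ncols, val = u - l)
    } else if (uf) {
      kind[v] <- "neg"; ncols <- ncols + 1L; colix[[v]] <- ncols
    } else {
      kind[v] <- "free"; colix[[v]] <- c(ncols + 1L, ncols + 2L); ncols <- ncols + 2L
    }
  }
  nrows0 <- length(lp$rows)
  n_slack <- sum(vapply(lp$rows, function(r) r$rel != "=", logical(1))) +
    length(extra_ub)
  ntot <- ncols + n_slack
  m <- nrows0 + length(extra_ub)
  Anum <- matrix(0, m, ntot); Aden <- matrix(1, m, ntot)
  A <- structure(list(num = Anum, den = Aden), class = "rq")
  b <- rq(numeric(m))
  slack_at <- ncols
  live_rows <- rep(TRUE, m)
  for (ri in seq_len(nrows0)) {
    row <- lp$rows[[ri]]
    rhs <- row$rhs
    for (k in seq_along(row$idx)) {
      v <- row$idx[k]; a <- row$coef[k]
      if (a$num == 0) next
      switch(kind[v],
        fixed = { rhs <- rhs - a * fixed_val[[v]] },
        shift = {
          A[ri, colix[[v]]] <- A[ri, colix[[v]], drop = TRUE] + a
          rhs <- rhs - a * lp$lb[[v]]
        },
        neg = {
          A[ri, colix[[v]]] <- A[ri, colix[[v]], drop = TRUE] - a
          rhs <- rhs - a * lp$ub[[v]]
        },
        free = {
          A[ri, colix[[v]][1]] <- A[ri, colix[[v]][1], drop = TRUE] + a
          A[ri, colix[[v]][2]] <- A[ri, colix[[v]][2], drop = TRUE] - a
        })
    }
    if (row$rel != "=") {
      slack_at <- slack_at + 1L
      A[ri, slack_at] <- if (row$rel == "<=") rq(1) else rq(-1)
    }
    b[ri] <- rhs
    # row entirely on fixed vars?
    if (all(A$num[ri, ] == 0)) {
      feas <- switch(row$rel,
                     "=" = rhs$num == 0,
                     "<=" = rhs$num >= 0,
                     ">=" = rhs$num <= 0)
      if (!feas) return(list(status = "infeasible"))
      live_rows[ri] <- FALSE
    }
  }
  for (k in seq_along(extra_ub)) {
    ri <- nrows0 + k
    A[ri, extra_ub[[k]]$col] <- rq(1)
    slack_at <- slack_at + 1L
    A[ri, slack_at] <- rq(1)
    b[ri] <- extra_ub[[k]]$val
  }
  # objective in standard-form columns
  if (!inherits(obj, "rq")) obj <- rq_from_decimal(obj)
  stopifnot(length(obj) == nv)
  cmin <- rq(numeric(ntot)); cconst <- rq(0)
  sgn <- if (sense == "min") rq(1) else rq(-1)
  for (v in seq_len(nv)) {
    a <- obj[v] * sgn
    if (a$num == 0) next
    switch(kind[v],
      fixed = { cconst <- cconst + a * fixed_val[[v]] },
      shift = { cmin[colix[[v]]] <- cmin[colix[[v]]] + a
                cconst <- cconst + a * lp$lb[[v]] },
      neg = { cmin[colix[[v]]] <- cmin[colix[[v]]] - a
              cconst <- cconst + a * lp$ub[[v]] },
      free = { cmin[colix[[v]][1]] <- cmin[colix[[v]][1]] + a
               cmin[colix[[v]][2]] <- cmin[colix[[v]][2]] - a })
  }
  if (!all(live_rows)) {
    A <- A[which(live_rows), , drop = FALSE]
    b <- b[which(live_rows)]
  }
  res <- rq_simplex(A, b, cmin)
  if (res$status == "infeasible") return(list(status = "infeasible"))

  y_to_x <- function(y, homogeneous = FALSE) {
    x <- rq(numeric(nv))
    for (v in seq_len(nv)) {
      x[v] <- switch(kind[v],
        fixed = if (homogeneous) rq(0) else fixed_val[[v]],
        shift = y[colix[[v]]] + (if (homogeneous) rq(0) else lp$lb[[v]]),
        neg = (if (homogeneous) rq(0) else lp$ub[[v]]) - y[colix[[v]]],
        free = y[colix[[v]][1]] - y[colix[[v]][2]])
    }
    x
  }
  if (res$status == "unbounded") {
    return(list(status = "unbounded", x = y_to_x(res$y),
                ray = y_to_x(res$ray, homogeneous = TRUE)))
  }
  # the simplex minimized the sign-adjusted objective; undo the adjustment
  val <- res$obj + cconst
  if (sense == "max") val <- -val
  list(status = "optimal", x = y_to_x(res$y), obj = val)
}

# ---- FBA / FVA -------------------------------------------------------------

# rlp encoding of a model's feasible flux set: variables = reactions,
# steady-state rows over non-boundary species
model_rlp <- function(model) {
  rxns <- fs_rxn_ids(model)
  lp <- rlp_new(rxns)
  for (j in seq_along(rxns)) {
    r <- model$reactions[[j]]
    lp <- rlp_set_bounds(lp, j, r$lb, r$ub)
  }
  sm <- stoich_matrix(model)
  for (i in seq_along(sm$species)) {
    nz <- which(sm$mat$num[i, ] != 0)
    if (length(nz) == 0) next
    lp <- rlp_add_row(lp, nz, sm$mat[i, nz, drop = TRUE], "=", rq(0))
  }
  lp
}

#' Solve an FBA problem exactly
#'
#' Maximizes (or minimizes) the model objective `c' J` subject to exact
#' steady state `N J = 0` and the flux bounds, with a rational simplex.
#' The returned flux is a basic feasible solution of the constraint system.
#'
#' @param model a `stoich_model`.
#' @param sense `"max"` or `"min"`.
#' @param objective optional named numeric/rq vector overriding the model's
#'   objective coefficients.
#' @return An `fba_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, or `"unbounded"`), `objective_value` (rq), `flux`
#'   ([flux_vector()]), and for unbounded problems a certificate `ray`.
#' @examples
#' sol <- solve_fba(build_toy_model())
#' format(sol$objective_value)  # "1"
#' @export
solve_fba <- function(model, sense = c("max", "min"), objective = NULL) {
  sense <- match.arg(sense)
  fs_validate(model)
  rxns <- fs_rxn_ids(model)
  cobj <- if (is.null(objective)) fs_obj_coeffs(model) else {
    stopifnot(!is.null(names(objective)))
    v <- rq(numeric(length(rxns)))
    ix <- match(names(objective), rxns)
    if (anyNA(ix)) stop("objective names unknown reactions")
    ov <- if (inherits(objective, "rq")) objective else rq_from_decimal(objective)
    for (k in seq_along(ix)) v[ix[k]] <- ov[k]
    v
  }
  if (all(cobj$num == 0)) stop("no nonzero objective coefficient")
  res <- rlp_solve(model_rlp(model), cobj, sense)
  out <- list(status = res$status)
  if (res$status == "optimal") {
    out$objective_value <- res$obj
    out$flux <- flux_vector(res$x, rxns)
  } else if (res$status == "unbounded") {
    out$ray <- flux_vector(res$ray, rxns)
  }
  class(out) <- "fba_solution"
  out
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution: status", x$status)
  if (x$status == "optimal") {
    cat(", objective", format(x$objective_value),
        sprintf("(%.6g)", as.double(x$objective_value)))
  }
  cat("\n")
  invisible(x)
}

#' Exact flux variability analysis
#'
#' For each reaction, the exact minimum and maximum flux over the optimal
#' solution space (the feasible set with the objective pinned to
#' `fix_objective_at` by an equality row). Interval endpoints can be
#' `-Inf`/`Inf` when the optimum is unbounded in that direction (futile
#' cycles, linealities).
#'
#' @param model a `stoich_model`.
#' @param fix_objective_at rq (or number): the FBA optimum, or any feasible
#'   objective value.
#' @param reactions optional character vector restricting the scan.
#' @return An `fva_result`: list with `rxns` and per-reaction `min`/`max`
#'   (lists of rq scalars or infinite sentinels).
#' @export
fva <- function(model, fix_objective_at, reactions = NULL) {
  rxns <- fs_rxn_ids(model)
  if (is.null(reactions)) reactions <- rxns
  ix <- match(reactions, rxns)
  if (anyNA(ix)) stop("unknown reactions: ", paste(reactions[is.na(ix)], collapse = ", "))
  cobj <- fs_obj_coeffs(model)
  if (!inherits(fix_objective_at, "rq")) fix_objective_at <- rq_from_decimal(fix_objective_at)
  lp <- model_rlp(model)
  nzc <- which(cobj$num != 0)
  lp <- rlp_add_row(lp, nzc, cobj[nzc], "=", fix_objective_at)
  lo <- vector("list", length(ix)); hi <- vector("list", length(ix))
  for (k in seq_along(ix)) {
    ej <- rq(numeric(length(rxns))); ej[ix[k]] <- rq(1)
    rmin <- rlp_solve(lp, ej, "min")
    rmax <- rlp_solve(lp, ej, "max")
    if (rmin$status == "infeasible" || rmax$status == "infeasible") {
      stop("FVA infeasible at the fixed objective value")
    }
    lo[[k]] <- if (rmin$status == "unbounded") -Inf else rmin$obj
    hi[[k]] <- if (rmax$status == "unbounded") Inf else rmax$obj
  }
  structure(list(rxns = reactions, min = lo, max = hi), class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  df <- data.frame(
    reaction = x$rxns,
    min = vapply(x$min, fmt_bound, character(1)),
    max = vapply(x$max, fmt_bound, character(1)))
  print(df, row.names = FALSE)
  invisible(x)
}

# width of an FVA interval: TRUE when max > min (Inf endpoints count)
fva_variable <- function(fv) {
  vapply(seq_along(fv$rxns), function(k) {
    lo <- fv$min[[k]]; hi <- fv$max[[k]]
    if (!bound_finite(lo) || !bound_finite(hi)) return(TRUE)
    isTRUE(hi > lo)
  }, logical(1))
}
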