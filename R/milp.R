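# Branch-and-bound mixed-integer optimization over the exact LP layer.
# Used for pathway-length minimization: binary activity indicators linked
# to fluxes through exact big-M constraints.

rq_ceil <- function(v) {
  stopifnot(inherits(v, "rq"), length(v) == 1)
  -((-v$num) %/% v$den)
}

#' Minimize the number of active indicated fluxes (exact MILP)
#'
#' Solves `min sum(y)` over the model's flux polyhedron (optionally with
#' the objective pinned), with one binary activity variable per indicated
#' reaction linked by `J_j <= M⁺_j y_j` (and `J_j >= M⁻_j y_j` for
#' reactions that may run negative). Branch and bound over the exact LP
#' relaxation; bounds and verdicts are rational throughout.
#'
#' @param model a `stoich_model`.
#' @param indicator_spec list with entries `rxn` (id), `M_plus` (rq > 0
#'   activity bound), and optionally `M_minus` (rq < 0) for reactions with
#'   a negative flux range. Reactions without an entry carry no indicator.
#' @param fix_objective_at optional rq: adds the equality `c' J = value`.
#' @return list with `status`, `optimal_value` (integer count), `flux`
#'   ([flux_vector()] witness), `y` (named integer activity vector).
#' @export
solve_milp <- function(model, indicator_spec, fix_objective_at = NULL) {
  rxns <- fs_rxn_ids(model)
  ids <- vapply(indicator_spec, `[[`, character(1), "rxn")
  if (anyNA(match(ids, rxns))) stop("indicator_spec names unknown reactions")
  ni <- length(indicator_spec)
  lp <- rlp_new(c(rxns, paste0(".y_", ids)))
  for (j in seq_along(rxns)) {
    r <- model$reactions[[j]]
    lp <- rlp_set_bounds(lp, j, r$lb, r$ub)
  }
  nr <- length(rxns)
  for (k in seq_len(ni)) lp <- rlp_set_bounds(lp, nr + k, 0, 1)
  sm <- stoich_matrix(model)
  for (i in seq_along(sm$species)) {
    nz <- which(sm$mat$num[i, ] != 0)
    if (length(nz)) lp <- rlp_add_row(lp, nz, sm$mat[i, nz, drop = TRUE], "=", rq(0))
  }
  if (!is.null(fix_objective_at)) {
    cobj <- fs_obj_coeffs(model)
    nz <- which(cobj$num != 0)
    if (length(nz) == 0) stop("objective fix requested but model has no objective")
    if (!inherits(fix_objective_at, "rq")) fix_objective_at <- rq_from_decimal(fix_objective_at)
    lp <- rlp_add_row(lp, nz, cobj[nz], "=", fix_objective_at)
  }
  for (k in seq_len(ni)) {
    spec <- indicator_spec[[k]]
    j <- match(spec$rxn, rxns)
    Mp <- spec$M_plus; Mm <- spec$M_minus
    if (is.null(Mp) && is.null(Mm)) {
      stop("no finite activity bound M for reaction ", spec$rxn,
           "; supply explicit bounds")
    }
    if (!is.null(Mp)) {
      stopifnot(inherits(Mp, "rq"), Mp$num > 0)
      lp <- rlp_add_row(lp, c(j, nr + k), rq_c(rq(1), -Mp), "<=", rq(0))
    } else {
      # no positive range over the optimum: pin that side to zero
      lp <- rlp_add_row(lp, j, rq(1), "<=", rq(0))
    }
    lbj <- model$reactions[[j]]$lb
    can_neg <- !bound_finite(lbj) || lbj$num < 0
    if (can_neg) {
      if (!is.null(Mm)) {
        stopifnot(inherits(Mm, "rq"), Mm$num < 0)
        lp <- rlp_add_row(lp, c(j, nr + k), rq_c(rq(1), -Mm), ">=", rq(0))
      } else {
        lp <- rlp_add_row(lp, j, rq(1), ">=", rq(0))
      }
    }
  }
  obj <- rq(c(numeric(nr), rep(1, ni)))

  best_val <- Inf
  best <- NULL
  yix <- nr + seq_len(ni)

  count_support <- function(x) sum(x$num[seq_len(nr)][match(ids, rxns)] != 0)

  node_stack <- list(list())  # each node: named list y index -> 0/1
  while (length(node_stack)) {
    fixes <- node_stack[[length(node_stack)]]
    node_stack[[length(node_stack)]] <- NULL
    lpn <- lp
    for (nm in names(fixes)) {
      k <- as.integer(nm)
      lpn <- rlp_set_bounds(lpn, yix[k], fixes[[nm]], fixes[[nm]])
    }
    res <- rlp_solve(lpn, obj, "min")
    if (res$status != "optimal") next
    if (is.finite(best_val) && rq_ceil(res$obj) >= best_val) next
    # rounding the relaxation witness (y_j = 1 iff J_j != 0) is feasible
    # and gives an incumbent
    up <- count_support(res$x)
    if (up < best_val) {
      best_val <- up
      best <- list(x = res$x, y = as.integer(res$x$num[match(ids, rxns)] != 0))
    }
    if (rq_ceil(res$obj) >= best_val) next
    yvals <- res$x[yix]
    frac <- which(yvals$num != 0 & !(yvals$num == yvals$den))
    if (length(frac) == 0) {
      v <- sum(yvals)
      stopifnot(v$den == 1)
      if (v$num < best_val) {
        best_val <- v$num
        best <- list(x = res$x, y = as.integer(yvals$num != 0))
      }
      next
    }
    k <- frac[1]
    # explore y=0 first (favors sparse solutions)
    f1 <- fixes; f1[[as.character(k)]] <- 1
    f0 <- fixes; f0[[as.character(k)]] <- 0
    node_stack <- c(node_stack, list(f1), list(f0))
  }
  if (is.null(best)) return(list(status = "infeasible"))
  list(status = "optimal", optimal_value = as.integer(best_val),
       flux = flux_vector(best$x[seq_len(nr)], rxns),
       y = stats::setNames(best$y, ids))
}
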