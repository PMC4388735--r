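# Independent oracles used across the suite. They deliberately avoid the
# code paths they check: the vertex oracle enumerates candidate active
# sets and solves each equality system by rational elimination, instead of
# running the double-description engine.

# all vertices of {N J = 0, c J = z, lb <= J <= ub} for a model WITHOUT
# free (unbounded-below) variables, by brute force over support subsets:
# every subset F of reactions is tried as the not-at-a-bound set; the
# remaining reactions take each combination of their finite bounds; the
# equality system restricted to F must then determine the F-fluxes
# uniquely (rank |F|), and feasible solutions are kept and deduplicated.
oracle_vertices <- function(model, z_star) {
  rxns <- names(model$reactions)
  n <- length(rxns)
  sm <- stoich_matrix(model)
  cobj <- do.call(rq_c, lapply(model$reactions, `[[`, "obj"))
  crow <- cobj; dim(crow) <- c(1, n)
  Aeq <- rq_rbind(sm$mat, crow)
  if (!inherits(z_star, "rq")) z_star <- rq_from_decimal(z_star)
  beq <- rq_c(rq(numeric(length(sm$species))), z_star)
  m <- nrow(Aeq$num)
  lbs <- lapply(model$reactions, `[[`, "lb")
  ubs <- lapply(model$reactions, `[[`, "ub")
  bound_opts <- lapply(seq_len(n), function(j) {
    opts <- list()
    if (inherits(lbs[[j]], "rq")) opts <- c(opts, list(lbs[[j]]))
    if (inherits(ubs[[j]], "rq")) opts <- c(opts, list(ubs[[j]]))
    stopifnot(length(opts) >= 1)  # oracle needs no free variables
    opts
  })
  maxk <- min(n, rq_rank(Aeq))
  found <- list(); keys <- character(0)
  for (k in 0:maxk) {
    for (Fset in combn_list(n, k)) {
      rest <- setdiff(seq_len(n), Fset)
      grids <- expand_bound_grid(bound_opts[rest])
      for (g in grids) {
        rhs <- beq
        for (ii in seq_along(rest)) {
          j <- rest[ii]
          col <- Aeq[, j, drop = TRUE]
          rhs <- rhs - col * g[[ii]]
        }
        x <- rq(numeric(n))
        if (k > 0) {
          AF <- Aeq[, Fset, drop = FALSE]
          if (k == 1) AF <- rq_matrix(AF, m, 1)
          rhsm <- rhs; dim(rhsm) <- c(m, 1)
          sol <- rq_rref(rq_cbind(AF, rhsm))
          if ((k + 1) %in% sol$pivots) next   # inconsistent
          if (sol$rank != k) next             # underdetermined
          for (ii in seq_len(k)) x[Fset[ii]] <- sol$rref[ii, k + 1, drop = TRUE]
        } else {
          if (any(rhs$num != 0)) next
        }
        for (ii in seq_along(rest)) x[rest[ii]] <- g[[ii]]
        # verify all equalities and bounds exactly
        xv <- x; dim(xv) <- c(n, 1)
        if (!all((rq_matmul(Aeq, xv)[, 1, drop = TRUE] - beq)$num == 0)) next
        feas <- TRUE
        for (j in seq_len(n)) {
          if (inherits(lbs[[j]], "rq") && isTRUE(x[j] < lbs[[j]])) feas <- FALSE
          if (inherits(ubs[[j]], "rq") && isTRUE(x[j] > ubs[[j]])) feas <- FALSE
          if (!feas) break
        }
        if (!feas) next
        key <- paste(format(x), collapse = ",")
        if (!key %in% keys) {
          keys <- c(keys, key)
          found <- c(found, list(flux_vector(x, rxns)))
        }
      }
    }
  }
  found[order(vapply(found, function(v) paste(format(v$values), collapse = ","),
                     character(1)))]
}

combn_list <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  utils::combn(n, k, simplify = FALSE)
}

# cartesian product of per-variable bound options (lists of rq scalars)
expand_bound_grid <- function(opts) {
  if (length(opts) == 0) return(list(list()))
  sizes <- vapply(opts, length, integer(1))
  total <- prod(sizes)
  stopifnot(total <= 100000)
  out <- vector("list", total)
  for (i in seq_len(total)) {
    rem <- i - 1
    g <- vector("list", length(opts))
    for (j in seq_along(opts)) {
      g[[j]] <- opts[[j]][[rem %% sizes[j] + 1]]
      rem <- rem %/% sizes[j]
    }
    out[[i]] <- g
  }
  out
}

vertex_set_key <- function(vs) {
  sort(vapply(vs, function(v) paste(format(v$values), collapse = ","), character(1)))
}

# a random split model with one restricting input bound and its optimum;
# NULL when the draw has a zero optimum (no flux reaches the output)
random_split_fixture <- function(seed, n_species = 3, n_reactions = 6) {
  m <- generate_random_model(n_species, n_reactions, seed, p_reversible = 0.4)
  m <- fs_set_bounds(m, "R1", ub = 1)
  sp <- split_reversible(m)
  sol <- solve_fba(sp$model)
  if (sol$status != "optimal" || sol$objective_value$num == 0) return(NULL)
  list(model = sp$model, z = sol$objective_value, split_map = sp$split_map,
       original = m)
}

toy_demand_variant <- function() {
  toy <- build_toy_model()
  toy$species <- rbind(toy$species, data.frame(id = "W", boundary = TRUE))
  toy$reactions[["R19"]] <- fs_reaction("R19", c(B = -1, W = 1),
                                        lb = rq(1, 4), ub = rq(1, 4))
  toy
}
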