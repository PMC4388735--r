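# The optimal-space container: fixed part + per-module vertex lists + rays
# + linealities, with whole-network vertices available lazily as the
# product over modules.

#' Characterize the optimal solution space of a model
#'
#' Runs the full pipeline: FBA, exact FVA, flux-module detection, per-module
#' vertex enumeration on the module submodels, and ray/lineality
#' enumeration on the whole network. Whole-network vertices are the product
#' of the per-module vertex choices and are reconstructed lazily via
#' [space_vertex()]; the total count is the product of the per-module
#' counts.
#'
#' @param model a `stoich_model` (split or non-split).
#' @param z_star optional known optimum; computed by [solve_fba()] when
#'   `NULL`.
#' @return An `optimal_space`: list with `model`, `decomposition`,
#'   `module_vertices` (per module, values on the module's reactions),
#'   `module_counts`, `subnetworks` (modules with >= 2 vertex
#'   alternatives), `rays`, `linealities`, and `counts` (list `s` = vertex
#'   product, `vertex_sum`, `t` = rays, `u` = linealities).
#' @examples
#' sp <- split_reversible(build_toy_model())
#' os <- optimal_space(sp$model)
#' os$counts$s  # 12
#' @export
optimal_space <- function(model, z_star = NULL) {
  fs_validate(model)
  if (is.null(z_star)) {
    sol <- solve_fba(model)
    if (sol$status != "optimal") stop("FBA not optimal: status ", sol$status)
    z_star <- sol$objective_value
  } else if (!inherits(z_star, "rq")) z_star <- rq_from_decimal(z_star)
  variable <- find_variable_reactions(model, z_star)
  dec <- decompose_modules(model, variable, z_star)
  module_vertices <- list()
  module_counts <- integer(0)
  for (k in seq_along(dec$modules)) {
    m <- dec$modules[[k]]
    sub <- build_module_model(model, m)
    vs <- enumerate_vertices(sub)
    mv <- lapply(vs$vertices, function(v) {
      ix <- match(m$reactions, v$rxns)
      flux_vector(v$values[ix], m$reactions)
    })
    # deduplicate after projecting out the pseudo-reactions
    key <- vapply(mv, function(v) vertex_key(v$values), character(1))
    mv <- mv[!duplicated(key)]
    mv <- mv[order(vapply(mv, function(v) vertex_key(v$values), character(1)))]
    module_vertices[[k]] <- mv
    module_counts[k] <- length(mv)
  }
  rays <- enumerate_rays(model, z_star)
  lins <- lineality_space(model)
  s <- if (length(module_counts)) prod(pmax(module_counts, 1L)) else 1
  structure(list(
    model = model, decomposition = dec,
    module_vertices = module_vertices, module_counts = module_counts,
    subnetworks = which(module_counts >= 2L),
    rays = rays, linealities = lins,
    counts = list(s = s,
                  vertex_sum = if (length(module_counts)) sum(module_counts) else 1,
                  t = length(rays), u = length(lins))),
    class = "optimal_space")
}

#' @export
print.optimal_space <- function(x, ...) {
  cat("optimal solution space\n")
  cat(sprintf("  objective: %s (%.6g)\n",
              format(x$decomposition$objective_value),
              as.double(x$decomposition$objective_value)))
  cat(sprintf("  vertices: %s (product over modules; sum %d)\n",
              format(x$counts$s, big.mark = ","), x$counts$vertex_sum))
  cat(sprintf("  rays: %d, linealities: %d\n", x$counts$t, x$counts$u))
  cat(sprintf("  modules: %d (%d subnetworks with alternatives: counts %s)\n",
              length(x$module_counts), length(x$subnetworks),
              paste(x$module_counts, collapse = " x ")))
  invisible(x)
}

#' Vertex counting by module combinatorics
#'
#' The total number of vertices of the optimal solution space is the
#' product of the per-module vertex counts, while the enumeration work is
#' only their sum — the source of the combinatorial explosion of FBA
#' optima.
#'
#' @param x an `optimal_space`, or a bare numeric vector of per-module
#'   vertex counts.
#' @return list with `product` and `sum`.
#' @examples
#' count_vertices(c(6, 3, 5184, 3, 2, 54, 2, 2))$product  # 120932352
#' @export
count_vertices <- function(x) {
  counts <- if (inherits(x, "optimal_space")) pmax(x$module_counts, 1L) else as.numeric(x)
  if (length(counts) == 0) counts <- 1
  list(product = prod(counts), sum = sum(counts))
}

#' Reconstruct one whole-network vertex from per-module choices
#'
#' Merges the fixed part with the selected vertex of each module. The
#' result is an exact optimal flux of the full model.
#'
#' @param space an `optimal_space`.
#' @param choice integer vector, one vertex index per module (modules with
#'   a single vertex take index 1).
#' @return A [flux_vector()] on the model's reactions.
#' @export
reconstruct_vertex <- function(space, choice) {
  nm <- length(space$module_vertices)
  stopifnot(length(choice) == nm)
  rxns <- fs_rxn_ids(space$model)
  vals <- rq(numeric(length(rxns)))
  fx <- space$decomposition$fixed_flux
  for (i in seq_along(fx$rxns)) vals[match(fx$rxns[i], rxns)] <- fx$values[i]
  for (k in seq_len(nm)) {
    idx <- choice[k]
    mv <- space$module_vertices[[k]]
    if (idx < 1 || idx > length(mv)) {
      stop("invalid vertex index ", idx, " for module ", k,
           " (", length(mv), " vertices)")
    }
    v <- mv[[idx]]
    for (i in seq_along(v$rxns)) vals[match(v$rxns[i], rxns)] <- v$values[i]
  }
  flux_vector(vals, rxns)
}

#' Lazy indexing of the vertex product
#'
#' Maps a linear index `i` in `1..count_vertices(space)$product` to the
#' corresponding per-module choice (mixed-radix decoding) and reconstructs
#' that vertex, so the full product is iterable without materializing it.
#'
#' @param space an `optimal_space`.
#' @param i linear vertex index.
#' @return A [flux_vector()].
#' @export
space_vertex <- function(space, i) {
  counts <- pmax(space$module_counts, 1L)
  total <- prod(counts)
  stopifnot(i >= 1, i <= total)
  rem <- i - 1
  choice <- integer(length(counts))
  for (k in seq_along(counts)) {
    choice[k] <- rem %% counts[k] + 1
    rem <- rem %/% counts[k]
  }
  reconstruct_vertex(space, choice)
}

# exact optimality check of a flux vector against the space's model;
# returns TRUE or a character describing the violated constraint
check_optimal_flux <- function(space, j) {
  model <- space$model
  rxns <- fs_rxn_ids(model)
  stopifnot(identical(j$rxns, rxns))
  sm <- stoich_matrix(model)
  v <- j$values; dim(v) <- c(length(v), 1)
  res <- rq_matmul(sm$mat, v)
  bad <- which(res$num != 0)
  if (length(bad)) {
    return(sprintf("steady state violated at species %s (residual %s)",
                   sm$species[bad[1]], format(res[bad[1], 1, drop = TRUE])))
  }
  for (jx in seq_along(rxns)) {
    r <- model$reactions[[jx]]
    if (bound_finite(r$lb) && isTRUE(j$values[jx] < r$lb)) {
      return(sprintf("lower bound violated at %s", r$id))
    }
    if (bound_finite(r$ub) && isTRUE(j$values[jx] > r$ub)) {
      return(sprintf("upper bound violated at %s", r$id))
    }
  }
  cobj <- fs_obj_coeffs(model)
  zv <- rq_dot(cobj, j$values)
  if (!isTRUE(zv == space$decomposition$objective_value)) {
    return(sprintf("objective %s differs from the optimum %s",
                   format(zv), format(space$decomposition$objective_value)))
  }
  TRUE
}

#' Decompose a flux vector in the Minkowski sum of the optimal space
#'
#' Any optimal flux is a convex combination of vertices plus a conical
#' combination of rays plus a linear combination of linealities. For an
#' optimal-feasible `j`, one valid weight assignment is found by exact LP
#' feasibility; a non-optimal `j` is rejected with the violated constraint
#' as certificate.
#'
#' @param space an `optimal_space` (the vertex product is materialized, so
#'   use desk-scale models).
#' @param j a [flux_vector()] on the space's model.
#' @return list with `accepted`; when accepted, rq weight vectors `alpha`
#'   (convex, over vertices in linear index order), `beta` (conical, over
#'   rays) and `gamma` (free, over linealities); otherwise `certificate`.
#' @export
decompose_in_space <- function(space, j) {
  chk <- check_optimal_flux(space, j)
  if (!isTRUE(chk)) return(list(accepted = FALSE, certificate = chk))
  total <- count_vertices(space)$product
  stopifnot(total <= 10000)  # materialization guard
  verts <- lapply(seq_len(total), function(i) space_vertex(space, i))
  nr <- length(space$rays); nl <- length(space$linealities)
  rxns <- fs_rxn_ids(space$model)
  nv <- total + nr + nl
  lp <- rlp_new(c(paste0("alpha", seq_len(total)),
                  if (nr) paste0("beta", seq_len(nr)),
                  if (nl) paste0("gamma", seq_len(nl))))
  if (nl) for (k in seq_len(nl)) lp <- rlp_set_bounds(lp, total + nr + k, -Inf, Inf)
  for (rx in seq_along(rxns)) {
    coef <- list(); idx <- integer(0)
    for (i in seq_len(total)) {
      coef <- c(coef, list(verts[[i]]$values[rx])); idx <- c(idx, i)
    }
    if (nr) for (k in seq_len(nr)) {
      coef <- c(coef, list(space$rays[[k]]$direction$values[rx]))
      idx <- c(idx, total + k)
    }
    if (nl) for (k in seq_len(nl)) {
      coef <- c(coef, list(space$linealities[[k]]$values[rx]))
      idx <- c(idx, total + nr + k)
    }
    lp <- rlp_add_row(lp, idx, do.call(rq_c, coef), "=", j$values[rx])
  }
  lp <- rlp_add_row(lp, seq_len(total), rq(rep(1, total)), "=", rq(1))
  res <- rlp_solve(lp, rq(numeric(nv)), "min")
  if (res$status != "optimal") {
    # cannot happen for a truly optimal-feasible j with a complete space
    return(list(accepted = FALSE,
                certificate = "no valid Minkowski weights found"))
  }
  list(accepted = TRUE,
       alpha = res$x[seq_len(total)],
       beta = if (nr) res$x[total + seq_len(nr)] else rq(numeric(0)),
       gamma = if (nl) res$x[total + nr + seq_len(nl)] else rq(numeric(0)))
}

#' Override the bounds of one reaction
#'
#' Convenience for scenario edits such as adding a second restricting
#' constraint.
#'
#' @param model a `stoich_model`.
#' @param rxn reaction id.
#' @param lb,ub new bounds (`NULL` keeps the current one).
#' @return The modified model.
#' @export
fs_set_bounds <- function(model, rxn, lb = NULL, ub = NULL) {
  if (!rxn %in% fs_rxn_ids(model)) stop("unknown reaction: ", rxn)
  if (!is.null(lb)) model$reactions[[rxn]]$lb <- as_bound(lb)
  if (!is.null(ub)) model$reactions[[rxn]]$ub <- as_bound(ub)
  fs_validate(model)
  model
}
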