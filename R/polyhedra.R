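# Vertex / ray / lineality enumeration at the model level.

# assemble Aeq/beq/bounds for the (optionally objective-fixed) flux polyhedron
model_polyhedron <- function(model, z_star = NULL) {
  sm <- stoich_matrix(model)
  n <- length(sm$rxns)
  Aeq <- sm$mat
  beq <- rq(numeric(rq_nrow(Aeq)))
  if (!is.null(z_star)) {
    cobj <- fs_obj_coeffs(model)
    if (all(cobj$num == 0)) stop("objective fix requested but model has no objective")
    crow <- cobj; dim(crow) <- c(1, n)
    Aeq <- rq_rbind(Aeq, crow)
    if (!inherits(z_star, "rq")) z_star <- rq_from_decimal(z_star)
    beq <- rq_c(beq, z_star)
  }
  lb <- lapply(model$reactions, `[[`, "lb")
  ub <- lapply(model$reactions, `[[`, "ub")
  list(Aeq = Aeq, beq = beq, lb = lb, ub = ub, rxns = sm$rxns)
}

# deterministic ordering key: support indices, then values
vertex_key <- function(v) {
  supp <- which(v$num != 0)
  paste(paste(sprintf("%03d", supp), collapse = ","),
        paste(format(v), collapse = ","), sep = "|")
}

#' Enumerate the vertices of an optimal solution space
#'
#' Computes all extreme points of the flux polyhedron `{N J = 0,
#' lb <= J <= ub}` (with the objective pinned at `z_star` when given) by
#' exact double description on the homogenized system. When the polyhedron
#' has a lineality space (non-split models), vertices are computed modulo
#' it: the returned representatives are orthogonal to every lineality
#' direction, which is the convention under which a non-split model has a
#' finite vertex list at all.
#'
#' @param model a `stoich_model` (whole network or a module submodel).
#' @param z_star optional rq/number: value at which to fix the objective.
#' @return list with `vertices` (list of [flux_vector()], deterministically
#'   ordered by support then values), `rays`, and `linealities` (lists of
#'   [flux_vector()] directions).
#' @examples
#' toy <- build_toy_model()
#' vs <- enumerate_vertices(toy, z_star = 1)
#' length(vs$vertices)  # 4
#' @export
enumerate_vertices <- function(model, z_star = NULL) {
  ph <- model_polyhedron(model, z_star)
  res <- dd_polyhedron(ph$Aeq, ph$beq, ph$lb, ph$ub)
  ord <- order(vapply(res$vertices, vertex_key, character(1)))
  list(
    vertices = lapply(res$vertices[ord], flux_vector, rxns = ph$rxns),
    rays = lapply(res$rays, flux_vector, rxns = ph$rxns),
    linealities = lapply(res$linealities, flux_vector, rxns = ph$rxns))
}

# does a direction have zero net action on every species, boundary included?
ray_is_cycle <- function(model, dirvec) {
  smf <- stoich_matrix(model, boundary = TRUE)
  v <- dirvec; dim(v) <- c(length(v), 1)
  all(rq_matmul(smf$mat, v)$num == 0)
}

# is the support exactly a forward/backward copy of one reaction?
ray_is_split_pair <- function(model, dirvec) {
  supp <- which(dirvec$num != 0)
  if (length(supp) != 2) return(FALSE)
  sm <- stoich_matrix(model, boundary = TRUE)
  a <- sm$mat[, supp[1], drop = TRUE]; b <- sm$mat[, supp[2], drop = TRUE]
  all((a + b)$num == 0)
}

#' Enumerate the extreme rays of the optimal solution space
#'
#' Extreme rays of the recession cone `{N r = 0, c' r = 0, r_i >= 0 where
#' lb_i is finite, r_i <= 0 where ub_i is finite}`, computed modulo the
#' lineality space. Each ray is classified as `"split-pair"` (the futile
#' forward/backward two-cycle of one split reversible reaction), `"cycle"`
#' (zero net action on all species), or `"input-output"`.
#'
#' @param model a `stoich_model`.
#' @param z_star optional objective value; when supplied the ray must keep
#'   the objective constant (`c' r = 0`), which is the optimal-space cone.
#' @return list of rays, each a list with `direction` ([flux_vector()]) and
#'   `kind`.
#' @export
enumerate_rays <- function(model, z_star = NULL) {
  ph <- model_polyhedron(model, if (is.null(z_star)) NULL else z_star)
  n <- length(ph$rxns)
  Aeq <- ph$Aeq
  if (!is.null(z_star)) {
    # recession of the objective-fixed polyhedron: c r = 0 row already in Aeq
    Aeq <- ph$Aeq
  }
  L <- dd_linealities(Aeq, ph$lb, ph$ub)
  if (rq_ncol(L) > 0) {
    Aeq <- rq_rbind(Aeq, t(L))
  }
  ineq <- list()
  for (i in seq_len(n)) {
    if (bound_finite(ph$lb[[i]])) {
      row <- rq(numeric(n)); row[i] <- rq(1)
      ineq[[length(ineq) + 1L]] <- row
    }
    if (bound_finite(ph$ub[[i]])) {
      row <- rq(numeric(n)); row[i] <- rq(-1)
      ineq[[length(ineq) + 1L]] <- row
    }
  }
  if (length(ineq) == 0) return(list())
  Aineq <- t(rq_matrix(do.call(rq_c, ineq), n, length(ineq)))
  rays <- dd_cone_rays(Aineq, Aeq)
  out <- list()
  for (j in seq_len(rq_ncol(rays))) {
    d <- rays[, j, drop = TRUE]
    kind <- if (ray_is_split_pair(model, d)) "split-pair"
            else if (ray_is_cycle(model, d)) "cycle"
            else "input-output"
    out[[length(out) + 1L]] <- list(direction = flux_vector(d, ph$rxns), kind = kind)
  }
  ord <- order(vapply(out, function(r) vertex_key(r$direction$values), character(1)))
  out[ord]
}

#' Basis of the lineality space
#'
#' Linealities are two-sided unbounded directions of the flux polyhedron:
#' nullspace directions of `N` supported entirely on reactions without any
#' finite bound (fully free reversible reactions). They correspond to
#' reversible cycles or reversible boundary-to-boundary pathways and cease
#' to exist after reversible-reaction splitting.
#'
#' @param model a `stoich_model`.
#' @return list of [flux_vector()] directions, canonicalized to primitive
#'   integer vectors with positive leading coordinate; empty for split
#'   (all-irreversible, lower-bounded) models.
#' @export
lineality_space <- function(model) {
  ph <- model_polyhedron(model, NULL)
  L <- dd_linealities(ph$Aeq, ph$lb, ph$ub)
  lapply(seq_len(rq_ncol(L)), function(j) {
    flux_vector(rq_primitive(L[, j, drop = TRUE]), ph$rxns)
  })
}
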