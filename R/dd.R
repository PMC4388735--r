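# Exact double description (Motzkin) enumeration of extreme rays of a
# pointed polyhedral cone. Used for vertex enumeration (via homogenization),
# extreme-ray enumeration of recession cones, and EFM enumeration (extreme
# rays of the split flux cone). Equalities are eliminated by restriction to
# their rational nullspace; the caller must quotient out any lineality
# beforehand (the engine refuses non-pointed cones).

# cone {x in R^n : Aeq x = 0, Aineq x >= 0}; Aeq may be NULL / 0-row.
# Returns rq matrix (n x k) whose columns are the primitive extreme rays.
dd_cone_rays <- function(Aineq, Aeq = NULL) {
  n <- rq_ncol(Aineq)
  if (!is.null(Aeq) && rq_nrow(Aeq) > 0) {
    B <- rq_nullspace(Aeq)
    k <- rq_ncol(B)
    if (k == 0) return(rq_matrix(rq(0), n, 0))
    Ar <- rq_matmul(Aineq, B)
  } else {
    k <- n
    B <- NULL
    Ar <- Aineq
  }
  # drop all-zero inequality rows
  nzrows <- which(apply(Ar$num != 0, 1, any))
  if (length(nzrows) == 0) stop("cone is a full subspace; not pointed")
  Ar <- Ar[nzrows, , drop = FALSE]
  if (rq_ncol(rq_nullspace(Ar)) > 0) {
    stop("cone is not pointed; quotient out the lineality space first")
  }
  rays <- dd_core(Ar, k)
  if (!is.null(B)) {
    out <- rq_matmul(B, rays)
    for (j in seq_len(rq_ncol(out))) out[, j] <- rq_primitive(out[, j, drop = TRUE], keep_sign = TRUE)
    out
  } else rays
}

# core DD on {A y >= 0} with rank(A) = k = dim(y); returns k x nrays rq matrix
dd_core <- function(A, k) {
  m <- rq_nrow(A)
  # initial simplicial subcone: k independent rows
  rr <- rq_rref(t(A))
  rows0 <- rr$pivots            # independent row indices of A
  stopifnot(length(rows0) == k)
  A0 <- A[rows0, , drop = FALSE]
  if (k == 1) A0 <- rq_matrix(A0, 1, 1)
  # rays of {A0 y >= 0} are the columns of A0^{-1}
  eye <- rq_matrix(rq(0), k, k)
  for (i in seq_len(k)) eye[i, i] <- rq(1)
  aug <- rq_rref(rq_cbind(A0, eye))
  stopifnot(aug$rank == k)
  R <- aug$rref[, k + seq_len(k), drop = FALSE]  # k x k, columns are rays
  if (k == 1) R <- rq_matrix(R, 1, 1)
  nrays <- k
  rays <- lapply(seq_len(k), function(j) rq_primitive(R[, j, drop = TRUE], keep_sign = TRUE))

  processed <- rows0
  # tight[r][i] TRUE iff constraint processed[i] is tight at ray r
  tightset <- lapply(rays, function(r) {
    vapply(processed, function(i) {
      rq_dot(A[i, , drop = TRUE], r)$num == 0
    }, logical(1))
  })

  for (i in setdiff(seq_len(m), rows0)) {
    a <- A[i, , drop = TRUE]
    vals <- lapply(rays, function(r) rq_dot(a, r))
    sg <- vapply(vals, function(v) sign(v$num), numeric(1))
    Ppos <- which(sg > 0); Z <- which(sg == 0); Nneg <- which(sg < 0)
    if (length(Nneg) == 0) {
      # constraint redundant for current rays; just record tightness
      processed <- c(processed, i)
      for (r in seq_along(rays)) tightset[[r]] <- c(tightset[[r]], sg[r] == 0)
      next
    }
    new_rays <- list(); new_tight <- list()
    for (p in Ppos) {
      for (q in Nneg) {
        common <- tightset[[p]] & tightset[[q]]
        # adjacency: no third ray whose tight set contains the common set
        adjacent <- TRUE
        for (w in seq_along(rays)) {
          if (w == p || w == q) next
          if (all(tightset[[w]][common])) { adjacent <- FALSE; break }
        }
        if (!adjacent) next
        r2 <- rq_primitive(rays[[p]] * vals[[q]] * rq(-1) + rays[[q]] * vals[[p]], keep_sign = TRUE)
        # exact tight set of the new ray over processed constraints + current
        tt <- vapply(processed, function(ii) {
          rq_dot(A[ii, , drop = TRUE], r2)$num == 0
        }, logical(1))
        new_rays[[length(new_rays) + 1L]] <- r2
        new_tight[[length(new_tight) + 1L]] <- c(tt, TRUE)
      }
    }
    keep <- c(Ppos, Z)
    rays <- c(rays[keep], new_rays)
    tightset <- c(lapply(keep, function(r) c(tightset[[r]], sg[r] == 0)), new_tight)
    processed <- c(processed, i)
    # dedupe (primitive canonical form makes duplicates exact)
    if (length(rays) > 1) {
      key <- vapply(rays, function(r) paste(format(r), collapse = ","), character(1))
      ix <- !duplicated(key)
      rays <- rays[ix]; tightset <- tightset[ix]
    }
  }
  if (length(rays) == 0) return(rq_matrix(rq(0), k, 0))
  out <- rq_matrix(rq(0), k, length(rays))
  for (j in seq_along(rays)) out[, j] <- rays[[j]]
  out
}

# ---- polyhedron-level wrappers --------------------------------------------

# lineality space of {Aeq x = beq, lb <= x <= ub}: nullspace of Aeq with
# zero-forcing on every variable carrying a finite bound.
# lb/ub: lists of bounds (rq or +-Inf). Returns n x u rq matrix.
dd_linealities <- function(Aeq, lb, ub) {
  n <- rq_ncol(Aeq)
  bounded <- which(vapply(seq_len(n), function(i) {
    bound_finite(lb[[i]]) || bound_finite(ub[[i]])
  }, logical(1)))
  rows <- Aeq
  if (length(bounded)) {
    zrows <- rq_matrix(rq(0), length(bounded), n)
    for (k in seq_along(bounded)) zrows[k, bounded[k]] <- rq(1)
    rows <- rq_rbind(Aeq, zrows)
  }
  rq_nullspace(rows)
}

# choose the support-minimal representative of v + span(L): vertices are
# only defined modulo the lineality space, and the support-minimal
# representative is the one under which a vertex is an instance of a
# minimal pathway (adding lineality flux can only cancel coordinates on
# unbounded reactions, so feasibility is preserved). Ties break by the
# deterministic vertex key. Falls back to v for large lineality spaces.
lineality_min_support <- function(v, L) {
  u <- rq_ncol(L)
  if (u == 0) return(v)
  lrows <- which(apply(L$num != 0, 1, any))
  if (u > 3 || length(lrows) > 12) return(v)
  best <- v; best_n <- sum(v$num != 0)
  best_key <- vertex_key(v)
  subsets <- list(integer(0))
  for (sz in seq_len(u)) {
    subsets <- c(subsets, utils::combn(lrows, sz, simplify = FALSE))
  }
  for (S in subsets) {
    if (length(S) == 0) next
    LS <- L[S, , drop = FALSE]
    if (length(S) == 1) LS <- rq_matrix(LS, 1, u)
    vS <- -v[S]
    dim(vS) <- c(length(S), 1)
    sol <- rq_rref(rq_cbind(LS, vS))
    # inconsistent system: a pivot in the rhs column
    if ((u + 1) %in% sol$pivots) next
    gamma <- rq(numeric(u))
    for (ii in seq_along(sol$pivots)) {
      gamma[sol$pivots[ii]] <- sol$rref[ii, u + 1, drop = TRUE]
    }
    gm <- gamma; dim(gm) <- c(u, 1)
    cand <- v + rq_matmul(L, gm)[, 1, drop = TRUE]
    n <- sum(cand$num != 0)
    key <- vertex_key(cand)
    if (n < best_n || (n == best_n && key < best_key)) {
      best <- cand; best_n <- n; best_key <- key
    }
  }
  best
}

# vertices + recession-cone extreme rays of the polyhedron
# {Aeq x = beq, lb <= x <= ub}, computed modulo its lineality space
# (support-minimal canonical representatives).
# Returns list(vertices = list of rq vectors, rays = list of rq vectors,
#              linealities = list of rq vectors)
dd_polyhedron <- function(Aeq, beq, lb, ub) {
  n <- rq_ncol(Aeq)
  L <- dd_linealities(Aeq, lb, ub)
  u <- rq_ncol(L)
  eqs <- list()
  # homogenized equalities [Aeq | -beq]
  bm <- -beq; dim(bm) <- c(length(beq), 1)
  eqs[[1]] <- rq_cbind(Aeq, bm)
  if (u > 0) {
    # orthogonality to each lineality direction (quotient representatives)
    zc <- rq_matrix(rq(0), u, 1)
    eqs[[2]] <- rq_cbind(t(L), zc)
  }
  Aeq_h <- do.call(rq_rbind, eqs)
  ineq <- list()
  for (i in seq_len(n)) {
    if (bound_finite(lb[[i]])) {
      row <- rq(numeric(n + 1)); row[i] <- rq(1); row[n + 1] <- -lb[[i]]
      ineq[[length(ineq) + 1L]] <- row
    }
    if (bound_finite(ub[[i]])) {
      row <- rq(numeric(n + 1)); row[i] <- rq(-1); row[n + 1] <- ub[[i]]
      ineq[[length(ineq) + 1L]] <- row
    }
  }
  lam <- rq(numeric(n + 1)); lam[n + 1] <- rq(1)
  ineq[[length(ineq) + 1L]] <- lam
  Aineq <- rq_matrix(do.call(rq_c, ineq), n + 1, length(ineq))
  Aineq <- t(Aineq)
  rays_h <- dd_cone_rays(Aineq, Aeq_h)
  verts <- list(); rays <- list()
  for (j in seq_len(rq_ncol(rays_h))) {
    r <- rays_h[, j, drop = TRUE]
    lamv <- r[n + 1]
    if (lamv$num > 0) {
      verts[[length(verts) + 1L]] <- lineality_min_support(r[seq_len(n)] / lamv, L)
    } else {
      rays[[length(rays) + 1L]] <- rq_primitive(r[seq_len(n)], keep_sign = TRUE)
    }
  }
  lins <- lapply(seq_len(u), function(j) rq_primitive(L[, j, drop = TRUE]))
  list(vertices = verts, rays = rays, linealities = lins)
}
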