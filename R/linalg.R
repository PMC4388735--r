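# Exact rational linear algebra: reduced row echelon form, rank, nullspace,
# and square solves. Entries are reduced rq rationals; the pivot is the
# candidate with the smallest numerator/denominator footprint, which keeps
# intermediate integers small and is deterministic.

#' Exact linear algebra on rational matrices
#'
#' Reduced row echelon form, rank, right-nullspace basis, and square
#' solves over `rq` rationals. These back the double-description engine,
#' the rank test, and the simplex, and are exported for use in
#' independent cross-checks.
#'
#' @param a an `rq` matrix ([rq_matrix()]).
#' @return `rq_rref()`: list with `rref` (rq matrix), `pivots` (pivot
#'   column indices), `rank`.
#' @export
rq_rref <- function(a) {
  m <- rq_nrow(a); n <- rq_ncol(a)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    # choose pivot: nonzero entry in col at/under `row` with smallest
    # |num|+|den| footprint (keeps growth down, deterministic)
    cand <- which(a$num[row:m, col] != 0) + row - 1L
    if (length(cand) == 0) next
    foot <- abs(a$num[cand, col]) + abs(a$den[cand, col])
    p <- cand[which.min(foot)]
    if (p != row) {  # swap rows
      idx <- seq_len(n)
      tmp_n <- a$num[row, idx]; tmp_d <- a$den[row, idx]
      a$num[row, idx] <- a$num[p, idx]; a$den[row, idx] <- a$den[p, idx]
      a$num[p, idx] <- tmp_n; a$den[p, idx] <- tmp_d
    }
    piv <- a[row, col, drop = TRUE]
    a[row, ] <- a[row, , drop = FALSE] / piv
    for (r in seq_len(m)) {
      if (r == row) next
      f <- a[r, col, drop = TRUE]
      if (f$num != 0) {
        a[r, ] <- a[r, , drop = FALSE] - a[row, , drop = FALSE] * f
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(rref = a, pivots = pivots, rank = length(pivots))
}

#' @rdname rq_rref
#' @return `rq_rank()`: integer rank.
#' @export
rq_rank <- function(a) rq_rref(a)$rank

#' @rdname rq_rref
#' @return `rq_nullspace()`: rq matrix (n x k) whose columns are a primitive
#'   integer basis of the right nullspace.
#' @export
rq_nullspace <- function(a) {
  n <- rq_ncol(a)
  r <- rq_rref(a)
  free <- setdiff(seq_len(n), r$pivots)
  k <- length(free)
  out <- rq_matrix(rq(0), n, max(k, 1))
  if (k == 0) return(rq_matrix(rq(0), n, 0))
  for (j in seq_along(free)) {
    v <- rq_matrix(rq(0), n, 1)
    v[free[j], 1] <- rq(1)
    if (r$rank > 0) {
      for (i in seq_len(r$rank)) {
        v[r$pivots[i], 1] <- -r$rref[i, free[j], drop = TRUE]
      }
    }
    out[, j] <- rq_primitive(v[, 1, drop = TRUE])
  }
  dim(out) <- c(n, k)
  out
}

#' @rdname rq_rref
#' @param b an `rq` vector (for `rq_solve`).
#' @return `rq_solve()`: the exact solution of `A x = b` for square
#'   nonsingular `A`, or `NULL` if singular.
#' @export
rq_solve <- function(a, b) {
  n <- rq_nrow(a)
  stopifnot(rq_ncol(a) == n, length(b) == n)
  bm <- b; dim(bm) <- c(n, 1)
  aug <- rq_cbind(a, bm)
  r <- rq_rref(aug)
  if (!identical(r$pivots, seq_len(n))) return(NULL)
  r$rref[, n + 1L, drop = TRUE]
}
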