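#' Exact rational vectors
#'
#' `rq` objects store vectors (or matrices, via a `dim` attribute) of exact
#' rational numbers as reduced numerator/denominator pairs. All polyhedral
#' computations in the package run on `rq` values so that feasibility,
#' optimality, vertex identity, and rank verdicts are tolerance-free.
#'
#' Numerators and denominators are kept as exact integers inside doubles;
#' every arithmetic result is reduced by the gcd and checked against the
#' 2^53 exact-integer limit. Exceeding the limit raises an error instead of
#' silently losing exactness.
#'
#' @param num integer-valued numerators.
#' @param den integer-valued denominators (recycled; must be nonzero).
#' @return An `rq` vector.
#' @examples
#' rq(1, 3) + rq(1, 6)   # 1/2
#' rq_parse(c("2/3", "-1", "5/10"))
#' @export
rq <- function(num, den = 1) {
  n <- as.numeric(num)
  d <- as.numeric(den)
  if (length(d) != length(n)) {
    if (length(d) == 1L) d <- rep(d, length(n))
    else if (length(n) == 1L) { n <- rep(n, length(d)) }
    else stop("num/den length mismatch")
  }
  rq_norm(n, d)
}

# largest magnitude representable exactly in a double
.RQ_MAX <- 2^53

rq_overflow_check <- function(x) {
  if (any(abs(x) >= .RQ_MAX)) {
    stop("exact rational overflow: intermediate integer exceeded 2^53")
  }
  x
}

rq_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    act <- b > 0
    r <- ifelse(act, a %% b, 0)
    a <- ifelse(act, b, a)
    b <- r
  }
  a
}

# normalize: integer check, den > 0, reduce by gcd
rq_norm <- function(n, d) {
  if (any(d == 0)) stop("zero denominator")
  if (any(n != floor(n)) || any(d != floor(d))) stop("non-integer numerator/denominator")
  rq_overflow_check(n); rq_overflow_check(d)
  s <- sign(d)
  n <- n * s; d <- d * s
  g <- rq_gcd(n, d)
  g[g == 0] <- 1
  n <- n / g
  n[n == 0] <- 0  # normalize -0
  structure(list(num = n, den = d / g), class = "rq")
}

#' @export
length.rq <- function(x) length(x$num)

#' @export
dim.rq <- function(x) attr(x$num, "dim")

#' @export
`dim<-.rq` <- function(x, value) {
  dim(x$num) <- value
  dim(x$den) <- value
  x
}

#' @export
`[.rq` <- function(x, i, j, ..., drop = TRUE) {
  if (missing(j) && is.null(dim(x))) {
    structure(list(num = x$num[i], den = x$den[i]), class = "rq")
  } else {
    n <- x$num; d <- x$den
    structure(list(num = n[i, j, drop = drop], den = d[i, j, drop = drop]),
              class = "rq")
  }
}

#' @export
`[<-.rq` <- function(x, i, j, ..., value) {
  stopifnot(inherits(value, "rq"))
  if (missing(j) && is.null(dim(x))) {
    x$num[i] <- value$num; x$den[i] <- value$den
  } else {
    x$num[i, j] <- value$num; x$den[i, j] <- value$den
  }
  x
}

#' @export
Ops.rq <- function(e1, e2) {
  if (missing(e2)) {  # unary
    if (.Generic == "-") return(rq_norm(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unsupported unary op for rq: ", .Generic)
  }
  if (!inherits(e1, "rq")) e1 <- rq(e1)
  if (!inherits(e2, "rq")) e2 <- rq(e2)
  n1 <- e1$num; d1 <- e1$den; n2 <- e2$num; d2 <- e2$den
  switch(.Generic,
    "+" = rq_norm(rq_overflow_check(n1 * d2) + rq_overflow_check(n2 * d1),
                  rq_overflow_check(d1 * d2)),
    "-" = rq_norm(rq_overflow_check(n1 * d2) - rq_overflow_check(n2 * d1),
                  rq_overflow_check(d1 * d2)),
    "*" = rq_norm(rq_overflow_check(n1 * n2), rq_overflow_check(d1 * d2)),
    "/" = {
      if (any(n2 == 0)) stop("rational division by zero")
      rq_norm(rq_overflow_check(n1 * d2), rq_overflow_check(d1 * n2))
    },
    "==" = rq_overflow_check(n1 * d2) == rq_overflow_check(n2 * d1),
    "!=" = rq_overflow_check(n1 * d2) != rq_overflow_check(n2 * d1),
    "<"  = rq_overflow_check(n1 * d2) <  rq_overflow_check(n2 * d1),
    "<=" = rq_overflow_check(n1 * d2) <= rq_overflow_check(n2 * d1),
    ">"  = rq_overflow_check(n1 * d2) >  rq_overflow_check(n2 * d1),
    ">=" = rq_overflow_check(n1 * d2) >= rq_overflow_check(n2 * d1),
    stop("unsupported op for rq: ", .Generic)
  )
}

#' @export
abs.rq <- function(x) rq_norm(abs(x$num), x$den)

#' @export
sum.rq <- function(..., na.rm = FALSE) {
  xs <- list(...)
  acc <- rq(0)
  for (x in xs) {
    stopifnot(inherits(x, "rq"))
    n <- length(x)
    if (n == 0) next
    for (i in seq_len(n)) acc <- acc + x[i]
  }
  acc
}

#' @export
rep.rq <- function(x, times, ...) {
  structure(list(num = rep(x$num, times, ...), den = rep(x$den, times, ...)),
            class = "rq")
}

#' Concatenate rq vectors
#' @param ... rq vectors (or numerics coercible to rq).
#' @return An `rq` vector.
#' @export
rq_c <- function(...) {
  xs <- lapply(list(...), function(x) if (inherits(x, "rq")) x else rq(x))
  structure(list(num = unname(unlist(lapply(xs, function(x) as.vector(x$num)))),
                 den = unname(unlist(lapply(xs, function(x) as.vector(x$den))))),
            class = "rq")
}

#' @export
format.rq <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num),
         sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
print.rq <- function(x, ...) {
  if (!is.null(dim(x))) {
    m <- array(format.rq(x), dim = dim(x))
    print(m, quote = FALSE)
  } else {
    print(format(x), quote = FALSE)
  }
  invisible(x)
}

#' @export
as.character.rq <- function(x, ...) as.vector(format(x))

#' @export
as.double.rq <- function(x, ...) {
  r <- x$num / x$den
  attributes(r) <- attributes(x$num)
  r
}

#' Parse rationals from strings
#'
#' Accepts `"p/q"`, plain integers, and (exact) decimal strings such as
#' `"0.5"`; `"inf"`/`"-inf"` are not rationals and are rejected.
#'
#' @param s character vector.
#' @return An `rq` vector.
#' @export
rq_parse <- function(s) {
  s <- trimws(as.character(s))
  n <- numeric(length(s)); d <- numeric(length(s))
  for (i in seq_along(s)) {
    si <- s[i]
    if (grepl("/", si, fixed = TRUE)) {
      parts <- strsplit(si, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("cannot parse rational: ", si)
      n[i] <- as.numeric(parts[1]); d[i] <- as.numeric(parts[2])
    } else if (grepl("^[+-]?[0-9]+$", si)) {
      n[i] <- as.numeric(si); d[i] <- 1
    } else if (grepl("^[+-]?[0-9]*\\.[0-9]+$", si)) {
      k <- nchar(sub("^[^.]*\\.", "", si))
      n[i] <- as.numeric(sub(".", "", si, fixed = TRUE)); d[i] <- 10^k
    } else {
      stop("cannot parse rational: ", si)
    }
  }
  rq_norm(n, d)
}

#' Convert doubles to exact rationals via their shortest decimal form
#'
#' Model files frequently carry decimal data (bounds such as 12.77). The
#' shortest decimal representation that round-trips the double is taken as
#' the intended exact value and converted to `p/10^k`.
#'
#' @param x numeric vector (finite).
#' @return An `rq` vector.
#' @export
rq_from_decimal <- function(x) {
  stopifnot(all(is.finite(x)))
  rq_parse(vapply(x, function(v) format(v, digits = 15, scientific = FALSE),
                  character(1)))
}

# ---- rq matrices -----------------------------------------------------------

#' Build an rq matrix
#' @param x rq vector (or numeric) of entries, column-major.
#' @param nrow,ncol dimensions.
#' @return An `rq` matrix (an rq with a dim attribute).
#' @export
rq_matrix <- function(x, nrow, ncol) {
  if (!inherits(x, "rq")) x <- rq(x)
  if (length(x) == 1L && nrow * ncol != 1L) x <- rep(x, nrow * ncol)
  stopifnot(length(x) == nrow * ncol)
  dim(x) <- c(nrow, ncol)
  x
}

#' @export
t.rq <- function(x) {
  structure(list(num = t(x$num), den = t(x$den)), class = "rq")
}

rq_nrow <- function(x) dim(x)[1]
rq_ncol <- function(x) dim(x)[2]

#' Exact matrix product of rq matrices
#' @param a,b rq matrices with conforming dimensions.
#' @return An `rq` matrix.
#' @export
rq_matmul <- function(a, b) {
  stopifnot(rq_ncol(a) == rq_nrow(b))
  m <- rq_nrow(a); k <- rq_ncol(a); n <- rq_ncol(b)
  out <- rq_matrix(rq(0), m, n)
  for (j in seq_len(n)) {
    col <- rq_matrix(rq(0), m, 1)
    for (l in seq_len(k)) {
      bl <- b[l, j, drop = TRUE]
      if (bl$num != 0) col <- col + a[, l, drop = FALSE] * bl
    }
    out[, j] <- col
  }
  out
}

#' Bind rq matrices by row/column
#' @param ... rq matrices.
#' @return An `rq` matrix.
#' @export
rq_rbind <- function(...) {
  xs <- list(...)
  structure(list(num = do.call(rbind, lapply(xs, function(x) x$num)),
                 den = do.call(rbind, lapply(xs, function(x) x$den))),
            class = "rq")
}

#' @rdname rq_rbind
#' @export
rq_cbind <- function(...) {
  xs <- list(...)
  structure(list(num = do.call(cbind, lapply(xs, function(x) x$num)),
                 den = do.call(cbind, lapply(xs, function(x) x$den))),
            class = "rq")
}

rq_is_zero <- function(x) x$num == 0

rq_sign <- function(x) sign(x$num)

# dot product of two rq vectors
rq_dot <- function(a, b) {
  stopifnot(length(a) == length(b))
  acc <- rq(0)
  nz <- which(a$num != 0 & b$num != 0)
  for (i in nz) acc <- acc + a[i] * b[i]
  acc
}

# scale a vector to primitive integers: multiply by lcm of dens, divide by gcd
# of nums; sign fixed so the first nonzero entry is positive (unless keep_sign)
rq_primitive <- function(x, keep_sign = FALSE) {
  n <- x$num; d <- x$den
  nz <- which(n != 0)
  if (length(nz) == 0) return(x)
  L <- 1
  for (i in nz) {
    g <- rq_gcd(L, d[i])
    L <- rq_overflow_check(L / g * d[i])
  }
  ints <- rq_overflow_check(n * (L / d))
  G <- 0
  for (i in nz) G <- rq_gcd(G, ints[i])
  ints <- ints / G
  if (!keep_sign && ints[nz[1]] < 0) ints <- -ints
  r <- rq(ints)
  dim(r) <- dim(x)
  r
}
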