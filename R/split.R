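#' Split reversible reactions into forward/backward irreversible pairs
#'
#' Every reversible reaction `R` is replaced by an irreversible forward copy
#' `Rf` (same stoichiometry) and an irreversible backward copy `Rb` (negated
#' stoichiometry). Bounds transfer as `Rf in [0, ub]`, `Rb in [0, -lb]`;
#' the objective coefficient goes to the forward copy and its negation to
#' the backward copy, so the net objective of any flux is preserved.
#' Splitting makes all flux variables nonnegative: the optimal solution
#' space then has no lineality space, and its vertices are exactly the
#' non-decomposable optimal pathways.
#'
#' @param model a `stoich_model`.
#' @return A `split_model`: list with `model` (all-irreversible
#'   `stoich_model`) and `split_map` (named list: original reaction id ->
#'   c(forward id, backward id), backward `NA` for originally irreversible
#'   reactions). Idempotent on an already-irreversible model.
#' @export
split_reversible <- function(model) {
  fs_validate(model)
  rx <- list()
  split_map <- list()
  for (r in model$reactions) {
    if (!r$reversible) {
      rx[[length(rx) + 1L]] <- r
      split_map[[r$id]] <- c(r$id, NA_character_)
    } else {
      fid <- paste0(r$id, "f"); bid <- paste0(r$id, "b")
      fwd <- r
      fwd$id <- fid; fwd$reversible <- FALSE
      fwd$lb <- rq(0)
      bwd <- r
      bwd$id <- bid; bwd$reversible <- FALSE
      bwd$stoich <- -r$stoich
      attr(bwd$stoich, "species") <- attr(r$stoich, "species")
      bwd$lb <- rq(0)
      bwd$ub <- if (bound_finite(r$lb)) -r$lb else Inf
      bwd$obj <- -r$obj
      rx[[length(rx) + 1L]] <- fwd
      rx[[length(rx) + 1L]] <- bwd
      split_map[[r$id]] <- c(fid, bid)
    }
  }
  ids <- vapply(rx, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("splitting produced duplicate reaction ids")
  structure(list(model = fs_model(model$species, rx), split_map = split_map),
            class = "split_model")
}

#' @export
print.split_model <- function(x, ...) {
  n_split <- sum(vapply(x$split_map, function(p) !is.na(p[2]), logical(1)))
  cat(sprintf("split_model: %d reactions (%d split pairs)\n",
              length(x$model$reactions), n_split))
  invisible(x)
}

#' Map a split-model flux back to net fluxes on the original reactions
#'
#' Net flux per original reaction is forward minus backward; steady state is
#' preserved because the backward column is the negated forward column.
#'
#' @param split_flux a [flux_vector()] on the split model's reactions.
#' @param split_map the `split_map` of [split_reversible()].
#' @return A `flux_vector` on the original reactions.
#' @export
unsplit_flux <- function(split_flux, split_map) {
  orig <- names(split_map)
  vals <- rq(numeric(length(orig)))
  for (i in seq_along(orig)) {
    pair <- split_map[[i]]
    f <- match(pair[1], split_flux$rxns)
    if (is.na(f)) stop("reaction ", pair[1], " missing from split flux")
    v <- split_flux$values[f]
    if (!is.na(pair[2])) {
      b <- match(pair[2], split_flux$rxns)
      if (is.na(b)) stop("reaction ", pair[2], " missing from split flux")
      v <- v - split_flux$values[b]
    }
    vals[i] <- v
  }
  flux_vector(vals, orig)
}
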