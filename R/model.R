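#' Stoichiometric model objects
#'
#' A `stoich_model` holds a metabolic network: species (with a boundary flag;
#' boundary species are sources/sinks excluded from steady-state balancing),
#' and reactions with exact-rational stoichiometry, reversibility, flux
#' bounds, objective coefficients, and optional gene-protein-reaction (GPR)
#' rules. All coefficients are `rq` rationals; bounds may be the numeric
#' sentinels `-Inf`/`Inf` for unbounded directions.
#'
#' @param species data.frame with columns `id` (character) and `boundary`
#'   (logical).
#' @param reactions list of reactions from [fs_reaction()].
#' @return A `stoich_model`.
#' @seealso [build_toy_model()], [read_model()], [split_reversible()]
#' @export
fs_model <- function(species, reactions) {
  stopifnot(is.data.frame(species), all(c("id", "boundary") %in% names(species)))
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  m <- structure(list(species = species, reactions = reactions),
                 class = "stoich_model")
  fs_validate(m)
  m
}

#' Construct a reaction
#'
#' @param id reaction identifier.
#' @param stoich named `rq` vector (or named numeric) over species ids;
#'   negative entries are consumed, positive produced.
#' @param reversible logical.
#' @param lb,ub lower/upper flux bound: an `rq` scalar, a number, or
#'   `-Inf`/`Inf`. Defaults: `[0, Inf)` for irreversible, `(-Inf, Inf)` for
#'   reversible reactions.
#' @param obj objective coefficient (rq or number).
#' @param gpr optional GPR rule string, e.g. `"(p1 and p2) or p3"`.
#' @return A `reaction` object.
#' @export
fs_reaction <- function(id, stoich, reversible = FALSE,
                        lb = if (reversible) -Inf else 0, ub = Inf,
                        obj = 0, gpr = NA_character_) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (!inherits(stoich, "rq")) {
    nm <- names(stoich)
    stoich <- rq_from_decimal(as.numeric(stoich))
    attr(stoich, "species") <- nm
  } else if (is.null(attr(stoich, "species"))) {
    stop("rq stoichiometry needs a 'species' attribute naming the species")
  }
  keep <- which(stoich$num != 0)
  sp <- attr(stoich, "species")[keep]
  stoich <- stoich[keep]
  attr(stoich, "species") <- sp
  if (length(keep) == 0) stop("reaction ", id, ": empty stoichiometry")
  if (anyDuplicated(sp)) stop("reaction ", id, ": duplicate species in stoichiometry")
  structure(list(id = id, stoich = stoich, reversible = isTRUE(reversible),
                 lb = as_bound(lb), ub = as_bound(ub),
                 obj = if (inherits(obj, "rq")) obj else rq_from_decimal(obj),
                 gpr = gpr),
            class = "fs_reaction")
}

# bounds: rq scalar when finite, bare +-Inf when not
as_bound <- function(b) {
  if (inherits(b, "rq")) return(b)
  if (is.infinite(b)) return(b)
  rq_from_decimal(b)
}

bound_finite <- function(b) inherits(b, "rq")

# compare bounds, tolerating the Inf sentinels
bound_leq <- function(a, b) {
  if (!bound_finite(a)) return(if (a < 0) TRUE else !bound_finite(b) && b > 0)
  if (!bound_finite(b)) return(b > 0)
  !isTRUE((a > b))
}

#' Validate a stoichiometric model
#'
#' Checks id uniqueness, bound ordering (`lb <= ub`), the irreversibility
#' convention (`lb >= 0` for irreversible reactions), nonempty stoichiometry,
#' and that all referenced species are declared.
#'
#' @param model a `stoich_model`.
#' @return The model, invisibly; errors describe the offending element.
#' @export
fs_validate <- function(model) {
  sp <- model$species
  if (anyDuplicated(sp$id)) stop("duplicate species ids")
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  for (r in model$reactions) {
    miss <- setdiff(attr(r$stoich, "species"), sp$id)
    if (length(miss)) stop("reaction ", r$id, ": unknown species ", paste(miss, collapse = ", "))
    if (!bound_leq(r$lb, r$ub)) stop("reaction ", r$id, ": lower bound exceeds upper bound")
    if (!r$reversible) {
      lbneg <- bound_finite(r$lb) && isTRUE(r$lb < rq(0))
      if (lbneg || (!bound_finite(r$lb))) {
        stop("reaction ", r$id, ": irreversible reaction with negative lower bound")
      }
    }
  }
  invisible(model)
}

#' @export
print.stoich_model <- function(x, ...) {
  nb <- sum(x$species$boundary)
  cat(sprintf("stoich_model: %d species (%d boundary), %d reactions (%d reversible)\n",
              nrow(x$species), nb, length(x$reactions),
              sum(vapply(x$reactions, `[[`, logical(1), "reversible"))))
  invisible(x)
}

#' Reaction ids of a model, in model order
#' @param model a `stoich_model`.
#' @return character vector.
#' @export
fs_rxn_ids <- function(model) names(model$reactions)

fs_obj_coeffs <- function(model) {
  do.call(rq_c, lapply(model$reactions, `[[`, "obj"))
}

#' Stoichiometric matrix of a model
#'
#' Rows are non-boundary (balanced) species, columns are reactions, entries
#' exact rationals.
#'
#' @param model a `stoich_model`.
#' @param boundary if `TRUE`, include boundary-species rows too.
#' @return list with `mat` (rq matrix), `species` (row ids), `rxns` (column ids).
#' @export
stoich_matrix <- function(model, boundary = FALSE) {
  spp <- model$species$id[if (boundary) TRUE else !model$species$boundary]
  rxns <- fs_rxn_ids(model)
  mat <- rq_matrix(rq(0), length(spp), length(rxns))
  for (j in seq_along(rxns)) {
    r <- model$reactions[[j]]
    ids <- attr(r$stoich, "species")
    for (k in seq_along(ids)) {
      i <- match(ids[k], spp)
      if (!is.na(i)) mat[i, j] <- r$stoich[k]
    }
  }
  list(mat = mat, species = spp, rxns = rxns)
}

#' Flux vectors
#'
#' An exact assignment of a rational flux to every reaction of a model.
#'
#' @param values `rq` vector (or numeric, converted exactly from decimals).
#' @param rxns character vector of reaction ids, same length.
#' @return A `flux_vector`.
#' @export
flux_vector <- function(values, rxns) {
  if (!inherits(values, "rq")) values <- rq_from_decimal(as.numeric(values))
  stopifnot(length(values) == length(rxns))
  structure(list(values = values, rxns = as.character(rxns)),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  df <- data.frame(reaction = x$rxns, flux = format(x$values))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.flux_vector <- function(x, ...) {
  data.frame(reaction = x$rxns, flux = format(x$values),
             numeric = as.double(x$values))
}

#' Look up one reaction's flux in a flux vector
#' @param fv a [flux_vector()].
#' @param id reaction id.
#' @return rq scalar.
#' @export
fv_get <- function(fv, id) fv$values[match(id, fv$rxns)]

#' Check steady state of a flux vector
#'
#' Evaluates `N J` exactly over the non-boundary species.
#'
#' @param model a `stoich_model`; `flux` a [flux_vector()] on its reactions.
#' @param flux flux vector.
#' @return `TRUE` iff `N J = 0` exactly.
#' @export
is_steady_state <- function(model, flux) {
  sm <- stoich_matrix(model)
  stopifnot(identical(sm$rxns, flux$rxns))
  v <- flux$values; dim(v) <- c(length(v), 1)
  all(rq_matmul(sm$mat, v)$num == 0)
}

# check bound satisfaction, exactly
fs_within_bounds <- function(model, flux) {
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    v <- flux$values[j]
    if (bound_finite(r$lb) && isTRUE(v < r$lb)) return(FALSE)
    if (bound_finite(r$ub) && isTRUE(v > r$ub)) return(FALSE)
  }
  TRUE
}

# ---- fixtures --------------------------------------------------------------

#' The 18-species / 18-reaction demonstration network
#'
#' A linear pathway from boundary substrate X to boundary product Y with two
#' branched segments and an ATP/ADP cofactor couple. Reactions R2, R3, R4,
#' R13 and R14 are reversible; the input R1 carries the single restricting
#' capacity constraint `J_1 <= 2`; the objective is maximization of the
#' product export flux through R18. Under FBA the optimum is 1, and the
#' optimal solution space exhibits: 4 vertices, 1 lineality and 2 subnetworks
#' without reversible-reaction splitting; 12 vertices, 7 rays and 3
#' subnetworks with splitting; and 13 elementary flux modes of which 12 have
#' optimal yield.
#'
#' @return A `stoich_model`.
#' @export
build_toy_model <- function() {
  spp <- c("X", "A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
           "M", "N", "ATP", "ADP", "Y")
  species <- data.frame(id = spp, boundary = spp %in% c("X", "Y"))
  rx <- list(
    fs_reaction("R1",  c(X = -1, A = 1), ub = 2),
    fs_reaction("R2",  c(A = -1, B = 1), reversible = TRUE),
    fs_reaction("R3",  c(A = -1, C = 1), reversible = TRUE),
    fs_reaction("R4",  c(C = -1, B = 1), reversible = TRUE),
    fs_reaction("R5",  c(B = -1, D = 1)),
    fs_reaction("R6",  c(D = -1, E = 1)),
    fs_reaction("R7",  c(E = -1, F = 1)),
    fs_reaction("R8",  c(F = -1, ADP = -1, H = 1, ATP = 1)),
    fs_reaction("R9",  c(D = -1, G = 1)),
    fs_reaction("R10", c(G = -1, ADP = -1, H = 1, ATP = 1)),
    fs_reaction("R11", c(H = -1, I = 1)),
    fs_reaction("R12", c(I = -1, J = 1)),
    fs_reaction("R13", c(J = -1, K = 1), reversible = TRUE),
    fs_reaction("R14", c(K = -1, L = 1), reversible = TRUE),
    fs_reaction("R15", c(I = -1, L = 1)),
    fs_reaction("R16", c(J = -1, L = -1, M = 1)),
    fs_reaction("R17", c(M = -1, ATP = -2, N = 1, ADP = 2)),
    fs_reaction("R18", c(N = -1, Y = 1), obj = 1)
  )
  fs_model(species, rx)
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a small random connected metabolic network
#'
#' Builds a backbone chain from a boundary substrate X through all internal
#' species to a boundary product Y (guaranteeing a nonzero steady-state
#' route), then adds random internal reactions with integer stoichiometric
#' coefficients in `{-2..2}`. Draws are resampled until every reaction is
#' reachable from the input in the species-reaction graph. Intended as a
#' property-test fixture: the same seed always returns the same model.
#'
#' @param n_species number of internal species (<= ~15 so brute-force oracles
#'   stay feasible).
#' @param n_reactions total reactions, at least `n_species + 1` (the chain).
#' @param seed integer seed.
#' @param p_reversible probability that a non-exchange reaction is reversible.
#' @return A `stoich_model` whose objective is the product export flux.
#' @export
generate_random_model <- function(n_species, n_reactions, seed,
                                  p_reversible = 0.3) {
  stopifnot(n_species >= 1, n_reactions >= n_species + 1)
  with_seed(seed, {
    spp <- paste0("S", seq_len(n_species))
    species <- data.frame(id = c("X", spp, "Y"),
                          boundary = c(TRUE, rep(FALSE, n_species), TRUE))
    chain_sp <- c("X", spp, "Y")
    n_extra <- n_reactions - (n_species + 1)
    for (attempt in 1:50) {
      rx <- list()
      for (i in seq_len(n_species + 1)) {
        st <- c(-1, 1)
        names(st) <- chain_sp[c(i, i + 1)]
        rev <- i > 1 && i <= n_species && stats::runif(1) < p_reversible
        rx[[i]] <- fs_reaction(paste0("R", i), st, reversible = rev,
                               obj = if (i == n_species + 1) 1 else 0)
      }
      for (k in seq_len(n_extra)) {
        # mass-conserving random reactions (equal total stoichiometry on
        # both sides) so that a bounded input implies a bounded optimum
        ns <- sample(seq_len(min(2, n_species - 1)), 1)
        subs <- sample(spp, ns)
        avail <- length(spp) - ns
        sc <- sample(1:2, ns, replace = TRUE)
        total <- sum(sc)
        if (avail == 1 && total > 2) { sc <- rep(1, ns); total <- ns }
        pc_opts <- list(`1` = list(1), `2` = list(2, c(1, 1)),
                        `3` = list(c(1, 2)), `4` = list(c(2, 2)))
        pc <- Filter(function(p) length(p) <= avail, pc_opts[[as.character(total)]])
        pc <- pc[[sample(length(pc), 1)]]
        prods <- sample(setdiff(spp, subs), length(pc))
        st <- c(-sc, pc)
        names(st) <- c(subs, prods)
        rx[[n_species + 1 + k]] <-
          fs_reaction(paste0("R", n_species + 1 + k), st,
                      reversible = stats::runif(1) < p_reversible)
      }
      m <- fs_model(species, rx)
      if (all(reachable_reactions(m, "X"))) return(m)
    }
    stop("could not draw a connected feasible model in 50 attempts")
  })
}

# logical vector: is each reaction reachable from the given source species
# in the directed species-reaction graph (reversible reactions traversable
# both ways)?
reachable_reactions <- function(model, source_species) {
  sp_seen <- source_species
  rx_seen <- rep(FALSE, length(model$reactions))
  repeat {
    grew <- FALSE
    for (j in seq_along(model$reactions)) {
      if (rx_seen[j]) next
      r <- model$reactions[[j]]
      ids <- attr(r$stoich, "species")
      cons <- ids[r$stoich$num < 0]; prod <- ids[r$stoich$num > 0]
      fire_fwd <- all(cons %in% sp_seen)
      fire_bwd <- r$reversible && all(prod %in% sp_seen)
      if (fire_fwd || fire_bwd) {
        rx_seen[j] <- TRUE
        new_sp <- if (fire_fwd) prod else cons
        if (r$reversible) new_sp <- ids
        add <- setdiff(new_sp, sp_seen)
        if (length(add)) { sp_seen <- c(sp_seen, add); grew <- TRUE }
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  rx_seen
}
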