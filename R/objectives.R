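# Secondary objectives over the optimal solution space: pathway length
# P_L (active-reaction count), pathway flux sum P_J (sum of absolute
# fluxes), pathway cost P_C (protein-cost-weighted flux sum), and the
# cost vectors derived from gene-protein-reaction rules.

#' Pathway length of a flux: number of active reactions
#'
#' @param flux a [flux_vector()] (exact zero test), or a bare numeric
#'   vector (then `zero_tol` applies).
#' @param zero_tol threshold below which a numeric flux counts as zero;
#'   ignored for exact flux vectors.
#' @return integer count.
#' @export
pathway_length <- function(flux, zero_tol = 1e-9) {
  if (inherits(flux, "flux_vector")) return(sum(flux$values$num != 0))
  sum(abs(as.numeric(flux)) > zero_tol)
}

#' Pathway flux sum: sum of absolute fluxes
#' @param flux a [flux_vector()].
#' @return rq scalar.
#' @export
pathway_flux_sum <- function(flux) sum(abs(flux$values))

#' Pathway cost: cost-weighted sum of absolute fluxes
#' @param flux a [flux_vector()].
#' @param costs a `cost_vector` from [build_cost_vector()] (or a named rq /
#'   numeric vector covering all reactions of the flux).
#' @return rq scalar.
#' @export
pathway_cost <- function(flux, costs) {
  cv <- if (inherits(costs, "cost_vector")) {
    ix <- match(flux$rxns, costs$rxns)
    if (anyNA(ix)) stop("missing cost entry for reaction(s): ",
                        paste(flux$rxns[is.na(ix)], collapse = ", "))
    costs$values[ix]
  } else {
    if (is.null(names(costs))) stop("costs must be named by reaction")
    ix <- match(flux$rxns, names(costs))
    if (anyNA(ix)) stop("missing cost entry for reaction(s): ",
                        paste(flux$rxns[is.na(ix)], collapse = ", "))
    v <- if (inherits(costs, "rq")) costs else rq_from_decimal(as.numeric(costs))
    v[ix]
  }
  rq_dot(cv, abs(flux$values))
}

# ---- GPR parsing -----------------------------------------------------------

# tokenize + recursive descent for boolean protein rules:
# expr := term ("or" term)* ; term := factor ("and" factor)* ;
# factor := "(" expr ")" | protein-id
parse_gpr <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NULL
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.null(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.null(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.null(t)) stop("GPR parse error: unexpected end of '", s, "'")
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) stop("GPR parse error: missing ')' in '", s, "'")
      advance()
      return(e)
    }
    if (t %in% c(")", "and", "or")) stop("GPR parse error near '", t, "' in '", s, "'")
    advance()
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("GPR parse error: trailing tokens in '", s, "'")
  out
}

gpr_proteins <- function(tree) {
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_proteins)))
}

# evaluate a GPR tree to a protein length: AND = complex = sum of subunit
# lengths; OR = isozymes = min/max/mean per rule
gpr_eval <- function(tree, lengths, rule) {
  if (is.character(tree)) return(lengths[[tree]])
  vals <- lapply(tree$args, gpr_eval, lengths = lengths, rule = rule)
  if (tree$op == "and") {
    acc <- vals[[1]]
    for (k in seq_along(vals)[-1]) acc <- acc + vals[[k]]
    return(acc)
  }
  switch(rule,
    min = { acc <- vals[[1]]
            for (k in seq_along(vals)[-1]) if (isTRUE(vals[[k]] < acc)) acc <- vals[[k]]
            acc },
    max = { acc <- vals[[1]]
            for (k in seq_along(vals)[-1]) if (isTRUE(vals[[k]] > acc)) acc <- vals[[k]]
            acc },
    average = { acc <- vals[[1]]
                for (k in seq_along(vals)[-1]) acc <- acc + vals[[k]]
                acc / rq(length(vals)) },
    stop("unknown OR rule: ", rule))
}

#' Build a per-reaction protein cost vector from GPR rules
#'
#' The cost of a reaction is the length of the protein (complex) its GPR
#' evaluates to — an AND rule sums subunit lengths, an OR rule takes the
#' minimum, maximum, or average over isozymes — scaled by the mean length
#' over all proteins annotated in the model, so `c_j < 1` marks a
#' cheaper-than-average enzyme. Reactions without a GPR get `c_j = 1`;
#' rule `"equal"` sets every cost to 1, under which pathway cost reduces
#' to the plain sum of absolute fluxes.
#'
#' @param model a `stoich_model` with GPR strings on (some) reactions.
#' @param protein_lengths named numeric/rq vector or two-column data.frame
#'   (`protein`, `length`, in residues).
#' @param rule `"min"`, `"max"`, `"average"`, or `"equal"`.
#' @return A `cost_vector`: list with `rxns`, `values` (rq), `rule`,
#'   `scale` (the mean annotated protein length used for normalization).
#' @examples
#' m <- build_toy_model()
#' m$reactions$R8$gpr <- "p1 and p2"
#' cv <- build_cost_vector(m, c(p1 = 100, p2 = 300), rule = "min")
#' format(cv$values[match("R8", cv$rxns)])  # "2" = (100+300)/200
#' @export
build_cost_vector <- function(model, protein_lengths = NULL,
                              rule = c("min", "max", "average", "equal")) {
  rule <- match.arg(rule)
  rxns <- fs_rxn_ids(model)
  if (rule == "equal") {
    return(structure(list(rxns = rxns, values = rq(rep(1, length(rxns))),
                          rule = rule, scale = rq(1)), class = "cost_vector"))
  }
  if (is.data.frame(protein_lengths)) {
    protein_lengths <- stats::setNames(protein_lengths[[2]], protein_lengths[[1]])
  }
  lens <- lapply(protein_lengths, function(x) if (inherits(x, "rq")) x else rq_from_decimal(x))
  names(lens) <- names(protein_lengths)
  gprs <- lapply(model$reactions, `[[`, "gpr")
  trees <- lapply(gprs, function(g) if (is.na(g)) NULL else parse_gpr(g))
  used <- unique(unlist(lapply(trees[!vapply(trees, is.null, logical(1))],
                               gpr_proteins)))
  unknown <- setdiff(used, names(lens))
  if (length(unknown)) stop("unknown protein id(s) in GPR: ",
                            paste(unknown, collapse = ", "))
  if (length(used) == 0) {
    return(structure(list(rxns = rxns, values = rq(rep(1, length(rxns))),
                          rule = rule, scale = rq(1)), class = "cost_vector"))
  }
  tot <- rq(0)
  for (p in used) tot <- tot + lens[[p]]
  avg <- tot / rq(length(used))
  vals <- rq(rep(1, length(rxns)))
  for (j in seq_along(rxns)) {
    if (!is.null(trees[[j]])) vals[j] <- gpr_eval(trees[[j]], lens, rule) / avg
  }
  structure(list(rxns = rxns, values = vals, rule = rule, scale = avg),
            class = "cost_vector")
}

#' @export
print.cost_vector <- function(x, ...) {
  cat(sprintf("cost_vector (rule %s, scale %s): %d reactions, %d non-unit\n",
              x$rule, format(x$scale), length(x$rxns), sum(!(x$values == rq(1)))))
  invisible(x)
}

# ---- secondary optimization ------------------------------------------------

# exact activity bounds for the pathway-length MILP: FVA max at the fixed
# optimum where finite; otherwise an exact cap derived from the vertex hull
# (futile circulation can make FVA unbounded even on split models)
milp_activity_bounds <- function(model, z_star, space) {
  fv <- fva(model, z_star)
  rxns <- fv$rxns
  hull_max <- hull_min <- NULL
  need_hull <- any(!vapply(fv$max, bound_finite, logical(1))) ||
    any(vapply(seq_along(rxns), function(k) {
      !bound_finite(fv$min[[k]]) && bound_finite(model$reactions[[k]]$lb)
    }, logical(1))) ||
    any(!vapply(fv$min, bound_finite, logical(1)))
  if (need_hull) {
    if (is.null(space)) space <- optimal_space(model, z_star)
    total <- count_vertices(space)$product
    hull_max <- rq(numeric(length(rxns)))
    hull_min <- rq(numeric(length(rxns)))
    for (i in seq_len(total)) {
      v <- space_vertex(space, i)
      ix <- match(rxns, v$rxns)
      vv <- v$values[ix]
      for (k in seq_along(rxns)) {
        if (isTRUE(vv[k] > hull_max[k])) hull_max[k] <- vv[k]
        if (isTRUE(vv[k] < hull_min[k])) hull_min[k] <- vv[k]
      }
    }
  }
  # flux scale: the largest finite bound magnitude and the optimum itself
  scale <- rq(1)
  for (r in model$reactions) {
    for (bb in list(r$lb, r$ub)) {
      if (bound_finite(bb) && isTRUE(abs(bb) > scale)) scale <- abs(bb)
    }
  }
  za <- abs(if (inherits(z_star, "rq")) z_star else rq_from_decimal(z_star))
  if (isTRUE(za > scale)) scale <- za
  spec <- list()
  for (k in seq_along(rxns)) {
    Mp <- if (bound_finite(fv$max[[k]])) fv$max[[k]] else
      hull_max[k] * rq(2) + scale
    entry <- list(rxn = rxns[k], M_plus = if (Mp$num > 0) Mp else NULL)
    lbk <- model$reactions[[k]]$lb
    can_neg <- !bound_finite(lbk) || lbk$num < 0
    if (can_neg) {
      Mm <- if (bound_finite(fv$min[[k]])) fv$min[[k]] else
        hull_min[k] * rq(2) - scale
      entry$M_minus <- if (Mm$num < 0) Mm else NULL
    }
    # reactions that cannot carry positive flux need no upper indicator
    if (is.null(entry$M_plus) && is.null(entry$M_minus)) entry <- NULL
    spec[[length(spec) + 1L]] <- entry
  }
  list(spec = Filter(Negate(is.null), spec), space = space)
}

#' Minimize pathway length over the optimal solution space
#'
#' Solves the exact mixed-integer program minimizing the number of active
#' reactions with the primary objective fixed at `z_star`. Activity
#' big-Ms come from exact FVA; reactions whose FVA interval is unbounded
#' (futile-cycle directions) are capped from the enumerated vertex hull
#' with circulation headroom. On split models the minimum over the
#' polyhedron provably equals the minimum over the vertex hull, and the
#' count of enumerated vertices attaining it is reported.
#'
#' @param model a `stoich_model` (split model recommended).
#' @param z_star the primary FBA optimum.
#' @param space optional precomputed [optimal_space()] (avoids
#'   re-enumeration; required implicitly when FVA is unbounded).
#' @return A `secondary_result`: list with `objective = "P_L"`,
#'   `optimal_value`, `witness_flux`, `n_optimal_vertices` (count of
#'   vertices attaining the minimum; `NA` when the space was not
#'   enumerated).
#' @export
minimize_pathway_length <- function(model, z_star, space = NULL) {
  if (!inherits(z_star, "rq")) z_star <- rq_from_decimal(z_star)
  ab <- milp_activity_bounds(model, z_star, space)
  space <- ab$space
  res <- solve_milp(model, ab$spec, fix_objective_at = z_star)
  if (res$status != "optimal") stop("pathway-length MILP ", res$status,
                                    " at the supplied optimum")
  # indicators cover every reaction that can run, so the MILP value is the
  # full active-reaction count of the witness
  pl <- pathway_length(res$flux)
  stopifnot(pl == res$optimal_value)
  n_opt <- NA_integer_
  if (!is.null(space)) {
    total <- count_vertices(space)$product
    pls <- vapply(seq_len(total), function(i) pathway_length(space_vertex(space, i)),
                  integer(1))
    n_opt <- sum(pls == pl)
  }
  structure(list(objective = "P_L", optimal_value = pl,
                 witness_flux = res$flux, n_optimal_vertices = n_opt),
            class = "secondary_result")
}

#' Minimize a linear secondary objective (flux sum or protein cost)
#'
#' On a split model all fluxes are nonnegative, so the sum of (cost-
#' weighted) absolute fluxes is a plain linear program over the optimal
#' space. The count of enumerated vertices attaining the minimum is
#' reported when a space is supplied.
#'
#' @param model a split (all-irreversible, lower-bounded) `stoich_model`.
#' @param z_star the primary FBA optimum.
#' @param costs a `cost_vector` (rule `"equal"` minimizes the plain flux
#'   sum P_J).
#' @param space optional precomputed [optimal_space()].
#' @return A `secondary_result` with `objective` `"P_C"` (or `"P_J"` for
#'   equal costs), `optimal_value` (rq), `witness_flux`,
#'   `n_optimal_vertices`.
#' @export
minimize_linear_secondary <- function(model, z_star, costs, space = NULL) {
  if (!inherits(z_star, "rq")) z_star <- rq_from_decimal(z_star)
  bad <- Filter(function(r) !bound_finite(r$lb) || r$lb$num < 0, model$reactions)
  if (length(bad)) stop("linear secondary objectives need a split model; ",
                        "reaction(s) with negative range: ",
                        paste(vapply(bad, `[[`, character(1), "id"), collapse = ", "))
  rxns <- fs_rxn_ids(model)
  cv <- if (inherits(costs, "cost_vector")) {
    ix <- match(rxns, costs$rxns)
    if (anyNA(ix)) stop("cost vector does not cover all reactions")
    costs$values[ix]
  } else stop("costs must be a cost_vector")
  lp <- model_rlp(model)
  cobj <- fs_obj_coeffs(model)
  nz <- which(cobj$num != 0)
  lp <- rlp_add_row(lp, nz, cobj[nz], "=", z_star)
  res <- rlp_solve(lp, cv, "min")
  if (res$status != "optimal") stop("secondary LP ", res$status)
  witness <- flux_vector(res$x, rxns)
  n_opt <- NA_integer_
  if (!is.null(space)) {
    total <- count_vertices(space)$product
    n_opt <- 0L
    for (i in seq_len(total)) {
      pc <- pathway_cost(space_vertex(space, i), costs)
      if (isTRUE(pc == res$obj)) n_opt <- n_opt + 1L
    }
  }
  structure(list(objective = if (costs$rule == "equal") "P_J" else "P_C",
                 optimal_value = res$obj, witness_flux = witness,
                 n_optimal_vertices = n_opt),
            class = "secondary_result")
}

#' @export
print.secondary_result <- function(x, ...) {
  cat(sprintf("secondary optimization %s: minimum %s", x$objective,
              format(x$optimal_value)))
  if (!is.na(x$n_optimal_vertices)) {
    cat(sprintf(" (attained by %d enumerated vertex/vertices)", x$n_optimal_vertices))
  }
  cat("\n")
  invisible(x)
}

#' Per-vertex secondary-objective statistics
#'
#' Iterates the (lazily indexed) vertices of an optimal space and
#' tabulates pathway length, flux sum, and cost under the supplied cost
#' vectors, together with a plain histogram of each column and a
#' per-module cost decomposition (the cost range over each module's
#' alternatives), which localizes multimodal cost distributions to
#' individual subnetworks.
#'
#' @param space an `optimal_space`.
#' @param costs a `cost_vector` or named list of them (a `P_C_<rule>`
#'   column per entry).
#' @param max_vertices iterate at most this many vertices; beyond it, a
#'   seeded uniform sample of the product is taken.
#' @param seed RNG seed for the sample.
#' @return list with `table` (data.frame: vertex, choice, P_L, P_J, cost
#'   columns), `histograms` (named list of `table`s), and
#'   `module_cost_ranges` (per module x cost rule: min/max alternative
#'   cost).
#' @export
vertex_statistics <- function(space, costs = NULL, max_vertices = 10000,
                              seed = 1) {
  total <- count_vertices(space)$product
  idx <- if (total <= max_vertices) seq_len(total) else
    with_seed(seed, sort(sample.int(total, max_vertices)))
  if (inherits(costs, "cost_vector")) costs <- list(costs)
  cost_names <- if (length(costs)) {
    vapply(seq_along(costs), function(k) {
      nm <- names(costs)[k]
      if (!is.null(nm) && nzchar(nm)) nm else paste0("P_C_", costs[[k]]$rule)
    }, character(1))
  } else character(0)
  rows <- lapply(idx, function(i) {
    v <- space_vertex(space, i)
    row <- data.frame(vertex = i,
                      P_L = pathway_length(v),
                      P_J = as.double(pathway_flux_sum(v)))
    for (k in seq_along(costs)) {
      row[[cost_names[k]]] <- as.double(pathway_cost(v, costs[[k]]))
    }
    row
  })
  tab <- do.call(rbind, rows)
  hist_cols <- c("P_L", "P_J", cost_names)
  histograms <- lapply(hist_cols, function(cn) table(tab[[cn]]))
  names(histograms) <- hist_cols
  module_cost_ranges <- list()
  for (m in seq_along(space$module_vertices)) {
    mv <- space$module_vertices[[m]]
    for (k in seq_along(costs)) {
      vals <- vapply(mv, function(v) as.double(pathway_cost(v, costs[[k]])),
                     numeric(1))
      module_cost_ranges[[length(module_cost_ranges) + 1L]] <-
        data.frame(module = m, rule = costs[[k]]$rule,
                   min_cost = min(vals), max_cost = max(vals),
                   n_alternatives = length(vals))
    }
  }
  list(table = tab,
       histograms = histograms,
       module_cost_ranges = if (length(module_cost_ranges))
         do.call(rbind, module_cost_ranges) else NULL)
}
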