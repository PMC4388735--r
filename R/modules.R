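# Flux-module detection: decompose the variable part of the optimum into
# subnetworks with fixed net input-output stoichiometry (N_A J_A = d over
# the whole optimal solution space), verified by exact LPs.

#' Reactions with variable flux over the optimum
#'
#' Runs exact FVA with the objective fixed at `z_star` and returns the
#' reactions whose interval has nonzero width (exact comparison, no
#' epsilon). The complement is the fixed network; each fixed reaction
#' carries a unique exact flux.
#'
#' @param model a `stoich_model`.
#' @param z_star the FBA optimum (rq or number).
#' @return Character vector of variable reaction ids, with the full
#'   `fva_result` attached as attribute `"fva"`.
#' @export
find_variable_reactions <- function(model, z_star) {
  fv <- fva(model, z_star)
  ids <- fv$rxns[fva_variable(fv)]
  attr(ids, "fva") <- fv
  ids
}

# connected components of the species-reaction graph restricted to the
# variable reactions (connected through species touched by >= 2 of them)
variable_components <- function(model, variable) {
  touched <- list()
  for (id in variable) {
    r <- model$reactions[[id]]
    for (s in attr(r$stoich, "species")) {
      touched[[s]] <- c(touched[[s]], id)
    }
  }
  hub_species <- names(touched)[vapply(touched, length, integer(1)) >= 2]
  if (length(variable) == 0) return(list())
  edges <- character(0)
  for (s in hub_species) for (id in touched[[s]]) {
    edges <- c(edges, paste0("rxn:", id), paste0("sp:", s))
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(unique(c(paste0("rxn:", variable),
                              if (length(edges)) unique(edges))))
  if (length(edges)) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    mem <- names(comp$membership)[comp$membership == ci]
    rxns <- sub("^rxn:", "", mem[startsWith(mem, "rxn:")])
    if (length(rxns)) out[[length(out) + 1L]] <- sort(rxns)
  }
  out[order(vapply(out, `[`, character(1), 1))]
}

# exact min/max of the net production of species `sp` by the reactions in
# `rxns`, over the optimal space; returns list(min, max) bounds
net_production_range <- function(lp_opt, model, rxns, sp) {
  all_rxns <- fs_rxn_ids(model)
  obj <- rq(numeric(length(all_rxns)))
  for (id in rxns) {
    r <- model$reactions[[id]]
    k <- match(sp, attr(r$stoich, "species"))
    if (!is.na(k)) obj[match(id, all_rxns)] <- obj[match(id, all_rxns)] + r$stoich[k]
  }
  rmin <- rlp_solve(lp_opt, obj, "min")
  rmax <- rlp_solve(lp_opt, obj, "max")
  list(min = if (rmin$status == "unbounded") -Inf else rmin$obj,
       max = if (rmax$status == "unbounded") Inf else rmax$obj)
}

# verify that a reaction set has a constant net interface over the optimum;
# returns list(ok, species, d) with nonzero-entry species only
verify_component <- function(lp_opt, model, rxns) {
  touched <- unique(unlist(lapply(rxns, function(id) {
    attr(model$reactions[[id]]$stoich, "species")
  })))
  touched <- model$species$id[model$species$id %in% touched]  # model order
  sp_out <- character(0); d_out <- list()
  for (s in touched) {
    rng <- net_production_range(lp_opt, model, rxns, s)
    if (!bound_finite(rng$min) || !bound_finite(rng$max) ||
        !isTRUE(rng$min == rng$max)) {
      return(list(ok = FALSE, species = s))
    }
    if (rng$min$num != 0) {
      sp_out <- c(sp_out, s)
      d_out <- c(d_out, list(rng$min))
    }
  }
  list(ok = TRUE, species = sp_out,
       d = if (length(d_out)) do.call(rq_c, d_out) else rq(numeric(0)))
}

#' Decompose the variable reactions into flux modules
#'
#' Partitions the variable reactions into connected components of the
#' species-reaction graph (components joined through species touched by at
#' least two variable reactions) and verifies each component as a flux
#' module: for every species the component touches, its net production by
#' the component's reactions must be constant over the whole optimal space
#' (two exact LPs per species). Components failing verification are merged
#' with the components sharing the offending species and verification
#' repeats to a fixed point.
#'
#' @param model a `stoich_model`.
#' @param variable character vector from [find_variable_reactions()].
#' @param z_star the FBA optimum.
#' @return An `optimum_decomposition`: list with `fixed_flux`
#'   ([flux_vector()] on the non-variable reactions), `modules` (each a
#'   list with `reactions`, `interface` (species ids + rq `d`), `essential`
#'   = any nonzero interface entry, `internal_species`), and
#'   `objective_value`. Interface magnitudes are per the model's flux
#'   scale at `z_star` (recorded in `z_scale`).
#' @export
decompose_modules <- function(model, variable, z_star) {
  if (!inherits(z_star, "rq")) z_star <- rq_from_decimal(z_star)
  cobj <- fs_obj_coeffs(model)
  lp_opt <- model_rlp(model)
  nzc <- which(cobj$num != 0)
  lp_opt <- rlp_add_row(lp_opt, nzc, cobj[nzc], "=", z_star)

  comps <- variable_components(model, variable)
  verified <- list()
  for (iter in seq_len(length(comps) + 1L)) {
    verified <- lapply(comps, function(cc) verify_component(lp_opt, model, cc))
    bad <- which(!vapply(verified, `[[`, logical(1), "ok"))
    if (length(bad) == 0) break
    if (iter > length(comps)) stop("module merge loop failed to converge")
    # merge every component touching the offending species with the first
    # failing component
    s_bad <- verified[[bad[1]]]$species
    touch_bad <- vapply(comps, function(cc) {
      any(vapply(cc, function(id) {
        s_bad %in% attr(model$reactions[[id]]$stoich, "species")
      }, logical(1)))
    }, logical(1))
    if (sum(touch_bad) < 2) stop("module verification failed irreparably at species ", s_bad)
    merged <- sort(unique(unlist(comps[touch_bad])))
    comps <- c(list(merged), comps[!touch_bad])
    comps <- comps[order(vapply(comps, `[`, character(1), 1))]
  }

  all_rxns <- fs_rxn_ids(model)
  fixed_ids <- setdiff(all_rxns, variable)
  fv <- attr(variable, "fva")
  if (is.null(fv)) fv <- fva(model, z_star, fixed_ids)
  fx <- lapply(fixed_ids, function(id) fv$min[[match(id, fv$rxns)]])
  fixed_flux <- flux_vector(do.call(rq_c, c(fx, list(rq(numeric(0))))), fixed_ids)

  modules <- list()
  for (k in seq_along(comps)) {
    vc <- verified[[k]]
    rxns <- comps[[k]]
    touched <- unique(unlist(lapply(rxns, function(id) {
      attr(model$reactions[[id]]$stoich, "species")
    })))
    internal <- Filter(function(s) {
      others <- setdiff(all_rxns, rxns)
      !any(vapply(others, function(id) {
        s %in% attr(model$reactions[[id]]$stoich, "species")
      }, logical(1)))
    }, touched)
    modules[[k]] <- list(
      reactions = rxns,
      interface = list(species = vc$species, d = vc$d),
      essential = length(vc$species) > 0,
      internal_species = unlist(internal) %||% character(0))
  }
  structure(list(fixed_flux = fixed_flux, modules = modules,
                 objective_value = z_star, z_scale = z_star),
            class = "optimum_decomposition")
}

#' @export
print.optimum_decomposition <- function(x, ...) {
  cat(sprintf("optimum decomposition: objective %s, %d fixed reactions, %d modules\n",
              format(x$objective_value), length(x$fixed_flux$rxns),
              length(x$modules)))
  for (k in seq_along(x$modules)) {
    m <- x$modules[[k]]
    cat(sprintf("  module %d (%s): {%s}; interface: %s\n", k,
                if (m$essential) "essential" else "non-essential",
                paste(m$reactions, collapse = ", "),
                if (length(m$interface$species) == 0) "d = 0" else
                  paste(sprintf("%s: %s", m$interface$species,
                                format(m$interface$d)), collapse = ", ")))
  }
  invisible(x)
}

#' Exact interface of a verified module
#'
#' Recomputes the fixed net input-output vector `d` of a module by exact
#' LPs over the optimal space (minimum and maximum net production per
#' species must coincide). Errors if the interface is not constant, which
#' would signal a module-invariant violation.
#'
#' @param model a `stoich_model`.
#' @param module a module (list with `reactions`) or character vector of
#'   reaction ids.
#' @param z_star the FBA optimum.
#' @return list with `species`, `d` (rq, nonzero entries), and `essential`.
#' @export
module_interface <- function(model, module, z_star) {
  rxns <- if (is.list(module)) module$reactions else module
  if (!inherits(z_star, "rq")) z_star <- rq_from_decimal(z_star)
  cobj <- fs_obj_coeffs(model)
  lp_opt <- model_rlp(model)
  nzc <- which(cobj$num != 0)
  lp_opt <- rlp_add_row(lp_opt, nzc, cobj[nzc], "=", z_star)
  vc <- verify_component(lp_opt, model, rxns)
  if (!vc$ok) stop("module interface not constant at species ", vc$species,
                   " (module invariant violation)")
  list(species = vc$species, d = vc$d, essential = length(vc$species) > 0)
}

#' Build the standalone submodel of a flux module
#'
#' The submodel contains exactly the module's reactions and the species
#' they touch. For an essential module (nonzero interface `d`), an input
#' pseudo-reaction supplies the net-consumed species and an output
#' pseudo-reaction removes the net-produced species, both pinned to unit
#' flux, so the submodel's solution space is exactly the module's slice of
#' the parent optimum. A dummy species produced by the input and consumed
#' by the output reaction guarantees that both run.
#'
#' @param model parent `stoich_model`.
#' @param module module object (list with `reactions` and `interface`)
#'   from [decompose_modules()].
#' @return A `stoich_model` with pseudo-reactions `"IN"` and `"OUT"` (for
#'   essential modules) and dummy species `"DUMMY"`.
#' @export
build_module_model <- function(model, module) {
  rxns <- module$reactions
  iface <- module$interface
  touched <- unique(unlist(lapply(rxns, function(id) {
    attr(model$reactions[[id]]$stoich, "species")
  })))
  touched <- model$species$id[model$species$id %in% touched]
  essential <- length(iface$species) > 0
  spdf <- model$species[model$species$id %in% touched, , drop = FALSE]
  rx <- model$reactions[rxns]
  if (essential) {
    spdf <- rbind(spdf, data.frame(id = "DUMMY", boundary = FALSE))
    neg <- which(iface$d$num < 0); pos <- which(iface$d$num > 0)
    in_st <- rq_c(-iface$d[neg], rq(1))
    attr(in_st, "species") <- c(iface$species[neg], "DUMMY")
    out_st <- rq_c(-iface$d[pos], rq(-1))
    attr(out_st, "species") <- c(iface$species[pos], "DUMMY")
    rx <- c(rx, list(fs_reaction("IN", in_st, lb = 1, ub = 1),
                     fs_reaction("OUT", out_st, lb = 1, ub = 1)))
  }
  rownames(spdf) <- NULL
  fs_model(spdf, rx)
}
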