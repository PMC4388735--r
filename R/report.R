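# Pipeline commands and report writers: each cmd_* runs one analysis
# end-to-end from a run configuration and writes deterministic TSV/JSON
# reports (rationals serialized as "p/q" strings; decimals only in the
# human-readable summary).

#' Run configurations
#'
#' A run configuration names the model, the preprocessing (reversible
#' splitting, bound overrides), the secondary objective, and the output
#' directory. Reruns with an identical configuration produce byte-identical
#' outputs. The configuration is serialized alongside every report.
#'
#' @param model path to a model file, or `"toy"` for the built-in fixture.
#' @param format model format for [read_model()].
#' @param split split reversible reactions before analysis?
#' @param bounds named list of bound overrides: reaction id ->
#'   `c(lb, ub)` (strings parsed as rationals, `"inf"`/`"-inf"` allowed,
#'   `NA` keeps the current bound).
#' @param secondary `"P_L"`, `"P_J"`, or `"P_C"`.
#' @param rule cost rule for P_C: `"min"`, `"max"`, `"average"`, `"equal"`.
#' @param protein_lengths path to a two-column TSV (protein id, length in
#'   residues), or `NULL`.
#' @param seed integer seed for any sampling.
#' @param out output directory.
#' @return A `run_config`.
#' @export
run_config <- function(model = "toy", format = "auto", split = TRUE,
                       bounds = list(), secondary = "P_L",
                       rule = "equal", protein_lengths = NULL,
                       seed = 1L, out = ".") {
  structure(list(model = model, format = format, split = isTRUE(split),
                 bounds = bounds, secondary = secondary, rule = rule,
                 protein_lengths = protein_lengths,
                 seed = as.integer(seed), out = out),
            class = "run_config")
}

#' Read a run configuration from a flat key-value file
#'
#' Lines of the form `key = value`; bound overrides as
#' `bound.<rxn> = lb, ub`. Unknown keys are an error.
#'
#' @param path file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- run_config()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("cannot parse config line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (startsWith(key, "bound.")) {
      rxn <- sub("^bound\\.", "", key)
      parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      if (length(parts) != 2) stop("bound override needs 'lb, ub': ", ln)
      cfg$bounds[[rxn]] <- parts
    } else if (key %in% c("model", "format", "secondary", "rule",
                          "protein_lengths", "out")) {
      cfg[[key]] <- val
    } else if (key == "split") {
      cfg$split <- tolower(val) %in% c("true", "yes", "1")
    } else if (key == "seed") {
      cfg$seed <- as.integer(val)
    } else stop("unknown config key: ", key)
  }
  cfg
}

#' Growth-condition presets as bound-override fragments
#'
#' Named bound fragments for standard growth setups, applicable to any
#' model exposing the matching exchange/maintenance reactions (ids are
#' supplied by the caller, never hardcoded): glucose uptake capped at
#' 12.77, ATP maintenance demanded at 8.39, and oxygen uptake unlimited
#' (`"aerobic"`), capped at 18.5 (`"aerobic-restricted"`), or zero
#' (`"anaerobic"`); fluxes in mmol/gDW/h.
#'
#' @param name preset name.
#' @param glucose,oxygen,atpm reaction ids of the glucose uptake, oxygen
#'   uptake, and ATP maintenance reactions.
#' @return Named list of bound overrides for [run_config()].
#' @export
growth_preset <- function(name = c("aerobic", "aerobic-restricted", "anaerobic"),
                          glucose, oxygen, atpm) {
  name <- match.arg(name)
  b <- list()
  b[[glucose]] <- c(NA, "1277/100")
  b[[atpm]] <- c("839/100", "839/100")
  b[[oxygen]] <- switch(name,
    "aerobic" = c(NA, "inf"),
    "aerobic-restricted" = c(NA, "37/2"),
    "anaerobic" = c(NA, "0"))
  b
}

# load + preprocess the model a config names; returns list(model, split_map)
config_model <- function(config) {
  m <- if (identical(config$model, "toy")) build_toy_model()
       else read_model(config$model, config$format)
  for (rxn in names(config$bounds)) {
    if (!rxn %in% fs_rxn_ids(m)) stop("bound override for unknown reaction: ", rxn)
    bo <- config$bounds[[rxn]]
    lb <- if (is.na(bo[1])) NULL else parse_bound(bo[1])
    ub <- if (is.na(bo[2])) NULL else parse_bound(bo[2])
    m <- fs_set_bounds(m, rxn, lb, ub)
  }
  if (config$split) {
    sp <- split_reversible(m)
    list(model = sp$model, split_map = sp$split_map, original = m)
  } else {
    list(model = m, split_map = NULL, original = m)
  }
}

config_json <- function(config) {
  unclass(config)
}

write_flux_table <- function(fluxes, rxns, path, what = "vertex") {
  rows <- vapply(seq_along(fluxes), function(i) {
    v <- fluxes[[i]]
    ix <- match(rxns, v$rxns)
    paste(c(paste0(what, i), format(v$values[ix])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("id", rxns), collapse = "\t"), rows), path)
}

space_report <- function(space) {
  dec <- space$decomposition
  list(
    objective_value = format(dec$objective_value),
    counts = list(vertices_product = space$counts$s,
                  vertices_sum = space$counts$vertex_sum,
                  rays = space$counts$t,
                  linealities = space$counts$u,
                  modules = length(dec$modules),
                  subnetworks = length(space$subnetworks)),
    module_vertex_counts = space$module_counts,
    fixed_flux = stats::setNames(as.list(format(dec$fixed_flux$values)),
                                 dec$fixed_flux$rxns),
    modules = lapply(seq_along(dec$modules), function(k) {
      m <- dec$modules[[k]]
      list(reactions = m$reactions,
           essential = m$essential,
           is_subnetwork = k %in% space$subnetworks,
           n_vertices = space$module_counts[k],
           interface = stats::setNames(as.list(format(m$interface$d)),
                                       m$interface$species))
    }))
}

#' Enumerate and report the optimal solution space
#'
#' Runs FBA, FVA, module detection, and per-module vertex enumeration,
#' and writes `space.json` (counts, modules, interfaces, fixed fluxes),
#' `vertices.tsv` / `rays.tsv` / `linealities.tsv`, `config.json`, and a
#' human summary `summary.txt` to the configured output directory.
#'
#' @param config a [run_config()].
#' @return The `optimal_space`, invisibly; reports on disk.
#' @export
cmd_enumerate <- function(config) {
  cm <- config_model(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  sol <- solve_fba(cm$model)
  if (sol$status != "optimal") stop("FBA stage failed: status ", sol$status)
  space <- optimal_space(cm$model, sol$objective_value)
  rxns <- fs_rxn_ids(cm$model)
  rep <- space_report(space)
  jsonlite::write_json(c(list(config = config_json(config)), rep),
                       file.path(config$out, "space.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  total <- space$counts$s
  if (total <= 10000) {
    verts <- lapply(seq_len(total), function(i) space_vertex(space, i))
    write_flux_table(verts, rxns, file.path(config$out, "vertices.tsv"), "V")
  }
  write_flux_table(lapply(space$rays, `[[`, "direction"), rxns,
                   file.path(config$out, "rays.tsv"), "R")
  write_flux_table(space$linealities, rxns,
                   file.path(config$out, "linealities.tsv"), "L")
  summary_lines <- c(
    "optimal solution space summary",
    sprintf("objective optimum: %s (%.6g)", format(sol$objective_value),
            as.double(sol$objective_value)),
    sprintf("vertices: %s (product of %s); sum %d",
            format(total, big.mark = ","),
            paste(space$module_counts, collapse = " x "),
            space$counts$vertex_sum),
    sprintf("rays: %d", space$counts$t),
    sprintf("linealities: %d", space$counts$u),
    sprintf("modules: %d (%d subnetworks with alternatives)",
            length(space$module_counts), length(space$subnetworks)))
  writeLines(summary_lines, file.path(config$out, "summary.txt"))
  invisible(space)
}

#' Enumerate and report elementary flux modes
#'
#' Writes the EFM table (`efms.tsv`, rows = modes, columns = reactions,
#' rational strings), the optimal-yield subset (`efms_optimal_yield.tsv`),
#' and the vertex-EFM matching report (`efm_report.json`).
#'
#' @param config a [run_config()].
#' @return list with `efms`, `optimal_yield`, `matching`, invisibly.
#' @export
cmd_efm <- function(config) {
  cm <- config_model(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  rxns <- fs_rxn_ids(cm$model)
  efms <- enumerate_efms(cm$model)
  sol <- solve_fba(cm$model)
  if (sol$status != "optimal") stop("FBA stage failed: status ", sol$status)
  oy <- optimal_yield_filter(efms, cm$model, sol$objective_value)
  vs <- enumerate_vertices(cm$model, z_star = sol$objective_value)
  mm <- match_vertices_to_efms(vs$vertices, oy)
  write_flux_table(lapply(efms, `[[`, "flux"), rxns,
                   file.path(config$out, "efms.tsv"), "EFM")
  write_flux_table(lapply(oy, `[[`, "flux"), rxns,
                   file.path(config$out, "efms_optimal_yield.tsv"), "EFM")
  jsonlite::write_json(list(
    config = config_json(config),
    n_efms = length(efms),
    n_optimal_yield = length(oy),
    n_vertices = length(vs$vertices),
    n_efms_with_vertex = mm$n_matched_efms,
    n_efms_without_vertex = length(oy) - mm$n_matched_efms,
    bijection = mm$bijection,
    map = mm$map), file.path(config$out, "efm_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(efms = efms, optimal_yield = oy, matching = mm))
}

#' Optimize a secondary objective and report
#'
#' Fixes the primary optimum, optimizes the configured secondary objective
#' (`P_L` via exact MILP; `P_J`/`P_C` via exact LP on a split model), and
#' writes `secondary.json` (optimal value as a rational string, witness
#' flux, number of optimal vertices) and the per-vertex statistics table
#' `vertex_stats.tsv`.
#'
#' @param config a [run_config()].
#' @return The `secondary_result`, invisibly.
#' @export
cmd_secondary <- function(config) {
  cm <- config_model(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  sol <- solve_fba(cm$model)
  if (sol$status != "optimal") stop("FBA stage failed: status ", sol$status)
  z <- sol$objective_value
  space <- optimal_space(cm$model, z)
  costs <- if (config$secondary == "P_C" && config$rule != "equal") {
    pl <- if (is.null(config$protein_lengths)) NULL else
      utils::read.delim(config$protein_lengths, header = FALSE,
                        col.names = c("protein", "length"))
    build_cost_vector(cm$model, pl, rule = config$rule)
  } else build_cost_vector(cm$model, rule = "equal")
  res <- switch(config$secondary,
    P_L = minimize_pathway_length(cm$model, z, space = space),
    P_J = minimize_linear_secondary(cm$model, z,
                                    build_cost_vector(cm$model, rule = "equal"),
                                    space = space),
    P_C = minimize_linear_secondary(cm$model, z, costs, space = space),
    stop("unknown secondary objective: ", config$secondary))
  stats <- vertex_statistics(space, costs, seed = config$seed)
  utils::write.table(stats$table, file.path(config$out, "vertex_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wd <- as.data.frame(res$witness_flux)
  jsonlite::write_json(list(
    config = config_json(config),
    objective = res$objective,
    optimal_value = format(res$optimal_value),
    optimal_value_numeric = as.double(if (inherits(res$optimal_value, "rq"))
      as.double(res$optimal_value) else res$optimal_value),
    n_optimal_vertices = res$n_optimal_vertices,
    witness = stats::setNames(as.list(wd$flux), wd$reaction)),
    file.path(config$out, "secondary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
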