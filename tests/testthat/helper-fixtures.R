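# Lazily computed, cached fixtures shared across test files (helpers are
# loaded once per test run, so expensive enumerations happen only once).

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, fn) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- fn()
  .fx_cache[[name]]
}

fx_toy <- function() fx("toy", build_toy_model)
fx_toy_split <- function() fx("toy_split", function() split_reversible(fx_toy()))
fx_z <- function() fx("z", function() solve_fba(fx_toy())$objective_value)
fx_space_split <- function() fx("space_split", function()
  optimal_space(fx_toy_split()$model, fx_z()))
fx_space_nonsplit <- function() fx("space_nonsplit", function()
  optimal_space(fx_toy(), fx_z()))
fx_efms <- function() fx("efms", function() enumerate_efms(fx_toy()))
fx_efms_split <- function() fx("efms_split", function()
  enumerate_efms(fx_toy_split()$model))
fx_oy <- function() fx("oy", function()
  optimal_yield_filter(fx_efms(), fx_toy(), fx_z()))
fx_oy_split <- function() fx("oy_split", function()
  optimal_yield_filter(fx_efms_split(), fx_toy_split()$model, fx_z()))
fx_verts_nonsplit <- function() fx("verts_nonsplit", function()
  enumerate_vertices(fx_toy(), z_star = fx_z()))
fx_verts_split <- function() fx("verts_split", function()
  enumerate_vertices(fx_toy_split()$model, z_star = fx_z()))
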