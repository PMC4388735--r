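# Flux-module detection and module submodels.

test_that("the variable set of the non-split fixture is the 12 branch reactions", {
  toy <- fx_toy()
  vr <- find_variable_reactions(toy, fx_z())
  expect_setequal(as.character(vr),
                  c("R2", "R3", "R4", "R6", "R7", "R8", "R9", "R10",
                    "R12", "R13", "R14", "R15"))
  expect_false("R18" %in% vr)  # pinned by the objective
})

test_that("modules partition the variable set and verify their interfaces", {
  toy <- fx_toy()
  vr <- find_variable_reactions(toy, fx_z())
  dec <- decompose_modules(toy, vr, fx_z())
  sets <- lapply(dec$modules, `[[`, "reactions")
  expect_setequal(unlist(sets), as.character(vr))            # cover
  expect_equal(anyDuplicated(unlist(sets)), 0L)              # disjoint
  expect_setequal(vapply(sets, paste, character(1), collapse = ","),
                  c("R10,R6,R7,R8,R9", "R12,R13,R14,R15", "R2,R3,R4"))
  # fixed part carries its unique exact flux
  expect_true(fv_get(dec$fixed_flux, "R1") == rq(2))
  expect_true(fv_get(dec$fixed_flux, "R16") == rq(1))
})

test_that("module interfaces reproduce the known net conversions", {
  toy <- fx_toy()
  mi <- module_interface(toy, c("R6", "R7", "R8", "R9", "R10"), fx_z())
  expect_true(mi$essential)
  d <- stats::setNames(format(mi$d), mi$species)
  # net conversion: 2 D + 2 ADP -> 2 H + 2 ATP per unit objective flux
  expect_equal(d[["D"]], "-2"); expect_equal(d[["ADP"]], "-2")
  expect_equal(d[["H"]], "2"); expect_equal(d[["ATP"]], "2")
  mi2 <- module_interface(toy, c("R2", "R3", "R4"), fx_z())
  expect_equal(stats::setNames(format(mi2$d), mi2$species),
               c(A = "-2", B = "2"))
  # a set with varying net production is rejected as a module
  expect_error(module_interface(toy, c("R6", "R7"), fx_z()),
               "not constant")
})

test_that("a pure reversible two-cycle module is non-essential (d = 0)", {
  m <- fs_model(
    data.frame(id = c("X", "S1", "S2", "Y"),
               boundary = c(TRUE, FALSE, FALSE, TRUE)),
    list(fs_reaction("Rin", c(X = -1, S1 = 1), ub = 1),
         fs_reaction("Rab", c(S1 = -1, S2 = 1), reversible = TRUE),
         fs_reaction("Rba", c(S2 = -1, S1 = 1), reversible = TRUE),
         fs_reaction("Rout", c(S1 = -1, Y = 1), obj = 1)))
  z <- solve_fba(m)$objective_value
  vr <- find_variable_reactions(m, z)
  expect_setequal(as.character(vr), c("Rab", "Rba"))
  dec <- decompose_modules(m, vr, z)
  expect_length(dec$modules, 1)
  expect_false(dec$modules[[1]]$essential)
})

test_that("a unique-optimum model decomposes into zero modules", {
  chain <- fs_model(
    data.frame(id = c("X", "S1", "Y"), boundary = c(TRUE, FALSE, TRUE)),
    list(fs_reaction("Rin", c(X = -1, S1 = 1), ub = 1),
         fs_reaction("Rout", c(S1 = -1, Y = 1), obj = 1)))
  z <- solve_fba(chain)$objective_value
  vr <- find_variable_reactions(chain, z)
  expect_length(vr, 0)
  dec <- decompose_modules(chain, vr, z)
  expect_length(dec$modules, 0)
})

test_that("module submodels enumerate the documented alternatives", {
  sp <- fx_toy_split()
  space <- fx_space_split()
  counts <- stats::setNames(
    space$module_counts,
    vapply(space$decomposition$modules, function(m) paste(sort(m$reactions), collapse = ","),
           character(1)))
  expect_equal(counts[["R10,R6,R7,R8,R9"]], 2L)
  expect_equal(counts[["R12,R13b,R13f,R14b,R14f,R15"]], 3L)
  expect_equal(counts[["R2b,R2f,R3b,R3f,R4b,R4f"]], 2L)
  # within a module, every vertex support is exactly one alternative
  m1 <- space$decomposition$modules[[
    which(vapply(space$decomposition$modules,
                 function(m) "R6" %in% m$reactions, logical(1)))]]
  k1 <- which(vapply(space$decomposition$modules,
                     function(m) "R6" %in% m$reactions, logical(1)))
  supports <- lapply(space$module_vertices[[k1]], function(v)
    sort(v$rxns[v$values$num != 0]))
  expect_setequal(vapply(supports, paste, character(1), collapse = ","),
                  c("R6,R7,R8", "R10,R9"))
  # interface recomputed from any enumerated module vertex matches d
  mod2 <- space$decomposition$modules[[k1]]
  sm <- stoich_matrix(sp$model, boundary = TRUE)
  for (v in space$module_vertices[[k1]]) {
    full <- rq(numeric(length(sm$rxns)))
    for (i in seq_along(v$rxns)) full[match(v$rxns[i], sm$rxns)] <- v$values[i]
    dim(full) <- c(length(full), 1)
    net <- rq_matmul(sm$mat, full)[, 1, drop = TRUE]
    for (si in seq_along(mod2$interface$species)) {
      expect_true(net[match(mod2$interface$species[si], sm$species)] ==
                    mod2$interface$d[si])
    }
  }
})

test_that("build_module_model pins the interface with unit pseudo-fluxes", {
  space <- fx_space_split()
  m <- space$decomposition$modules[[1]]
  sub <- build_module_model(fx_toy_split()$model, m)
  expect_true(all(c("IN", "OUT") %in% names(sub$reactions)))
  expect_true("DUMMY" %in% sub$species$id)
  expect_true(sub$reactions$IN$lb == rq(1) && sub$reactions$IN$ub == rq(1))
  # non-essential module: no exchange pseudo-reactions
  mod0 <- list(reactions = c("Rab", "Rba"),
               interface = list(species = character(0), d = rq(numeric(0))))
  m0 <- fs_model(
    data.frame(id = c("S1", "S2"), boundary = c(FALSE, FALSE)),
    list(fs_reaction("Rab", c(S1 = -1, S2 = 1)),
         fs_reaction("Rba", c(S2 = -1, S1 = 1))))
  sub0 <- build_module_model(m0, mod0)
  expect_false(any(c("IN", "OUT") %in% names(sub0$reactions)))
})

test_that("reconstruction identity: every vertex choice is an exact optimum", {
  space <- fx_space_split()
  total <- count_vertices(space)$product
  expect_equal(total, 12)
  keys <- character(0)
  for (i in seq_len(total)) {
    v <- space_vertex(space, i)
    expect_true(isTRUE(fluxspace:::check_optimal_flux(space, v)))
    keys <- c(keys, paste(format(v$values), collapse = ","))
  }
  expect_equal(anyDuplicated(keys), 0L)  # all distinct
  # and on sampled combinations of a random model's space
  fxr <- random_split_fixture(5)
  rs <- optimal_space(fxr$model, fxr$z)
  tot <- count_vertices(rs)$product
  for (i in seq_len(min(tot, 6))) {
    expect_true(isTRUE(fluxspace:::check_optimal_flux(rs, space_vertex(rs, i))))
  }
})
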