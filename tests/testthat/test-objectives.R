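# Secondary objectives: pathway length, flux sum, protein cost, and the
# MILP/LP minimizers.

test_that("pathway statistics follow their definitions", {
  fvv <- flux_vector(rq(c(1, -2, 0)), c("a", "b", "c"))
  expect_equal(pathway_length(fvv), 1L + 1L)
  expect_true(pathway_flux_sum(fvv) == rq(3))
  expect_true(pathway_cost(fvv, c(a = 2, b = 1, c = 5)) == rq(4))
  expect_true(pathway_cost(fvv, c(a = 1, b = 1, c = 1)) == pathway_flux_sum(fvv))
  zero <- flux_vector(rq(numeric(3)), c("a", "b", "c"))
  expect_equal(pathway_length(zero), 0L)
  expect_true(pathway_cost(zero, c(a = 2, b = 1, c = 5)) == rq(0))
  expect_error(pathway_cost(fvv, c(a = 1)), "missing cost")
  # numeric fluxes use the documented threshold
  expect_equal(pathway_length(c(1e-12, 0.5, -2)), 2L)
  # P_L recount oracle: direct support count on every fixture vertex
  for (i in 1:12) {
    v <- space_vertex(fx_space_split(), i)
    expect_equal(pathway_length(v), sum(as.double(v$values) != 0))
  }
})

test_that("GPR cost rules follow the complex/isozyme semantics", {
  m <- fx_toy()
  m$reactions$R8$gpr <- "p1 and p2"
  m$reactions$R10$gpr <- "p1 or p2"
  lens <- c(p1 = 100, p2 = 300)  # corpus average 200
  cv_and <- build_cost_vector(m, lens, rule = "min")
  expect_true(cv_and$values[match("R8", cv_and$rxns)] == rq(2))    # (100+300)/200
  expect_true(cv_and$values[match("R10", cv_and$rxns)] == rq(1, 2))  # 100/200
  cv_max <- build_cost_vector(m, lens, rule = "max")
  expect_true(cv_max$values[match("R10", cv_max$rxns)] == rq(3, 2))  # 300/200
  cv_avg <- build_cost_vector(m, lens, rule = "average")
  expect_true(cv_avg$values[match("R10", cv_avg$rxns)] == rq(1))     # 200/200
  # reactions without annotation cost 1
  expect_true(cv_and$values[match("R5", cv_and$rxns)] == rq(1))
  # equal rule: all unit costs
  cv_eq <- build_cost_vector(m, rule = "equal")
  expect_true(all(cv_eq$values == rq(1)))
  # unknown protein ids are reported
  m$reactions$R9$gpr <- "p1 and mystery"
  expect_error(build_cost_vector(m, lens, rule = "min"), "mystery")
  # nested rules parse
  tree <- fluxspace:::parse_gpr("(a and (b or c)) or d")
  expect_identical(tree$op, "or")
  expect_error(fluxspace:::parse_gpr("a and (b or"), "parse error")
})

test_that("minimal pathway length is 11, rising to 12 under a second constraint", {
  space <- fx_space_split()
  r1 <- minimize_pathway_length(fx_toy_split()$model, fx_z(), space = space)
  expect_equal(r1$optimal_value, 11L)
  expect_equal(r1$n_optimal_vertices, 1L)
  expect_true(isTRUE(fluxspace:::check_optimal_flux(space, r1$witness_flux)))
  # second restricting constraint: minimum rises (monotonicity) to 12
  toy2 <- fs_set_bounds(fx_toy(), "R15", ub = rq(1, 2))
  sp2 <- split_reversible(toy2)
  z2 <- solve_fba(sp2$model)$objective_value
  r2 <- minimize_pathway_length(sp2$model, z2)
  expect_equal(r2$optimal_value, 12L)
  expect_gte(r2$optimal_value, r1$optimal_value)
})

test_that("without splitting the minimal pathway is not a vertex", {
  r0 <- minimize_pathway_length(fx_toy(), fx_z(), space = fx_space_nonsplit())
  expect_equal(r0$optimal_value, 11L)
  expect_equal(r0$n_optimal_vertices, 0L)
  # it is, however, a convex combination of two vertices: check the witness
  # is optimal-feasible and decomposes with two active vertex weights
  d <- decompose_in_space(fx_space_nonsplit(), r0$witness_flux)
  expect_true(d$accepted)
  expect_gte(sum(d$alpha$num != 0), 2L)
})

test_that("every vertex bounds the MILP/LP optimum from above", {
  space <- fx_space_split()
  eq <- build_cost_vector(fx_toy_split()$model, rule = "equal")
  rj <- minimize_linear_secondary(fx_toy_split()$model, fx_z(), eq, space = space)
  pj <- vapply(seq_len(12), function(i)
    as.double(pathway_flux_sum(space_vertex(space, i))), numeric(1))
  expect_true(all(pj >= as.double(rj$optimal_value)))
  expect_gte(rj$n_optimal_vertices, 1L)  # a linear minimum sits on a vertex
  expect_true(min(abs(pj - as.double(rj$optimal_value))) == 0)
})

test_that("generic strictly positive costs single out a unique vertex", {
  m <- fx_toy_split()$model
  rxns <- fs_rxn_ids(m)
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83)
  cv <- structure(list(rxns = rxns, values = rq(primes[seq_along(rxns)], 100),
                       rule = "generic", scale = rq(1)), class = "cost_vector")
  res <- minimize_linear_secondary(m, fx_z(), cv, space = fx_space_split())
  expect_equal(res$n_optimal_vertices, 1L)
  # all-zero costs: optimum 0, attained everywhere
  cv0 <- structure(list(rxns = rxns, values = rq(numeric(length(rxns))),
                        rule = "zero", scale = rq(1)), class = "cost_vector")
  res0 <- minimize_linear_secondary(m, fx_z(), cv0, space = fx_space_split())
  expect_true(res0$optimal_value == rq(0))
  expect_equal(res0$n_optimal_vertices, 12L)
})

test_that("linear secondary objectives refuse non-split models", {
  expect_error(minimize_linear_secondary(
    fx_toy(), fx_z(), build_cost_vector(fx_toy(), rule = "equal")),
    "split model")
})

test_that("MILP minimum matches the vertex-hull oracle on random split models", {
  for (s in c(4, 11, 21)) {
    fxr <- random_split_fixture(s)
    if (is.null(fxr)) next
    rs <- optimal_space(fxr$model, fxr$z)
    res <- minimize_pathway_length(fxr$model, fxr$z, space = rs)
    tot <- count_vertices(rs)$product
    oracle_min <- min(vapply(seq_len(tot), function(i)
      pathway_length(space_vertex(rs, i)), integer(1)))
    expect_equal(res$optimal_value, oracle_min,
                 label = sprintf("seed %d MILP", s))
  }
})

test_that("vertex statistics tabulate the whole product with cost identities", {
  space <- fx_space_split()
  m <- fx_toy_split()$model
  eq <- build_cost_vector(m, rule = "equal")
  stats <- vertex_statistics(space, list(equal = eq))
  expect_equal(nrow(stats$table), 12L)
  expect_equal(min(stats$table$P_L), 11L)
  # equal-cost column equals the flux-sum column on every row
  expect_equal(stats$table$equal, stats$table$P_J)
  expect_named(stats$histograms, c("P_L", "P_J", "equal"))
  expect_equal(sum(stats$histograms$P_L), 12L)
  expect_equal(nrow(stats$module_cost_ranges), 3L)
  # single-vertex space: one row
  chain <- fs_model(
    data.frame(id = c("X", "S1", "Y"), boundary = c(TRUE, FALSE, TRUE)),
    list(fs_reaction("Rin", c(X = -1, S1 = 1), ub = 1),
         fs_reaction("Rout", c(S1 = -1, Y = 1), obj = 1)))
  cs <- optimal_space(chain)
  expect_equal(nrow(vertex_statistics(cs)$table), 1L)
})
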