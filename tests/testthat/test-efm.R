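# Elementary flux modes, optimal-yield filtering, rank tests, matching.

test_that("the fixture has 13 EFMs of which 12 carry optimal yield", {
  efms <- fx_efms()
  expect_length(efms, 13)
  oy <- fx_oy()
  expect_length(oy, 12)
  # the non-operational mode is the reversible triangle (zero objective flux)
  keys <- vapply(efms, function(e) paste(sort(e$support), collapse = ","),
                 character(1))
  oykeys <- vapply(oy, function(e) paste(sort(e$support), collapse = ","),
                   character(1))
  nonop <- efms[[which(!keys %in% oykeys)]]
  expect_setequal(nonop$support, c("R2", "R3", "R4"))
  cobj <- fluxspace:::fs_obj_coeffs(fx_toy())
  expect_true(fluxspace:::rq_dot(cobj, nonop$flux$values)$num == 0)
  # optimal-yield modes are normalized to unit objective flux
  for (e in oy) expect_true(fv_get(e$flux, "R18") == rq(1))
})

test_that("splitting adds exactly the futile modes and keeps optimal yield", {
  efms_s <- fx_efms_split()
  # 12 optimal-yield + 5 split-pair two-cycles + both triangle directions
  expect_length(efms_s, 19)
  oy_s <- fx_oy_split()
  expect_length(oy_s, 12)
  # optimal-yield sets agree after the unsplit mapping
  sp <- fx_toy_split()
  imgs <- lapply(oy_s, function(e) unsplit_flux(e$flux, sp$split_map))
  k1 <- sort(vapply(imgs, function(v) paste(format(v$values), collapse = ","),
                    character(1)))
  k0 <- sort(vapply(fx_oy(), function(e)
    paste(format(e$flux$values), collapse = ","), character(1)))
  expect_identical(k1, k0)
})

test_that("a linear chain has a single EFM", {
  chain <- fs_model(
    data.frame(id = c("X", "S1", "Y"), boundary = c(TRUE, FALSE, TRUE)),
    list(fs_reaction("Rin", c(X = -1, S1 = 1), ub = 1),
         fs_reaction("Rout", c(S1 = -1, Y = 1), obj = 1)))
  efms <- enumerate_efms(chain)
  expect_length(efms, 1)
  oy <- optimal_yield_filter(efms, chain, 1)
  expect_length(oy, 1)
})

test_that("the rank test certifies elementarity exactly", {
  toy <- fx_toy()
  for (e in fx_efms()) {
    rt <- rank_test(e$flux, toy)
    expect_true(rt$verdict)
    expect_equal(rt$nullity, 1L)
    # SVD cross-check agrees
    expect_true(rank_test_svd(e$flux, toy)$verdict)
  }
  # superpositions of two distinct modes fail
  oy <- fx_oy()
  pairs <- list(c(1, 2), c(3, 8), c(5, 12))
  for (p in pairs) {
    s <- flux_vector(oy[[p[1]]]$flux$values + oy[[p[2]]]$flux$values,
                     oy[[p[1]]]$flux$rxns)
    if (sum(s$values$num != 0) >
        max(length(oy[[p[1]]]$support), length(oy[[p[2]]]$support))) {
      rt <- rank_test(s, toy)
      expect_false(rt$verdict)
      expect_false(rank_test_svd(s, toy)$verdict)
    }
  }
  # a split two-cycle is one-dimensional: nullity 1
  sp <- fx_toy_split()
  two <- rq(numeric(length(sp$model$reactions)))
  two[match(c("R13f", "R13b"), fs_rxn_ids(sp$model))] <- rq(c(1, 1))
  expect_true(rank_test(flux_vector(two, fs_rxn_ids(sp$model)), sp$model)$verdict)
  expect_error(rank_test(flux_vector(rq(numeric(18)), fs_rxn_ids(toy)), toy),
               "zero flux")
})

test_that("one third of optimal-yield EFMs have a non-split vertex", {
  mm <- match_vertices_to_efms(fx_verts_nonsplit()$vertices, fx_oy())
  expect_equal(mm$n_matched_efms, 4L)
  expect_equal(length(fx_oy()) - mm$n_matched_efms, 8L)
  expect_equal(mm$frac_efms_with_vertex, 1 / 3)
  expect_false(mm$bijection)
  expect_false(anyNA(mm$map$efm))  # every vertex IS an EFM instance here
})

test_that("after splitting the vertex-EFM matching is a bijection", {
  mm <- match_vertices_to_efms(fx_verts_split()$vertices, fx_oy_split())
  expect_true(mm$bijection)
  expect_equal(mm$n_matched_efms, 12L)
  # empty vertex list: empty mapping
  mm0 <- match_vertices_to_efms(list(), fx_oy_split())
  expect_equal(nrow(mm0$map), 0L)
})

test_that("a second restricting constraint creates composite vertices", {
  toy2 <- fs_set_bounds(fx_toy(), "R15", ub = rq(1, 2))
  sp2 <- split_reversible(toy2)
  z2 <- solve_fba(sp2$model)$objective_value
  expect_true(z2 == rq(1))
  vs <- enumerate_vertices(sp2$model, z_star = z2)
  efms2 <- enumerate_efms(sp2$model)
  oy2 <- suppressWarnings(optimal_yield_filter(efms2, sp2$model, z2))
  mm <- match_vertices_to_efms(vs$vertices, oy2)
  expect_true(anyNA(mm$map$efm))  # at least one vertex is composite
  comp <- vs$vertices[[which(is.na(mm$map$efm))[1]]]
  expect_false(rank_test(comp, sp2$model)$verdict)
})

test_that("a demanding constraint makes vertices non-elementary", {
  toyd <- toy_demand_variant()
  spd <- split_reversible(toyd)
  z <- solve_fba(spd$model)$objective_value
  expect_true(z == rq(7, 8))
  vs <- enumerate_vertices(spd$model, z_star = z)
  verdicts <- vapply(vs$vertices, function(v) rank_test(v, spd$model)$verdict,
                     logical(1))
  expect_true(any(!verdicts))
})
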