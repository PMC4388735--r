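# Vertex / ray / lineality enumeration and the Minkowski-sum operations.

test_that("the fixture's polyhedral census matches in both representations", {
  vs0 <- fx_verts_nonsplit()
  expect_length(vs0$vertices, 4)
  expect_length(vs0$linealities, 1)
  expect_length(enumerate_rays(fx_toy(), fx_z()), 0)
  vs1 <- fx_verts_split()
  expect_length(vs1$vertices, 12)
  expect_length(lineality_space(fx_toy_split()$model), 0)
  rays <- enumerate_rays(fx_toy_split()$model, fx_z())
  expect_length(rays, 7)
  kinds <- table(vapply(rays, `[[`, character(1), "kind"))
  expect_equal(unname(kinds[["split-pair"]]), 5)
  expect_equal(unname(kinds[["cycle"]]), 2)
})

test_that("the non-split lineality is the reversible triangle", {
  lin <- lineality_space(fx_toy())
  expect_length(lin, 1)
  supp <- lin[[1]]$rxns[lin[[1]]$values$num != 0]
  expect_setequal(supp, c("R2", "R3", "R4"))
  # fully irreversible model: no linealities
  expect_length(lineality_space(fx_toy_split()$model), 0)
})

test_that("a single split pair yields exactly one two-cycle ray", {
  # bounded exchanges leave the forward/backward futile cycle as the only
  # unbounded direction
  m <- fs_model(
    data.frame(id = c("X", "A", "B", "Y"), boundary = c(TRUE, FALSE, FALSE, TRUE)),
    list(fs_reaction("Rin", c(X = -1, A = 1), ub = 1),
         fs_reaction("R", c(A = -1, B = 1), reversible = TRUE),
         fs_reaction("Rout", c(B = -1, Y = 1), ub = 1, obj = 1)))
  sp <- split_reversible(m)
  rays <- enumerate_rays(sp$model)
  expect_length(rays, 1)
  expect_identical(rays[[1]]$kind, "split-pair")
  supp <- rays[[1]]$direction$rxns[rays[[1]]$direction$values$num != 0]
  expect_setequal(supp, c("Rf", "Rb"))
})

test_that("enumeration order is deterministic", {
  a <- enumerate_vertices(fx_toy_split()$model, z_star = 1)
  b <- enumerate_vertices(fx_toy_split()$model, z_star = 1)
  expect_identical(lapply(a$vertices, function(v) format(v$values)),
                   lapply(b$vertices, function(v) format(v$values)))
})

test_that("vertex counting multiplies per-module counts and reports the sum", {
  expect_equal(count_vertices(c(2, 2, 3)), list(product = 12, sum = 7))
  expect_equal(count_vertices(c(6, 3, 5184, 3, 2, 54, 2, 2)),
               list(product = 120932352, sum = 5256))
  expect_equal(count_vertices(numeric(0)), list(product = 1, sum = 1))
  expect_equal(count_vertices(fx_space_split())$product, 12)
  expect_equal(count_vertices(fx_space_nonsplit())$product, 4)
})

test_that("reconstruct_vertex honours choices and flags invalid indices", {
  space <- fx_space_split()
  # find the choice selecting {R9,R10} and {R12,R15}: it has 11 active reactions
  pls <- vapply(seq_len(12), function(i) pathway_length(space_vertex(space, i)),
                integer(1))
  expect_equal(min(pls), 11L)
  expect_equal(sum(pls == 11L), 1L)
  v11 <- space_vertex(space, which.min(pls))
  supp <- v11$rxns[v11$values$num != 0]
  expect_true(all(c("R9", "R10", "R12", "R15") %in% supp))
  expect_false(any(c("R6", "R13f", "R13b") %in% supp))
  expect_error(reconstruct_vertex(space, c(99, 1, 1)), "invalid vertex index")
  # zero modules: the fixed flux comes back unchanged
  chain <- fs_model(
    data.frame(id = c("X", "S1", "Y"), boundary = c(TRUE, FALSE, TRUE)),
    list(fs_reaction("Rin", c(X = -1, S1 = 1), ub = 1),
         fs_reaction("Rout", c(S1 = -1, Y = 1), obj = 1)))
  cs <- optimal_space(chain)
  expect_equal(count_vertices(cs)$product, 1)
  v <- reconstruct_vertex(cs, integer(0))
  expect_equal(format(v$values), c("1", "1"))
})

test_that("Minkowski decomposition accepts optimal fluxes and rejects others", {
  space <- fx_space_split()
  v1 <- space_vertex(space, 1)
  d1 <- decompose_in_space(space, v1)
  expect_true(d1$accepted)
  expect_true(sum(d1$alpha) == rq(1))
  expect_equal(sum(d1$alpha$num != 0), 1L)  # a vertex is itself
  v2 <- space_vertex(space, 2)
  mid <- flux_vector((v1$values + v2$values) / rq(2), v1$rxns)
  dm <- decompose_in_space(space, mid)
  expect_true(dm$accepted)
  expect_setequal(format(dm$alpha[dm$alpha$num != 0]), "1/2")
  # sub-optimal flux: scaled-down optimum violates the objective equality
  sub <- flux_vector(v1$values * rq(1, 2), v1$rxns)
  ds <- decompose_in_space(space, sub)
  expect_false(ds$accepted)
  expect_match(ds$certificate, "objective")
})

test_that("random optimal mixtures decompose; perturbed fluxes are rejected", {
  space <- fx_space_split()
  total <- count_vertices(space)$product
  rxns <- fs_rxn_ids(space$model)
  set.seed(4)
  for (rep in 1:25) {
    # exact random convex weights + small conical ray weights
    w <- rq(sample(0:4, total, replace = TRUE))
    if (all(w$num == 0)) w[1] <- rq(1)
    w <- w / sum(w)
    acc <- rq(numeric(length(rxns)))
    for (i in seq_len(total)) {
      if (w$num[i] != 0) acc <- acc + space_vertex(space, i)$values * w[i]
    }
    for (r in space$rays) {
      b <- rq(sample(0:2, 1), 3)
      if (b$num != 0) acc <- acc + r$direction$values * b
    }
    j <- flux_vector(acc, rxns)
    expect_true(decompose_in_space(space, j)$accepted)
    # perturb one coordinate: must be rejected with a certificate
    k <- sample(length(rxns), 1)
    accp <- acc; accp[k] <- accp[k] + rq(1, 9)
    dp <- decompose_in_space(space, flux_vector(accp, rxns))
    expect_false(dp$accepted)
    expect_true(nzchar(dp$certificate))
  }
})

test_that("unsplit images of split vertices cover the non-split vertices", {
  sp <- fx_toy_split()
  space0 <- fx_space_nonsplit()
  imgs <- lapply(seq_len(12), function(i)
    unsplit_flux(space_vertex(fx_space_split(), i), sp$split_map))
  keys0 <- vapply(fx_verts_nonsplit()$vertices,
                  function(v) paste(format(v$values), collapse = ","), character(1))
  keysI <- vapply(imgs, function(v) paste(format(v$values), collapse = ","),
                  character(1))
  expect_true(all(keys0 %in% keysI))
  # the remaining images are optimal fluxes decomposable in the non-split space
  for (v in imgs) {
    expect_true(decompose_in_space(space0, v)$accepted)
  }
})
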