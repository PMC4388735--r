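# Model types, the fixture network, splitting, I/O, and the random
# generator.

test_that("the fixture network has the documented structure", {
  toy <- fx_toy()
  expect_equal(nrow(toy$species), 18)
  expect_equal(length(toy$reactions), 18)
  expect_equal(sum(toy$species$boundary), 2)
  expect_setequal(toy$species$id[toy$species$boundary], c("X", "Y"))
  expect_equal(sum(vapply(toy$reactions, `[[`, logical(1), "reversible")), 5)
  expect_true(toy$reactions$R1$ub == rq(2))
  expect_true(toy$reactions$R18$obj == rq(1))
  sm <- stoich_matrix(toy)
  expect_equal(dim(sm$mat$num), c(16L, 18L))
})

test_that("model validation rejects inconsistent reactions", {
  toy <- fx_toy()
  expect_error(fs_set_bounds(toy, "R1", lb = 3, ub = 2), "lower bound exceeds")
  expect_error(fs_set_bounds(toy, "R5", lb = -1), "irreversible")
  expect_error(fs_reaction("bad", c(A = 0)), "empty stoichiometry")
  expect_error(fs_set_bounds(toy, "nope", ub = 1), "unknown reaction")
})

test_that("splitting adds one reaction per reversible and preserves nets", {
  toy <- fx_toy()
  sp <- fx_toy_split()
  expect_equal(length(sp$model$reactions), 18 + 5)
  expect_true(all(!vapply(sp$model$reactions, `[[`, logical(1), "reversible")))
  for (r in sp$model$reactions) {
    expect_true(inherits(r$lb, "rq") && r$lb$num >= 0)
  }
  # backward stoichiometry is the negation of forward
  for (id in names(sp$split_map)) {
    pair <- sp$split_map[[id]]
    if (is.na(pair[2])) next
    f <- sp$model$reactions[[pair[1]]]; b <- sp$model$reactions[[pair[2]]]
    ord <- match(attr(f$stoich, "species"), attr(b$stoich, "species"))
    expect_true(all((f$stoich + b$stoich[ord])$num == 0))
  }
  # idempotent on an irreversible model
  sp2 <- split_reversible(sp$model)
  expect_equal(length(sp2$model$reactions), length(sp$model$reactions))
  expect_true(all(vapply(sp2$split_map, function(p) is.na(p[2]), logical(1))))
  # single reversible reaction -> forward/backward pair
  one <- fs_model(data.frame(id = c("A", "B"), boundary = c(TRUE, TRUE)),
                  list(fs_reaction("R", c(A = -1, B = 1), reversible = TRUE)))
  so <- split_reversible(one)
  expect_equal(names(so$model$reactions), c("Rf", "Rb"))
})

test_that("unsplit_flux recovers net fluxes and preserves steady state", {
  sp <- fx_toy_split()
  toy <- fx_toy()
  # forward 2, backward 2 cancels to zero net
  sol <- solve_fba(sp$model)
  back <- unsplit_flux(sol$flux, sp$split_map)
  expect_true(is_steady_state(toy, back))
  expect_true(fluxspace:::fs_within_bounds(toy, back))
  expect_true(fluxspace:::rq_dot(fluxspace:::fs_obj_coeffs(toy), back$values) == rq(1))
  # every split vertex maps to a feasible optimal flux of the original model
  for (v in fx_verts_split()$vertices[1:4]) {
    nv <- unsplit_flux(v, sp$split_map)
    expect_true(is_steady_state(toy, nv))
    expect_true(fluxspace:::fs_within_bounds(toy, nv))
  }
  # missing reaction in the map is an error
  expect_error(unsplit_flux(sol$flux, list(RX = c("nope", NA))), "missing")
})

test_that("tabular and SBML round-trips preserve the model exactly", {
  toy <- fx_toy()
  toy$reactions$R8$gpr <- "(p1 and p2) or p3"
  for (fmt in c("tabular", "sbml")) {
    path <- tempfile(fileext = if (fmt == "sbml") ".xml" else ".tsv")
    write_model(toy, path, format = fmt)
    back <- read_model(path)
    expect_true(fs_model_equal(toy, back), label = paste(fmt, "round-trip"))
    unlink(path)
  }
  # rational bounds survive the tabular dialect verbatim
  m2 <- fs_set_bounds(toy, "R15", ub = rq(1, 2))
  path <- tempfile(fileext = ".tsv")
  write_model(m2, path)
  expect_true(read_model(path)$reactions$R15$ub == rq(1, 2))
  unlink(path)
  # invariant violations surface as parse-time errors
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("boundary: X", "R1 : X --> A ; 3, 2 ; 1"), bad)
  expect_error(read_model(bad), "lower bound exceeds")
  unlink(bad)
  expect_error(read_model(tempfile()), "no such file")
})

test_that("a model without objective coefficients warns on read", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("boundary: X Y", "R1 : X --> A", "R2 : A --> Y"), path)
  expect_warning(read_model(path), "no objective")
  unlink(path)
})

test_that("random models are deterministic, connected, and bounded", {
  m1 <- generate_random_model(5, 8, seed = 42)
  m2 <- generate_random_model(5, 8, seed = 42)
  expect_true(fs_model_equal(m1, m2))
  m3 <- generate_random_model(5, 8, seed = 43)
  expect_false(fs_model_equal(m1, m3) && identical(format(m1), format(m3)))
  for (s in c(1, 7, 23)) {
    m <- generate_random_model(4, 7, seed = s)
    expect_true(all(fluxspace:::reachable_reactions(m, "X")))
    mb <- fs_set_bounds(m, "R1", ub = 1)
    sol <- solve_fba(mb)
    expect_identical(sol$status, "optimal")
    # write-then-read round-trip of a generated model
    path <- tempfile(fileext = ".tsv")
    write_model(m, path)
    expect_true(fs_model_equal(m, read_model(path)))
    unlink(path)
  }
})

test_that("splitting preserves the feasible net-flux set on random models", {
  for (s in c(3, 9, 17)) {
    m <- fs_set_bounds(generate_random_model(4, 7, seed = s), "R1", ub = 1)
    sp <- split_reversible(m)
    a <- solve_fba(m); b <- solve_fba(sp$model)
    expect_identical(a$status, b$status)
    if (a$status == "optimal") {
      expect_true(a$objective_value == b$objective_value)
      back <- unsplit_flux(b$flux, sp$split_map)
      expect_true(is_steady_state(m, back))
      expect_true(fluxspace:::fs_within_bounds(m, back))
    }
  }
})
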