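# Pipeline commands, configs, and report determinism.

test_that("cmd_enumerate writes the split-model census", {
  out <- tempfile()
  cfg <- run_config(model = "toy", split = TRUE, out = out)
  space <- cmd_enumerate(cfg)
  expect_equal(space$counts$s, 12)
  js <- jsonlite::read_json(file.path(out, "space.json"))
  expect_equal(js$counts$vertices_product, 12)
  expect_equal(js$counts$rays, 7)
  expect_equal(js$counts$linealities, 0)
  expect_equal(js$counts$subnetworks, 3)
  expect_equal(js$objective_value, "1")
  v <- readLines(file.path(out, "vertices.tsv"))
  expect_length(v, 13)  # header + 12 vertices
  expect_length(readLines(file.path(out, "rays.tsv")), 8)
  s <- readLines(file.path(out, "summary.txt"))
  expect_true(any(grepl("vertices: 12", s)))
  unlink(out, recursive = TRUE)
})

test_that("cmd_enumerate without splitting reports the lineality census", {
  out <- tempfile()
  space <- cmd_enumerate(run_config(model = "toy", split = FALSE, out = out))
  js <- jsonlite::read_json(file.path(out, "space.json"))
  expect_equal(js$counts$vertices_product, 4)
  expect_equal(js$counts$rays, 0)
  expect_equal(js$counts$linealities, 1)
  expect_equal(js$counts$subnetworks, 2)
  expect_equal(js$counts$modules, 3)
  unlink(out, recursive = TRUE)
})

test_that("reruns with an identical config are byte-identical", {
  out <- tempfile()
  cfg <- run_config(model = "toy", split = TRUE, out = out)
  files <- c("space.json", "vertices.tsv", "rays.tsv", "linealities.tsv",
             "summary.txt")
  cmd_enumerate(cfg)
  first <- lapply(files, function(f) readLines(file.path(out, f)))
  unlink(out, recursive = TRUE)
  cmd_enumerate(cfg)
  second <- lapply(files, function(f) readLines(file.path(out, f)))
  expect_identical(first, second)
  unlink(out, recursive = TRUE)
})

test_that("bound overrides are validated before solving", {
  expect_error(cmd_enumerate(run_config(model = "toy",
                                        bounds = list(R99 = c(NA, "1")),
                                        out = tempfile())),
               "unknown reaction")
})

test_that("cmd_efm reports counts and the matching", {
  out <- tempfile()
  res <- cmd_efm(run_config(model = "toy", split = FALSE, out = out))
  js <- jsonlite::read_json(file.path(out, "efm_report.json"))
  expect_equal(js$n_efms, 13)
  expect_equal(js$n_optimal_yield, 12)
  expect_equal(js$n_efms_without_vertex, 8)
  expect_false(js$bijection)
  out2 <- tempfile()
  res2 <- cmd_efm(run_config(model = "toy", split = TRUE, out = out2))
  js2 <- jsonlite::read_json(file.path(out2, "efm_report.json"))
  expect_true(js2$bijection)
  expect_equal(js2$n_optimal_yield, 12)
  unlink(c(out, out2), recursive = TRUE)
})

test_that("cmd_secondary reproduces the pathway-length minima", {
  out <- tempfile()
  res <- cmd_secondary(run_config(model = "toy", split = TRUE,
                                  secondary = "P_L", out = out))
  expect_equal(res$optimal_value, 11L)
  js <- jsonlite::read_json(file.path(out, "secondary.json"))
  expect_equal(js$optimal_value, "11")
  expect_equal(js$n_optimal_vertices, 1)
  stats <- utils::read.delim(file.path(out, "vertex_stats.tsv"))
  expect_equal(nrow(stats), 12)
  unlink(out, recursive = TRUE)
  out2 <- tempfile()
  res2 <- cmd_secondary(run_config(model = "toy", split = TRUE,
                                   secondary = "P_L",
                                   bounds = list(R15 = c(NA, "1/2")),
                                   out = out2))
  expect_equal(res2$optimal_value, 12L)
  unlink(out2, recursive = TRUE)
})

test_that("configs round-trip through the flat key-value format", {
  path <- tempfile()
  writeLines(c("model = toy", "split = false", "secondary = P_J",
               "rule = average", "seed = 7", "out = somewhere",
               "bound.R15 = 0, 1/2"), path)
  cfg <- read_run_config(path)
  expect_identical(cfg$model, "toy")
  expect_false(cfg$split)
  expect_identical(cfg$secondary, "P_J")
  expect_identical(cfg$rule, "average")
  expect_equal(cfg$seed, 7L)
  expect_identical(cfg$bounds$R15, c("0", "1/2"))
  writeLines("nonsense = 1", path)
  expect_error(read_run_config(path), "unknown config key")
  unlink(path)
})

test_that("growth presets are parameterized by user-supplied reaction ids", {
  b <- growth_preset("anaerobic", glucose = "EX_glc", oxygen = "EX_o2",
                     atpm = "ATPM")
  expect_identical(b$EX_o2[2], "0")
  expect_identical(b$EX_glc[2], "1277/100")
  expect_identical(b$ATPM, c("839/100", "839/100"))
  b2 <- growth_preset("aerobic-restricted", glucose = "g", oxygen = "o",
                      atpm = "a")
  expect_identical(b2$o[2], "37/2")
})
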