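test_that("generation is deterministic per seed", {
  p <- synth_cell_params(R0 = 50, N = 6, window = c(2, 5), img = 200,
                         seed = 9)
  a <- generate_sequence(p)
  b <- generate_sequence(p)
  expect_identical(a$cell, b$cell)
  p2 <- synth_cell_params(R0 = 50, N = 6, window = c(2, 5), img = 200,
                          seed = 10)
  expect_false(identical(generate_sequence(p2)$cell, a$cell))
})

test_that("degenerate and inconsistent geometries are handled", {
  ## w = l = 2 R0 collapses to a single circle
  p <- synth_cell_params(R0 = 40, N = 3, window = c(1, 2),
                         elongation = 0, neck_frac = 1, img = 160,
                         noise_sd = 0, salt_pepper = 0)
  g <- generate_sequence(p)
  expect_equal(g$truth$w, g$truth$l)
  r <- measure_frame(g$cell[[1]], clean = FALSE)
  expect_equal(r$F, 80, tolerance = 1)
  expect_equal(r$L, 80, tolerance = 1)
  ## neck wider than the tip-to-tip length has no two-circle solution
  expect_error(cytomech:::synth_schedules(
    structure(list(R0 = 40, N = 3, window = c(1L, 2L), elongation = -0.5,
                   neck_frac = 1, profile = "large", vc0 = NA,
                   vc_rate = 0), class = "synth_cell_params")),
    "two-circle")
  expect_error(synth_cell_params(R0 = 200, img = 256), "fit")
  expect_error(synth_cell_params(window = c(10, 5)), "window")
})

test_that("populations draw distinct reproducible cells", {
  pop <- generate_population(population_preset("sk18"), 5, seed = 3)
  expect_length(pop$cells, 5)
  expect_equal(length(unique(pop$table$seed)), 5)
  pop2 <- generate_population(population_preset("sk18"), 5, seed = 3)
  expect_identical(pop$table, pop2$table)
})

test_that("preset V/C medians land in their documented windows", {
  vc18 <- population_vc_curves(generate_population(
    population_preset("sk18"), 23, seed = 11))
  vc26 <- population_vc_curves(generate_population(
    population_preset("sk26"), 32, seed = 11))
  expect_gt(median(vc18[, 1]), 1.27)
  expect_lt(median(vc18[, 1]), 1.37)
  expect_gt(median(vc26[, 1]), 1.43)
  expect_lt(median(vc26[, 1]), 1.53)
  ## cool-incubation envelope becomes tight late, warm stays loose
  expect_lt(median(vc18[, 11]), 1.1)
  expect_gt(median(vc26[, 11]), 1.1)
})

test_that("population elongation curves start at one and grow", {
  el <- population_elongation_curves(generate_population(
    population_preset("sk26"), 6, seed = 2))
  expect_equal(el[, 1], rep(1, 6))
  expect_true(all(el[, 11] > 1.1))
})
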