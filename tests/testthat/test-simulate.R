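## module tests run on deliberately coarse meshes for speed; the
## acceptance suite exercises the default resolution

coarse <- list(target_edge = 10, n_theta = 12)

test_that("a zero-load schedule leaves the cell unchanged", {
  sched <- contraction_schedule(furrow_width = 2, furrow_factor = 0)
  sim <- simulate_cleavage(sched, target_edge = coarse$target_edge,
                           n_theta = coarse$n_theta)
  expect_equal(sim$curves$L_n, rep(1, 11), tolerance = 1e-9)
  expect_equal(sim$total_energy, 0, tolerance = 1e-12)
})

test_that("free-boundary furrow-only elongation is monotone and symmetric", {
  sched <- contraction_schedule(furrow_width = 2)
  sim <- simulate_cleavage(sched, target_edge = coarse$target_edge,
                           n_theta = coarse$n_theta, keep_meshes = TRUE)
  expect_true(all(diff(sim$curves$L_n) > 0))
  expect_true(all(sim$curves$W[-1] >= 0))
  expect_equal(sim$curves$L_n[1], 1)
  ## furrow diameter shrinks along the run
  expect_true(all(diff(sim$curves$F_n) < 0))
  ## mirror symmetry of the deformed shape about z = 0
  final <- sim$meshes[[11]]
  zmax <- max(final$nodes[, 3]); zmin <- min(final$nodes[, 3])
  expect_lt(abs(zmax + zmin) / (zmax - zmin), 0.01)
})

test_that("schedule validation enforces invariants", {
  expect_error(contraction_schedule(furrow_width = 2, furrow_factor = 1.2),
               "furrow_factor")
  expect_error(contraction_schedule(furrow_width = c(2, 2)), "length")
  expect_error(contraction_schedule(furrow_width = 2,
                                    spindle_length = c(30, rep(20, 10))),
               "non-decreasing")
  ## NA widths reuse the previous value
  s <- contraction_schedule(furrow_width = c(13, 12, 11, 10, 9, 8, 7, 6,
                                             5, 3.6, NA))
  expect_equal(s$furrow_width[11], 3.6)
})

test_that("tight sliding confinement blocks polar elongation", {
  sched <- contraction_schedule(furrow_width = 2)
  sim <- simulate_cleavage(sched, confinement_spec("tight_sliding"),
                           target_edge = coarse$target_edge,
                           n_theta = coarse$n_theta)
  expect_equal(sim$curves$L_n[11], 1, tolerance = 0.01)
  expect_true(all(abs(sim$curves$L_n - 1) <= 0.011))
})

test_that("energy ratio is 1 for identical runs and invariant in E", {
  sched <- contraction_schedule(furrow_width = 2, n_steps = 3)
  a <- simulate_cleavage(sched, target_edge = coarse$target_edge,
                         n_theta = coarse$n_theta)
  expect_equal(energy_ratio(a, a), 1)
  b <- simulate_cleavage(sched, mat = material(young_modulus = 7),
                         target_edge = coarse$target_edge,
                         n_theta = coarse$n_theta)
  expect_equal(b$total_energy / a$total_energy, 7, tolerance = 1e-6)
  expect_equal(energy_ratio(b, b), 1)
})

test_that("halving the increment size changes the outcome marginally", {
  a <- simulate_cleavage(contraction_schedule(furrow_width = 2,
                                              n_steps = 5,
                                              furrow_factor = 0.05),
                         target_edge = coarse$target_edge,
                         n_theta = coarse$n_theta)
  b <- simulate_cleavage(contraction_schedule(furrow_width = 2,
                                              n_steps = 10,
                                              furrow_factor = 0.025),
                         target_edge = coarse$target_edge,
                         n_theta = coarse$n_theta)
  ## nearly the same total contraction, consistent response
  expect_lt(abs(b$curves$L_n[11] / a$curves$L_n[6] - 1), 0.01)
})

test_that("sensitivity scan reproduces the stated orderings", {
  sc <- sensitivity_scan(fw_um = c(4, 16), log_ratios = c(-0.3, 0, 0.3),
                         target_edge = 10, n_theta = 12)
  g <- attr(sc, "grid")
  expect_true(all(is.finite(g)))
  ## wider furrow elongates more at every stiffness ratio
  expect_true(all(g[2, ] > g[1, ]))
  ## stiffer equator elongates more around the homogeneous point
  expect_true(all(g[, 3] > g[, 2]))
  expect_true(all(g[, 2] > g[, 1]))
})

test_that("simulation driven from a configuration list runs end to end", {
  cfg <- list(cell_cross_section_um = 400, furrow_width_um = 8,
              n_steps = 3, target_edge = 10, n_theta = 12)
  sim <- simulate_from_config(cfg)
  expect_s3_class(sim, "cleavage_sim")
  expect_equal(nrow(sim$curves), 4)
  expect_error(read_sim_config(c(cfg, list(bogus_key = 1))), "unknown")
})
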