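## fitting tests use short schedules and coarse meshes; the full printed
## small-egg fit runs in the acceptance suite

test_that("the stepwise fit recovers a known spindle schedule", {
  n <- 4
  fw <- rep(3, n + 1)
  sl_true <- c(30, 36, 42, 47, 52)
  fwd <- simulate_cleavage(contraction_schedule(fw, n_steps = n,
                                                spindle_length = sl_true),
                           target_edge = 10, n_theta = 12)
  fit <- fit_schedule(fwd$curves$L_n, furrow_width = fw, free = "spindle",
                      target_edge = 10, n_theta = 12)
  expect_lt(max(abs(fit$steps$spindle_length - sl_true[-1]) / sl_true[-1]),
            0.05)
  expect_lt(max(fit$steps$residual), 0.005)
  expect_true(all(fit$steps$monotone_ok))
})

test_that("a null target keeps the spindle at its initial length", {
  n <- 3
  target <- rep(1, n + 1)
  fit <- fit_schedule(target, furrow_width = rep(2, n + 1),
                      free = "spindle", furrow_factor = 0,
                      target_edge = 10, n_theta = 12)
  expect_equal(fit$steps$spindle_length, rep(30, n), tolerance = 0.01)
  expect_lt(max(fit$steps$residual), 1e-3)
})

test_that("the fit is deterministic at the reported-table level", {
  n <- 3
  target <- c(1, 1.03, 1.06, 1.09)
  f1 <- fit_schedule(target, furrow_width = rep(3, n + 1),
                     target_edge = 10, n_theta = 12)
  f2 <- fit_schedule(target, furrow_width = rep(3, n + 1),
                     target_edge = 10, n_theta = 12)
  expect_identical(f1$steps, f2$steps)
})

test_that("unreachable targets are flagged at the bounds", {
  n <- 2
  target <- c(1, 2.5, 3.5)      # far beyond any feasible elongation
  fit <- fit_schedule(target, furrow_width = rep(2, n + 1),
                      bounds = c(0, 60), target_edge = 10, n_theta = 12)
  expect_true(all(fit$steps$at_bound))
  expect_true(all(fit$steps$residual > 0.1))
})

test_that("group comparison behaves under null, alternative and oracle", {
  set.seed(21)
  tgrid <- 11
  mk <- function(n, shift = 0, sd = 0.02)
    t(replicate(n, cumsum(c(1, rep(0.03, tgrid - 1))) +
                  rnorm(tgrid, shift, sd)))
  a <- mk(8)
  ## identical groups: no difference
  expect_gte(compare_curves(a, a)$p_value, 0.99)
  ## strong separation: ten sigma offset
  b <- mk(10, shift = 0.2, sd = 0.02)
  expect_lt(compare_curves(mk(10), b)$p_value, 0.01)
  expect_lt(compare_curves(mk(10), b, method = "permutation")$p_value, 0.01)
  ## small-sample permutation equals exhaustive enumeration
  x <- mk(3); y <- mk(3, shift = 0.05)
  res <- compare_curves(x, y, method = "permutation")
  expect_equal(res$p_value, permutation_oracle(x, y), tolerance = 1e-12)
  expect_match(res$test, "exact")
  ## timepoint-restricted scope
  late <- compare_curves(mk(10), b, scope = "timepoints",
                         timepoints = 8:11)
  expect_lt(late$p_value, 0.01)
  expect_error(compare_curves(a[1, , drop = FALSE], a), "at least 2")
})
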