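test_that("masked median filter matches the brute-force oracle", {
  set.seed(11)
  expect_equal(smooth_series(rep(4, 10)), rep(4, 10))
  expect_equal(smooth_series(c(1, 1, 9, 1, 1)),
               median_filter_oracle(c(1, 1, 9, 1, 1)))
  expect_equal(smooth_series(c(1, 1, 9, 1, 1))[3], 1)
  expect_equal(smooth_series(c(3, 7)), median_filter_oracle(c(3, 7)))
  for (r in 1:20) {
    v <- rnorm(sample(1:30, 1))
    expect_equal(smooth_series(v), median_filter_oracle(v))
  }
  ## idempotence on strictly monotone input away from the edges
  v <- sort(rnorm(15))
  expect_equal(smooth_series(v)[3:13], v[3:13])
})

test_that("frame measurement recovers disks and dumbbells", {
  ## isotropic disk: F = L = diameter
  img <- 256; d <- 121
  xs <- matrix(rep(seq_len(img), each = img), img)
  ys <- matrix(rep(seq_len(img), times = img), img)
  disk <- (xs - 128.5)^2 + (ys - 128.5)^2 <= (d / 2)^2
  r <- measure_frame(disk, clean = FALSE)
  expect_equal(r$F, d, tolerance = 1)
  expect_equal(r$L, d, tolerance = 1)
  expect_false(r$excluded)
  ## two-circle dumbbell with exact programmed geometry
  p <- synth_cell_params(R0 = 80, N = 4, window = c(2, 3),
                         elongation = 0.28, neck_frac = 0.45, img = 420,
                         noise_sd = 0, salt_pepper = 0)
  g <- generate_sequence(p)
  last <- length(g$cell)
  r2 <- measure_frame(g$cell[[last]], clean = FALSE)
  expect_equal(r2$L, g$truth$l[last], tolerance = 1)
  expect_equal(r2$F, g$truth$w[last], tolerance = 1)
  expect_error(measure_frame(matrix(FALSE, 5, 5)), "empty")
})

test_that("vitelline extent yields the V/C ratio", {
  p <- synth_cell_params(R0 = 80, N = 6, window = c(2, 5),
                         elongation = 0.2, vc0 = 1.2, img = 420,
                         noise_sd = 0, salt_pepper = 0)
  g <- generate_sequence(p)
  r <- measure_frame(g$cell[[1]], g$vitelline[[1]], clean = FALSE)
  expect_equal(r$V / (g$truth$V[1]), 1, tolerance = 0.02)
  ## vitelline diameter equal to the cell polar length: V/C = 1
  img <- 420
  xs <- matrix(rep(seq_len(img), each = img), img)
  ys <- matrix(rep(seq_len(img), times = img), img)
  dd <- sqrt((xs - 210.5)^2 + (ys - 210.5)^2)
  cell <- dd <= 80
  ring <- abs(dd - 80) <= 1.5
  r2 <- measure_frame(cell, ring, clean = FALSE)
  expect_equal(r2$V / r2$L, 1, tolerance = 0.02)
})

test_that("asymmetric divisions are flagged for exclusion", {
  img <- 300
  xs <- matrix(rep(seq_len(img), each = img), img)
  ys <- matrix(rep(seq_len(img), times = img), img)
  big <- (xs - 110)^2 + (ys - 150)^2 <= 70^2
  small <- (xs - 215)^2 + (ys - 150)^2 <= 38^2
  r <- measure_frame(big | small, clean = FALSE)
  expect_true(r$excluded)
  expect_gt(r$asymmetry, 1.25)
})

test_that("cleavage window detection matches programmed transitions", {
  ## S-shaped transition over a programmed frame interval, constant
  ## schedules outside, light measurement noise; unit-level check
  set.seed(5)
  shape <- cytomech:::elongation_profile("large")
  for (r in 1:20) {
    n <- 60; a <- 18; b <- 42
    tt <- pmin(1, pmax(0, (seq_len(n) - a) / (b - a)))
    sig <- stats::approx(seq(0, 1, 0.1), shape, xout = tt)$y
    L <- 200 * (1 + 0.3 * sig) + rnorm(n, 0, 0.3)
    F <- 200 * (1 - 0.6 * sig) + rnorm(n, 0, 0.3)
    w <- detect_cleavage_window(smooth_series(F), smooth_series(L))
    expect_lte(abs(w$s_s - a), 1)
    expect_lte(abs(w$s_e - b), 1)
  }
})

test_that("degenerate SAD inputs raise the no-cleavage error", {
  s <- seq_len(30)
  expect_error(detect_cleavage_window(100 - s, 100 + s), "no cleavage")
  expect_error(detect_cleavage_window(rep(5, 30), rep(7, 30)), "no cleavage")
  expect_error(detect_cleavage_window(1:4, 1:4), "at least 5")
})

test_that("with two transitions the window brackets the larger one", {
  n <- 80
  step <- function(at, width, amp) {
    tt <- pmin(1, pmax(0, (seq_len(n) - at) / width))
    amp * (3 * tt^2 - 2 * tt^3)
  }
  L <- 200 + step(10, 8, 6) + step(50, 12, 60)
  F <- 200 - step(10, 8, 6) - step(50, 12, 60)
  w <- detect_cleavage_window(smooth_series(F), smooth_series(L))
  expect_gte(w$s_s, 40)
  expect_lte(w$s_e, 68)
})

test_that("curve normalisation is exact, scale and sampling invariant", {
  series <- data.frame(s = 1:41, F = seq(200, 120, length.out = 41),
                       L = seq(200, 400, length.out = 41),
                       V = rep(NA_real_, 41))
  win <- structure(list(s_s = 11, s_e = 31), class = "cleavage_window")
  cv <- normalize_curves(series, win)
  expect_identical(cv$L_n[1], 1)
  ## L doubling linearly across the window
  L_s <- series$L[11]; L_e <- series$L[31]
  series2 <- series; series2$L <- seq(100, 100 + (41 - 1) * 10, by = 10)
  series2$L <- 150 + (series2$s - 11) * 150 / 20   # L(s_e) = 2 L(s_s)
  cv2 <- normalize_curves(series2, win)
  expect_equal(cv2$L_n[11], 2, tolerance = 1e-12)
  ## uniform spatial rescale leaves the curve unchanged
  series3 <- series; series3$F <- series$F * 3.7; series3$L <- series$L * 3.7
  expect_equal(normalize_curves(series3, win)$L_n, cv$L_n, tolerance = 1e-12)
  ## offset convention
  expect_equal(normalize_curves(series, win, convention = "offset")$L_n[1], 0)
  expect_error(normalize_curves(series,
    structure(list(s_s = 11, s_e = 11), class = "cleavage_window")),
    "shorter")
})

test_that("temporal subsampling by two barely changes the curve", {
  p <- synth_cell_params(vc0 = 1.4, seed = 3)
  g <- generate_sequence(p)
  q1 <- quantify_series(g$cell, g$vitelline)
  idx <- seq(1, length(g$cell), by = 2)
  q2 <- quantify_series(g$cell[idx], g$vitelline[idx])
  expect_lt(max(abs(q2$curves$L_n - q1$curves$L_n)), 0.02)
})

test_that("V/C series equals one when V coincides with L", {
  series <- data.frame(s = 1:20, F = rep(100, 20), L = seq(100, 150, length.out = 20))
  series$V <- series$L
  win <- structure(list(s_s = 5, s_e = 15), class = "cleavage_window")
  vc <- vc_ratio_series(series, win)
  expect_equal(vc$vc, rep(1, 11), tolerance = 1e-12)
  series$V <- NA_real_
  expect_error(vc_ratio_series(series, win), "vitelline")
})
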