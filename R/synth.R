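## Synthetic dividing-cell time-lapse generator. Each frame is the union of
## two equal circles whose radius and centre separation are solved in
## closed form from the programmed tip-to-tip length l(s) and neck width
## w(s), so the geometric ground truth is exact. A vitelline ring with its
## own dilation schedule, boundary jitter and salt-and-pepper noise emulate
## the appearance of segmented embryo masks.

## normalised elongation shapes (fractions of the final elongation reached
## at each tenth of the cleavage window); the "large-egg" profile is
## nearly linear with a late plateau, the "small-egg" profile is strongly
## front-loaded. Used to give synthetic cells realistic curve shapes.
elongation_profile <- function(kind = c("large", "small")) {
  kind <- match.arg(kind)
  if (kind == "large")
    c(0, 0.097, 0.233, 0.375, 0.515, 0.641, 0.751, 0.848, 0.922, 0.977, 1)
  else
    c(0, 0.185, 0.340, 0.470, 0.577, 0.662, 0.728, 0.781, 0.829, 0.893, 1)
}

#' Parameters of one synthetic dividing cell
#'
#' @param R0 initial cell radius, pixels.
#' @param N number of frames.
#' @param window integer frame interval `c(a, b)` of the programmed
#'   cleavage (schedules are constant outside it).
#' @param elongation final relative polar elongation (`l(b)/l(a) - 1`)
#'   before any vitelline capping.
#' @param neck_frac final neck width as a fraction of the initial
#'   diameter.
#' @param profile elongation curve shape, `"large"` (near-linear) or
#'   `"small"` (front-loaded).
#' @param vc0 initial vitelline-to-cell ratio (`NA` for no vitelline).
#' @param vc_rate relative dilation of the vitelline diameter over the
#'   cleavage window (0 = rigid envelope). The cell length is capped at
#'   the vitelline diameter (tight confinement).
#' @param noise_sd boundary jitter standard deviation, pixels.
#' @param salt_pepper salt-and-pepper pixel flip rate.
#' @param img image side length, pixels.
#' @param seed RNG seed for the noise.
#' @return an object of class `synth_cell_params`.
#' @export
synth_cell_params <- function(R0 = 100, N = 60, window = c(15, 45),
                              elongation = 0.31, neck_frac = 0.35,
                              profile = c("large", "small"),
                              vc0 = NA, vc_rate = 0,
                              noise_sd = 0.4, salt_pepper = 5e-4,
                              img = 512, seed = 1) {
  profile <- match.arg(profile)
  if (window[1] >= window[2] || window[2] > N || window[1] < 1)
    stop("window must satisfy 1 <= a < b <= N")
  if (elongation < 0 || neck_frac <= 0 || neck_frac > 1)
    stop("invalid elongation or neck_frac")
  if (2 * R0 * (1 + elongation) > img - 10)
    stop("cell does not fit the image; increase img or reduce R0")
  structure(list(R0 = R0, N = as.integer(N), window = as.integer(window),
                 elongation = elongation, neck_frac = neck_frac,
                 profile = profile, vc0 = vc0, vc_rate = vc_rate,
                 noise_sd = noise_sd, salt_pepper = salt_pepper,
                 img = as.integer(img), seed = as.integer(seed)),
            class = "synth_cell_params")
}

## per-frame schedules and the exact two-circle geometry
synth_schedules <- function(params) {
  p <- params
  s <- seq_len(p$N)
  frac <- numeric(p$N)
  inwin <- s >= p$window[1] & s <= p$window[2]
  tt <- (s[inwin] - p$window[1]) / (p$window[2] - p$window[1])
  shape <- elongation_profile(p$profile)
  frac[inwin] <- stats::approx(seq(0, 1, 0.1), shape, xout = tt)$y
  frac[s > p$window[2]] <- 1
  l0 <- 2 * p$R0
  l <- l0 * (1 + p$elongation * frac)
  w <- l0 * (1 - (1 - p$neck_frac) * frac)
  V <- rep(NA_real_, p$N)
  if (!is.na(p$vc0)) {
    V <- p$vc0 * l0 * (1 + p$vc_rate * frac)
    capped <- l > V
    l[capped] <- V[capped]                # tight vitelline confinement
  }
  if (any(w > l + 1e-9))
    stop("no two-circle solution at frame ", which(w > l + 1e-9)[1],
         ": neck wider than tip-to-tip length")
  rho <- (l / 2 + w^2 / (2 * l)) / 2
  cc <- (l / 2 - w^2 / (2 * l)) / 2
  data.frame(s = s, l = l, w = w, V = V, rho = rho, half_sep = cc)
}

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic dividing-cell mask sequence
#'
#' @param params a [synth_cell_params()] object.
#' @param masks rasterize the binary masks (set FALSE to obtain only the
#'   exact ground-truth schedules, e.g. for fast population statistics).
#' @return list with `truth` (per-frame data.frame: `s`, `l`, `w`, `V`),
#'   `window`, `params`, and (when `masks = TRUE`) `cell` and
#'   `vitelline` lists of binary matrices. Deterministic per seed.
#' @export
generate_sequence <- function(params, masks = TRUE) {
  stopifnot(inherits(params, "synth_cell_params"))
  sch <- synth_schedules(params)
  out <- list(truth = sch[, c("s", "l", "w", "V")],
              window = params$window, params = params)
  if (!masks) return(out)
  p <- params
  ctr <- (p$img + 1) / 2
  xs <- matrix(rep(seq_len(p$img), each = p$img), p$img)   # column = x
  ys <- matrix(rep(seq_len(p$img), times = p$img), p$img)  # row = y
  out$cell <- vector("list", p$N)
  out$vitelline <- if (!is.na(p$vc0)) vector("list", p$N) else NULL
  with_seed(p$seed, {
    for (i in seq_len(p$N)) {
      c1x <- ctr - sch$half_sep[i]; c2x <- ctr + sch$half_sep[i]
      d1 <- sqrt((xs - c1x)^2 + (ys - ctr)^2)
      d2 <- sqrt((xs - c2x)^2 + (ys - ctr)^2)
      d <- pmin(d1, d2) - sch$rho[i]
      if (p$noise_sd > 0)
        d <- d + matrix(stats::rnorm(p$img^2, 0, p$noise_sd), p$img)
      m <- d <= 0
      if (p$salt_pepper > 0) {
        flip <- matrix(stats::runif(p$img^2) < p$salt_pepper, p$img)
        m <- xor(m, flip)
      }
      out$cell[[i]] <- m
      if (!is.null(out$vitelline)) {
        dv <- sqrt((xs - ctr)^2 + (ys - ctr)^2) - sch$V[i] / 2
        out$vitelline[[i]] <- abs(dv) <= 1.5   # ring of ~3 px thickness
      }
    }
  })
  out
}

#' Population presets for the two incubation-temperature experiments
#'
#' Named presets emulating the statistical structure of the two observed
#' egg populations: `"sk18"` (cool incubation; narrow vitelline, median
#' V/C at cleavage start 1.32, envelope dilating so slowly that the
#' elongating cell reaches it in the late phase) and `"sk26"` (warm
#' incubation; median V/C 1.48 and a faster-dilating envelope that is
#' never reached). All per-cell quantities are log-normal draws.
#'
#' @param name `"sk18"` or `"sk26"`.
#' @return an object of class `population_preset`.
#' @export
population_preset <- function(name = c("sk18", "sk26")) {
  name <- match.arg(name)
  base <- list(name = name, R0 = 100, N = 60, img = 512,
               window_mean = c(15, 45),
               meanlog_elong = log(0.36), sdlog_elong = 0.15,
               meanlog_winlen = log(30), sdlog_winlen = 0.12,
               sdlog_vc0 = 0.06, noise_sd = 0.4, salt_pepper = 5e-4,
               profile = "large")
  if (name == "sk18") {
    base$meanlog_vc0 <- log(1.32)
    base$meanlog_rate <- log(0.02); base$sdlog_rate <- 0.3
  } else {
    base$meanlog_vc0 <- log(1.48)
    base$meanlog_rate <- log(0.08); base$sdlog_rate <- 0.3
  }
  structure(base, class = "population_preset")
}

#' Generate a population of synthetic dividing cells
#'
#' Draws per-cell parameters from the preset distributions (child seeds
#' derived deterministically from the master seed) and generates each
#' cell's sequence.
#'
#' @param preset a [population_preset()].
#' @param n_cells number of cells (the two observed vitelline populations
#'   had 23 and 32 cells).
#' @param seed master seed.
#' @param masks rasterize masks (FALSE returns ground truth only).
#' @return list with `cells` (list of [generate_sequence()] results) and
#'   `table` (per-cell parameter data.frame).
#' @export
generate_population <- function(preset, n_cells, seed = 1, masks = FALSE) {
  stopifnot(inherits(preset, "population_preset"))
  if (n_cells < 1) stop("n_cells must be at least 1")
  draws <- with_seed(seed, {
    data.frame(
      cell = seq_len(n_cells),
      elongation = stats::rlnorm(n_cells, preset$meanlog_elong,
                                 preset$sdlog_elong),
      vc0 = stats::rlnorm(n_cells, preset$meanlog_vc0, preset$sdlog_vc0),
      vc_rate = stats::rlnorm(n_cells, preset$meanlog_rate,
                              preset$sdlog_rate),
      winlen = pmin(50, pmax(12, round(stats::rlnorm(
        n_cells, preset$meanlog_winlen, preset$sdlog_winlen)))),
      a = round(stats::runif(n_cells, 6, 12)))
  })
  draws$seed <- (seed %% 100000L) * 10000L + draws$cell
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    pr <- synth_cell_params(
      R0 = preset$R0, N = preset$N, img = preset$img,
      window = c(draws$a[i], min(preset$N - 2, draws$a[i] + draws$winlen[i])),
      elongation = draws$elongation[i], profile = preset$profile,
      vc0 = draws$vc0[i], vc_rate = draws$vc_rate[i],
      noise_sd = preset$noise_sd, salt_pepper = preset$salt_pepper,
      seed = draws$seed[i])
    cells[[i]] <- generate_sequence(pr, masks = masks)
  }
  list(cells = cells, table = draws, preset = preset)
}

#' Ground-truth V/C curves of a synthetic population
#'
#' Convenience accessor: samples each cell's exact vitelline-to-cell ratio
#' on the dimensionless time grid of its programmed cleavage window.
#'
#' @param pop result of [generate_population()].
#' @param n_samples t-grid size.
#' @return matrix (cells x timepoints) of V/C values.
#' @export
population_vc_curves <- function(pop, n_samples = 11) {
  tg <- seq(0, 1, length.out = n_samples)
  t(vapply(pop$cells, function(cl) {
    tr <- cl$truth; win <- cl$window
    sg <- win[1] + tg * (win[2] - win[1])
    V <- stats::approx(tr$s, tr$V, xout = sg)$y
    L <- stats::approx(tr$s, tr$l, xout = sg)$y
    V / L
  }, numeric(n_samples)))
}

#' Ground-truth elongation curves of a synthetic population
#' @inheritParams population_vc_curves
#' @return matrix (cells x timepoints) of `L_n` values (ratio convention).
#' @export
population_elongation_curves <- function(pop, n_samples = 11) {
  tg <- seq(0, 1, length.out = n_samples)
  t(vapply(pop$cells, function(cl) {
    tr <- cl$truth; win <- cl$window
    sg <- win[1] + tg * (win[2] - win[1])
    L <- stats::approx(tr$s, tr$l, xout = sg)$y
    L / L[1]
  }, numeric(n_samples)))
}
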