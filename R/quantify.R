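## Shape quantification of time-lapse binary masks of dividing cells:
## per-frame furrow and polar axis lengths, masked median smoothing,
## SAD-based cleavage-window detection, dimensionless normalisation and
## vitelline-to-cell ratio curves.

## 3x3 binary opening (erosion then dilation) via matrix shifts; removes
## salt noise without touching extents by more than a pixel.
binary_open <- function(m) {
  shift <- function(x, dr, dc) {
    n <- nrow(x); p <- ncol(x)
    out <- matrix(FALSE, n, p)
    sr <- max(1, 1 + dr):min(n, n + dr)
    sc <- max(1, 1 + dc):min(p, p + dc)
    out[sr, sc] <- x[sr - dr, sc - dc]
    out
  }
  m <- m > 0
  er <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) er <- er & shift(m, dr, dc)
  di <- er
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) di <- di | shift(er, dr, dc)
  di
}

#' Measure one frame of a dividing-cell mask
#'
#' The polar (division) axis is the major principal axis of the cell mask
#' (second moments). `L` is the extent of the mask projected on that axis;
#' `F` is the furrow width: the interior minimum of the perpendicular
#' width profile within the central half of the axial extent when a neck
#' exists, otherwise the width at the mask centre (the minor axis of a
#' pre-furrow cell). `V` is the extent of the vitelline mask along the same
#' axis.
#'
#' @param cell_mask logical or 0/1 matrix; nonempty.
#' @param vitelline_mask optional mask of the vitelline membrane.
#' @param clean apply a 3x3 binary opening before measuring (removes salt
#'   noise); default TRUE.
#' @return list with `F`, `L`, `centroid` (x, y in pixel coordinates),
#'   `V` (`NA` without a vitelline mask), `asymmetry` (area ratio of the
#'   two halves split at the neck) and `excluded` (TRUE when asymmetry
#'   exceeds 1.25, flagging non-symmetric divisions).
#' @export
measure_frame <- function(cell_mask, vitelline_mask = NULL, clean = TRUE) {
  m <- cell_mask > 0
  if (!any(m)) stop("empty cell mask")
  if (clean) m <- binary_open(m)
  if (!any(m)) stop("cell mask vanished after noise cleaning")
  px <- which(m, arr.ind = TRUE)
  x <- px[, 2]; y <- px[, 1]
  cx <- mean(x); cy <- mean(y)
  xm <- x - cx; ym <- y - cy
  cov <- matrix(c(mean(xm^2), mean(xm * ym), mean(xm * ym), mean(ym^2)), 2)
  ev <- eigen(cov, symmetric = TRUE)
  ax <- ev$vectors[, 1]                    # major principal axis
  a <- xm * ax[1] + ym * ax[2]
  p <- -xm * ax[2] + ym * ax[1]
  ## trimmed extent: drop the 3 outermost pixels on each side so that
  ## boundary-jitter outliers do not inflate the axis length
  ext <- function(v, k = 3) {
    v <- sort(v)
    n <- length(v)
    if (n <= 2 * k + 1) return(diff(range(v)) + 1)
    v[n - k] - v[k + 1] + 1
  }
  L <- ext(a)
  ## width profile along the axis over the central 50% of the extent.
  ## The width at axial position a0 is measured as the pixel count in an
  ## overlapping slab of thickness tau divided by tau (an area-based
  ## width): boundary jitter averages out, and there is no sensitivity to
  ## pixel-lattice alignment. The profile is median-smoothed before the
  ## minimum search.
  lo <- min(a) + 0.25 * (L - 1); hi <- max(a) - 0.25 * (L - 1)
  tau <- 1.0                                      # slab thickness, px
  nb <- as.integer(floor((hi - lo) / tau)) + 1L
  ## anti-aliased area profile: each pixel is a unit square whose
  ## projection onto the axis is an interval of width |ax_1| + |ax_2|;
  ## its mass is split over the bins it overlaps. This removes the
  ## lattice resonances of naive point counting at any axis angle.
  h <- (abs(ax[1]) + abs(ax[2])) / 2
  al <- a - h; ar <- a + h
  kl <- floor((al - lo) / tau)
  wb <- numeric(nb)
  for (off in 0:ceiling(2 * h / tau)) {
    k <- kl + off
    ov <- pmin(ar, lo + (k + 1) * tau) - pmax(al, lo + k * tau)
    keep <- ov > 0 & k >= 0 & k < nb
    if (any(keep)) {
      acc <- rowsum(ov[keep] / (2 * h), k[keep])
      idx <- as.integer(rownames(acc)) + 1L
      wb[idx] <- wb[idx] + acc[, 1]
    }
  }
  wb <- wb / tau
  bz <- lo + (seq_len(nb) - 0.5) * tau
  Fv <- NA_real_; neck_at <- NA_real_; jmin <- NA_integer_
  if (length(wb) >= 3) {
    interior <- 2:(length(wb) - 1)
    locmin <- interior[wb[interior] <= wb[interior - 1] &
                         wb[interior] <= wb[interior + 1]]
    if (length(locmin)) {
      cand <- locmin[which.min(wb[locmin])]
      ## a genuine neck sits clearly below the central-region edges; a
      ## shallow not-yet-formed neck is covered by the centre fallback
      if (wb[cand] < 0.95 * min(wb[1], wb[length(wb)])) {
        Fv <- wb[cand]; neck_at <- bz[cand]; jmin <- cand
      }
    }
  }
  if (is.na(Fv)) {
    jmin <- which.min(abs(bz - 0))
    Fv <- wb[jmin]; neck_at <- bz[jmin]
  }
  ## V-flank correction: slab averaging plus the unit-square projection
  ## smooth the vertex of a V-shaped profile upwards by about
  ## slope * (tau + 2 h) / 4; slope estimated on a +-2 px stencil.
  ## A parabolic sub-grid interpolation recovers a vertex that falls
  ## between bins (clamped to at most one bin of correction).
  st <- as.integer(2 / tau)
  if (jmin > st && jmin <= length(wb) - st) {
    slope <- max(0, (wb[jmin - st] + wb[jmin + st] - 2 * wb[jmin]) / 4)
    Fv <- max(1, Fv - slope * (tau + 2 * h) / 4)
    den <- wb[jmin + 1] + wb[jmin - 1] - 2 * wb[jmin]
    if (den > 1e-9) {
      sub <- (wb[jmin + 1] - wb[jmin - 1])^2 / (8 * den)
      Fv <- max(1, Fv - min(sub, tau))
    }
  }
  asym <- {
    n1 <- sum(a < neck_at); n2 <- sum(a > neck_at)
    max(n1, n2) / max(1, min(n1, n2))
  }
  V <- NA_real_
  if (!is.null(vitelline_mask)) {
    vm <- which(vitelline_mask > 0, arr.ind = TRUE)
    if (nrow(vm) == 0) stop("empty vitelline mask")
    va <- (vm[, 2] - cx) * ax[1] + (vm[, 1] - cy) * ax[2]
    V <- diff(range(va)) + 1
  }
  list(F = Fv, L = L, centroid = c(x = cx, y = cy), V = V,
       asymmetry = asym, excluded = asym > 1.25)
}

#' Measure a whole mask time series
#'
#' @param masks list of cell-mask matrices (or a 3D array, frames in the
#'   third dimension).
#' @param vitelline optional parallel list/array of vitelline masks.
#' @param pixel_size_um optional micrometres per pixel (measurements are
#'   reported in pixels; the pixel size is carried as an attribute).
#' @param clean see [measure_frame()].
#' @return a `shape_series` data.frame with columns `s`, `F`, `L`, `cx`,
#'   `cy`, `V`, `asymmetry`, `excluded`.
#' @export
measure_series <- function(masks, vitelline = NULL, pixel_size_um = NULL,
                           clean = TRUE) {
  if (is.array(masks) && length(dim(masks)) == 3)
    masks <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
  if (!is.null(vitelline) && is.array(vitelline) &&
      length(dim(vitelline)) == 3)
    vitelline <- lapply(seq_len(dim(vitelline)[3]),
                        function(i) vitelline[, , i])
  n <- length(masks)
  out <- data.frame(s = seq_len(n), F = NA_real_, L = NA_real_,
                    cx = NA_real_, cy = NA_real_, V = NA_real_,
                    asymmetry = NA_real_, excluded = FALSE)
  for (i in seq_len(n)) {
    r <- measure_frame(masks[[i]],
                       if (!is.null(vitelline)) vitelline[[i]],
                       clean = clean)
    out$F[i] <- r$F; out$L[i] <- r$L
    out$cx[i] <- r$centroid[1]; out$cy[i] <- r$centroid[2]
    out$V[i] <- r$V; out$asymmetry[i] <- r$asymmetry
    out$excluded[i] <- r$excluded
  }
  if (!is.null(pixel_size_um)) attr(out, "pixel_size_um") <- pixel_size_um
  class(out) <- c("shape_series", "data.frame")
  out
}

#' 5-point masked median filter
#'
#' Sliding median with a centred window of five samples; at the sequence
#' edges the out-of-range samples are masked out (the window truncates).
#' Even-sized windows use the lower median for integer stability.
#'
#' @param values numeric vector.
#' @param width window width (default 5).
#' @return smoothed vector of the same length.
#' @export
smooth_series <- function(values, width = 5) {
  n <- length(values)
  if (n <= 1) return(values)
  h <- width %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- sort(values[max(1, i - h):min(n, i + h)])
    out[i] <- w[(length(w) + 1) %/% 2]     # lower median when even
  }
  out
}

#' Detect the cleavage window from furrow and polar length series
#'
#' Computes the discrete derivatives of `F(s)` and `L(s)` (central
#' differences, one-sided at the ends), forms the sum of absolute
#' derivatives `SAD = |F'| + |L'|`, and takes the start/end of the first
#' cleavage as the nearest local minima of SAD left and right of its
#' absolute maximum. Endpoints count as local minima; argmax ties break to
#' the earliest frame.
#'
#' @param F,L numeric sequences of equal length (at least 5), typically
#'   [smooth_series()]-smoothed.
#' @param smooth_sad apply the same 5-point masked median to the SAD
#'   indicator before locating its extrema (suppresses spurious local
#'   minima from pixel quantisation); default TRUE.
#' @return a `cleavage_window`: list with `s_s`, `s_e`, and `sad`.
#' @export
detect_cleavage_window <- function(F, L, smooth_sad = TRUE) {
  n <- length(F)
  if (length(L) != n) stop("F and L must have equal length")
  if (n < 5) stop("need at least 5 frames")
  deriv <- function(v) {
    d <- numeric(n)
    d[1] <- v[2] - v[1]
    d[n] <- v[n] - v[n - 1]
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    d
  }
  sad <- abs(deriv(F)) + abs(deriv(L))
  if (smooth_sad) sad <- smooth_series(sad)
  if (diff(range(sad)) <= 1e-9 * max(abs(sad), 1))
    stop("no cleavage detected (flat SAD)")
  s_star <- which.max(sad)                 # earliest on ties
  if (s_star == 1 || s_star == n)
    stop("no cleavage detected (SAD maximum at the sequence edge)")
  ## nearest local minimum on each side: descend the SAD valley with a
  ## hysteresis band so that jitter-scale dips do not stop the search;
  ## endpoints and the plateau sample nearest the peak count as minima.
  hyst <- 0.35 * diff(range(sad))
  ## quiescent baseline: mean of the lowest quartile of SAD samples
  baseline <- mean(sort(sad)[seq_len(max(1L, n %/% 4))])
  floor_lv <- baseline + 0.1 * (max(sad) - baseline)
  descend <- function(dir) {
    best <- s_star + dir
    if (sad[best] <= floor_lv) return(best)
    i <- best
    while (i + dir >= 1 && i + dir <= n) {
      i <- i + dir
      if (sad[i] <= floor_lv) return(i)     # reached the quiescent baseline
      if (sad[i] < sad[best]) best <- i
      else if (sad[i] > sad[best] + hyst) break
    }
    best
  }
  left_min <- descend(-1L)
  right_min <- descend(1L)
  ## the centred derivative spreads an onset one frame backwards; advance
  ## the start edge accordingly
  left_min <- min(left_min + 1L, s_star - 1L)
  structure(list(s_s = left_min, s_e = right_min, s_star = s_star,
                 sad = sad),
            class = "cleavage_window")
}

#' @export
print.cleavage_window <- function(x, ...) {
  cat("Cleavage window: frames", x$s_s, "to", x$s_e,
      "(SAD peak at", x$s_star, ")\n")
  invisible(x)
}

#' Dimensionless normalised elongation curves
#'
#' Maps the detected cleavage window onto dimensionless time
#' `t = (s - s_s) / (s_e - s_s)` and interpolates the normalised furrow
#' and polar lengths onto a regular t grid. The ratio convention
#' (`L_n(0) = 1`) is the default; the offset convention reports
#' `L/L(0) - 1`.
#'
#' @param series a `shape_series` (see [measure_series()]).
#' @param window a `cleavage_window`.
#' @param n_samples grid size (default 11: t = 0, 0.1, ..., 1).
#' @param convention `"ratio"` or `"offset"`.
#' @return an `elongation_curve` data.frame with columns `t`, `L_n`,
#'   `F_n`, and `V_n` when the series has vitelline measurements.
#' @export
normalize_curves <- function(series, window, n_samples = 11,
                             convention = c("ratio", "offset")) {
  convention <- match.arg(convention)
  if (window$s_e - window$s_s < 1)
    stop("cleavage window shorter than 2 frames")
  if (window$s_s < min(series$s) || window$s_e > max(series$s))
    stop("cleavage window outside the series range")
  tg <- seq(0, 1, length.out = n_samples)
  sg <- window$s_s + tg * (window$s_e - window$s_s)
  ip <- function(v) stats::approx(series$s, v, xout = sg,
                                  ties = "ordered")$y
  L <- ip(series$L); Fv <- ip(series$F)
  out <- data.frame(t = tg, L_n = L / L[1], F_n = Fv / Fv[1])
  if (!all(is.na(series$V))) {
    V <- ip(series$V)
    out$V_n <- V / V[1]
  }
  if (convention == "offset") {
    out$L_n <- out$L_n - 1
    out$F_n <- out$F_n - 1
    if (!is.null(out$V_n)) out$V_n <- out$V_n - 1
  }
  attr(out, "convention") <- convention
  attr(out, "window") <- c(s_s = window$s_s, s_e = window$s_e)
  class(out) <- c("elongation_curve", "data.frame")
  out
}

#' Vitelline-to-cell ratio over dimensionless cleavage time
#'
#' `V/C(t)`: vitelline membrane cross-section divided by the polar cell
#' length, sampled on the dimensionless time grid of the cleavage window.
#'
#' @inheritParams normalize_curves
#' @return data.frame with columns `t` and `vc`.
#' @export
vc_ratio_series <- function(series, window, n_samples = 11) {
  if (all(is.na(series$V)))
    stop("series has no vitelline measurements")
  tg <- seq(0, 1, length.out = n_samples)
  sg <- window$s_s + tg * (window$s_e - window$s_s)
  ip <- function(v) stats::approx(series$s, v, xout = sg,
                                  ties = "ordered")$y
  data.frame(t = tg, vc = ip(series$V) / ip(series$L))
}

#' Full quantification pipeline for one mask sequence
#'
#' Measures every frame, smooths the furrow and polar length series with
#' the 5-point masked median filter, detects the cleavage window from the
#' SAD indicator, and returns the dimensionless elongation (and V/C)
#' curves.
#'
#' @inheritParams measure_series
#' @param n_samples t-grid size for the output curves.
#' @return list with `series` (smoothed `shape_series`), `window`,
#'   `curves` (an `elongation_curve`), and `vc` (or NULL).
#' @export
quantify_series <- function(masks, vitelline = NULL, pixel_size_um = NULL,
                            n_samples = 11, clean = TRUE) {
  series <- measure_series(masks, vitelline, pixel_size_um, clean = clean)
  series$F <- smooth_series(series$F)
  series$L <- smooth_series(series$L)
  if (!all(is.na(series$V))) series$V <- smooth_series(series$V)
  window <- detect_cleavage_window(series$F, series$L)
  curves <- normalize_curves(series, window, n_samples)
  vc <- if (!all(is.na(series$V)))
    vc_ratio_series(series, window, n_samples) else NULL
  list(series = series, window = window, curves = curves, vc = vc)
}
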