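## Stepwise multiparametric fitting of furrow-width / spindle-length
## schedules to a target elongation curve, and rank-based comparison of
## elongation or V/C curve populations.

golden_search <- function(f, lower, upper, tol = 1e-3, max_eval = 50) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c1 <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c1); fd <- f(d); n_eval <- 2L
  while (abs(b - a) > tol && n_eval < max_eval) {
    if (fc < fd) {
      b <- d; d <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- f(c1)
    } else {
      a <- c1; c1 <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d)
    }
    n_eval <- n_eval + 1L
  }
  if (fc < fd) list(par = c1, value = fc) else list(par = d, value = fd)
}

#' Stepwise fit of a contraction schedule to an elongation curve
#'
#' Reproduces a target elongation curve `L_n(t_k)` with the incremental
#' cleavage model by searching one free parameter per increment — the
#' spindle pole separation (`free = "spindle"`) or the furrow band width
#' (`free = "furrow"`) — while the other follows its supplied schedule.
#' The fit is sequential: the deformed state of step `k - 1` is kept and
#' only step `k`'s parameter is searched (bounded golden-section search).
#' Steps whose target is unreachable within the bounds keep the best
#' boundary value and are flagged.
#'
#' @param target numeric vector of target `L_n` values at
#'   `t = 0, 1/n, ..., 1` (ratio convention, `target[1] = 1`), e.g. a row
#'   of the packaged elongation table (see [elongation_tables()]).
#' @param furrow_width furrow-width schedule in model units (length
#'   `n_steps + 1`, `NA` reuses previous); fixed when `free = "spindle"`,
#'   the starting schedule otherwise.
#' @param free which parameter is searched per step.
#' @param spindle_init initial spindle pole separation, model units
#'   (default 30); ignored for `free = "furrow"` unless a spindle schedule
#'   is also given via `spindle_length`.
#' @param spindle_length fixed spindle schedule when `free = "furrow"`
#'   (optional).
#' @param bounds length-2 vector of search bounds for the free parameter
#'   (model units). Defaults: spindle `[0, 60]`; furrow `[3, 17]` scaled to
#'   model units by the caller.
#' @param monotone_spindle constrain the fitted spindle to be
#'   non-decreasing (search lower bound = previous separation); default
#'   TRUE.
#' @param furrow_factor per-step furrow contraction fraction (default
#'   0.05).
#' @param tol golden-section tolerance on the parameter (default 1e-3).
#' @param max_eval maximum objective evaluations per step (default 50).
#' @param mat,confinement,cell_radius,target_edge,n_theta,n_rings as in
#'   [simulate_cleavage()].
#' @return an object of class `cleavage_fit` with `$steps` (data.frame:
#'   `t`, `furrow_width`, `spindle_length`, `L_target`, `L_fit`,
#'   `residual`, `at_bound`, `monotone_ok`) and the run parameters.
#' @export
fit_schedule <- function(target, furrow_width,
                         free = c("spindle", "furrow"),
                         spindle_init = 30, spindle_length = NULL,
                         bounds = NULL, monotone_spindle = TRUE,
                         furrow_factor = 0.05, tol = 1e-3, max_eval = 50,
                         mat = material(),
                         confinement = confinement_spec("free"),
                         cell_radius = 50,
                         target_edge = cell_radius / 10,
                         n_theta = 16, n_rings = NULL) {
  free <- match.arg(free)
  n <- length(target) - 1L
  if (n < 1) stop("target must have at least 2 time points")
  if (abs(target[1] - 1) > 1e-9)
    stop("target must be in ratio convention with target[1] = 1")
  if (is.null(bounds))
    bounds <- if (free == "spindle") c(0, 60) else c(3, 17)
  sched <- contraction_schedule(
    furrow_width = furrow_width, n_steps = n, furrow_factor = furrow_factor,
    spindle_length = if (free == "spindle") rep(spindle_init, n + 1)
                     else spindle_length)
  has_spindle <- free == "spindle" || !is.null(spindle_length)
  if (free == "spindle") sched$spindle_length <- rep(spindle_init, n + 1)
  state <- new_cleavage_state(cell_radius, sched, confinement, mat,
                              target_edge, n_theta, n_rings)
  out <- data.frame(t = sched$t[-1], furrow_width = NA_real_,
                    spindle_length = NA_real_, L_target = target[-1],
                    L_fit = NA_real_, residual = NA_real_,
                    at_bound = FALSE, monotone_ok = NA)
  for (k in seq_len(n)) {
    tgt <- target[k + 1]
    if (free == "spindle") {
      fw <- sched$furrow_width[k + 1]
      ctx <- step_context(state, fw)
      lo <- if (monotone_spindle) max(bounds[1], state$sep) else bounds[1]
      hi <- bounds[2]
      ## monotone-response probe: L_n must increase with the separation
      probe <- seq(lo, hi, length.out = 5)
      pl <- vapply(probe, function(s) ctx$eval(s)$L, numeric(1))
      mono <- all(diff(pl) > -1e-9)
      obj <- function(s) abs(ctx$eval(s)$L / state$L0 - tgt)
      gs <- golden_search(obj, lo, hi, tol = tol, max_eval = max_eval)
      par <- gs$par
      ## targets beyond the reachable range: keep the boundary value
      if (obj(lo) <= gs$value + 1e-12) par <- lo
      if (obj(hi) < obj(par)) par <- hi
      res <- ctx$eval(par)
      at_bound <- par <= lo + 2 * tol || par >= hi - 2 * tol
      state <- step_commit(state, ctx, res, sl = par)
      out$furrow_width[k] <- fw
      out$spindle_length[k] <- par
      out$monotone_ok[k] <- mono
    } else {
      sl <- if (has_spindle) sched$spindle_length[k + 1] else NULL
      obj_fw <- function(fw) {
        ctx <- step_context(state, fw)
        abs(ctx$eval(sl)$L / state$L0 - tgt)
      }
      gs <- golden_search(obj_fw, bounds[1], bounds[2], tol = tol,
                          max_eval = max_eval)
      par <- gs$par
      ctx <- step_context(state, par)
      res <- ctx$eval(sl)
      at_bound <- par <= bounds[1] + 2 * tol || par >= bounds[2] - 2 * tol
      state <- step_commit(state, ctx, res, sl = sl)
      out$furrow_width[k] <- par
      out$spindle_length[k] <- if (has_spindle) sl else NA_real_
      out$monotone_ok[k] <- TRUE
    }
    out$L_fit[k] <- res$L / state$L0
    out$residual[k] <- abs(out$L_fit[k] - tgt)
    out$at_bound[k] <- at_bound
  }
  structure(list(steps = out, free = free, bounds = bounds,
                 furrow_factor = furrow_factor, cell_radius = cell_radius,
                 target_edge = target_edge),
            class = "cleavage_fit")
}

#' @export
print.cleavage_fit <- function(x, ...) {
  n <- nrow(x$steps)
  cat("Stepwise cleavage-schedule fit (free parameter:", x$free, ")\n")
  cat("  max |L_n residual| =", format(signif(max(x$steps$residual), 3)),
      "\n")
  if (x$free == "spindle")
    cat("  fitted spindle length at t = 1:",
        round(x$steps$spindle_length[n], 2), "model units\n")
  else
    cat("  fitted furrow width at t = 1:",
        round(x$steps$furrow_width[n], 2), "model units\n")
  if (any(x$steps$at_bound))
    cat("  steps at search bounds:",
        paste(which(x$steps$at_bound), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cleavage_fit <- function(object, ...) {
  print(object)
  print(round(object$steps[, c("t", "furrow_width", "spindle_length",
                               "L_target", "L_fit", "residual")], 4))
  invisible(object$steps)
}

#' @export
coef.cleavage_fit <- function(object, ...) {
  stats::setNames(
    if (object$free == "spindle") object$steps$spindle_length
    else object$steps$furrow_width,
    paste0("t=", object$steps$t))
}

#' @export
plot.cleavage_fit <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(c(0, x$steps$t), c(1, x$steps$L_target), type = "b",
                 pch = 1, xlab = "t", ylab = expression(L[n](t)), ...)
  graphics::lines(c(0, x$steps$t), c(1, x$steps$L_fit), type = "b",
                  pch = 16)
  graphics::legend("topleft", c("target", "fit"), pch = c(1, 16), bty = "n")
  y <- if (x$free == "spindle") x$steps$spindle_length
       else x$steps$furrow_width
  graphics::plot(x$steps$t, y, type = "b", pch = 16, xlab = "t",
                 ylab = paste("fitted", x$free, "(model units)"))
  invisible(x)
}

## ---- curve comparison -------------------------------------------------

curves_to_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  if (is.list(x)) return(do.call(rbind, lapply(x, as.numeric)))
  matrix(x, nrow = 1)
}

#' Compare two groups of elongation or V/C curves
#'
#' Two-sided comparison of curve populations, either pooling all sampled
#' values (`scope = "whole"`) or restricting to a timepoint subset
#' (`scope = "timepoints"`, e.g. the late cleavage phase). The default test
#' is the Mann-Whitney (Wilcoxon rank-sum) test; a permutation test on the
#' difference of per-curve means is available, with exhaustive enumeration
#' of group relabelings when feasible.
#'
#' @param group_a,group_b matrices (curves in rows) or lists of numeric
#'   vectors, all sampled on a common t grid.
#' @param scope `"whole"` or `"timepoints"`.
#' @param timepoints column indices used when `scope = "timepoints"`.
#' @param method `"wilcoxon"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo permutation count when exhaustive enumeration
#'   exceeds `max_exact` relabelings.
#' @param max_exact largest number of relabelings enumerated exhaustively.
#' @return an object of class `curve_comparison`: `p_value`, `test`,
#'   `statistic`, group sizes and the scope used.
#' @export
compare_curves <- function(group_a, group_b,
                           scope = c("whole", "timepoints"),
                           timepoints = NULL,
                           method = c("wilcoxon", "permutation"),
                           n_perm = 9999, max_exact = 20000) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  a <- curves_to_matrix(group_a); b <- curves_to_matrix(group_b)
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need at least 2 curves per group")
  if (scope == "timepoints") {
    if (is.null(timepoints)) stop("scope = 'timepoints' needs timepoints")
    a <- a[, timepoints, drop = FALSE]
    b <- b[, timepoints, drop = FALSE]
  }
  if (method == "wilcoxon") {
    va <- as.vector(a); vb <- as.vector(b)
    wt <- suppressWarnings(stats::wilcox.test(va, vb, exact =
                                                length(va) < 50 &&
                                                length(vb) < 50))
    res <- list(p_value = wt$p.value, test = "Mann-Whitney U (pooled values)",
                statistic = unname(wt$statistic))
  } else {
    sa <- rowMeans(a); sb <- rowMeans(b)
    obs <- abs(mean(sa) - mean(sb))
    pooled <- c(sa, sb); na <- length(sa); ntot <- length(pooled)
    n_comb <- choose(ntot, na)
    if (n_comb <= max_exact) {
      idx <- utils::combn(ntot, na)
      stat <- apply(idx, 2, function(ii)
        abs(mean(pooled[ii]) - mean(pooled[-ii])))
      p <- mean(stat >= obs - 1e-12)
      test <- sprintf("permutation (exact, %d relabelings)", n_comb)
    } else {
      stat <- vapply(seq_len(n_perm), function(i) {
        ii <- sample.int(ntot, na)
        abs(mean(pooled[ii]) - mean(pooled[-ii]))
      }, numeric(1))
      p <- (1 + sum(stat >= obs - 1e-12)) / (n_perm + 1)
      test <- sprintf("permutation (Monte Carlo, %d draws)", n_perm)
    }
    res <- list(p_value = p, test = test, statistic = obs)
  }
  res$n <- c(a = nrow(a), b = nrow(b))
  res$scope <- scope
  class(res) <- "curve_comparison"
  res
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat("Curve-population comparison:", x$test, "\n")
  cat("  groups n =", x$n[1], "vs", x$n[2], "; scope:", x$scope, "\n")
  cat("  p-value:", format(signif(x$p_value, 3)), "\n")
  invisible(x)
}
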