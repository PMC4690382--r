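## Incremental cleavage driver: the furrow band contracts radially by a
## small fraction each step, the mitotic spindle (when present) extends
## along the division axis, confinement constraints are applied, the linear
## elastostatic problem is solved, and the deformed surface is remeshed
## before the next increment.

#' Furrow/spindle contraction schedule
#'
#' Describes the load program of an incremental cleavage simulation: the
#' number of increments, the per-step furrow contraction factor, the furrow
#' band width at each dimensionless time point, and (optionally) the
#' pole-to-pole spindle length at each time point. Step `k` maps to
#' dimensionless time `t_k = k / n_steps`.
#'
#' @param furrow_width band width in model units: a scalar (constant width)
#'   or a vector of length `n_steps + 1` giving the width at
#'   `t = 0, 1/n, ..., 1`; `NA` entries reuse the previous value.
#' @param n_steps number of increments (default 10).
#' @param furrow_factor per-step fractional contraction of the furrow-band
#'   cylindrical radius (default 0.05, i.e., radius times 0.95 per step,
#'   compounding).
#' @param spindle_length optional vector of length `n_steps + 1` with the
#'   spindle pole separation at each time point (model units,
#'   non-decreasing); `spindle_length[1]` is the initial separation.
#' @return an object of class `contraction_schedule`.
#' @examples
#' contraction_schedule(furrow_width = 2)                  # Sk-like, constant
#' @export
contraction_schedule <- function(furrow_width, n_steps = 10,
                                 furrow_factor = 0.05,
                                 spindle_length = NULL) {
  if (!is.finite(furrow_factor) || furrow_factor < 0 || furrow_factor >= 1)
    stop("furrow_factor must lie in [0, 1)")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1) stop("n_steps must be at least 1")
  fw <- furrow_width
  if (length(fw) == 1) fw <- rep(fw, n_steps + 1)
  if (length(fw) != n_steps + 1)
    stop("furrow_width must be scalar or length n_steps + 1")
  for (i in seq_along(fw)) if (is.na(fw[i])) {
    if (i == 1) stop("furrow_width[1] must not be NA")
    fw[i] <- fw[i - 1]
  }
  if (any(fw <= 0)) stop("furrow widths must be positive")
  if (!is.null(spindle_length)) {
    if (length(spindle_length) != n_steps + 1)
      stop("spindle_length must have length n_steps + 1")
    if (any(!is.finite(spindle_length)) || any(spindle_length <= 0))
      stop("spindle lengths must be positive")
    if (any(diff(spindle_length) < -1e-9))
      stop("spindle_length must be non-decreasing")
  }
  structure(list(n_steps = n_steps, furrow_factor = furrow_factor,
                 furrow_width = fw, spindle_length = spindle_length,
                 t = seq(0, 1, length.out = n_steps + 1)),
            class = "contraction_schedule")
}

#' Vitelline confinement specification
#'
#' `free` applies no outer constraint (Neumann boundary, loose vitelline);
#' `tight_sliding` constrains every non-furrow surface node to tangential
#' motion along the vitelline sphere (`u . n = 0`, n radial);
#' `contact` applies the sliding constraint only to surface nodes currently
#' at the vitelline radius (unilateral approximation of late-phase
#' hindrance).
#'
#' @param mode one of `"free"`, `"tight_sliding"`, `"contact"`.
#' @param vitelline_radius radius of the confining sphere in model units: a
#'   scalar or a per-time-point vector (`n_steps + 1` values, dilation
#'   schedule). Defaults to the initial cell radius at simulation time.
#' @return an object of class `confinement_spec`.
#' @export
confinement_spec <- function(mode = c("free", "tight_sliding", "contact"),
                             vitelline_radius = NULL) {
  mode <- match.arg(mode)
  if (mode != "free" && !is.null(vitelline_radius) &&
      any(vitelline_radius <= 0))
    stop("vitelline_radius must be positive")
  structure(list(mode = mode, vitelline_radius = vitelline_radius),
            class = "confinement_spec")
}

## ---- internal stepping machinery -------------------------------------

## spindle: axial line element. Axis nodes with |z| <= sep/2 are stretched
## affinely so that the end separation follows the schedule.
spindle_axis_nodes <- function(mesh, sep) {
  r <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  which(r < 1e-6 & abs(mesh$nodes[, 3]) <= sep / 2 + 1e-9 &
          abs(mesh$nodes[, 3]) > 1e-9)
}

new_cleavage_state <- function(cell_radius, schedule, confinement, mat,
                               target_edge, n_theta, n_rings) {
  fw0 <- schedule$furrow_width[min(2, length(schedule$furrow_width))]
  sep0 <- if (!is.null(schedule$spindle_length)) schedule$spindle_length[1]
          else NULL
  extra <- if (!is.null(sep0)) c(-sep0 / 2, sep0 / 2) else numeric(0)
  mesh <- make_sphere_mesh(cell_radius, target_edge, fine_band = fw0 / 2,
                           extra_stations = extra, n_theta = n_theta,
                           n_rings = n_rings)
  vr <- confinement$vitelline_radius
  if (is.null(vr)) vr <- cell_radius
  if (length(vr) == 1) vr <- rep(vr, schedule$n_steps + 1)
  list(mesh = mesh, cell_radius = cell_radius,
       L0 = diff(range(mesh$nodes[mesh$surface_nodes, 3])),
       F0 = 2 * cell_radius, V0 = mesh_volume(mesh),
       sep = sep0, k = 0L, schedule = schedule, confinement = confinement,
       mat = mat, target_edge = target_edge, n_theta = n_theta,
       n_rings = n_rings, vitelline = vr)
}

## furrow (neck) diameter of a surface: interior local minimum of the ring
## radius profile within the central half of the axial extent, else the
## width at the equator (pre-furrow minor axis).
neck_diameter <- function(nodes, surface_nodes) {
  z <- nodes[surface_nodes, 3]
  r <- sqrt(nodes[surface_nodes, 1]^2 + nodes[surface_nodes, 2]^2)
  ext <- range(z); mid <- mean(ext); half <- diff(ext) / 4
  sel <- abs(z - mid) <= half
  zz <- z[sel]; rr <- r[sel]
  ord <- order(zz)
  zz <- zz[ord]; rr <- rr[ord]
  grp <- cumsum(c(TRUE, diff(zz) > 1e-6))
  prof <- tapply(rr, grp, max)             # ring radius per axial level
  if (length(prof) >= 3) {
    interior <- 2:(length(prof) - 1)
    locmin <- interior[prof[interior] <= prof[interior - 1] &
                         prof[interior] <= prof[interior + 1]]
    if (length(locmin)) return(2 * min(prof[locmin]))
  }
  pz <- tapply(zz, grp, mean)
  2 * prof[which.min(abs(pz - mid))]
}

## Build the elastostatic operator of increment k (band Dirichlet + spindle
## + confinement structure); returns a context whose $eval(sl) solves with a
## trial spindle separation without re-factorising.
step_context <- function(state, fw, factor = NULL) {
  mesh <- tag_regions(state$mesh, fw)
  band <- mesh$tags$furrow_band
  if (is.null(factor)) factor <- state$schedule$furrow_factor
  shrink <- -factor
  dirich <- list(list(nodes = band,
                      value = cbind(shrink * mesh$nodes[band, 1],
                                    shrink * mesh$nodes[band, 2], 0)))
  ax <- if (!is.null(state$sep)) spindle_axis_nodes(mesh, state$sep)
        else integer(0)
  mk_bc <- function(sl) {
    direc <- list()
    if (length(ax) && !is.null(sl)) {
      vals <- mesh$nodes[ax, 3] * (sl / state$sep - 1)
      direc <- list(list(nodes = ax,
                         dirs = matrix(c(0, 0, 1), length(ax), 3,
                                       byrow = TRUE),
                         values = vals))
    }
    cm <- state$confinement$mode
    if (cm %in% c("tight_sliding", "contact")) {
      rv <- state$vitelline[state$k + 1L]
      sn <- setdiff(mesh$surface_nodes, band)
      if (cm == "contact") {
        rad <- sqrt(rowSums(mesh$nodes[sn, , drop = FALSE]^2))
        sn <- sn[rad >= rv * (1 - 1e-3)]
      }
      if (length(sn)) {
        nrm <- mesh$nodes[sn, , drop = FALSE]
        nrm <- nrm / sqrt(rowSums(nrm^2))
        direc <- c(direc, list(list(nodes = sn, dirs = nrm, values = 0)))
      }
    }
    boundary_spec(dirich, direc)
  }
  op <- elastic_operator(mesh, state$mat, mk_bc(state$sep))
  eval_sl <- function(sl = state$sep) {
    f <- op$solve(mk_bc(sl))
    def <- mesh$nodes + f$u
    list(field = f,
         L = diff(range(def[mesh$surface_nodes, 3])),
         neck = neck_diameter(def, mesh$surface_nodes),
         W = strain_energy(f))
  }
  list(mesh = mesh, band = band, eval = eval_sl)
}

## Commit an increment: deform, measure, remesh (volume preserving; clamped
## to the vitelline sphere under tight sliding).
step_commit <- function(state, ctx, res, sl = state$sep) {
  mesh <- ctx$mesh
  def <- mesh$nodes + res$field$u
  dvol <- deformed_volume(mesh, res$field)  # errors on inverted elements
  surf <- extract_boundary(mesh)
  surf$nodes <- def[mesh$surface_nodes, , drop = FALSE]
  k_next <- state$k + 1L
  fw_next <- state$schedule$furrow_width[min(k_next + 2L,
                                             state$schedule$n_steps + 1L)]
  extra <- if (!is.null(sl)) c(-sl / 2, sl / 2) else numeric(0)
  newmesh <- remesh_from_surface(surf, target_edge = state$target_edge,
                                 fine_band = fw_next / 2,
                                 extra_stations = extra,
                                 n_theta = state$n_theta,
                                 n_rings = state$n_rings)
  if (state$confinement$mode == "tight_sliding") {
    rv <- state$vitelline[min(k_next + 1L, length(state$vitelline))]
    newmesh <- clamp_to_sphere(newmesh, rv)
  }
  if (state$confinement$mode == "contact") {
    rv <- state$vitelline[min(k_next + 1L, length(state$vitelline))]
    rad <- sqrt(rowSums(newmesh$nodes^2))
    out <- rad > rv
    if (any(out))
      newmesh$nodes[out, ] <- newmesh$nodes[out, ] * (rv / rad[out])
  }
  state$mesh <- newmesh
  state$sep <- sl
  state$k <- k_next
  state
}

## scale radial columns of a revolution mesh so no surface station exceeds
## the confining sphere
clamp_to_sphere <- function(mesh, radius) {
  r <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  z <- mesh$nodes[, 3]
  for (st in unique(mesh$surface_info$station)) {
    srow <- mesh$surface_info$node[mesh$surface_info$station == st]
    ro <- mean(r[srow]); zo <- mean(z[srow])
    rv2 <- radius^2 - zo^2
    if (rv2 <= 0) next
    rv <- sqrt(rv2)
    if (ro > rv) {
      cols <- which(abs(z - zo) < 1e-9)
      mesh$nodes[cols, 1:2] <- mesh$nodes[cols, 1:2] * (rv / ro)
    }
  }
  mesh
}

#' Simulate the first embryonic cleavage
#'
#' Runs the incremental contractile-ring simulation: at each of the
#' `n_steps` increments the furrow band (surface nodes with
#' `|z| <= FW(t_k)/2`) is contracted radially by the schedule's furrow
#' factor, the spindle (if present) is extended to its scheduled
#' pole-to-pole separation, confinement constraints are applied, the
#' elastostatic problem is solved, polar length and furrow diameter are
#' measured on the deformed boundary, and the surface is remeshed.
#'
#' @param schedule a [contraction_schedule()] (model units).
#' @param confinement a [confinement_spec()]; default free boundary.
#' @param mat an [material()]; default homogeneous near-incompressible.
#' @param cell_radius initial cell radius in model units (default 50, i.e.,
#'   cross-section 100).
#' @param target_edge mesh edge length; default `cell_radius / 10`.
#' @param n_theta angular mesh resolution (the problem is axisymmetric, so
#'   a moderate angular resolution suffices; default 16).
#' @param n_rings radial rings per disk (default derived from
#'   `target_edge`).
#' @param keep_meshes retain the per-step meshes in the result.
#' @return an object of class `cleavage_sim` with `$curves` (data.frame
#'   with columns `t`, `L_n`, `F_n`, `W`), `$total_energy`, `$volume_drift`
#'   (relative volume change over the run), and the run parameters.
#' @examples
#' \donttest{
#' sk <- simulate_cleavage(contraction_schedule(furrow_width = 2),
#'                         target_edge = 10)
#' sk$curves
#' }
#' @export
simulate_cleavage <- function(schedule,
                              confinement = confinement_spec("free"),
                              mat = material(),
                              cell_radius = 50,
                              target_edge = cell_radius / 10,
                              n_theta = 16, n_rings = NULL,
                              keep_meshes = FALSE) {
  stopifnot(inherits(schedule, "contraction_schedule"),
            inherits(confinement, "confinement_spec"),
            inherits(mat, "elastic_material"))
  state <- new_cleavage_state(cell_radius, schedule, confinement, mat,
                              target_edge, n_theta, n_rings)
  n <- schedule$n_steps
  L_n <- c(1, numeric(n)); F_n <- c(1, numeric(n)); W <- numeric(n)
  meshes <- if (keep_meshes) vector("list", n + 1) else NULL
  if (keep_meshes) meshes[[1]] <- state$mesh
  for (k in seq_len(n)) {
    fw <- schedule$furrow_width[k + 1]
    sl <- if (!is.null(schedule$spindle_length)) schedule$spindle_length[k + 1]
          else NULL
    ctx <- tryCatch(step_context(state, fw),
                    error = function(e)
                      stop("increment ", k, " failed: ",
                           conditionMessage(e), call. = FALSE))
    res <- ctx$eval(sl)
    W[k] <- res$W
    L_n[k + 1] <- res$L / state$L0
    F_n[k + 1] <- res$neck / state$F0
    state <- tryCatch(step_commit(state, ctx, res, sl),
                      error = function(e)
                        stop("remeshing after increment ", k, " failed (",
                             k - 1L, " increments completed): ",
                             conditionMessage(e), call. = FALSE))
    if (keep_meshes) meshes[[k + 1]] <- state$mesh
  }
  structure(list(curves = data.frame(t = schedule$t, L_n = L_n, F_n = F_n,
                                     W = c(NA, W)),
                 total_energy = sum(W),
                 volume_drift = mesh_volume(state$mesh) / state$V0 - 1,
                 schedule = schedule, confinement = confinement, mat = mat,
                 cell_radius = cell_radius, target_edge = target_edge,
                 n_theta = n_theta, meshes = meshes,
                 final_mesh = state$mesh),
            class = "cleavage_sim")
}

#' Mechanical energy ratio of two cleavage runs
#'
#' Ratio of the total accumulated strain energy (sum of the per-increment
#' energies) between two simulations, typically a vitelline-confined and a
#' free-boundary run with otherwise identical parameters.
#'
#' @param confined,free `cleavage_sim` objects.
#' @return `sum(W_confined) / sum(W_free)`.
#' @export
energy_ratio <- function(confined, free) {
  stopifnot(inherits(confined, "cleavage_sim"), inherits(free, "cleavage_sim"))
  if (free$total_energy <= 0)
    stop("free run has zero strain energy; ratio undefined")
  confined$total_energy / free$total_energy
}

#' Furrow-width / stiffness-gradient sensitivity scan
#'
#' Simulates the polar elongation produced by an initial 10% contraction of
#' the cleavage furrow over a grid of furrow widths and
#' equatorial-to-polar stiffness ratios (single increment, free boundary).
#' The two printed interpretations of a "10% furrow contraction" are
#' supported: `"area"` contracts the furrow cross-sectional area by the
#' given fraction (radius factor `sqrt(1 - contraction)`), `"radius"`
#' contracts the band radius itself.
#'
#' @param fw_um furrow widths in micrometres (default 4, 8, 16, 20).
#' @param log_ratios decimal log of the equatorial-to-polar stiffness ratio
#'   (default 9 points in `[-2, 2]`).
#' @param cell_um cell cross-section in micrometres (default 400).
#' @param contraction contracted fraction (default 0.10).
#' @param semantics `"area"` (default) or `"radius"`; see Details.
#' @param poisson_ratio,stabilize material options passed to [material()].
#' @param cell_radius,target_edge,n_theta mesh options as in
#'   [simulate_cleavage()].
#' @return an object of class `sensitivity_scan`: a data.frame with columns
#'   `fw_um`, `log_ratio`, `elongation_pct` (`NA` with a diagnostic message
#'   for grid cells that fail to solve), plus the grid as a matrix
#'   attribute.
#' @export
sensitivity_scan <- function(fw_um = c(4, 8, 16, 20),
                             log_ratios = seq(-2, 2, length.out = 9),
                             cell_um = 400, contraction = 0.10,
                             semantics = c("area", "radius"),
                             poisson_ratio = 0.499, stabilize = FALSE,
                             cell_radius = 50,
                             target_edge = cell_radius / 10, n_theta = 16) {
  semantics <- match.arg(semantics)
  factor <- if (semantics == "area") sqrt(1 - contraction) else 1 - contraction
  scale_f <- 2 * cell_radius / cell_um    # model units per um
  grid <- matrix(NA_real_, length(fw_um), length(log_ratios),
                 dimnames = list(paste0(fw_um, "um"),
                                 sprintf("%+.2f", log_ratios)))
  notes <- character(0)
  for (i in seq_along(fw_um)) {
    fw <- fw_um[i] * scale_f
    mesh <- make_sphere_mesh(cell_radius, target_edge, fine_band = fw / 2,
                             n_theta = n_theta)
    mesh <- tag_regions(mesh, fw)
    band <- mesh$tags$furrow_band
    L0 <- diff(range(mesh$nodes[mesh$surface_nodes, 3]))
    bc <- boundary_spec(dirichlet = list(list(
      nodes = band,
      value = cbind((factor - 1) * mesh$nodes[band, 1],
                    (factor - 1) * mesh$nodes[band, 2], 0))))
    for (j in seq_along(log_ratios)) {
      mt <- material(1, poisson_ratio,
                     equatorial_modulus = 10^log_ratios[j],
                     equatorial_halfwidth = fw / 2, stabilize = stabilize)
      res <- tryCatch({
        f <- solve_elastostatic(mesh, mt, bc)
        def <- mesh$nodes + f$u
        100 * (diff(range(def[mesh$surface_nodes, 3])) / L0 - 1)
      }, error = function(e) {
        notes <<- c(notes, sprintf("FW %g um, log ratio %g: %s", fw_um[i],
                                   log_ratios[j], conditionMessage(e)))
        NA_real_
      })
      grid[i, j] <- res
    }
  }
  df <- data.frame(fw_um = rep(fw_um, times = length(log_ratios)),
                   log_ratio = rep(log_ratios, each = length(fw_um)),
                   elongation_pct = as.vector(grid))
  structure(df, grid = grid, failures = notes, semantics = semantics,
            class = c("sensitivity_scan", "data.frame"))
}

## ---- methods ----------------------------------------------------------

#' @export
print.cleavage_sim <- function(x, ...) {
  cat("Incremental cleavage simulation (", x$schedule$n_steps, " steps, ",
      x$confinement$mode, " boundary)\n", sep = "")
  cat("  final polar elongation L_n(1) =",
      format(round(x$curves$L_n[nrow(x$curves)], 4)), "\n")
  cat("  total strain energy =", format(signif(x$total_energy, 5)),
      "  volume drift =", sprintf("%+.2f%%", 100 * x$volume_drift), "\n")
  invisible(x)
}

#' @export
summary.cleavage_sim <- function(object, ...) {
  cat("Cleavage simulation summary\n")
  cat("  boundary mode:", object$confinement$mode, "\n")
  cat("  cell radius:", object$cell_radius, "model units;  mesh edge:",
      object$target_edge, "\n")
  print(round(object$curves, 4))
  invisible(object$curves)
}

#' @export
plot.cleavage_sim <- function(x, which = c("elongation", "energy"), ...) {
  which <- match.arg(which)
  if (which == "elongation") {
    graphics::plot(x$curves$t, x$curves$L_n, type = "b", pch = 16,
                   xlab = "dimensionless cleavage time t",
                   ylab = expression(L[n](t)), ...)
    graphics::lines(x$curves$t, x$curves$F_n, type = "b", pch = 1, lty = 2)
    graphics::legend("topleft", legend = c("polar length", "furrow"),
                     pch = c(16, 1), lty = c(1, 2), bty = "n")
  } else {
    graphics::barplot(x$curves$W[-1], names.arg = x$curves$t[-1],
                      xlab = "t", ylab = "incremental strain energy", ...)
  }
  invisible(x)
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  g <- attr(x, "grid")
  cat("Sensitivity scan (", attr(x, "semantics"),
      " contraction semantics): relative elongation %\n", sep = "")
  print(round(g, 2))
  cat("range: [", round(min(g, na.rm = TRUE), 2), ",",
      round(max(g, na.rm = TRUE), 2), "] %\n")
  if (length(attr(x, "failures")))
    cat("failed cells:\n ", paste(attr(x, "failures"), collapse = "\n  "),
        "\n")
  invisible(x)
}
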