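## Fixtures, tabular/mesh readers-writers and configuration support shared
## by all modules.

#' Packaged elongation and schedule tables
#'
#' Returns the packaged reference tables: `elongation`, the relative polar
#' elongation `L_n(t)` of the measured and simulated cell populations on
#' the dimensionless time grid (columns: two incubation temperatures of
#' the large acorn-worm eggs, their average, the spindle-free FE
#' simulation, the small sea-urchin egg data and its FE fit), and
#' `schedules`, the fitted per-step furrow width and spindle length of the
#' small-egg model in micrometres (the furrow width at t = 1 is not
#' reported and is `NA`; simulations reuse the t = 0.9 value).
#'
#' @return list of two data.frames, `elongation` and `schedules`.
#' @examples
#' elongation_tables()$schedules
#' @export
elongation_tables <- function() {
  path <- system.file("extdata", package = "cytomech")
  list(elongation = utils::read.csv(file.path(path, "elongation_table.csv")),
       schedules = utils::read.csv(file.path(path,
                                             "furrow_spindle_table.csv")))
}

#' Build the small-egg (100 um cell) schedule from the packaged table
#'
#' Converts the packaged furrow-width/spindle-length schedule to model
#' units and wraps it in a [contraction_schedule()].
#'
#' @param cell_um cell cross-section in micrometres (default 100).
#' @param model_cross_section model cross-section (default 100).
#' @return a `contraction_schedule`.
#' @export
cj_schedule <- function(cell_um = 100, model_cross_section = 100) {
  tab <- elongation_tables()$schedules
  f <- model_cross_section / cell_um
  contraction_schedule(furrow_width = tab$furrow_width_um * f,
                       n_steps = nrow(tab) - 1L,
                       spindle_length = tab$spindle_length_um * f)
}

## ---- curve CSV round trip ---------------------------------------------

#' Write / read simulation curves as CSV
#'
#' Plain CSV (header row, period decimal separator, UTF-8) with the
#' dimensionless time column named `t`. The reader returns bit-identical
#' values for files produced by the writer.
#'
#' @param curves a data.frame with a `t` column.
#' @param file path.
#' @return `read_curves` returns the data.frame.
#' @export
write_curves <- function(curves, file) {
  utils::write.csv(curves, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_curves
#' @export
read_curves <- function(file) {
  utils::read.csv(file, fileEncoding = "UTF-8")
}

## ---- mask stacks (TIFF) -----------------------------------------------

#' Write / read binary mask stacks as multi-page TIFF
#'
#' @param masks list of logical/0-1 matrices (one frame each).
#' @param file path to the TIFF file.
#' @return `read_mask_stack` returns a list of logical matrices.
#' @export
write_mask_stack <- function(masks, file) {
  imgs <- lapply(masks, function(m) {
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(imgs, file, bits.per.sample = 8L, compression = "none")
  invisible(file)
}

#' @rdname write_mask_stack
#' @export
read_mask_stack <- function(file) {
  imgs <- tiff::readTIFF(file, all = TRUE)
  lapply(imgs, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    m > 0.5
  })
}

## ---- mesh formats -----------------------------------------------------

#' Export a surface mesh as OFF or STL (ASCII)
#'
#' @param surface a `surface_mesh` (see [extract_boundary()]).
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_off <- function(surface, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(surface$nodes), nrow(surface$tris)),
             con)
  utils::write.table(format(surface$nodes, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, surface$tris - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an ASCII OFF surface file
#' @param file path.
#' @return a `surface_mesh`.
#' @export
read_off <- function(file) {
  ln <- readLines(file)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (ln[1] != "OFF") stop("not an OFF file")
  hd <- as.integer(strsplit(ln[2], "\\s+")[[1]])
  nv <- hd[1]; nf <- hd[2]
  nodes <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s)
    as.numeric(strsplit(s, "\\s+")[[1]][1:3])))
  tris <- do.call(rbind, lapply(ln[(3 + nv):(2 + nv + nf)], function(s) {
    v <- as.integer(strsplit(s, "\\s+")[[1]])
    if (v[1] != 3L) stop("only triangular faces are supported")
    v[2:4] + 1L
  }))
  structure(list(nodes = nodes, tris = tris, info = NULL),
            class = "surface_mesh")
}

#' @rdname write_off
#' @export
write_stl <- function(surface, file) {
  con <- file(file, "w"); on.exit(close(con))
  a <- surface$nodes[surface$tris[, 1], , drop = FALSE]
  b <- surface$nodes[surface$tris[, 2], , drop = FALSE]
  c3 <- surface$nodes[surface$tris[, 3], , drop = FALSE]
  nrm <- cbind((b[, 2] - a[, 2]) * (c3[, 3] - a[, 3]) -
                 (b[, 3] - a[, 3]) * (c3[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (c3[, 1] - a[, 1]) -
                 (b[, 1] - a[, 1]) * (c3[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) -
                 (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1]))
  nn <- sqrt(rowSums(nrm^2)); nn[nn == 0] <- 1
  nrm <- nrm / nn
  writeLines("solid surface", con)
  for (i in seq_len(nrow(surface$tris))) {
    writeLines(sprintf("  facet normal %g %g %g", nrm[i, 1], nrm[i, 2],
                       nrm[i, 3]), con)
    writeLines("    outer loop", con)
    writeLines(sprintf("      vertex %g %g %g", c(a[i, 1], b[i, 1], c3[i, 1]),
                       c(a[i, 2], b[i, 2], c3[i, 2]),
                       c(a[i, 3], b[i, 3], c3[i, 3])), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid surface", con)
  invisible(file)
}

#' Read an ASCII STL surface file
#' @param file path.
#' @param tol vertices closer than this are merged.
#' @return a `surface_mesh`.
#' @export
read_stl <- function(file, tol = 1e-9) {
  ln <- readLines(file)
  vx <- grep("^\\s*vertex", ln, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(v)
    as.numeric(v[2:4])))
  key <- apply(round(xyz / max(tol, 1e-12)), 1, paste, collapse = "_")
  uid <- !duplicated(key)
  nodes <- xyz[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  structure(list(nodes = nodes, tris = tris, info = NULL),
            class = "surface_mesh")
}

#' Export a volume mesh (with optional fields) as legacy ASCII VTK
#'
#' Writes the tetrahedral mesh as an unstructured grid; region tags are
#' written as point data, and per-node / per-element fields can be added
#' for visual inspection of displacement, strain or energy density.
#'
#' @param mesh a `volume_mesh`.
#' @param file output path.
#' @param point_data named list of per-node scalars or n x 3 vectors.
#' @param cell_data named list of per-element scalars.
#' @return the path, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  con <- file(file, "w"); on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "cytomech mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  utils::write.table(format(mesh$nodes, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  ## region tags as point data
  tagv <- numeric(n)
  if (length(mesh$tags)) {
    if (!is.null(mesh$tags$furrow_band)) tagv[mesh$tags$furrow_band] <- 1
    if (!is.null(mesh$tags$anchor_plus)) tagv[mesh$tags$anchor_plus] <- 2
    if (!is.null(mesh$tags$anchor_minus)) tagv[mesh$tags$anchor_minus] <- 3
  }
  point_data <- c(list(region_tag = tagv), point_data)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (is.matrix(v) && ncol(v) == 3) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      utils::write.table(format(v, digits = 10, trim = TRUE), con,
                         row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(v), digits = 10, trim = TRUE), con)
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(cell_data[[nm]]), digits = 10,
                        trim = TRUE), con)
    }
  }
  invisible(file)
}

## ---- configuration ----------------------------------------------------

sim_config_keys <- c("cell_cross_section_um", "model_cross_section",
                     "furrow_width_um", "spindle_length_um", "target_edge",
                     "mesh_seed", "n_steps", "furrow_factor", "boundary",
                     "vitelline_radius_um", "poisson_ratio", "n_theta")

#' Read and validate a simulation configuration
#'
#' Flat YAML configuration with the keys named in the module interfaces
#' (`cell_cross_section_um`, `model_cross_section`, `furrow_width_um`,
#' `spindle_length_um`, `target_edge`, `mesh_seed`, `n_steps`,
#' `furrow_factor`, `boundary`, `vitelline_radius_um`, `poisson_ratio`,
#' `n_theta`). Unknown keys are rejected.
#'
#' @param file path to a YAML file, or a named list.
#' @return validated named list.
#' @export
read_sim_config <- function(file) {
  cfg <- if (is.list(file)) file else yaml::read_yaml(file)
  unknown <- setdiff(names(cfg), sim_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$cell_cross_section_um))
    stop("cell_cross_section_um is required")
  if (is.null(cfg$furrow_width_um)) stop("furrow_width_um is required")
  cfg
}

#' Run a cleavage simulation from a configuration
#'
#' Convenience wrapper: converts the configured physical dimensions to
#' model units, builds the schedule and confinement, and calls
#' [simulate_cleavage()].
#'
#' @param config path to a YAML file or a named list (see
#'   [read_sim_config()]).
#' @return a `cleavage_sim` object.
#' @export
simulate_from_config <- function(config) {
  cfg <- read_sim_config(config)
  mcs <- cfg$model_cross_section %||% 100
  f <- mcs / cfg$cell_cross_section_um
  n_steps <- cfg$n_steps %||% 10
  sched <- contraction_schedule(
    furrow_width = cfg$furrow_width_um * f, n_steps = n_steps,
    furrow_factor = cfg$furrow_factor %||% 0.05,
    spindle_length = if (!is.null(cfg$spindle_length_um))
      cfg$spindle_length_um * f)
  conf <- confinement_spec(cfg$boundary %||% "free",
                           vitelline_radius =
                             if (!is.null(cfg$vitelline_radius_um))
                               cfg$vitelline_radius_um * f / 2)
  radius <- mcs / 2
  simulate_cleavage(sched, conf,
                    mat = material(poisson_ratio =
                                     cfg$poisson_ratio %||% 0.499),
                    cell_radius = radius,
                    target_edge = cfg$target_edge %||% (radius / 10),
                    n_theta = cfg$n_theta %||% 16)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
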