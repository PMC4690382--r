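#' Physical dimensions of a dividing egg cell
#'
#' Bundles the geometric quantities of a real cell (in micrometres) that the
#' simulator needs: the cell cross-section (diameter), the cleavage-furrow
#' width and, optionally, the mitotic spindle length and the vitelline
#' membrane cross-section.
#'
#' @param cell_cross_section_um Cell cross-section (diameter), micrometres.
#' @param furrow_width_um Width of the equatorial cleavage-furrow band,
#'   micrometres. Must be smaller than the cell cross-section.
#' @param spindle_length_um Optional pole-to-pole mitotic spindle length,
#'   micrometres.
#' @param vitelline_cross_section_um Optional vitelline membrane
#'   cross-section (diameter), micrometres.
#' @return An object of class `physical_dims`.
#' @examples
#' physical_dims(400, 8, spindle_length_um = 60)
#' @export
physical_dims <- function(cell_cross_section_um, furrow_width_um,
                          spindle_length_um = NULL,
                          vitelline_cross_section_um = NULL) {
  vals <- c(cell = cell_cross_section_um, furrow = furrow_width_um,
            spindle = spindle_length_um, vitelline = vitelline_cross_section_um)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical dimensions must be positive and finite")
  if (furrow_width_um >= cell_cross_section_um)
    stop("furrow_width_um must be smaller than cell_cross_section_um")
  structure(list(cell_cross_section_um = cell_cross_section_um,
                 furrow_width_um = furrow_width_um,
                 spindle_length_um = spindle_length_um,
                 vitelline_cross_section_um = vitelline_cross_section_um),
            class = "physical_dims")
}

#' Dimensionless model scale
#'
#' The virtual cell model is dimensionless; all physical lengths are mapped
#' so that the cell cross-section equals `model_cross_section` model units
#' (default 100). Relative proportions are preserved exactly.
#'
#' @param model_cross_section Cross-section of the virtual model in model
#'   units; default 100.
#' @return An object of class `model_scale`.
#' @export
model_scale <- function(model_cross_section = 100) {
  if (!is.finite(model_cross_section) || model_cross_section <= 0)
    stop("model_cross_section must be positive")
  structure(list(model_cross_section = model_cross_section),
            class = "model_scale")
}

#' Convert physical dimensions to dimensionless model units
#'
#' Each length is multiplied by `model_cross_section / cell_cross_section_um`,
#' so the cell cross-section maps to the model cross-section and all
#' proportions are preserved. A 400 um cell with an 8 um furrow and a 60 um
#' spindle maps, at the default scale, to (100, 2, 15).
#'
#' @param dims A [physical_dims()] object.
#' @param scale A [model_scale()] object.
#' @return A list with the converted lengths `cell_cross_section`,
#'   `furrow_width`, and (when given) `spindle_length`,
#'   `vitelline_cross_section`, plus `um_per_unit`, the micrometres per model
#'   unit.
#' @examples
#' to_model_units(physical_dims(400, 8, 60))
#' @export
to_model_units <- function(dims, scale = model_scale()) {
  stopifnot(inherits(dims, "physical_dims"), inherits(scale, "model_scale"))
  f <- scale$model_cross_section / dims$cell_cross_section_um
  out <- list(cell_cross_section = dims$cell_cross_section_um * f,
              furrow_width = dims$furrow_width_um * f)
  if (!is.null(dims$spindle_length_um))
    out$spindle_length <- dims$spindle_length_um * f
  if (!is.null(dims$vitelline_cross_section_um))
    out$vitelline_cross_section <- dims$vitelline_cross_section_um * f
  out$um_per_unit <- 1 / f
  out
}

#' @export
print.physical_dims <- function(x, ...) {
  cat("Physical cell dimensions (um):\n")
  cat("  cell cross-section:", x$cell_cross_section_um, "\n")
  cat("  furrow width:      ", x$furrow_width_um, "\n")
  if (!is.null(x$spindle_length_um))
    cat("  spindle length:    ", x$spindle_length_um, "\n")
  if (!is.null(x$vitelline_cross_section_um))
    cat("  vitelline:         ", x$vitelline_cross_section_um, "\n")
  invisible(x)
}
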