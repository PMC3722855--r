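#' Specimen geometry
#'
#' Describes a shear-test specimen: a cylinder (the tested brain samples,
#' nominally 18 mm diameter x 12 mm height) or a square-section prism
#' ("cube") whose side defaults to the value matching the cross-sectional
#' area of the reference cylinder, \eqn{s = \sqrt{\pi d^2/4}}.
#'
#' @param shape `"cylinder"` or `"cube"`.
#' @param height Specimen height (m). Default 0.012.
#' @param diameter Cylinder diameter (m). Default 0.018. For a cube this is
#'   the reference-cylinder diameter used to derive `side` when `side` is not
#'   given.
#' @param side Cube side length (m); if `NULL` (default) it is derived from
#'   `diameter` by area matching.
#' @return An object of class `specimen_geometry` with fields `shape`,
#'   `height`, `diameter` or `side`, and the derived cross-sectional `area`
#'   (m^2).
#' @examples
#' specimen_geometry()                  # default cylinder
#' specimen_geometry("cube")$side      # ~15.95 mm, area-matched
#' @export
specimen_geometry <- function(shape = c("cylinder", "cube"), height = 0.012,
                              diameter = 0.018, side = NULL) {
  shape <- match.arg(shape)
  if (height <= 0) stop("`height` must be positive.")
  if (shape == "cylinder") {
    if (is.null(diameter) || diameter <= 0) stop("`diameter` must be positive.")
    out <- list(shape = shape, height = height, diameter = diameter,
                area = pi * diameter^2 / 4)
  } else {
    if (is.null(side)) side <- sqrt(pi * diameter^2 / 4)
    if (side <= 0) stop("`side` must be positive.")
    out <- list(shape = shape, height = height, side = side, area = side^2)
  }
  structure(out, class = "specimen_geometry")
}

#' @export
print.specimen_geometry <- function(x, ...) {
  dim_str <- if (x$shape == "cylinder") {
    sprintf("diameter %.4g mm", 1e3 * x$diameter)
  } else {
    sprintf("side %.4g mm", 1e3 * x$side)
  }
  cat(sprintf("<specimen_geometry> %s, height %.4g mm, %s, area %.4g mm^2\n",
              x$shape, 1e3 * x$height, dim_str, 1e6 * x$area))
  invisible(x)
}

#' Rescale specimen height
#'
#' Returns the same geometry with height scaled by `factor`, keeping the
#' cross-section unchanged (the height-sensitivity protocol: height reduced
#' to 0.7 h at constant cross-sectional area).
#'
#' @param geometry A [specimen_geometry()].
#' @param factor Positive height multiplier.
#' @export
scale_height <- function(geometry, factor) {
  stopifnot(inherits(geometry, "specimen_geometry"), factor > 0)
  geometry$height <- geometry$height * factor
  geometry
}
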