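#' Pixel-to-micrometre calibration
#'
#' The microscope/camera chain is calibrated with a stage micrometer, giving a
#' single conversion ratio between image pixels and physical micrometres. The
#' default (0.30 +/- 0.001 um/pixel) is the ratio measured for the reference
#' imaging configuration this package models.
#'
#' @param ratio Conversion ratio in um per pixel. Must be > 0.
#' @param ratio_sd Standard deviation of the calibration ratio (um/pixel),
#'   retained as metadata; the conversion itself uses `ratio`.
#' @return An object of class `calibration`.
#' @examples
#' cal <- calibration()
#' px_to_um(10, cal)
#' @export
calibration <- function(ratio = 0.30, ratio_sd = 0.001) {
  stopifnot(is.numeric(ratio), length(ratio) == 1L, is.finite(ratio))
  if (ratio <= 0) abort("`ratio` must be > 0.")
  structure(list(ratio = ratio, ratio_sd = ratio_sd), class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.4g +/- %.2g um/pixel\n", x$ratio, x$ratio_sd))
  invisible(x)
}

#' Convert pixel lengths to micrometres
#'
#' @param length_px Numeric vector of lengths in pixels; must be >= 0.
#' @param cal A [calibration()] object.
#' @return Lengths in micrometres (`length_px * ratio`).
#' @export
px_to_um <- function(length_px, cal = calibration()) {
  stopifnot(inherits(cal, "calibration"), is.numeric(length_px))
  if (any(length_px < 0, na.rm = TRUE)) {
    abort("Pixel lengths must be non-negative.")
  }
  length_px * cal$ratio
}

#' Estimate cell volume from a 2D detection
#'
#' A single focal plane gives only the projected outline of a cell, so a
#' 2D-to-3D rule is required. Two conventions are supported:
#'
#' * `"spheroid"` (default): the cell is a prolate spheroid whose projection
#'   is the fitted ellipse, `V = (4/3) * pi * (L/2) * (W/2)^2` with `L`, `W`
#'   the calibrated major and minor axes. This suits elongated cells such as
#'   *Scenedesmus*.
#' * `"equivalent_sphere"`: a sphere with the same projected area,
#'   `V = (4/3) * pi * r^3`, `r = sqrt(area / pi)` calibrated.
#'
#' The two rules agree exactly when the projection is a circle (`L == W`).
#'
#' @param major_px,minor_px Full ellipse axes in pixels.
#' @param area_px2 Projected area in square pixels (used by the
#'   equivalent-sphere model; defaults to the ellipse area
#'   `pi * (L/2) * (W/2)`).
#' @param cal A [calibration()] object.
#' @param model Volume model, `"spheroid"` or `"equivalent_sphere"`.
#' @return Volumes in cubic micrometres.
#' @examples
#' estimate_volume(20, 10, cal = calibration(0.30))         # ~28.27 um^3
#' estimate_volume(20, 20, model = "equivalent_sphere")     # sphere, r = 3 um
#' @export
estimate_volume <- function(major_px, minor_px,
                            area_px2 = pi * (major_px / 2) * (minor_px / 2),
                            cal = calibration(),
                            model = c("spheroid", "equivalent_sphere")) {
  model <- arg_match(model)
  stopifnot(is.numeric(major_px), is.numeric(minor_px))
  if (any(minor_px <= 0, na.rm = TRUE)) {
    abort("Degenerate ellipse: minor axis must be > 0.")
  }
  if (any(major_px < minor_px, na.rm = TRUE)) {
    abort("Major axis must be >= minor axis.")
  }
  if (model == "spheroid") {
    L <- px_to_um(major_px, cal)
    W <- px_to_um(minor_px, cal)
    (4 / 3) * pi * (L / 2) * (W / 2)^2
  } else {
    r_um <- px_to_um(sqrt(area_px2 / pi), cal)
    (4 / 3) * pi * r_um^3
  }
}

#' Invert the volume model: ellipse semi-axes drawing a given volume
#'
#' Used by the synthetic renderer so that measuring a noise-free rendered cell
#' returns the generating volume by construction. For the spheroid model with
#' projected aspect ratio `q = b/a`, `V = (4/3) * pi * q^2 * a^3 * ratio^3`;
#' for the equivalent-sphere model the semi-axes preserve projected area.
#'
#' @param volume_um3 Target volume(s), um^3 (> 0).
#' @param aspect Minor/major semi-axis ratio in (0, 1].
#' @inheritParams estimate_volume
#' @return A list with numeric vectors `a_px` (semi-major) and `b_px`
#'   (semi-minor), in pixels.
#' @export
axes_from_volume <- function(volume_um3, aspect = 0.6, cal = calibration(),
                             model = c("spheroid", "equivalent_sphere")) {
  model <- arg_match(model)
  stopifnot(is.numeric(volume_um3), aspect > 0, aspect <= 1)
  if (any(volume_um3 <= 0, na.rm = TRUE)) abort("Volumes must be > 0.")
  r <- cal$ratio
  if (model == "spheroid") {
    a_um <- (3 * volume_um3 / (4 * pi * aspect^2))^(1 / 3)
    a_px <- a_um / r
  } else {
    r_eq_um <- (3 * volume_um3 / (4 * pi))^(1 / 3)
    a_px <- r_eq_um / (r * sqrt(aspect))
  }
  list(a_px = a_px, b_px = aspect * a_px)
}

#' Convert pixel detections to physical cell measurements
#'
#' Takes a detections table (as produced by [extract_cells()]) and appends
#' calibrated sizes: major/minor axes (um), projected area (um^2) and volume
#' (um^3) under the chosen 2D-to-3D model.
#'
#' @param detections A data frame with columns `major_px`, `minor_px`,
#'   `area_px2`.
#' @inheritParams estimate_volume
#' @return The input as a tibble with added columns `major_um`, `minor_um`,
#'   `area_um2`, `volume_um3`.
#' @export
measure_cells <- function(detections, cal = calibration(),
                          model = c("spheroid", "equivalent_sphere")) {
  model <- arg_match(model)
  stopifnot(is.data.frame(detections))
  need <- c("major_px", "minor_px", "area_px2")
  if (!all(need %in% names(detections))) {
    abort(paste0("`detections` must have columns: ",
                 paste(need, collapse = ", ")))
  }
  as_tibble(detections) |>
    mutate(
      major_um = px_to_um(.data$major_px, cal),
      minor_um = px_to_um(.data$minor_px, cal),
      area_um2 = .data$area_px2 * cal$ratio^2,
      volume_um3 = estimate_volume(.data$major_px, .data$minor_px,
                                   .data$area_px2, cal = cal, model = model)
    )
}
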