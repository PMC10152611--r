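#' Pixel-metric calibration
#'
#' A pixel pitch relating image pixels to millimetres at a given reference
#' height above the cultivation surface. Because the camera is not
#' telecentric, the pitch depends on object height; calibrations at different
#' heights are kept as independent objects and never interpolated.
#'
#' @param pixels_per_mm Pixels per millimetre (> 0).
#' @param reference_height_mm Object height (mm) at which the pitch was
#'   measured, e.g. 20 for the medium surface or 41 for a reference block.
#' @return An object of class `pixel_metric`.
#' @examples
#' pm <- pixel_metric(46.7, reference_height_mm = 41)
#' px_to_mm(pm, 10.9)
#' @export
pixel_metric <- function(pixels_per_mm, reference_height_mm = 0) {
  stopifnot(is.numeric(pixels_per_mm), length(pixels_per_mm) == 1L,
            is.finite(pixels_per_mm), pixels_per_mm > 0)
  structure(list(pixels_per_mm = pixels_per_mm,
                 reference_height_mm = reference_height_mm),
            class = "pixel_metric")
}

#' @export
print.pixel_metric <- function(x, ...) {
  cat(sprintf("<pixel_metric> %.3f px/mm at reference height %.1f mm\n",
              x$pixels_per_mm, x$reference_height_mm))
  invisible(x)
}

#' Convert pixel lengths and areas to metric units
#'
#' @param pm A [pixel_metric()].
#' @param length_px Length in pixels (>= 0).
#' @param area_px Area in pixels (>= 0).
#' @return Length in mm, or area in mm^2.
#' @export
px_to_mm <- function(pm, length_px) {
  stopifnot(inherits(pm, "pixel_metric"))
  if (any(length_px < 0, na.rm = TRUE)) stop("length_px must be nonnegative")
  length_px / pm$pixels_per_mm
}

#' @rdname px_to_mm
#' @export
area_px_to_mm2 <- function(pm, area_px) {
  stopifnot(inherits(pm, "pixel_metric"))
  if (any(area_px < 0, na.rm = TRUE)) stop("area_px must be nonnegative")
  area_px / pm$pixels_per_mm^2
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention used
#' for reported millimetre values; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fit the laser distance sensor calibration
#'
#' Ordinary least-squares line mapping raw sensor readout to reference height
#' (mm), as measured against a staircase-shaped reference object. The zero
#' plane readout (`zero_raw`) is the raw value whose fitted height is zero,
#' i.e. the bare cultivation surface.
#'
#' @param raw Raw sensor readouts.
#' @param height_mm Caliper-measured reference heights (mm).
#' @param max_valid_height_mm Heights above this are flagged invalid
#'   downstream (sensor working range); default 72.
#' @return An object of class `laser_calibration` with fields `slope`,
#'   `intercept`, `zero_raw`, `max_valid_height_mm` and `diagnostics`
#'   (a [regression_report()] of fitted vs reference heights).
#' @examples
#' raw <- 19430 + seq(0, 5000, by = 500)
#' cal <- fit_laser_calibration(raw, 0.01 * (raw - 19430))
#' raw_to_height(cal, 19430)
#' @export
fit_laser_calibration <- function(raw, height_mm, max_valid_height_mm = 72) {
  stopifnot(length(raw) == length(height_mm), length(raw) >= 2)
  if (length(unique(raw)) < 2)
    stop("cannot fit calibration: all raw readouts identical")
  fit <- stats::lm(height_mm ~ raw)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope == 0)
    stop("degenerate calibration fit")
  diag <- regression_report(height_mm, unname(stats::fitted(fit)))
  structure(list(slope = slope, intercept = intercept,
                 zero_raw = -intercept / slope,
                 max_valid_height_mm = max_valid_height_mm,
                 diagnostics = diag),
            class = "laser_calibration")
}

#' Construct a laser calibration from known coefficients
#'
#' @param slope mm per raw unit.
#' @param zero_raw Raw readout of the zero plane (cultivation surface).
#' @param max_valid_height_mm Validity limit (mm).
#' @return A `laser_calibration`.
#' @export
laser_calibration <- function(slope, zero_raw, max_valid_height_mm = 72) {
  stopifnot(is.finite(slope), slope != 0, is.finite(zero_raw))
  structure(list(slope = slope, intercept = -slope * zero_raw,
                 zero_raw = zero_raw,
                 max_valid_height_mm = max_valid_height_mm,
                 diagnostics = NULL),
            class = "laser_calibration")
}

#' @export
print.laser_calibration <- function(x, ...) {
  cat(sprintf(
    "<laser_calibration> height = %.6g * (raw - %.6g) mm, valid <= %.6g mm\n",
    x$slope, x$zero_raw, x$max_valid_height_mm))
  invisible(x)
}

#' Convert raw laser readouts to heights above the cultivation surface
#'
#' Heights are zeroed at the calibration's zero plane. Readouts mapping above
#' the sensor's reliable range, and non-finite readouts, are flagged invalid.
#' Negative heights (readouts beyond the zero plane) are kept but indicate
#' noise, since media shrinkage cannot go below the vessel floor.
#'
#' @param cal A `laser_calibration`.
#' @param raw Raw readouts (vector or matrix).
#' @return List with `height_mm` (same shape as `raw`) and logical `valid`.
#' @export
raw_to_height <- function(cal, raw) {
  stopifnot(inherits(cal, "laser_calibration"))
  h <- cal$slope * (raw - cal$zero_raw)
  valid <- is.finite(h) & h <= cal$max_valid_height_mm
  h[!is.finite(h)] <- NA_real_
  list(height_mm = h, valid = valid)
}

#' Invert a laser calibration (height to raw readout)
#'
#' @param cal A `laser_calibration`.
#' @param height_mm Heights (mm).
#' @return Raw readouts on the sensor scale.
#' @export
height_to_raw <- function(cal, height_mm) {
  stopifnot(inherits(cal, "laser_calibration"))
  cal$zero_raw + height_mm / cal$slope
}

#' Save or load a calibration set as JSON
#'
#' The stored object bundles the laser line and the pixel pitch so a whole
#' experiment can be reprocessed from one file.
#'
#' @param cal A `laser_calibration`.
#' @param pm A `pixel_metric`.
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns `list(laser =, pixel =)`.
#' @export
write_calibration <- function(cal, pm, path) {
  obj <- list(slope = cal$slope, intercept = cal$intercept,
              zero_raw = cal$zero_raw,
              max_valid_height_mm = cal$max_valid_height_mm,
              pixels_per_mm = pm$pixels_per_mm,
              reference_height_mm = pm$reference_height_mm)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(laser = laser_calibration(obj$slope, obj$zero_raw,
                                 obj$max_valid_height_mm),
       pixel = pixel_metric(obj$pixels_per_mm, obj$reference_height_mm))
}
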