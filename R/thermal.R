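#' Construct a thermal frame
#'
#' A radiometric thermal frame of 14-bit raw counts. Values outside the
#' 14-bit range are kept but flagged. An all-equal frame is flagged as a
#' likely mid-flat-field-calibration capture.
#'
#' @param raw Integer matrix of raw counts (rows x cols; nominal 120 x 160).
#' @param timestamp Optional acquisition timestamp.
#' @param foil_present Whether the vessel sealing foil was in the light path.
#' @return Object of class `thermal_frame`.
#' @export
thermal_frame <- function(raw, timestamp = NULL, foil_present = FALSE) {
  stopifnot(is.matrix(raw), is.numeric(raw))
  structure(list(raw = raw, timestamp = timestamp,
                 foil_present = foil_present,
                 flag_out_of_range = any(raw < 0 | raw >= 2^14, na.rm = TRUE),
                 flag_flat_field = length(unique(as.vector(raw))) == 1L),
            class = "thermal_frame")
}

#' Convert raw thermal counts to degrees Celsius
#'
#' Manufacturer conversion for radiometric 14-bit frames:
#' `T = raw / 100 - 273.15` (raw counts are centi-Kelvin). Exactly invertible
#' for integer raws via [celsius_to_raw()].
#'
#' @param raw Raw counts (vector, matrix, or `thermal_frame`).
#' @return Temperatures in degrees C, same shape.
#' @examples
#' raw_to_celsius(29815)  # 25 C
#' @export
raw_to_celsius <- function(raw) {
  if (inherits(raw, "thermal_frame")) raw <- raw$raw
  raw / 100 - 273.15
}

#' @rdname raw_to_celsius
#' @param celsius Temperatures in degrees C.
#' @export
celsius_to_raw <- function(celsius) {
  x <- round(100 * (celsius + 273.15))
  storage.mode(x) <- "integer"  # keeps matrix shape
  x
}

#' Summary statistics and histogram of a thermal frame
#'
#' @param frame A `thermal_frame` or raw matrix.
#' @param bin_width_c Histogram bin width in degrees C; the default 0.05
#'   matches the sensor's thermal sensitivity.
#' @return List with `mean_c`, `min_c`, `max_c`, `n_px` and a data frame
#'   `histogram` (`mid_c`, `count`).
#' @export
frame_stats <- function(frame, bin_width_c = 0.05) {
  tc <- raw_to_celsius(frame)
  tc <- tc[is.finite(tc)]
  if (length(tc) == 0) stop("frame has no finite pixels")
  lo <- floor(min(tc) / bin_width_c) * bin_width_c
  breaks <- seq(lo, max(tc) + bin_width_c, by = bin_width_c)
  hh <- graphics::hist(tc, breaks = breaks, plot = FALSE)
  list(mean_c = mean(tc), min_c = min(tc), max_c = max(tc),
       n_px = length(tc),
       histogram = data.frame(mid_c = hh$mids, count = hh$counts))
}

#' Thermal contrast index
#'
#' Difference between the 95th and 5th percentile temperature of a frame; a
#' diagnostic for how well plant and background separate thermally (imaging
#' through the sealing foil compresses it).
#'
#' @param frame A `thermal_frame` or raw matrix.
#' @return Contrast in degrees C (>= 0).
#' @export
contrast_index <- function(frame) {
  tc <- raw_to_celsius(frame)
  tc <- tc[is.finite(tc)]
  if (length(tc) == 0) stop("frame has no finite pixels")
  unname(diff(stats::quantile(tc, c(0.05, 0.95), type = 7)))
}

#' Export a thermal frame as a false-colour PNG
#'
#' Visualisation aid only; uses a fixed perceptually ordered palette
#' (grDevices "viridis"), scaling min..max temperature to the palette range.
#'
#' @param frame A `thermal_frame` or raw matrix.
#' @param path Output PNG path.
#' @return `path` invisibly.
#' @export
write_thermal_falsecolor <- function(frame, path) {
  tc <- raw_to_celsius(frame)
  rng <- range(tc, finite = TRUE)
  idx <- if (diff(rng) > 0) (tc - rng[1]) / diff(rng) else tc * 0
  pal <- grDevices::hcl.colors(256, "viridis")
  cols <- grDevices::col2rgb(pal[pmin(255L, as.integer(idx * 255)) + 1L]) / 255
  arr <- array(0, dim = c(nrow(tc), ncol(tc), 3))
  arr[, , 1] <- matrix(cols[1, ], nrow(tc)); arr[, , 2] <- matrix(cols[2, ], nrow(tc))
  arr[, , 3] <- matrix(cols[3, ], nrow(tc))
  png::writePNG(arr, path)
  invisible(path)
}
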