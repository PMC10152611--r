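#' Overlap area of a circle and an axis-aligned rectangle
#'
#' Composite-Simpson integration of the clipped chord; deterministic and
#' accurate to well below the flatness tolerances used on it.
#'
#' @param cx,cy Circle centre.
#' @param r Circle radius (> 0).
#' @param x0,x1,y0,y1 Rectangle bounds.
#' @param n Number of integration intervals (even).
#' @return Overlap area.
#' @keywords internal
circle_rect_overlap <- function(cx, cy, r, x0, x1, y0, y1, n = 2000L) {
  lo <- max(x0, cx - r); hi <- min(x1, cx + r)
  if (lo >= hi) return(0)
  u <- seq(lo, hi, length.out = n + 1L)
  w <- sqrt(pmax(r^2 - (u - cx)^2, 0))
  chord <- pmax(pmin(y1, cy + w) - pmax(y0, cy - w), 0)
  h <- (hi - lo) / n
  wts <- rep(c(4, 2), length.out = n - 1L)
  h / 3 * (chord[1L] + chord[n + 1L] + sum(wts * chord[2:n]))
}

#' Simulate a spot-size scan over a series of white squares
#'
#' Emulates the experimental determination of the spectrometer detection spot
#' size: a uniform circular spot of known diameter is moved in 1 mm steps
#' along a line through the centres of white squares of decreasing side on a
#' black field; the readout at each position is the white area covered by the
#' spot. Square centres sit on scan positions, as when the scan grid is
#' aligned with the printed target.
#'
#' @param true_diameter_mm Spot diameter to simulate.
#' @param square_sides_mm Square side lengths, largest first (default 30:21).
#' @param pitch_mm Scan step (default 1).
#' @param spacing_mm Distance between square centres; must exceed the largest
#'   side plus the spot diameter so peaks do not overlap.
#' @return A `spot_scan_profile`: list with `positions_mm`, `readouts`,
#'   `square_sides_mm`, `square_centers_mm`.
#' @examples
#' prof <- simulate_spot_profile(23.5)
#' determine_spot_size(prof)
#' @export
simulate_spot_profile <- function(true_diameter_mm,
                                  square_sides_mm = 30:21,
                                  pitch_mm = 1,
                                  spacing_mm = 70) {
  stopifnot(true_diameter_mm > 0, all(square_sides_mm > 0),
            spacing_mm > max(square_sides_mm) + true_diameter_mm)
  r <- true_diameter_mm / 2
  centers <- spacing_mm * seq_along(square_sides_mm)
  positions <- seq(0, max(centers) + spacing_mm / 2, by = pitch_mm)
  readouts <- numeric(length(positions))
  for (i in seq_along(square_sides_mm)) {
    s2 <- square_sides_mm[i] / 2
    cx <- centers[i]
    near <- which(abs(positions - cx) < r + s2)
    for (j in near)
      readouts[j] <- readouts[j] +
        circle_rect_overlap(positions[j], 0, r, cx - s2, cx + s2, -s2, s2)
  }
  structure(list(positions_mm = positions, readouts = readouts,
                 square_sides_mm = square_sides_mm,
                 square_centers_mm = centers),
            class = "spot_scan_profile")
}

#' Determine the spectrometer detection spot diameter from a square scan
#'
#' For each square (largest to smallest) the intensity peak is classified as
#' a plateau -- at least two adjacent scan positions within a flatness
#' tolerance of the peak maximum -- or a sharp maximum. A plateau means the
#' spot fits inside the square; the side length of the first square showing a
#' sharp maximum is reported as the spot diameter.
#'
#' @param profile A `spot_scan_profile` (see [simulate_spot_profile()]), or a
#'   list with the same fields for measured data.
#' @param flatness_tol Relative tolerance below the peak maximum within which
#'   readouts count as part of a plateau. The default 0.0115 separates, by
#'   closed-form circle-segment geometry, the largest possible 1 mm-offset
#'   signal drop of a square that still contains the spot (1.09%, side 22
#'   against a 21.5 mm spot) from the smallest drop of one that does not
#'   (1.20%, side 29 against a 29.5 mm spot) over the 21-30 mm series.
#' @return Spot diameter estimate in mm (a square side length).
#' @export
determine_spot_size <- function(profile, flatness_tol = 0.0115) {
  stopifnot(!is.null(profile$positions_mm), !is.null(profile$readouts),
            length(profile$positions_mm) == length(profile$readouts))
  pos <- profile$positions_mm
  if (is.unsorted(pos, strictly = TRUE))
    stop("scan positions must be strictly increasing")
  sides <- profile$square_sides_mm
  centers <- profile$square_centers_mm
  ord <- order(sides, decreasing = TRUE)
  half_win <- min(diff(sort(centers))) / 2
  for (i in ord) {
    win <- which(abs(pos - centers[i]) <= half_win)
    v <- profile$readouts[win]
    if (all(v <= 0)) next
    top <- max(v)
    flat <- v >= (1 - flatness_tol) * top
    runs <- rle(flat)
    has_plateau <- any(runs$lengths[runs$values] >= 2L)
    if (!has_plateau) return(sides[i])
  }
  stop("no sharp maximum found in any square peak")
}
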