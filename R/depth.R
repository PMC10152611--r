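#' Construct a depth grid from raw readouts
#'
#' @param raw Matrix of raw laser readouts (row = y, col = x); `NA` where the
#'   sensor returned no reading.
#' @param x_pitch,y_pitch Scan pitch (mm), default 1.
#' @param valid Optional logical matrix; defaults to finite raws.
#' @return Object of class `depth_grid`.
#' @export
depth_grid <- function(raw, x_pitch = 1, y_pitch = 1, valid = NULL) {
  stopifnot(is.matrix(raw), x_pitch > 0, y_pitch > 0)
  if (is.null(valid)) valid <- is.finite(raw)
  stopifnot(identical(dim(valid), dim(raw)))
  structure(list(raw = raw, valid = valid & is.finite(raw),
                 x_mm = (seq_len(ncol(raw)) - 1) * x_pitch,
                 y_mm = (seq_len(nrow(raw)) - 1) * y_pitch,
                 x_pitch = x_pitch, y_pitch = y_pitch),
            class = "depth_grid")
}

#' @export
print.depth_grid <- function(x, ...) {
  cat(sprintf("<depth_grid> %d x %d points, pitch %g x %g mm, %.1f%% valid\n",
              ncol(x$raw), nrow(x$raw), x$x_pitch, x$y_pitch,
              100 * mean(x$valid)))
  invisible(x)
}

#' Zero level of a depth scan
#'
#' Mean raw readout over four corner quadrilaterals of the scan area, where
#' only the bare cultivation surface is seen (the vessel floor carries the
#' medium disk centrally). Invalid points are excluded.
#'
#' @param grid A `depth_grid`.
#' @param corner_size Corner block side in grid points (default 10).
#' @return Zero-plane raw readout (scalar).
#' @export
zero_level <- function(grid, corner_size = 10) {
  stopifnot(inherits(grid, "depth_grid"))
  nr <- nrow(grid$raw); nc <- ncol(grid$raw)
  if (nr < 2 * corner_size || nc < 2 * corner_size)
    stop("grid too small for the requested corner blocks")
  ri <- c(seq_len(corner_size), nr - corner_size + seq_len(corner_size))
  ci <- c(seq_len(corner_size), nc - corner_size + seq_len(corner_size))
  sel <- matrix(FALSE, nr, nc)
  sel[seq_len(corner_size), ci] <- TRUE
  sel[nr - corner_size + seq_len(corner_size), ci] <- TRUE
  sel <- sel & grid$valid
  if (!any(sel)) stop("all corner points invalid")
  mean(grid$raw[sel])
}

#' Convert a depth grid to heights above the vessel floor
#'
#' Applies the laser calibration slope to readouts relative to the scan's
#' own zero level (per-vessel corner estimate), so each vessel is referenced
#' to its actual floor. Heights above the sensor's reliable range are
#' invalidated.
#'
#' @param grid A `depth_grid`.
#' @param cal A `laser_calibration` (supplies slope and validity limit).
#' @param zero_raw Zero-plane readout; default [zero_level()] of the grid.
#' @return List with `height` (mm matrix, `NA` where invalid) and `valid`.
#' @export
grid_heights <- function(grid, cal, zero_raw = NULL) {
  stopifnot(inherits(grid, "depth_grid"), inherits(cal, "laser_calibration"))
  if (is.null(zero_raw)) zero_raw <- zero_level(grid)
  h <- cal$slope * (grid$raw - zero_raw)
  valid <- grid$valid & is.finite(h) & h <= cal$max_valid_height_mm
  h[!valid] <- NA_real_
  list(height = h, valid = valid)
}

# gradient magnitude between valid neighbours; NA next to invalid points
height_gradient <- function(height) {
  nr <- nrow(height); nc <- ncol(height)
  gx <- matrix(NA_real_, nr, nc); gy <- gx
  gx[, 2:(nc - 1)] <- (height[, 3:nc] - height[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (height[3:nr, ] - height[1:(nr - 2), ]) / 2
  sqrt(gx^2 + gy^2)
}

#' Detect the culture-medium disk by circle Hough transform
#'
#' Edge points are grid positions whose height-gradient magnitude exceeds
#' `edge_threshold` (the ~20 mm medium step dwarfs noise). Each edge point
#' votes for circle centres at every candidate radius; the best-supported
#' circle is returned. Run on the Day-0 scan, where the medium rim is not
#' yet overgrown.
#'
#' @param height Height matrix in mm (from [grid_heights()]).
#' @param radius_range Radii to search, in grid units (default 30-45,
#'   bracketing the 37 mm vessel radius at 1 mm pitch).
#' @param edge_threshold Gradient magnitude (mm per grid step) above which a
#'   point is an edge (default 5).
#' @param min_support Minimum fraction of the circle circumference that must
#'   be supported by edge votes (default 0.3).
#' @return List with `center` (x, y in grid units, 0-based), `radius`
#'   (grid units) and `support` (fraction of rim detected).
#' @export
detect_medium_circle <- function(height, radius_range = c(30, 45),
                                 edge_threshold = 5, min_support = 0.3) {
  stopifnot(is.matrix(height))
  gmag <- height_gradient(height)
  edge <- which(is.finite(gmag) & gmag > edge_threshold, arr.ind = TRUE)
  if (nrow(edge) == 0) stop("no edges found: is there a raised medium disk?")
  nr <- nrow(height); nc <- ncol(height)
  ex <- edge[, 2] - 1L; ey <- edge[, 1] - 1L  # 0-based (x = col, y = row)
  radii <- seq(radius_range[1], radius_range[2])
  best <- list(score = -Inf)
  for (r in radii) {
    th <- seq(0, 2 * pi, length.out = max(16L, ceiling(2 * pi * r)) + 1L)
    th <- th[-length(th)]
    off <- unique(cbind(round(r * cos(th)), round(r * sin(th))))
    cx <- rep(ex, each = nrow(off)) + off[, 1]
    cy <- rep(ey, each = nrow(off)) + off[, 2]
    ok <- cx >= 0 & cx < nc & cy >= 0 & cy < nr
    idx <- cx[ok] * nr + cy[ok] + 1
    acc <- tabulate(idx, nbins = nr * nc)
    i <- which.max(acc)
    score <- acc[i] / nrow(off)
    if (score > best$score)
      best <- list(score = score, radius = r,
                   center = c((i - 1) %/% nr, (i - 1) %% nr))
  }
  if (best$score < min_support)
    stop("no circle above the accumulator threshold")
  list(center = best$center, radius = best$radius, support = best$score)
}

#' Edge-removed medium mask
#'
#' Boolean disk mask of the detected medium with the rim shaved off:
#' `r_new = r - 3` grid units, removing the disturbed medium edge before
#' plane fitting.
#'
#' @param center Circle centre (x, y), 0-based grid units.
#' @param radius Detected circle radius (grid units).
#' @param dim Raster dimension `c(nrow, ncol)`.
#' @param shrink_px Rim shave (default 3).
#' @return Logical matrix.
#' @export
edge_removed_mask <- function(center, radius, dim, shrink_px = 3) {
  r_new <- radius - shrink_px
  if (r_new <= 0) stop("shrunken radius must be positive")
  disk_mask(seq_len(dim[2]) - 1, seq_len(dim[1]) - 1,
            center[1], center[2], r_new)
}

#' RANSAC plane fit
#'
#' Random-sample-consensus estimation of the dominant plane `z = a x + b y + c`
#' in a point set: repeatedly fit an exact plane through 3 random
#' non-collinear points, count inliers within `distance_threshold` of it
#' (vertical residual, mm), keep the consensus-maximal plane, and refit it by
#' least squares on its inliers. Robust to plant points sticking out of the
#' medium surface.
#'
#' @param x,y,z Point coordinates (equal-length vectors; mm).
#' @param distance_threshold Inlier band half-width (mm, default 1.5).
#' @param sample_size Points per minimal sample (fixed at 3 for a plane).
#' @param iterations Number of random samples (default 10000).
#' @param seed RNG seed for reproducibility.
#' @return List with `plane` (a, b, c), logical `inliers`, `n_inliers`.
#' @export
ransac_plane <- function(x, y, z, distance_threshold = 1.5, sample_size = 3,
                         iterations = 10000, seed = 1L) {
  stopifnot(length(x) == length(y), length(y) == length(z), sample_size == 3)
  keep <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 valid points")
  planes <- with_seed(seed, {
    idx <- matrix(0L, iterations, 3)
    for (i in seq_len(iterations)) idx[i, ] <- sample.int(n, 3)
    idx
  })
  p1 <- planes[, 1]; p2 <- planes[, 2]; p3 <- planes[, 3]
  # exact plane through 3 points: solve the 2x2 system for (a, b)
  dx1 <- x[p2] - x[p1]; dy1 <- y[p2] - y[p1]; dz1 <- z[p2] - z[p1]
  dx2 <- x[p3] - x[p1]; dy2 <- y[p3] - y[p1]; dz2 <- z[p3] - z[p1]
  det <- dx1 * dy2 - dx2 * dy1
  ok <- abs(det) > 1e-9
  if (!any(ok)) stop("all random samples collinear")
  a <- (dz1 * dy2 - dz2 * dy1) / det
  b <- (dx1 * dz2 - dx2 * dz1) / det
  cc <- z[p1] - a * x[p1] - b * y[p1]
  a <- a[ok]; b <- b[ok]; cc <- cc[ok]
  # count inliers in chunks: residual matrix would be n x iterations
  best_i <- 0L; best_count <- -1L
  chunk <- max(1L, floor(2e6 / n))
  A <- cbind(x, y, 1)
  for (s in seq(1, length(a), by = chunk)) {
    e <- min(s + chunk - 1, length(a))
    res <- abs(z - A %*% rbind(a[s:e], b[s:e], cc[s:e]))
    counts <- colSums(res <= distance_threshold)
    i <- which.max(counts)
    if (counts[i] > best_count) { best_count <- counts[i]; best_i <- s + i - 1L }
  }
  res <- abs(z - (a[best_i] * x + b[best_i] * y + cc[best_i]))
  inl <- res <= distance_threshold
  fit <- stats::lm.fit(A[inl, , drop = FALSE], z[inl])
  plane <- unname(fit$coefficients)
  inliers_full <- rep(NA, length(keep))
  inliers_full[keep] <- abs(z - (plane[1] * x + plane[2] * y + plane[3])) <=
    distance_threshold
  list(plane = plane, inliers = inliers_full[keep], n_inliers = sum(inl))
}

#' Plane-correct a height grid and segment plant pixels
#'
#' Subtracts the fitted medium plane inside the mask; corrected heights at or
#' below the inlier band are medium (set to 0), the rest are plant pixels.
#' Invalid points stay `NA` and are never imputed.
#'
#' @param height Height matrix (mm).
#' @param plane Plane coefficients (a, b, c) in grid units.
#' @param mask Logical medium mask (e.g. [edge_removed_mask()]).
#' @param distance_threshold Medium/plant cut (mm); the RANSAC inlier band.
#' @return Matrix of plant heights above the medium plane (0 = medium,
#'   `NA` = outside mask or invalid).
#' @export
correct_and_segment <- function(height, plane, mask, distance_threshold = 1.5) {
  stopifnot(identical(dim(height), dim(mask)))
  g <- coord_grids(seq_len(ncol(height)) - 1, seq_len(nrow(height)) - 1)
  corrected <- height - (plane[1] * g$x + plane[2] * g$y + plane[3])
  corrected[!mask] <- NA_real_
  corrected[mask & is.finite(corrected) & corrected <= distance_threshold] <- 0
  corrected
}

#' Derived growth parameters from processed depth data
#'
#' The five depth-derived traits: medium height (mean of the fitted plane
#' over the medium mask), medium volume (circular conical frustum between
#' the vessel bottom radius and the detected top radius), average canopy
#' height (mean of nonzero plant heights), maximum plant height (mean of the
#' upper 10th percentile of plant heights, inclusive of the interpolated P90)
#' and projected plant area from depth data.
#'
#' @param plane Plane coefficients (a, b, c), grid units.
#' @param plant Plant height raster from [correct_and_segment()].
#' @param mask Medium mask used for the plane.
#' @param pitch_mm Grid pitch (mm); converts grid units to mm.
#' @param r1_mm Detected medium top radius (mm).
#' @param r2_mm Vessel bottom radius (mm, default 37).
#' @return List of class `depth_traits`: `medium_height_mm`,
#'   `medium_volume_mm3`, `avg_canopy_height_mm`, `max_plant_height_mm`,
#'   `projected_area_depth_mm2`, `n_plant_px`.
#' @export
depth_traits <- function(plane, plant, mask, pitch_mm = 1, r1_mm, r2_mm = 37) {
  g <- coord_grids(seq_len(ncol(mask)) - 1, seq_len(nrow(mask)) - 1)
  plane_h <- plane[1] * g$x + plane[2] * g$y + plane[3]
  medium_height <- mean(plane_h[mask])
  volume <- frustum_volume(medium_height, r1_mm, r2_mm)
  ph <- plant[mask]
  ph <- ph[is.finite(ph) & ph > 0]
  n_plant <- length(ph)
  if (n_plant > 0) {
    avg_canopy <- mean(ph)
    p90 <- stats::quantile(ph, 0.9, type = 7, names = FALSE)
    max_plant <- mean(ph[ph >= p90])
  } else {
    avg_canopy <- NA_real_; max_plant <- NA_real_
  }
  structure(list(medium_height_mm = medium_height,
                 medium_volume_mm3 = volume,
                 avg_canopy_height_mm = avg_canopy,
                 max_plant_height_mm = max_plant,
                 projected_area_depth_mm2 = n_plant * pitch_mm^2,
                 n_plant_px = n_plant),
            class = "depth_traits")
}

#' Volume of a circular conical frustum
#'
#' `V = (1/3) pi h (r1^2 + r1 r2 + r2^2)`; reduces to a cylinder at
#' `r1 = r2` and a cone at `r1 = 0`.
#'
#' @param h Height (mm).
#' @param r1 Top radius (mm).
#' @param r2 Bottom radius (mm, default 37).
#' @return Volume (mm^3).
#' @export
frustum_volume <- function(h, r1, r2 = 37) {
  stopifnot(r1 >= 0, r2 >= 0, h >= 0)
  pi * h * (r1^2 + r1 * r2 + r2^2) / 3
}

#' Full depth-processing pipeline for one scan
#'
#' Chains zero level, calibration conversion, medium circle detection (or a
#' circle carried over from Day 0), rim removal, RANSAC plane fit,
#' plane-corrected segmentation and trait extraction.
#'
#' @param grid A `depth_grid`.
#' @param cal A `laser_calibration`.
#' @param circle Optional circle (list with `center`, `radius`) from the
#'   Day-0 scan; detected from this scan when `NULL`.
#' @param distance_threshold RANSAC inlier band and medium/plant cut (mm).
#' @param iterations RANSAC iterations (default 10000).
#' @param seed RANSAC seed.
#' @param ... Passed to [detect_medium_circle()].
#' @return List with `zero_raw`, `circle`, `mask`, `plane`, `n_inliers`,
#'   `plant` (height raster) and `traits` (a `depth_traits`).
#' @export
depth_pipeline <- function(grid, cal, circle = NULL, distance_threshold = 1.5,
                           iterations = 10000, seed = 1L, ...) {
  z0 <- zero_level(grid)
  gh <- grid_heights(grid, cal, z0)
  if (is.null(circle)) circle <- detect_medium_circle(gh$height, ...)
  mask <- edge_removed_mask(circle$center, circle$radius, dim(gh$height))
  sel <- mask & gh$valid
  g <- coord_grids(seq_len(ncol(mask)) - 1, seq_len(nrow(mask)) - 1)
  fit <- ransac_plane(g$x[sel], g$y[sel], gh$height[sel],
                      distance_threshold = distance_threshold,
                      iterations = iterations, seed = seed)
  plant <- correct_and_segment(gh$height, fit$plane, mask, distance_threshold)
  traits <- depth_traits(fit$plane, plant, mask,
                         pitch_mm = grid$x_pitch,
                         r1_mm = circle$radius * grid$x_pitch)
  list(zero_raw = z0, circle = circle, mask = mask, plane = fit$plane,
       n_inliers = fit$n_inliers, plant = plant, traits = traits)
}
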