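#' Plant blob specification for synthetic scenes
#'
#' A rotationally symmetric mound standing on the medium surface. Hemisphere
#' blobs (`z = h sqrt(1 - (rho/r)^2)`) emulate compact rosettes; cones
#' (`z = h (1 - rho/r)`) emulate pointed shoots.
#'
#' @param center_xy Centre (x, y) in scene mm coordinates.
#' @param radius_mm Blob radius (> 0).
#' @param max_height_mm Apex height above the medium surface (>= 0).
#' @param shape `"hemisphere"` or `"cone"`.
#' @param color RGB triple (0-255) for the RGB render.
#' @return Object of class `plant_blob`.
#' @export
plant_blob <- function(center_xy, radius_mm, max_height_mm,
                       shape = c("hemisphere", "cone"),
                       color = c(60, 140, 60)) {
  shape <- match.arg(shape)
  stopifnot(length(center_xy) == 2, radius_mm > 0, max_height_mm >= 0,
            length(color) == 3)
  structure(list(center_xy = as.numeric(center_xy), radius_mm = radius_mm,
                 max_height_mm = max_height_mm, shape = shape,
                 color = as.numeric(color)),
            class = "plant_blob")
}

#' Ground-truth description of a synthetic culture-vessel scene
#'
#' The scene is a flat cultivation surface (height 0) carrying a raised
#' circular medium disk, optionally tilted, with plant blobs standing on the
#' medium. It is the single source of truth from which all four sensor
#' renders derive, so pipeline outputs can be checked against known
#' parameters. Coordinates: x right, y down, origin at the scan's top-left
#' corner; heights positive upward.
#'
#' @param medium_center_xy Medium disk centre (mm); default scan centre.
#' @param medium_radius_mm Disk radius; default 37, the vessel bottom radius.
#' @param medium_height_mm Medium surface height above the vessel floor (mm).
#' @param medium_tilt Tilt slopes `(dz/dx, dz/dy)` of the medium plane
#'   (mm/mm), e.g. from an unevenly poured medium.
#' @param plants List of [plant_blob()]s, all inside the medium disk.
#' @param noise_sd_mm Per-point depth noise SD (mm); default 0.1, the laser
#'   sensor's linearity.
#' @param dropout_slope_threshold Surface slope above which a depth readout
#'   fails (reflection lost on steep surfaces). For a hemispherical blob of
#'   apex height h and radius r the lost fraction of projected pixels is
#'   1/(1 + (t r / h)^2); the default 2.2 (~66 degrees) makes the default
#'   blob population (r 5-8 mm, h 6-14 mm) lose one third of its pixels on
#'   average, the loss regime reported for scanning-laser depth imaging of
#'   such cultures.
#' @param extent_mm Scan area (x, y) in mm; default 100 x 100.
#' @param seed Integer seed; every renderer derives an independent substream
#'   from it, so renders are reproducible individually and jointly.
#' @return Object of class `scene_truth`.
#' @examples
#' sc <- scene_truth(plants = list(plant_blob(c(40, 50), 8, 12)))
#' grid <- render_depth(sc, synthetic_laser_calibration())
#' @export
scene_truth <- function(medium_center_xy = c(50, 50),
                        medium_radius_mm = 37,
                        medium_height_mm = 20,
                        medium_tilt = c(0, 0),
                        plants = list(),
                        noise_sd_mm = 0.1,
                        dropout_slope_threshold = 2.2,
                        extent_mm = c(100, 100),
                        seed = 1L) {
  stopifnot(medium_radius_mm > 0, medium_height_mm > 0, noise_sd_mm >= 0,
            dropout_slope_threshold >= 0, length(medium_tilt) == 2)
  if (medium_center_xy[1] - medium_radius_mm < 0 ||
      medium_center_xy[1] + medium_radius_mm > extent_mm[1] ||
      medium_center_xy[2] - medium_radius_mm < 0 ||
      medium_center_xy[2] + medium_radius_mm > extent_mm[2])
    stop("medium disk must fit inside the scan area")
  for (p in plants) {
    stopifnot(inherits(p, "plant_blob"))
    d <- sqrt(sum((p$center_xy - medium_center_xy)^2))
    if (d + p$radius_mm > medium_radius_mm)
      stop("plant blobs must lie within the medium disk")
  }
  structure(list(medium_center_xy = as.numeric(medium_center_xy),
                 medium_radius_mm = medium_radius_mm,
                 medium_height_mm = medium_height_mm,
                 medium_tilt = as.numeric(medium_tilt),
                 plants = plants,
                 noise_sd_mm = noise_sd_mm,
                 dropout_slope_threshold = dropout_slope_threshold,
                 extent_mm = as.numeric(extent_mm),
                 seed = as.integer(seed)),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(paste0("<scene_truth> medium r=%g mm h=%g mm tilt=(%g, %g), ",
                     "%d plant(s), noise sd %g mm, seed %d\n"),
              x$medium_radius_mm, x$medium_height_mm, x$medium_tilt[1],
              x$medium_tilt[2], length(x$plants), x$noise_sd_mm, x$seed))
  invisible(x)
}

# blob height profile at radial distance rho (vectorised)
blob_height <- function(blob, rho) {
  u <- pmin(rho / blob$radius_mm, 1)
  switch(blob$shape,
         hemisphere = blob$max_height_mm * sqrt(pmax(1 - u^2, 0)),
         cone = blob$max_height_mm * (1 - u))
}

# |d blob_height / d rho| (vectorised); Inf at the hemisphere rim
blob_slope <- function(blob, rho) {
  r <- blob$radius_mm; h <- blob$max_height_mm
  inside <- rho < r
  s <- numeric(length(rho))
  if (blob$shape == "hemisphere") {
    denom <- sqrt(pmax(r^2 - rho^2, 0))
    s[inside] <- ifelse(denom[inside] > 0,
                        h * rho[inside] / (r * denom[inside]), Inf)
  } else {
    s[inside] <- h / r
  }
  s
}

#' Ideal (noise-free) height and slope fields of a scene
#'
#' Evaluates the true surface height (mm above the vessel floor) and the
#' analytic surface slope magnitude on arbitrary coordinate vectors. The
#' slope is the tilt of the reflecting surface itself; height discontinuities
#' at the medium rim do not count as slope (a nadir-viewing sensor sees
#' either the medium top or the floor there, both flat).
#'
#' @param scene A [scene_truth()].
#' @param x_mm,y_mm Coordinate vectors (mm).
#' @return List of matrices (`length(y_mm)` rows x `length(x_mm)` cols):
#'   `height`, `slope`, and logical `plant` (true where a blob covers the
#'   point).
#' @export
scene_height_field <- function(scene, x_mm, y_mm) {
  g <- coord_grids(x_mm, y_mm)
  cx <- scene$medium_center_xy[1]; cy <- scene$medium_center_xy[2]
  in_medium <- (g$x - cx)^2 + (g$y - cy)^2 <= scene$medium_radius_mm^2
  plane <- scene$medium_height_mm +
    scene$medium_tilt[1] * (g$x - cx) + scene$medium_tilt[2] * (g$y - cy)
  height <- ifelse(in_medium, plane, 0)
  tilt_mag <- sqrt(sum(scene$medium_tilt^2))
  slope <- ifelse(in_medium, tilt_mag, 0)
  plant <- matrix(FALSE, nrow(height), ncol(height))
  for (b in scene$plants) {
    rho <- sqrt((g$x - b$center_xy[1])^2 + (g$y - b$center_xy[2])^2)
    on_blob <- rho <= b$radius_mm
    height[on_blob] <- height[on_blob] + blob_height(b, rho[on_blob])
    # blob gradient is radial; combine with the planar tilt vectorially
    bs <- blob_slope(b, rho)
    dirx <- ifelse(rho > 0, (g$x - b$center_xy[1]) / rho, 0)
    diry <- ifelse(rho > 0, (g$y - b$center_xy[2]) / rho, 0)
    gx <- scene$medium_tilt[1] - bs * dirx
    gy <- scene$medium_tilt[2] - bs * diry
    sl <- sqrt(gx^2 + gy^2)
    sl[!is.finite(bs)] <- Inf
    slope[on_blob] <- sl[on_blob]
    plant <- plant | on_blob
  }
  list(height = height, slope = slope, plant = plant)
}

#' Synthetic laser calibration used by the renderers
#'
#' A documented stand-in for a device calibration: 0.01 mm per raw unit with
#' the zero plane at raw 19430 and a 72 mm validity limit.
#'
#' @return A `laser_calibration`.
#' @export
synthetic_laser_calibration <- function() {
  laser_calibration(slope = 0.01, zero_raw = 19430, max_valid_height_mm = 72)
}

#' Render a depth scan of a synthetic scene
#'
#' Produces the raw laser-readout raster a scan of the scene would yield:
#' the ideal height field plus Gaussian per-point noise, converted to raw
#' units through the calibration. Points whose true surface slope exceeds
#' the scene's dropout threshold return no reading (invalid), emulating the
#' loss of the reflected beam on steeply inclined leaf surfaces.
#'
#' @param scene A [scene_truth()].
#' @param cal A `laser_calibration` (default [synthetic_laser_calibration()]).
#' @param pitch_mm Scan pitch in x and y (default 1).
#' @return A `depth_grid`: list with `raw` and logical `valid` matrices
#'   (row = y), `x_mm`, `y_mm`, `x_pitch`, `y_pitch`.
#' @export
render_depth <- function(scene, cal = synthetic_laser_calibration(),
                         pitch_mm = 1) {
  stopifnot(inherits(scene, "scene_truth"), pitch_mm > 0)
  x_mm <- seq(0, scene$extent_mm[1] - pitch_mm, by = pitch_mm)
  y_mm <- seq(0, scene$extent_mm[2] - pitch_mm, by = pitch_mm)
  f <- scene_height_field(scene, x_mm, y_mm)
  h <- f$height
  if (scene$noise_sd_mm > 0)
    h <- h + with_seed(scene$seed + 1L,
                       matrix(stats::rnorm(length(h), 0, scene$noise_sd_mm),
                              nrow(h)))
  valid <- f$slope <= scene$dropout_slope_threshold
  raw <- height_to_raw(cal, h)
  raw[!valid] <- NA_real_
  structure(list(raw = raw, valid = valid, x_mm = x_mm, y_mm = y_mm,
                 x_pitch = pitch_mm, y_pitch = pitch_mm),
            class = "depth_grid")
}

#' Render a top-down RGB image of a synthetic scene with ground truth
#'
#' Medium drawn as an opaque whitish disk (the TiO2-opacified look), plants
#' as green blobs, background dark. Night frames are globally dimmed
#' (x 0.05) with the same additive sensor noise. The returned truth mask is
#' the exact blob rasterisation, unaffected by noise.
#'
#' @param scene A [scene_truth()].
#' @param pm A [pixel_metric()]; its pitch sets the render resolution. The
#'   default 3.77 px/mm gives a desk-scale 377 x 377 px frame of the 100 mm
#'   scan area (one tenth of the full-system pitch).
#' @param illumination `"day"` or `"night"`.
#' @param noise_sd Additive Gaussian noise SD on the 0-255 scale (default 2).
#' @return A `vessel_image`: list with `pixels` (H x W x 3 array, 0-255),
#'   `illumination`, `pixel_metric`, `truth_mask` (H x W logical).
#' @export
render_rgb <- function(scene, pm = pixel_metric(3.77, 20),
                       illumination = c("day", "night"), noise_sd = 2) {
  stopifnot(inherits(scene, "scene_truth"))
  illumination <- match.arg(illumination)
  w <- round(scene$extent_mm[1] * pm$pixels_per_mm)
  h <- round(scene$extent_mm[2] * pm$pixels_per_mm)
  x_mm <- (seq_len(w) - 0.5) / pm$pixels_per_mm
  y_mm <- (seq_len(h) - 0.5) / pm$pixels_per_mm
  g <- coord_grids(x_mm, y_mm)
  medium <- disk_mask(x_mm, y_mm, scene$medium_center_xy[1],
                      scene$medium_center_xy[2], scene$medium_radius_mm)
  # warm-tinted greys: enough chroma that pixel noise cannot randomise the
  # hue channel, as for real vessel floors and TiO2-whitened media
  px <- array(0, dim = c(h, w, 3))
  background <- c(45, 38, 25); medium_col <- c(235, 228, 210)
  for (k in 1:3) px[, , k] <- ifelse(medium, medium_col[k], background[k])
  truth <- matrix(FALSE, h, w)
  for (b in scene$plants) {
    m <- disk_mask(x_mm, y_mm, b$center_xy[1], b$center_xy[2], b$radius_mm)
    for (k in 1:3) { ch <- px[, , k]; ch[m] <- b$color[k]; px[, , k] <- ch }
    truth <- truth | m
  }
  if (illumination == "night") px <- px * 0.05
  px <- px + with_seed(scene$seed + 2L,
                       array(stats::rnorm(length(px), 0, noise_sd), dim(px)))
  px <- pmin(pmax(px, 0), 255)
  structure(list(pixels = px, illumination = illumination, pixel_metric = pm,
                 truth_mask = truth, timestamp = NULL),
            class = "vessel_image")
}

#' @export
print.vessel_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<vessel_image> %d x %d px, %s illumination\n",
              d[2], d[1], x$illumination))
  invisible(x)
}

#' Render a fluorescence spectrometer readout for a synthetic scene
#'
#' Baseline dark-current counts plus an excitation-leak Gaussian at 375 nm
#' (UV LEDs imperfectly blocked by the 420 nm long-pass filter) and, when a
#' plant sits in the detection spot, the two chlorophyll fluorescence
#' Gaussians near 690 and 735 nm. Counts are 10-bit integers.
#'
#' @param scene A [scene_truth()] (supplies the seed substream).
#' @param has_plant_in_spot Does a plant fall inside the detection spot?
#' @param amplitudes Peak amplitudes `c(A690, A735)` in counts.
#' @param excitation_amp Amplitude of the 375 nm leak (0 for none).
#' @param dark_level Mean dark-current level in counts.
#' @param dark_sd Dark-current noise SD in counts.
#' @param peak_sd_nm Gaussian peak width (the ~15 nm sensor resolution).
#' @param kind Passed to [spectrum()]; use `"dark"` when rendering dark
#'   readouts (no excitation, no plant).
#' @param seed_offset Substream offset; bump to draw repeated readouts.
#' @return A `spectrum`.
#' @export
render_spectrum <- function(scene, has_plant_in_spot = TRUE,
                            amplitudes = c(150, 120), excitation_amp = 200,
                            dark_level = 60, dark_sd = 3, peak_sd_nm = 15,
                            kind = "fluorescence", seed_offset = 0L) {
  stopifnot(inherits(scene, "scene_truth"))
  wl <- map_wavelengths(0:287)
  counts <- rep(dark_level, length(wl))
  if (excitation_amp > 0)
    counts <- counts + excitation_amp * exp(-(wl - 375)^2 / (2 * 8^2))
  if (has_plant_in_spot) {
    counts <- counts + amplitudes[1] * exp(-(wl - 690)^2 / (2 * peak_sd_nm^2))
    counts <- counts + amplitudes[2] * exp(-(wl - 735)^2 / (2 * peak_sd_nm^2))
  }
  counts <- counts + with_seed(scene$seed + 3L + seed_offset,
                               stats::rnorm(length(wl), 0, dark_sd))
  counts <- pmin(pmax(round(counts), 0), 1023)
  spectrum(wl, counts, kind = kind)
}

#' Render a thermal frame of a synthetic scene
#'
#' Plant pixels at `plant_temp_c`, everything else at `background_temp_c`,
#' quantised to the radiometric raw scale. Imaging through the sealing foil
#' compresses the contrast toward the frame mean and adds a warm offset
#' (sensor self-reflection), emulating the weak plant/background separation
#' seen through foil.
#'
#' @param scene A [scene_truth()].
#' @param plant_temp_c,background_temp_c Temperatures (degrees C).
#' @param foil Is the sealing foil in the optical path?
#' @param foil_contrast Residual contrast fraction under foil (default 0.3).
#' @param foil_offset_c Warm offset under foil (default 1.5 C).
#' @param width_px,height_px Frame size (default 160 x 120).
#' @param noise_sd_c Per-pixel temperature noise SD (default 0: exact).
#' @return A `thermal_frame` (raw matrix is `height_px` x `width_px`).
#' @export
render_thermal <- function(scene, plant_temp_c = 24, background_temp_c = 21.5,
                           foil = FALSE, foil_contrast = 0.3,
                           foil_offset_c = 1.5,
                           width_px = 160, height_px = 120, noise_sd_c = 0) {
  stopifnot(inherits(scene, "scene_truth"))
  # square scan area mapped onto the central square of the frame
  scale <- min(width_px, height_px) / max(scene$extent_mm)
  x_mm <- (seq_len(width_px) - (width_px - height_px) / 2 - 0.5) / scale
  y_mm <- (seq_len(height_px) - 0.5) / scale
  tc <- matrix(background_temp_c, height_px, width_px)
  for (b in scene$plants)
    tc[disk_mask(x_mm, y_mm, b$center_xy[1], b$center_xy[2], b$radius_mm)] <-
      plant_temp_c
  if (foil) tc <- mean(tc) + (tc - mean(tc)) * foil_contrast + foil_offset_c
  if (noise_sd_c > 0)
    tc <- tc + with_seed(scene$seed + 4L,
                         matrix(stats::rnorm(length(tc), 0, noise_sd_c),
                                height_px))
  thermal_frame(matrix(celsius_to_raw(tc), height_px, width_px),
                foil_present = foil)
}

#' Default plant layout for synthetic experiments
#'
#' Four hemisphere blobs on the medium, mirroring the four explants placed
#' per vessel. Blobs sit at equally spaced angles (with a little jitter) and
#' never overlap, so every blob's apex height is also the local canopy
#' height; sizes and heights come from narrow uniform ranges.
#'
#' @param seed Integer seed.
#' @param n_plants Number of blobs (default 4).
#' @return List of [plant_blob()]s.
#' @export
random_plants <- function(seed, n_plants = 4) {
  with_seed(seed, {
    ang <- (seq_len(n_plants) - 1) * 2 * pi / n_plants +
      stats::runif(n_plants, -0.15, 0.15)
    dist <- stats::runif(n_plants, 14, 20)
    lapply(seq_len(n_plants), function(i)
      plant_blob(center_xy = c(50 + dist[i] * cos(ang[i]),
                               50 + dist[i] * sin(ang[i])),
                 radius_mm = stats::runif(1, 5, 8),
                 max_height_mm = stats::runif(1, 6, 14),
                 color = c(50 + stats::runif(1, 0, 30), 130 + stats::runif(1, 0, 30),
                           50 + stats::runif(1, 0, 20))))
  })
}
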