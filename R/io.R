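#' Read and write depth grids
#'
#' Long-format CSV exchange (`x_mm`, `y_mm`, `raw`; one row per scan point,
#' empty `raw` where the sensor returned nothing) and 16-bit TIFF (raw
#' counts scaled by 1/65535; 0 encodes an invalid point).
#'
#' @param grid A `depth_grid`.
#' @param path File path.
#' @return Writers return `path` invisibly; readers a `depth_grid`.
#' @export
write_depth_csv <- function(grid, path) {
  stopifnot(inherits(grid, "depth_grid"))
  g <- coord_grids(grid$x_mm, grid$y_mm)
  utils::write.csv(data.frame(x_mm = as.vector(g$x), y_mm = as.vector(g$y),
                              raw = as.vector(grid$raw)),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_depth_csv
#' @export
read_depth_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x_mm", "y_mm", "raw") %in% names(df)))
  xs <- sort(unique(df$x_mm)); ys <- sort(unique(df$y_mm))
  raw <- matrix(NA_real_, length(ys), length(xs))
  raw[cbind(match(df$y_mm, ys), match(df$x_mm, xs))] <- df$raw
  xp <- if (length(xs) > 1) stats::median(diff(xs)) else 1
  yp <- if (length(ys) > 1) stats::median(diff(ys)) else 1
  depth_grid(raw, x_pitch = xp, y_pitch = yp)
}

#' @rdname write_depth_csv
#' @param x_pitch,y_pitch Scan pitch (mm) to attach when reading a TIFF.
#' @export
write_depth_tiff <- function(grid, path) {
  stopifnot(inherits(grid, "depth_grid"))
  raw <- round(grid$raw)  # counts are integral on the sensor scale
  raw[!grid$valid | !is.finite(raw)] <- 0
  tiff::writeTIFF(raw / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_depth_csv
#' @export
read_depth_tiff <- function(path, x_pitch = 1, y_pitch = 1) {
  raw <- round(tiff::readTIFF(path) * 65535)
  raw[raw == 0] <- NA_real_
  depth_grid(raw, x_pitch = x_pitch, y_pitch = y_pitch)
}

#' Read and write vessel images and masks as PNG
#'
#' @param img A `vessel_image` (or H x W x 3 array, 0-255).
#' @param mask Logical matrix.
#' @param path File path.
#' @param pm,illumination Metadata attached on read.
#' @return Writers return `path` invisibly.
#' @export
write_image_png <- function(img, path) {
  px <- if (inherits(img, "vessel_image")) img$pixels else img
  png::writePNG(px / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_vessel_image <- function(path, pm = pixel_metric(3.77, 20),
                              illumination = "unknown") {
  px <- png::readPNG(path) * 255
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  structure(list(pixels = px, illumination = illumination, pixel_metric = pm,
                 truth_mask = NULL, timestamp = NULL),
            class = "vessel_image")
}

#' @rdname write_image_png
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "plant_mask")) mask$mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Read and write thermal frames as 16-bit TIFF
#'
#' @param frame A `thermal_frame`.
#' @param path File path.
#' @export
write_thermal_tiff <- function(frame, path) {
  stopifnot(inherits(frame, "thermal_frame"))
  tiff::writeTIFF(frame$raw / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_thermal_tiff
#' @param foil_present Metadata attached on read.
#' @export
read_thermal_tiff <- function(path, foil_present = FALSE) {
  thermal_frame(round(tiff::readTIFF(path) * 65535), foil_present = foil_present)
}

#' Serialise a scene description to JSON
#'
#' @param scene A [scene_truth()].
#' @param path File path.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "scene_truth"))
  obj <- unclass(scene)
  obj$plants <- lapply(scene$plants, unclass)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  plants <- lapply(seq_len(if (is.data.frame(o$plants)) nrow(o$plants)
                           else length(o$plants)), function(i) {
    p <- if (is.data.frame(o$plants)) lapply(o$plants, function(cl)
      if (is.list(cl)) cl[[i]] else cl[i]) else o$plants[[i]]
    plant_blob(unlist(p$center_xy), p$radius_mm, p$max_height_mm,
               shape = p$shape, color = unlist(p$color))
  })
  scene_truth(medium_center_xy = unlist(o$medium_center_xy),
              medium_radius_mm = o$medium_radius_mm,
              medium_height_mm = o$medium_height_mm,
              medium_tilt = unlist(o$medium_tilt),
              plants = plants,
              noise_sd_mm = o$noise_sd_mm,
              dropout_slope_threshold = o$dropout_slope_threshold,
              extent_mm = unlist(o$extent_mm),
              seed = o$seed)
}
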