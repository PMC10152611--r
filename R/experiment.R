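#' Generate an on-disk synthetic experiment with ground truth
#'
#' Builds the directory tree an acquisition run would leave behind -- one
#' subfolder per culture vessel with per-timepoint RGB, depth, fluorescence
#' and thermal files -- entirely from the synthetic renderers, plus a truth
#' table of the generating parameters for parameter-recovery checks. Plants
#' grow and the medium shrinks over timepoints.
#'
#' @param root Output directory (created).
#' @param seed Global seed; every vessel/timepoint derives a substream.
#' @param n_vessels,n_timepoints Experiment size.
#' @param pm Pixel pitch for the RGB renders.
#' @param depth_timepoints Timepoint indices with a depth scan (default all;
#'   scans are slow, so real runs may skip some).
#' @return Invisibly, the truth table (also written to `<root>/truth.csv`).
#' @export
make_fixtures <- function(root, seed = 1L, n_vessels = 2, n_timepoints = 3,
                          pm = pixel_metric(3.77, 20),
                          depth_timepoints = seq_len(n_timepoints)) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  cal <- synthetic_laser_calibration()
  write_calibration(cal, pm, file.path(root, "calibration.json"))
  truth <- list()
  for (v in seq_len(n_vessels)) {
    vdir <- file.path(root, sprintf("vessel_%02d", v))
    dir.create(vdir, showWarnings = FALSE)
    vseed <- (seed %% 100000L) * 1000L + v * 37L
    plants0 <- random_plants(vseed)
    dark <- render_spectrum(scene_truth(seed = vseed), has_plant_in_spot = FALSE,
                            excitation_amp = 0, kind = "dark")
    write_spectrum_csv(dark, file.path(vdir, "dark.csv"))
    for (t in seq_len(n_timepoints)) {
      grow <- 1 + 0.15 * (t - 1)
      plants <- lapply(plants0, function(p)
        plant_blob(p$center_xy, min(p$radius_mm * grow, 9),
                   p$max_height_mm * grow, shape = p$shape, color = p$color))
      sc <- scene_truth(medium_height_mm = 20 - 0.3 * (t - 1),
                        plants = plants, seed = vseed + 101L * t)
      im <- render_rgb(sc, pm)
      write_image_png(im, file.path(vdir, sprintf("t%02d_rgb.png", t)))
      if (t %in% depth_timepoints)
        write_depth_csv(render_depth(sc, cal),
                        file.path(vdir, sprintf("t%02d_depth.csv", t)))
      write_spectrum_csv(render_spectrum(sc, amplitudes = c(150, 120) * grow),
                         file.path(vdir, sprintf("t%02d_spectrum.csv", t)))
      write_thermal_tiff(render_thermal(sc),
                         file.path(vdir, sprintf("t%02d_thermal.tif", t)))
      write_scene_json(sc, file.path(vdir, sprintf("t%02d_scene.json", t)))
      truth[[length(truth) + 1]] <- data.frame(
        vessel_id = sprintf("vessel_%02d", v), timepoint = t,
        medium_height_mm = sc$medium_height_mm,
        max_plant_height_mm = max(vapply(plants, `[[`, numeric(1),
                                         "max_height_mm")),
        plant_area_mm2 = sum(im$truth_mask) / pm$pixels_per_mm^2,
        has_depth = t %in% depth_timepoints)
    }
  }
  truth <- do.call(rbind, truth)
  utils::write.csv(truth, file.path(root, "truth.csv"), row.names = FALSE)
  invisible(truth)
}

trait_row <- function(vessel, timepoint, sensor, trait, value, unit) {
  data.frame(vessel_id = vessel, timepoint = timepoint, sensor = sensor,
             trait = trait, value = as.numeric(value), unit = unit)
}

#' Process a whole experiment directory into a tidy trait table
#'
#' The desk-scale analogue of the acquisition loop: for every vessel and
#' timepoint, the RGB frame is checked for night conditions and segmented,
#' traits are extracted, the depth scan (when present) runs through the
#' depth pipeline with the medium circle carried over from the vessel's
#' first scan, the fluorescence spectrum is dark-corrected and summarised,
#' and the thermal frame is converted. Results accumulate in a tidy CSV;
#' re-running skips vessel/timepoint/sensor combinations already present,
#' and unreadable files are logged and skipped.
#'
#' @param config A list or path to a JSON file with fields: `root`
#'   (experiment directory, required), `classifier` (path to a saved
#'   [pixel_classifier()]; when absent a default classifier is trained on
#'   internal synthetic scenes), `ransac_iterations` (default 10000), `seed`
#'   (default 1), `night_threshold` (default 30), `output` (default
#'   `<root>/traits.csv`).
#' @return The full tidy trait table (data frame), invisibly written to the
#'   output CSV.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(!is.null(config$root), dir.exists(config$root))
  root <- config$root
  iters <- config$ransac_iterations %||% 10000
  seed <- config$seed %||% 1L
  night_thr <- config$night_threshold %||% 30
  out_path <- config$output %||% file.path(root, "traits.csv")
  cals <- read_calibration(file.path(root, "calibration.json"))
  clf <- if (!is.null(config$classifier) && file.exists(config$classifier))
    read_pixel_classifier(config$classifier) else default_classifier(seed)
  done <- if (file.exists(out_path)) utils::read.csv(out_path) else NULL
  is_done <- function(v, t, s) !is.null(done) &&
    any(done$vessel_id == v & done$timepoint == t & done$sensor == s)
  rows <- list()
  add <- function(df) rows[[length(rows) + 1]] <<- df
  vessels <- sort(list.dirs(root, recursive = FALSE))
  vessels <- vessels[grepl("vessel_", basename(vessels))]
  for (vdir in vessels) {
    v <- basename(vdir)
    dark_path <- file.path(vdir, "dark.csv")
    dark <- if (file.exists(dark_path)) read_spectrum_csv(dark_path) else NULL
    circle <- NULL
    tps <- sort(as.integer(sub("^t(\\d+)_rgb\\.png$", "\\1",
                               basename(list.files(vdir,
                                                   pattern = "^t\\d+_rgb\\.png$")))))
    for (t in tps) {
      f_rgb <- file.path(vdir, sprintf("t%02d_rgb.png", t))
      if (!is_done(v, t, "rgb")) {
        res <- tryCatch({
          img <- read_vessel_image(f_rgb, pm = cals$pixel)
          night <- is_night(img, night_thr)
          tr <- extract_traits(segment(img, clf), cals$pixel)
          rbind(trait_row(v, t, "rgb", "is_night", as.numeric(night), "bool"),
                trait_row(v, t, "rgb", "projected_area_px",
                          tr$total$area_px, "px"),
                trait_row(v, t, "rgb", "projected_area_mm2",
                          tr$total$area_mm2, "mm2"),
                trait_row(v, t, "rgb", "degree_of_coverage",
                          tr$total$coverage, "fraction"),
                trait_row(v, t, "rgb", "n_objects", tr$total$n_objects, "count"))
        }, error = function(e) {
          message(sprintf("skipping %s (%s)", f_rgb, conditionMessage(e))); NULL
        })
        if (!is.null(res)) add(res)
      }
      f_depth <- file.path(vdir, sprintf("t%02d_depth.csv", t))
      if (file.exists(f_depth) && !is_done(v, t, "depth")) {
        res <- tryCatch({
          grid <- read_depth_csv(f_depth)
          dp <- depth_pipeline(grid, cals$laser, circle = circle,
                               iterations = iters, seed = seed)
          circle <- dp$circle  # day-0 circle reused for later scans
          tr <- dp$traits
          rbind(trait_row(v, t, "depth", "medium_height_mm",
                          tr$medium_height_mm, "mm"),
                trait_row(v, t, "depth", "medium_volume_mm3",
                          tr$medium_volume_mm3, "mm3"),
                trait_row(v, t, "depth", "avg_canopy_height_mm",
                          tr$avg_canopy_height_mm, "mm"),
                trait_row(v, t, "depth", "max_plant_height_mm",
                          tr$max_plant_height_mm, "mm"),
                trait_row(v, t, "depth", "projected_area_depth_mm2",
                          tr$projected_area_depth_mm2, "mm2"))
        }, error = function(e) {
          message(sprintf("skipping %s (%s)", f_depth, conditionMessage(e))); NULL
        })
        if (!is.null(res)) add(res)
      }
      f_spec <- file.path(vdir, sprintf("t%02d_spectrum.csv", t))
      if (file.exists(f_spec) && !is_done(v, t, "spectral")) {
        res <- tryCatch({
          sp <- read_spectrum_csv(f_spec)
          if (!is.null(dark)) sp <- subtract_dark(sp, dark)
          fl <- fluorescence_summary(mask_band(sp))
          rbind(trait_row(v, t, "spectral", "F690", fl$F690, "counts"),
                trait_row(v, t, "spectral", "F730", fl$F730, "counts"),
                trait_row(v, t, "spectral", "F740", fl$F740, "counts"),
                trait_row(v, t, "spectral", "ratio_F690_F740",
                          fl$ratio_F690_F740, "ratio"))
        }, error = function(e) {
          message(sprintf("skipping %s (%s)", f_spec, conditionMessage(e))); NULL
        })
        if (!is.null(res)) add(res)
      }
      f_th <- file.path(vdir, sprintf("t%02d_thermal.tif", t))
      if (file.exists(f_th) && !is_done(v, t, "thermal")) {
        res <- tryCatch({
          fr <- read_thermal_tiff(f_th)
          st <- frame_stats(fr)
          rbind(trait_row(v, t, "thermal", "mean_temp_c", st$mean_c, "C"),
                trait_row(v, t, "thermal", "min_temp_c", st$min_c, "C"),
                trait_row(v, t, "thermal", "max_temp_c", st$max_c, "C"),
                trait_row(v, t, "thermal", "contrast_c",
                          contrast_index(fr), "C"))
        }, error = function(e) {
          message(sprintf("skipping %s (%s)", f_th, conditionMessage(e))); NULL
        })
        if (!is.null(res)) add(res)
      }
    }
  }
  new <- if (length(rows)) do.call(rbind, rows) else NULL
  all_rows <- rbind(done, new)
  if (!is.null(all_rows))
    utils::write.csv(all_rows, out_path, row.names = FALSE)
  invisible(all_rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the default pixel classifier on internal synthetic scenes
#'
#' Four day scenes with the default generator settings, 2000 sampled labels
#' per class each; used by [run_experiment()] when no saved classifier is
#' configured.
#'
#' @param seed RNG seed.
#' @param n_scenes Number of training scenes.
#' @return A `pixel_classifier`.
#' @export
default_classifier <- function(seed = 1L, n_scenes = 4) {
  scenes <- lapply(seq_len(n_scenes), function(i)
    scene_truth(plants = random_plants(seed * 211L + i), seed = seed * 211L + i))
  imgs <- lapply(scenes, render_rgb)
  labs <- lapply(seq_along(imgs), function(i)
    labels_from_truth(imgs[[i]]$truth_mask, 2000, seed = seed + i))
  train_pixel_classifier(imgs, labs, seed = seed)
}
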