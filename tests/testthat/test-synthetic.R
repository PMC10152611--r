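test_that("noise-free depth renders are exact constructions", {
  cal <- synthetic_laser_calibration()
  sc <- scene_truth(noise_sd_mm = 0, seed = 1)
  grid <- render_depth(sc, cal)
  h <- grid_heights(grid, cal, zero_raw = cal$zero_raw)$height
  inside <- disk_mask(grid$x_mm, grid$y_mm, 50, 50, 37)
  expect_true(all(abs(h[inside] - 20) < 1e-9))
  expect_true(all(abs(h[!inside]) < 1e-9))
  # one cone of max 15 on a 20 mm medium: global max is 35 exactly
  sc2 <- scene_truth(noise_sd_mm = 0, dropout_slope_threshold = Inf,
                     plants = list(plant_blob(c(50, 50), 10, 15, shape = "cone")),
                     seed = 1)
  h2 <- grid_heights(render_depth(sc2, cal), cal, cal$zero_raw)$height
  expect_equal(max(h2), 35)
})

test_that("dropout follows the analytic surface slope", {
  cal <- synthetic_laser_calibration()
  blob <- plant_blob(c(50, 50), 10, 10, shape = "cone")  # slope 1 inside
  # threshold 0: every sloped (plant) point drops out, flat medium stays
  sc0 <- scene_truth(plants = list(blob), dropout_slope_threshold = 0,
                     noise_sd_mm = 0, seed = 1)
  g0 <- render_depth(sc0, cal)
  f <- scene_height_field(sc0, g0$x_mm, g0$y_mm)
  expect_true(all(!g0$valid[f$slope > 0]))
  expect_true(all(g0$valid[f$slope == 0]))
  # threshold above the cone slope keeps everything
  sc1 <- scene_truth(plants = list(blob), dropout_slope_threshold = 1.5,
                     noise_sd_mm = 0, seed = 1)
  expect_true(all(render_depth(sc1, cal)$valid))
  # default scenes lose about one third of plant pixels on average
  lost <- vapply(31:36, function(s) {
    sc2 <- make_scene(s)
    g2 <- render_depth(sc2, cal)
    f2 <- scene_height_field(sc2, g2$x_mm, g2$y_mm)
    sum(f2$plant & !g2$valid) / sum(f2$plant)
  }, numeric(1))
  expect_true(all(lost > 0.05 & lost < 0.6))
  expect_gt(mean(lost), 0.23); expect_lt(mean(lost), 0.43)
})

test_that("renders are bit-reproducible for a fixed seed and independent", {
  sc <- make_scene(17)
  g1 <- render_depth(sc); g2 <- render_depth(sc)
  expect_identical(g1$raw, g2$raw)
  i1 <- render_rgb(sc); i2 <- render_rgb(sc)
  expect_identical(i1$pixels, i2$pixels)
  s1 <- render_spectrum(sc); s2 <- render_spectrum(sc)
  expect_identical(s1$counts, s2$counts)
  # different seeds change the noise
  sc_b <- scene_truth(plants = sc$plants, seed = 18)
  expect_false(identical(render_depth(sc_b)$raw, g1$raw))
})

test_that("RGB renders carry exact truth masks and day/night contrast", {
  sc0 <- scene_truth(seed = 3)  # no plants
  im0 <- render_rgb(sc0)
  expect_equal(sum(im0$truth_mask), 0)
  # one disk blob: truth equals its rasterisation
  pmq <- pixel_metric(3.77, 20)
  blob <- plant_blob(c(50, 50), 8, 10)
  sc1 <- scene_truth(plants = list(blob), seed = 3)
  im1 <- render_rgb(sc1, pmq)
  x_mm <- (seq_len(dim(im1$pixels)[2]) - 0.5) / pmq$pixels_per_mm
  y_mm <- (seq_len(dim(im1$pixels)[1]) - 0.5) / pmq$pixels_per_mm
  expect_identical(im1$truth_mask, disk_mask(x_mm, y_mm, 50, 50, 8))
  day <- render_rgb(sc1, illumination = "day")
  night <- render_rgb(sc1, illumination = "night")
  expect_gt(mean(day$pixels), mean(night$pixels))
  expect_true(is_night(night$pixels))
  expect_false(is_night(day$pixels))
})

test_that("spectral renders show plant peaks only when a plant is in the spot", {
  sc <- make_scene(4)
  sp_plant <- render_spectrum(sc, has_plant_in_spot = TRUE)
  sp_empty <- render_spectrum(sc, has_plant_in_spot = FALSE)
  emission <- sp_plant$wavelengths_nm >= 660 & sp_plant$wavelengths_nm <= 780
  dark_level <- 60
  expect_gt(max(sp_plant$counts[emission]), dark_level + 50)
  expect_lt(max(sp_empty$counts[emission]), dark_level + 20)
  # no excitation leak when the UV amplitude is zero
  sp_noexc <- render_spectrum(sc, excitation_amp = 0, has_plant_in_spot = FALSE)
  near375 <- abs(sp_noexc$wavelengths_nm - 375) <= 10
  expect_lt(max(sp_noexc$counts[near375]), dark_level + 20)
})

test_that("scene invariants reject impossible constructions", {
  expect_error(scene_truth(medium_center_xy = c(10, 50)), "fit inside")
  expect_error(scene_truth(plants = list(plant_blob(c(80, 50), 10, 5))),
               "within the medium")
  expect_error(plant_blob(c(0, 0), -1, 5))
})

test_that("scenes and depth grids survive file round trips", {
  sc <- make_scene(12)
  p1 <- withr::local_tempfile(fileext = ".json")
  write_scene_json(sc, p1)
  back <- read_scene_json(p1)
  expect_equal(back$medium_height_mm, sc$medium_height_mm)
  expect_equal(length(back$plants), length(sc$plants))
  expect_equal(back$plants[[2]]$max_height_mm, sc$plants[[2]]$max_height_mm)
  g <- render_depth(sc)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_depth_csv(g, p2)
  g2 <- read_depth_csv(p2)
  expect_equal(g2$raw, g$raw)
  expect_identical(g2$valid, g$valid)
  p3 <- withr::local_tempfile(fileext = ".tif")
  write_depth_tiff(g, p3)
  g3 <- read_depth_tiff(p3)
  expect_equal(g3$raw[g$valid], round(g$raw[g$valid]))
})
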