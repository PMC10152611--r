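test_that("zero level averages the corner blocks and skips invalid points", {
  g <- depth_grid(matrix(19430, 40, 40))
  expect_equal(zero_level(g), 19430)
  # interior contamination does not leak into the corners
  raw <- matrix(19430, 40, 40); raw[15:25, 15:25] <- 20430
  expect_equal(zero_level(depth_grid(raw)), 19430)
  # one corner fully invalid: mean over the remaining 300 points
  raw2 <- matrix(19430, 40, 40); raw2[31:40, 31:40] <- NA
  raw2[1:10, 1:10] <- 19440
  expect_equal(zero_level(depth_grid(raw2)), (100 * 19440 + 200 * 19430) / 300)
  expect_error(zero_level(depth_grid(matrix(19430, 15, 15))), "too small")
  all_na <- matrix(19430, 40, 40)
  all_na[c(1:10, 31:40), c(1:10, 31:40)] <- NA
  expect_error(zero_level(depth_grid(all_na)), "corner")
})

test_that("Hough transform finds the medium circle within a pixel", {
  cal <- synthetic_laser_calibration()
  sc <- scene_truth(noise_sd_mm = 0, seed = 1)
  h <- grid_heights(render_depth(sc, cal), cal, cal$zero_raw)$height
  circ <- detect_medium_circle(h)
  expect_equal(circ$radius, 37, tolerance = 1)
  expect_equal(circ$center[1], 50, tolerance = 1)
  expect_equal(circ$center[2], 50, tolerance = 1)
  # with default sensor noise
  scn <- scene_truth(seed = 2)
  hn <- grid_heights(render_depth(scn, cal), cal, cal$zero_raw)$height
  circn <- detect_medium_circle(hn)
  expect_equal(circn$radius, 37, tolerance = 1)
  # flat grid: nothing to find
  expect_error(detect_medium_circle(matrix(0, 100, 100)), "edge")
})

test_that("edge-removed mask shaves three pixels off the rim", {
  m <- edge_removed_mask(c(50, 50), 37, c(100, 100))
  ref <- disk_mask(0:99, 0:99, 50, 50, 34)
  expect_identical(m, ref)
  expect_error(edge_removed_mask(c(50, 50), 3, c(100, 100)), "positive")
  # radius 4 leaves a tiny disk
  m4 <- edge_removed_mask(c(50, 50), 4, c(100, 100))
  expect_gte(sum(m4), 1)
  expect_lte(sum(m4), 9)
})

test_that("RANSAC recovers a plane under heavy outliers", {
  set.seed(3)
  n <- 2000
  x <- stats::runif(n, 0, 100); y <- stats::runif(n, 0, 100)
  z <- 20 + 0.01 * x
  out <- sample(n, n * 0.05)
  z[out] <- 40
  fit <- ransac_plane(x, y, z, iterations = 500, seed = 7)
  expect_equal(fit$plane, c(0.01, 0, 20), tolerance = 1e-6)
  expect_equal(sum(fit$inliers), n - length(out))
  # identical heights: horizontal plane
  fit2 <- ransac_plane(x, y, rep(20, n), iterations = 100, seed = 1)
  expect_equal(fit2$plane, c(0, 0, 20), tolerance = 1e-9)
  # degenerate: fewer than 3 points
  expect_error(ransac_plane(1, 1, 1), "at least 3")
})

test_that("RANSAC coefficients are within 3 standard errors under noise", {
  set.seed(8)
  n <- 3000
  x <- stats::runif(n, 0, 100); y <- stats::runif(n, 0, 100)
  z <- 20 + 0.012 * x - 0.007 * y + stats::rnorm(n, 0, 0.1)
  fit <- ransac_plane(x, y, z, iterations = 300, seed = 2)
  ls <- stats::lm(z ~ x + y)
  se <- summary(ls)$coefficients[, 2]
  expect_lt(abs(fit$plane[1] - 0.012), 3 * se["x"])
  expect_lt(abs(fit$plane[2] + 0.007), 3 * se["y"])
  expect_lt(abs(fit$plane[3] - 20), 3 * se["(Intercept)"])
})

test_that("RANSAC is reproducible for a fixed seed and stable across seeds", {
  set.seed(4)
  n <- 1500
  x <- stats::runif(n, 0, 100); y <- stats::runif(n, 0, 100)
  z <- 20 + 0.01 * x + stats::rnorm(n, 0, 0.1)
  f1 <- ransac_plane(x, y, z, iterations = 400, seed = 9)
  f2 <- ransac_plane(x, y, z, iterations = 400, seed = 9)
  expect_identical(f1$plane, f2$plane)
  sizes <- sapply(1:5, function(s)
    ransac_plane(x, y, z, iterations = 400, seed = s)$n_inliers)
  expect_lt(diff(range(sizes)) / mean(sizes), 0.01)
})

test_that("plane correction zeroes the medium and exposes plant heights", {
  cal <- synthetic_laser_calibration()
  sc <- scene_truth(noise_sd_mm = 0, medium_tilt = c(0.02, -0.01), seed = 1)
  h <- grid_heights(render_depth(sc, cal), cal, cal$zero_raw)$height
  mask <- edge_removed_mask(c(50, 50), 37, dim(h))
  plane <- c(0.02, -0.01, 20 - 0.02 * 50 + 0.01 * 50)
  corr <- correct_and_segment(h, plane, mask)
  expect_true(all(corr[mask] == 0))
  expect_true(all(is.na(corr[!mask])))
  # a 15 mm cone pokes out by exactly 15 at its apex
  sc2 <- scene_truth(noise_sd_mm = 0, dropout_slope_threshold = Inf,
                     plants = list(plant_blob(c(50, 50), 10, 15, shape = "cone")),
                     seed = 1)
  h2 <- grid_heights(render_depth(sc2, cal), cal, cal$zero_raw)$height
  corr2 <- correct_and_segment(h2, c(0, 0, 20), mask)
  expect_equal(max(corr2, na.rm = TRUE), 15)
  expect_lte(sum(corr2 > 0, na.rm = TRUE), sum(mask))
})

test_that("depth traits follow their closed-form definitions", {
  # frustum limits: cylinder and cone
  expect_equal(frustum_volume(3, 37, 37), pi * 37^2 * 3)
  expect_equal(frustum_volume(3, 0, 37), pi * 3 * 37^2 / 3)
  expect_equal(frustum_volume(0, 30, 37), 0)
  # percentile rule: heights 1..20 -> mean of {19, 20}
  plant <- matrix(NA_real_, 30, 30)
  mask <- matrix(FALSE, 30, 30); mask[1:25, 1:25] <- TRUE
  plant[mask] <- 0
  plant[1, 1:20] <- 1:20
  tr <- depth_traits(c(0, 0, 5), plant, mask, pitch_mm = 1, r1_mm = 37)
  expect_equal(tr$max_plant_height_mm, 19.5)
  expect_equal(tr$avg_canopy_height_mm, mean(1:20))
  expect_equal(tr$projected_area_depth_mm2, 20)
  expect_equal(tr$medium_height_mm, 5)
  expect_equal(tr$medium_volume_mm3, frustum_volume(5, 37, 37))
  # no plant pixels: canopy metrics missing, area zero
  plant0 <- plant; plant0[1, 1:20] <- 0
  tr0 <- depth_traits(c(0, 0, 5), plant0, mask, 1, r1_mm = 37)
  expect_true(is.na(tr0$avg_canopy_height_mm))
  expect_equal(tr0$projected_area_depth_mm2, 0)
})

test_that("the full pipeline recovers scene parameters", {
  cal <- synthetic_laser_calibration()
  sc <- scene_truth(medium_tilt = c(0.008, -0.004),
                    plants = random_plants(71), seed = 71)
  res <- depth_pipeline(render_depth(sc, cal), cal, iterations = 2000, seed = 5)
  truth <- scene_depth_truth(sc)
  n_corner <- 400
  tol_h <- 3 * sc$noise_sd_mm * sqrt(1 / res$n_inliers + 1 / n_corner)
  expect_lt(abs(res$traits$medium_height_mm - truth$medium_height_mm), tol_h)
  expect_lt(abs(res$plane[1] - 0.008), 5e-4)
  expect_lt(abs(res$plane[2] + 0.004), 5e-4)
  expect_lt(abs(res$traits$avg_canopy_height_mm - truth$canopy_mm),
            3 * sc$noise_sd_mm)
  expect_lt(abs(res$traits$max_plant_height_mm - truth$max_mm),
            3 * sc$noise_sd_mm)
  # dropout only removes plant pixels relative to the RGB truth
  im <- render_rgb(sc)
  rgb_area <- sum(im$truth_mask) / 3.77^2
  expect_lte(res$traits$projected_area_depth_mm2, rgb_area)
})
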