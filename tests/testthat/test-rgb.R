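test_that("contrast stretching maps percentile range to full scale", {
  # constant image unchanged
  const <- array(100, c(10, 10, 3))
  expect_identical(stretch_contrast(const), const)
  # uniform channel spanning [50, 200]: ends map to 0/255 after clipping
  set.seed(1)
  img <- array(stats::runif(3e4, 50, 200), c(100, 100, 3))
  img[1] <- 50; img[2] <- 200
  out <- stretch_contrast(img)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  # already full-range uniform: unchanged up to clipping at the ends
  img2 <- array(stats::runif(3e4, 0, 255), c(100, 100, 3))
  out2 <- stretch_contrast(img2)
  mid <- img2 > 50 & img2 < 200
  expect_lt(max(abs(out2[mid] - img2[mid])), 6)
})

test_that("downscaling uses tile means with a trailing partial tile", {
  # 4x4 constant, factor 4 -> single identical pixel
  expect_equal(as.vector(downscale(array(7, c(4, 4, 3)), 4)),
               rep(7, 3))
  # checkerboard, factor 2: tile mean 127.5 rounds half-to-even to 128
  cb <- array(0, c(4, 4, 3))
  for (k in 1:3) cb[, , k] <- matrix(c(0, 255), 4, 4)
  expect_true(all(downscale(cb, 2) == 128))
  # ceiling sizes: the full-frame geometry maps 4054 x 3040 to 1014 x 760
  expect_equal(dim(downscale(array(0, c(10, 7, 3)), 4))[1:2], c(3, 2))
  expect_equal(ceiling(c(4054, 3040) / 4), c(1014, 760))
  # partial tiles average only the pixels they cover
  m <- array(0, c(2, 5, 1)); m[, 5, 1] <- 10
  expect_equal(as.vector(downscale(m, 4)), c(0, 10))
})

test_that("Otsu equals the exhaustive between-class-variance maximiser", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(50:500, 1)
    v <- switch(1 + i %% 3,
                round(c(stats::rnorm(n, 60, 15), stats::rnorm(n, 170, 20))),
                round(stats::runif(n, 0, 255)),
                sample(c(30, 90), n, replace = TRUE, prob = c(0.6, 0.4)))
    v <- pmin(pmax(v, 0), 255)
    expect_identical(otsu_threshold(v), otsu_brute_force(v),
                     info = sprintf("case %d", i))
  }
  # bimodal masses at 30 and 90
  v <- c(rep(30, 500), rep(90, 300))
  expect_identical(otsu_threshold(v), otsu_brute_force(v))
})

test_that("8-connected labelling joins diagonals and separates gaps", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE       # diagonal pair: one object
  m[5, 5] <- TRUE                        # far pixel: second object
  l <- label8(m)
  expect_equal(max(l), 2)
  expect_equal(l[1, 1], l[2, 2])
  expect_false(l[5, 5] == l[1, 1])
})

test_that("trait extraction matches exact geometry on squares and disks", {
  pm <- pixel_metric(10)
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  tr <- extract_traits(sq, pm)
  expect_equal(tr$objects$area_px, 100)
  expect_equal(tr$objects$hull_area_px, 100)
  expect_equal(tr$objects$solidity, 1)
  expect_equal(tr$objects$perimeter_px, 36)
  expect_equal(tr$total$area_mm2, 1)
  expect_equal(tr$total$coverage, 100 / 400)
  # rasterised disk: solidity ~ 1; stockiness reflects the sqrt(2)-weighted
  # chain metric, which overestimates a circle's circumference by ~5%
  dk <- disk_mask(1:120, 1:120, 60, 60, 50)
  trd <- extract_traits(dk, pm)
  expect_equal(trd$objects$solidity, 1, tolerance = 0.01)
  expect_equal(trd$objects$stockiness, 0.907, tolerance = 0.02)
  # empty mask: zeroed record
  tre <- extract_traits(matrix(FALSE, 5, 5), pm)
  expect_equal(tre$total$area_px, 0)
  expect_equal(nrow(tre$objects), 0)
  # full frame: coverage 1
  expect_equal(extract_traits(matrix(TRUE, 8, 8), pm)$total$coverage, 1)
})

test_that("cumulative area equals the sum of per-object areas", {
  sc <- make_scene(41)
  im <- render_rgb(sc)
  tr <- extract_traits(im$truth_mask, pixel_metric(3.77, 20))
  expect_equal(tr$total$area_px, sum(tr$objects$area_px))
  expect_equal(tr$total$coverage * tr$total$total_px, tr$total$area_px)
  expect_equal(tr$total$n_objects, 4)
  expect_true(all(tr$objects$solidity > 0 & tr$objects$solidity <= 1 + 1e-9))
})

test_that("classifier training demands both classes and separates a toy scene", {
  img <- array(30, c(80, 80, 3)); img[, 41:80, 2] <- 200
  lab <- matrix(0L, 80, 80); lab[, 1:16] <- 1L; lab[, 65:80] <- 2L
  clf <- train_pixel_classifier(list(img), list(lab), factor = 1,
                                num_trees = 50)
  pm <- segment(img, clf)
  # held-out pixels away from the boundary classify perfectly
  expect_true(all(pm$mask[, 46:80]))
  expect_true(all(!pm$mask[, 1:35]))
  lab1 <- lab; lab1[lab1 == 2L] <- 1L
  expect_error(train_pixel_classifier(list(img), list(lab1)), "both classes")
})

test_that("segmentation finds components and survives empty scenes", {
  clf <- get_test_classifier()
  sc <- make_scene(51)
  im <- render_rgb(sc)
  pm <- segment(im, clf)
  expect_equal(dim(pm$mask), dim(im$truth_mask))
  cs <- confusion_stats(pm$mask, im$truth_mask)
  expect_gt(cs$accuracy, 0.97)
  expect_gte(pm$n_components, 4)   # four blobs (plus possible specks)
  big <- sum(tabulate(pm$labels[pm$labels > 0]) > 100)
  expect_equal(big, 4)
  # empty scene
  im0 <- render_rgb(scene_truth(seed = 52))
  pm0 <- segment(im0, clf)
  expect_lt(sum(pm0$mask) / length(pm0$mask), 0.001)
})

test_that("mask rescaling error is bounded by boundary tiles", {
  clf <- get_test_classifier()
  f <- clf$factor
  sc <- make_scene(53)
  im <- render_rgb(sc)
  small <- downscale(stretch_contrast(im$pixels), f)
  pred <- segment(im, clf)
  # upscaled area is exactly f^2 times the downscaled mask area (interior
  # tiles), up to partial trailing tiles
  n_small <- sum(matrix(pred$mask[seq(1, nrow(pred$mask), by = f),
                                  seq(1, ncol(pred$mask), by = f)], ncol = 1))
  expect_lte(abs(sum(pred$mask) - n_small * f^2),
             (f^2 - 1) * (2 * (dim(small)[1] + dim(small)[2])))
})

test_that("plant positions come from hue-Otsu centroid offsets", {
  # one blob at the image midpoint: zero offset
  sc <- scene_truth(plants = list(plant_blob(c(50, 50), 8, 10)), seed = 61)
  im <- render_rgb(sc)
  pos <- find_plant_positions(im, motion_xy = c(0, 0))
  # the blob is by far the largest object (noise may add tiny specks)
  expect_gt(pos$area_px[1], 1000)
  expect_lt(abs(pos$x_mm[1]), 0.3)
  expect_lt(abs(pos$y_mm[1]), 0.3)
  # gantry offset adds through
  pos2 <- find_plant_positions(im, motion_xy = c(120, 80))
  expect_equal(pos2$x_mm[1] - 120, pos$x_mm[1], tolerance = 1e-9)
  # six blobs of distinct sizes: the four largest are returned
  blobs <- lapply(1:6, function(i)
    plant_blob(c(50 + 24 * cos(i * pi / 3), 50 + 24 * sin(i * pi / 3)),
               2 + i, 5))
  sc6 <- scene_truth(plants = blobs, seed = 62)
  im6 <- render_rgb(sc6)
  pos6 <- find_plant_positions(im6, motion_xy = c(50, 50))
  expect_equal(nrow(pos6), 4)
  got <- apply(pos6[, c("x_mm", "y_mm")], 1, function(p)
    which.min(sapply(blobs, function(b) sum((b$center_xy - p)^2))))
  expect_setequal(got, 3:6)
})

test_that("night detection uses a strict mean-intensity threshold", {
  expect_true(is_night(array(0, c(4, 4, 3))))
  expect_false(is_night(array(255, c(4, 4, 3))))
  expect_false(is_night(array(30, c(4, 4, 3)), threshold = 30))  # tie: day
  expect_true(is_night(array(29.9, c(4, 4, 3)), threshold = 30))
})
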