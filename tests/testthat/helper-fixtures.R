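# shared test fixtures, built in code once per test run

.fixture_env <- new.env(parent = emptyenv())

# default day scene with four non-overlapping hemisphere plants
make_scene <- function(seed, ...) {
  scene_truth(plants = random_plants(seed), seed = seed, ...)
}

# classifier trained on four synthetic day scenes; cached across test files
get_test_classifier <- function() {
  if (is.null(.fixture_env$clf)) {
    scenes <- lapply(1:4, make_scene)
    imgs <- lapply(scenes, render_rgb)
    labs <- lapply(seq_along(imgs), function(i)
      labels_from_truth(imgs[[i]]$truth_mask, 2000, seed = i))
    .fixture_env$clf <- train_pixel_classifier(imgs, labs, seed = 42)
  }
  .fixture_env$clf
}

# literal per-threshold two-group Otsu oracle (kept naive on purpose)
otsu_brute_force <- function(values) {
  v <- as.integer(round(values))
  best <- -1; best_t <- 0L
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    s <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (s > best) { best <- s; best_t <- t }
  }
  best_t
}

# per-scene depth ground truth from the ideal surface, using the same
# geometric rules the pipeline applies (rim-shaved disk, medium/plant cut)
scene_depth_truth <- function(scene, cut = 1.5, shrink = 3) {
  xs <- 0:(scene$extent_mm[1] - 1); ys <- 0:(scene$extent_mm[2] - 1)
  f <- scene_height_field(scene, xs, ys)
  cx <- scene$medium_center_xy[1]; cy <- scene$medium_center_xy[2]
  g <- coord_grids(xs, ys)
  plane <- scene$medium_height_mm +
    scene$medium_tilt[1] * (g$x - cx) + scene$medium_tilt[2] * (g$y - cy)
  mask <- (g$x - cx)^2 + (g$y - cy)^2 <= (scene$medium_radius_mm - shrink)^2
  ph <- f$height - plane
  sel <- mask & f$slope <= scene$dropout_slope_threshold & ph > cut
  ph <- ph[sel]
  list(medium_height_mm = scene$medium_height_mm,
       canopy_mm = if (length(ph)) mean(ph) else NA_real_,
       max_mm = if (length(ph))
         mean(ph[ph >= stats::quantile(ph, 0.9, type = 7)]) else NA_real_,
       n_plant = length(ph))
}
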