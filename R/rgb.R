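#' Histogram-stretch brightness/contrast adjustment
#'
#' Per-channel linear map sending the 1st/99th intensity percentiles to
#' 0/255 with clipping; robust to specular highlights. Constant channels are
#' left unchanged.
#'
#' @param img A `vessel_image` or an H x W x 3 array on the 0-255 scale.
#' @return Same type as the input.
#' @export
stretch_contrast <- function(img) {
  px <- if (inherits(img, "vessel_image")) img$pixels else img
  stopifnot(length(dim(px)) == 3)
  for (k in seq_len(dim(px)[3])) {
    ch <- px[, , k]
    q <- stats::quantile(ch, c(0.01, 0.99), type = 7, names = FALSE)
    if (q[2] > q[1]) {
      ch <- (ch - q[1]) * 255 / (q[2] - q[1])
      px[, , k] <- pmin(pmax(ch, 0), 255)
    }
  }
  if (inherits(img, "vessel_image")) { img$pixels <- px; img } else px
}

# block mean over f x f tiles; trailing partial tiles average the pixels
# they actually cover, so an n-pixel axis yields ceiling(n/f) tiles
block_mean <- function(m, f) {
  ri <- ceiling(seq_len(nrow(m)) / f)
  cs <- ceiling(seq_len(ncol(m)) / f)
  s <- rowsum(m, ri)
  s <- t(rowsum(t(s), cs))
  cnt <- outer(tabulate(ri), tabulate(cs))
  s / cnt
}

#' Area-average downscaling
#'
#' Reduces resolution by an integer factor using tile means (a trailing
#' partial tile averages its available pixels, so 4054 px maps to 1014).
#' Tile means are rounded half-to-even back to the 8-bit scale.
#'
#' @param img A `vessel_image` or H x W x 3 array (0-255).
#' @param factor Integer downscale factor (default 4).
#' @return Same type as the input, at reduced resolution; for a
#'   `vessel_image` the attached pixel pitch is scaled accordingly.
#' @export
downscale <- function(img, factor = 4) {
  stopifnot(factor >= 1, factor == as.integer(factor))
  px <- if (inherits(img, "vessel_image")) img$pixels else img
  out <- array(0, dim = c(ceiling(dim(px)[1] / factor),
                          ceiling(dim(px)[2] / factor), dim(px)[3]))
  for (k in seq_len(dim(px)[3])) out[, , k] <- round(block_mean(px[, , k], factor))
  if (inherits(img, "vessel_image")) {
    img$pixels <- out
    img$pixel_metric <- pixel_metric(img$pixel_metric$pixels_per_mm / factor,
                                     img$pixel_metric$reference_height_mm)
    img
  } else out
}

#' Otsu threshold by exhaustive search
#'
#' Maximises the between-class variance over all 256 candidate thresholds of
#' an 8-bit histogram. Ties are broken toward the smallest threshold.
#' Foreground is `value > threshold`.
#'
#' @param values Numeric vector on the 0-255 scale (rounded to integers), or
#'   a 256-bin histogram of counts when `is_histogram = TRUE`.
#' @param is_histogram Interpret `values` as bin counts for levels 0..255.
#' @return Integer threshold in 0..254.
#' @export
otsu_threshold <- function(values, is_histogram = FALSE) {
  counts <- if (is_histogram) {
    stopifnot(length(values) == 256)
    as.numeric(values)
  } else {
    tabulate(as.integer(round(values)) + 1L, nbins = 256L)
  }
  n <- sum(counts)
  if (n == 0) stop("empty input")
  lev <- 0:255
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * lev)
  mt <- m0[256]
  w1 <- n - w0
  # between-class variance for threshold t = lev (foreground > t)
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (mt - m0) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  bcv <- bcv[1:255]  # t in 0..254
  which.max(bcv) - 1L
}

# 8-connected labelling: 4-connected pass, then merge labels touching
# diagonally (union-find over the label adjacency pairs)
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  l <- EBImage::bwlabel(mask * 1)
  nl <- max(l)
  if (nl <= 1) return(l)
  nr <- nrow(l); nc <- ncol(l)
  d1 <- cbind(as.vector(l[-nr, -nc]), as.vector(l[-1, -1]))    # \ diagonal
  d2 <- cbind(as.vector(l[-nr, -1]), as.vector(l[-1, -nc]))    # / diagonal
  pr <- rbind(d1, d2)
  pr <- unique(pr[pr[, 1] > 0 & pr[, 2] > 0 & pr[, 1] != pr[, 2], , drop = FALSE])
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(pr))) {
    a <- find(pr[i, 1]); b <- find(pr[i, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- l
  out[l > 0] <- remap[l[l > 0]]
  out
}

# gaussian-smoothed channel; EBImage gblur with the kernel clamped to fit
# small rasters (support must not exceed the image)
smooth_gauss <- function(m, sigma) {
  radius <- 2 * ceiling(3 * sigma) + 1
  fit <- min(dim(m)) - (min(dim(m)) + 1) %% 2  # largest odd <= min dim
  EBImage::gblur(m, sigma = sigma, radius = min(radius, fit))
}

# central-difference gradient magnitude with replicated edges
grad_mag <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  xp <- m[, c(2:nc, nc)]; xm <- m[, c(1, 1:(nc - 1))]
  yp <- m[c(2:nr, nr), ]; ym <- m[c(1, 1:(nr - 1)), ]
  sqrt(((xp - xm) / 2)^2 + ((yp - ym) / 2)^2)
}

# discrete 4-neighbour laplacian with replicated edges
laplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[, c(2:nc, nc)] + m[, c(1, 1:(nc - 1))] +
    m[c(2:nr, nr), ] + m[c(1, 1:(nr - 1)), ] - 4 * m
}

#' Per-pixel feature bank for trainable segmentation
#'
#' The fixed 14-feature bank the pixel classifier is trained on: the three
#' RGB channels; hue, saturation and value; Gaussian-smoothed intensity at
#' scales 1, 3.5 and 10 px; gradient magnitude of the smoothed intensity at
#' scales 1.6 and 5 px; its Laplacian at scales 1.6 and 5 px; and a
#' difference of Gaussians (1.6 minus 5 px). Computed at the working
#' (downscaled) resolution.
#'
#' @param px H x W x 3 array on the 0-255 scale.
#' @return Numeric matrix of `H*W` rows and 14 named columns (pixels in
#'   column-major raster order).
#' @export
pixel_features <- function(px) {
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 255)
  intensity <- (r + g + b) / 3
  s1 <- smooth_gauss(intensity, 1)
  s35 <- smooth_gauss(intensity, 3.5)
  s10 <- smooth_gauss(intensity, 10)
  s16 <- smooth_gauss(intensity, 1.6)
  s5 <- smooth_gauss(intensity, 5)
  f <- cbind(R = as.vector(r), G = as.vector(g), B = as.vector(b),
             H = hsv[1, ], S = hsv[2, ], V = hsv[3, ],
             gauss1 = as.vector(s1), gauss3.5 = as.vector(s35),
             gauss10 = as.vector(s10),
             grad1.6 = as.vector(grad_mag(s16)), grad5 = as.vector(grad_mag(s5)),
             lap1.6 = as.vector(laplacian(s16)), lap5 = as.vector(laplacian(s5)),
             dog = as.vector(s16 - s5))
  f
}

# majority label per tile (0 = unlabeled wins only if no labeled pixel)
downscale_labels <- function(labels, factor) {
  c1 <- block_mean((labels == 1) * 1, factor)
  c2 <- block_mean((labels == 2) * 1, factor)
  out <- matrix(0L, nrow(c1), ncol(c1))
  out[c1 > 0 & c1 >= c2] <- 1L
  out[c2 > 0 & c2 > c1] <- 2L
  out
}

#' Train the pixel-wise random-forest plant/background classifier
#'
#' Images are contrast-stretched and downscaled, the 14-feature bank is
#' computed, and a random forest is fit on the labeled pixels. Labels use
#' 0 = unlabeled, 1 = background, 2 = plant (partial labelling is the normal
#' case); label rasters at native resolution are reduced to the working
#' resolution by per-tile majority.
#'
#' @param images List of `vessel_image`s or H x W x 3 arrays.
#' @param labels List of integer label rasters congruent with the images.
#' @param factor Downscale factor (default 4).
#' @param num_trees Forest size (default 100).
#' @param seed RNG seed for the forest.
#' @return Object of class `pixel_classifier` (ranger model + metadata).
#' @export
train_pixel_classifier <- function(images, labels, factor = 4,
                                   num_trees = 100, seed = 1L) {
  stopifnot(length(images) == length(labels), length(images) >= 1)
  all_labs <- unlist(lapply(labels, function(l) unique(l[l > 0])))
  if (!all(c(1L, 2L) %in% all_labs))
    stop("training labels must contain both classes")
  feats <- list(); labs <- list()
  for (i in seq_along(images)) {
    img <- stretch_contrast(images[[i]])
    px <- if (inherits(img, "vessel_image")) img$pixels else img
    stopifnot(identical(dim(px)[1:2], dim(labels[[i]])))
    small <- downscale(px, factor)
    lab <- downscale_labels(labels[[i]], factor)
    f <- pixel_features(small)
    sel <- as.vector(lab) > 0
    feats[[i]] <- f[sel, , drop = FALSE]
    labs[[i]] <- as.vector(lab)[sel]
  }
  f <- do.call(rbind, feats)
  y <- factor(unlist(labs), levels = c(1, 2), labels = c("background", "plant"))
  df <- data.frame(f, y = y)
  model <- ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                          seed = seed, num.threads = 1)
  structure(list(model = model, factor = factor,
                 features = colnames(f), num_trees = num_trees),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %d trees, %d features, factor %d, OOB error %.4f\n",
              x$num_trees, length(x$features), x$factor,
              x$model$prediction.error))
  invisible(x)
}

#' Save/load a pixel classifier
#'
#' The model is serialised to a single RDS file with a JSON sidecar
#' documenting the feature bank and downscale factor.
#'
#' @param clf A `pixel_classifier`.
#' @param path RDS file path (sidecar written as `<path>.json`).
#' @return `write_pixel_classifier` returns `path` invisibly.
#' @export
write_pixel_classifier <- function(clf, path) {
  saveRDS(clf, path)
  jsonlite::write_json(list(features = clf$features, factor = clf$factor,
                            num_trees = clf$num_trees),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pixel_classifier
#' @export
read_pixel_classifier <- function(path) {
  clf <- readRDS(path)
  stopifnot(inherits(clf, "pixel_classifier"))
  clf
}

#' Segment plant pixels in a vessel image
#'
#' Applies contrast stretching, downscales, classifies every pixel with the
#' trained forest, rescales the binary mask back to the native resolution by
#' nearest neighbour (preserving binarity), and labels connected components
#' with 8-connectivity.
#'
#' @param img A `vessel_image` or H x W x 3 array (0-255).
#' @param clf A `pixel_classifier`.
#' @return Object of class `plant_mask`: list with logical `mask` (native
#'   resolution), integer `labels` raster, `n_components`.
#' @export
segment <- function(img, clf) {
  stopifnot(inherits(clf, "pixel_classifier"))
  px <- if (inherits(img, "vessel_image")) img$pixels else img
  small <- downscale(stretch_contrast(px), clf$factor)
  f <- pixel_features(small)
  pred <- stats::predict(clf$model, data = data.frame(f),
                         num.threads = 1)$predictions
  msmall <- matrix(pred == "plant", dim(small)[1], dim(small)[2])
  # nearest-neighbour upscale: native pixel (i, j) maps to tile
  # (ceiling(i/f), ceiling(j/f)), the exact inverse of the tiling
  ri <- ceiling(seq_len(dim(px)[1]) / clf$factor)
  ci <- ceiling(seq_len(dim(px)[2]) / clf$factor)
  mask <- msmall[ri, ci, drop = FALSE]
  labels <- label8(mask)
  structure(list(mask = mask, labels = labels,
                 n_components = max(labels)),
            class = "plant_mask")
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("<plant_mask> %d x %d px, %d plant px, %d component(s)\n",
              ncol(x$mask), nrow(x$mask), sum(x$mask), x$n_components))
  invisible(x)
}

# Moore-neighbour boundary tracing; returns the closed contour length with
# diagonal steps weighted sqrt(2). Single pixels use the unit-square
# perimeter 4; dominoes and lines trace out and back.
moore_perimeter <- function(m) {
  pts <- which(m, arr.ind = TRUE)
  if (nrow(pts) == 1) return(4)
  o <- order(pts[, 1], pts[, 2])
  start <- pts[o[1], ]
  # clockwise Moore ring starting W: W NW N NE E SE S SW as (drow, dcol)
  ring <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                 ncol = 2, byrow = TRUE)
  inside <- function(p) p[1] >= 1 && p[1] <= nrow(m) && p[2] >= 1 && p[2] <= ncol(m)
  cur <- start
  back_dir <- 1L  # scanning entered from the W neighbour (background)
  per <- 0
  start_state <- NULL
  steps <- 0L
  repeat {
    found_d <- 0L
    for (s in 1:8) {
      d <- ((back_dir - 1L + s) %% 8L) + 1L
      p <- cur + ring[d, ]
      if (inside(p) && m[p[1], p[2]]) { found_d <- d; break }
    }
    if (found_d == 0L) return(per)  # no 8-neighbour: defensive
    state <- c(cur, found_d)
    # stop on repeating the initial (pixel, exit-direction) state: the
    # contour is closed (handles 1-px-wide parts revisiting the start)
    if (!is.null(start_state) && all(state == start_state)) break
    if (is.null(start_state)) start_state <- state
    p <- cur + ring[found_d, ]
    per <- per + if (sum(abs(ring[found_d, ])) == 2L) sqrt(2) else 1
    prev_d <- ((found_d - 2L) %% 8L) + 1L
    rel <- (cur + ring[prev_d, ]) - p
    back_dir <- which(ring[, 1] == rel[1] & ring[, 2] == rel[2])
    cur <- p
    steps <- steps + 1L
    if (steps > 8L * nrow(pts) + 8L) break  # safety bound
  }
  per
}

# convex hull "pixel count" area by Pick's theorem on the hull of pixel
# centres: interior + boundary lattice points = A + B/2 + 1
hull_area_px <- function(pts) {
  if (nrow(pts) <= 2) return(nrow(pts))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n <= 2) {
    # collinear object: lattice points on the segment
    d <- hp[min(2, n), ] - hp[1, ]
    return(ifelse(n == 1, 1, gcd2(abs(d[1]), abs(d[2])) + 1))
  }
  xs <- hp[, 2]; ys <- hp[, 1]
  a2 <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys))
  bb <- sum(vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    gcd2(abs(xs[j] - xs[i]), abs(ys[j] - ys[i]))
  }, numeric(1)))
  a2 / 2 + bb / 2 + 1
}

gcd2 <- function(a, b) if (b == 0) max(a, 1) else Recall(b, a %% b)

#' Extract morphometric traits from a plant mask
#'
#' Per-object projected area (pixel count), perimeter (8-connected boundary
#' contour length, diagonal steps weighted sqrt(2)), convex hull area (as
#' equivalent pixel count), solidity (area / hull area), stockiness
#' (4 pi area / perimeter^2, 1 for a circle), plus cumulative area and the
#' degree of coverage (plant pixels / total pixels). Metric conversions via
#' the pixel pitch.
#'
#' @param mask A `plant_mask` from [segment()], or a logical matrix.
#' @param pm A [pixel_metric()] for mm conversions.
#' @return List of class `trait_record`: `objects` data frame (one row per
#'   component, columns `object_id`, `area_px`, `area_mm2`, `perimeter_px`,
#'   `hull_area_px`, `solidity`, `stockiness`) and `total` list
#'   (`area_px`, `area_mm2`, `coverage`, `n_objects`, `total_px`).
#' @export
extract_traits <- function(mask, pm = pixel_metric(37.7, 20)) {
  if (inherits(mask, "plant_mask")) {
    labels <- mask$labels; m <- mask$mask
  } else {
    m <- mask > 0
    labels <- label8(m)
  }
  total_px <- length(m)
  nl <- max(labels)
  if (nl == 0) {
    objects <- data.frame(object_id = integer(0), area_px = numeric(0),
                          area_mm2 = numeric(0), perimeter_px = numeric(0),
                          hull_area_px = numeric(0), solidity = numeric(0),
                          stockiness = numeric(0))
  } else {
    objects <- do.call(rbind, lapply(seq_len(nl), function(i) {
      om <- labels == i
      pts <- which(om, arr.ind = TRUE)
      area <- nrow(pts)
      per <- moore_perimeter(om)
      hull <- hull_area_px(pts)
      data.frame(object_id = i, area_px = area,
                 area_mm2 = area_px_to_mm2(pm, area),
                 perimeter_px = per, hull_area_px = hull,
                 solidity = area / hull,
                 stockiness = 4 * pi * area / per^2)
    }))
  }
  cum_area <- sum(objects$area_px)
  structure(list(objects = objects,
                 total = list(area_px = cum_area,
                              area_mm2 = area_px_to_mm2(pm, cum_area),
                              coverage = cum_area / total_px,
                              n_objects = nl, total_px = total_px)),
            class = "trait_record")
}

#' @export
print.trait_record <- function(x, ...) {
  cat(sprintf("<trait_record> %d object(s), %g plant px (%.2f%% coverage)\n",
              x$total$n_objects, x$total$area_px, 100 * x$total$coverage))
  invisible(x)
}

#' Determine plant positions from an initial vessel image
#'
#' Converts the image to hue-saturation-value space, thresholds the hue
#' channel with Otsu's method (exhaustive between-class-variance search),
#' keeps the largest connected objects (at most `n`), and converts their
#' centroid offsets from the image midpoint to scene millimetres added to
#' the gantry position.
#'
#' @param img A `vessel_image` or H x W x 3 array (0-255).
#' @param motion_xy Gantry (x, y) position of the image midpoint (mm).
#' @param pm A [pixel_metric()]; defaults to the one attached to `img`.
#' @param n Maximum number of positions (default 4, one per explant).
#' @return Data frame with columns `x_mm`, `y_mm`, `area_px`; zero rows when
#'   nothing is found.
#' @export
find_plant_positions <- function(img, motion_xy = c(0, 0), pm = NULL, n = 4) {
  px <- if (inherits(img, "vessel_image")) img$pixels else img
  if (is.null(pm))
    pm <- if (inherits(img, "vessel_image")) img$pixel_metric else
      stop("pm required when img carries no pixel metric")
  hsv <- grDevices::rgb2hsv(rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                                  as.vector(px[, , 3])), maxColorValue = 255)
  hue <- matrix(hsv[1, ] * 255, dim(px)[1], dim(px)[2])
  t <- otsu_threshold(hue)
  fg <- hue > t
  labels <- label8(fg)
  if (max(labels) == 0)
    return(data.frame(x_mm = numeric(0), y_mm = numeric(0), area_px = numeric(0)))
  sizes <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(n, sum(sizes > 0)))]
  mid <- c((dim(px)[2] + 1) / 2, (dim(px)[1] + 1) / 2)  # (x, y) in px
  out <- do.call(rbind, lapply(keep, function(i) {
    pts <- which(labels == i, arr.ind = TRUE)
    cen <- c(mean(pts[, 2]), mean(pts[, 1]))
    data.frame(x_mm = motion_xy[1] + (cen[1] - mid[1]) / pm$pixels_per_mm,
               y_mm = motion_xy[2] + (cen[2] - mid[2]) / pm$pixels_per_mm,
               area_px = nrow(pts))
  }))
  rownames(out) <- NULL
  out
}

#' Night-image detection
#'
#' An image captured without system illumination is classified as night when
#' its mean intensity over all channels falls strictly below the threshold.
#'
#' @param img A `vessel_image` or H x W x 3 array (0-255).
#' @param threshold Mean-intensity cut (default 30).
#' @return `TRUE` for night.
#' @export
is_night <- function(img, threshold = 30) {
  px <- if (inherits(img, "vessel_image")) img$pixels else img
  mean(px) < threshold
}

#' Sample sparse training labels from a ground-truth mask
#'
#' Builds the partial label raster (0 unlabeled, 1 background, 2 plant) a
#' human annotator would scribble, by sampling pixels of each class from the
#' renderer's exact truth.
#'
#' @param truth Logical ground-truth plant mask.
#' @param n_per_class Labeled pixels per class (default 2000).
#' @param seed RNG seed.
#' @return Integer label raster congruent with `truth`.
#' @export
labels_from_truth <- function(truth, n_per_class = 2000, seed = 1L) {
  lab <- matrix(0L, nrow(truth), ncol(truth))
  with_seed(seed, {
    pl <- which(truth); bg <- which(!truth)
    lab[sample(pl, min(n_per_class, length(pl)))] <- 2L
    lab[sample(bg, min(n_per_class, length(bg)))] <- 1L
  })
  lab
}
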