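#' Pixel-wise confusion statistics between a predicted and a truth mask
#'
#' Plant pixels are the positive class, background the negative class, as in
#' segmentation validation against manually annotated ground truth. Rates
#' with an empty denominator are returned as `NA`.
#'
#' @param pred Logical raster (or 0/1) of predicted plant pixels.
#' @param truth Logical raster of true plant pixels, same shape.
#' @return List with integer counts `tp`, `fp`, `fn`, `tn` and rates
#'   `accuracy`, `sensitivity`, `specificity`, `precision`.
#' @examples
#' confusion_stats(matrix(c(TRUE, TRUE, FALSE, FALSE), 2),
#'                 matrix(c(TRUE, FALSE, FALSE, FALSE), 2))
#' @export
confusion_stats <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth masks must have identical shape")
  p <- as.logical(pred); t <- as.logical(truth)
  if (anyNA(p) || anyNA(t)) stop("masks must not contain NA")
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  n <- tp + fp + fn + tn
  if (n == 0) stop("empty masks")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / n,
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       precision = rate(tp, tp + fp))
}

#' Regression validation report
#'
#' Ordinary least-squares fit of `y` on `x` together with the error metrics
#' used to validate one measurement pipeline against another: adjusted
#' R-squared (Ezekiel form, `1 - (1 - R2)(n - 1)/(n - p - 1)` with one
#' predictor), MAE, RMSE, and the signed mean relative error in percent
#' (positive when `y` overestimates `x`). Coefficient p-values come from
#' two-sided t-tests.
#'
#' @param x Reference values (e.g. ground truth).
#' @param y Compared values (e.g. pipeline output).
#' @return List of class `regression_report`: `slope`, `intercept`, `r2`,
#'   `adj_r2`, `mae`, `rmse`, `mre_pct`, `n`, `p_slope`, `p_intercept`.
#'   With `n == 2` point estimates are returned and p-values are `NA`.
#' @examples
#' regression_report(1:10, 1:10 * 1.02)
#' @export
regression_report <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stop("need at least 2 finite (x, y) pairs")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  res <- y - x
  r2 <- if (stats::var(y) > 0 && stats::var(x) > 0) stats::cor(x, y)^2 else 1
  adj_r2 <- if (n >= 3) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  p_slope <- p_int <- NA_real_
  # a perfect fit has zero residual variance; t-tests are then degenerate
  perfect <- mean(stats::resid(fit)^2) < 1e-20 * (mean(y^2) + 1)
  if (n >= 3 && !perfect) {
    sm <- summary(fit)$coefficients
    if (nrow(sm) == 2 && ncol(sm) == 4) {
      p_int <- sm[1, 4]; p_slope <- sm[2, 4]
    }
  }
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r2 = r2, adj_r2 = adj_r2,
                 mae = mean(abs(res)),
                 rmse = sqrt(mean(res^2)),
                 mre_pct = if (all(x != 0)) mean(res / x) * 100 else NA_real_,
                 n = n, p_slope = p_slope, p_intercept = p_int),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    paste0("<regression_report> n = %d\n",
           "  y = %.4g + %.4g x   adj R2 = %.4f\n",
           "  MAE = %.4g  RMSE = %.4g  MRE = %.3g%%\n"),
    x$n, x$intercept, x$slope, x$adj_r2, x$mae, x$rmse, x$mre_pct))
  invisible(x)
}

#' Repositioning repeatability as mean absolute error
#'
#' Mean absolute deviation (px) of per-event positions from the day-0
#' reference, converted to millimetres via the pixel pitch measured at the
#' reference object's height. Reported mm values are rounded half-up to two
#' decimals, matching the presentation convention for repeatability tables.
#'
#' @param deviations_px Per-event deviations from the reference, in pixels.
#' @param pm A [pixel_metric()].
#' @return List with `mae_px` and `mae_mm` (rounded to 2 decimals).
#' @examples
#' repositioning_mae(c(10.9, -10.9), pixel_metric(46.7, 41))
#' @export
repositioning_mae <- function(deviations_px, pm) {
  stopifnot(length(deviations_px) >= 1)
  mae_px <- mean(abs(deviations_px))
  list(mae_px = mae_px,
       mae_mm = round_half_up(px_to_mm(pm, mae_px), 2))
}
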