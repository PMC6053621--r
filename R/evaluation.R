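#' Pixelwise confusion counts between two binary masks
#'
#' @param pred,ref Binary masks (0/1 or 0/255) of equal size; `ref` is the
#'   ground truth, foreground = ear.
#' @return Named integer vector `c(TP, TN, FP, FN)`; the four counts sum to
#'   the pixel count.
#' @export
confusion <- function(pred, ref) {
  p <- as_binary_mask(pred, "pred")
  r <- as_binary_mask(ref, "ref")
  if (!all(dim(p) == dim(r)))
    stop("pred and ref sizes differ", call. = FALSE)
  c(TP = sum(p == 1L & r == 1L), TN = sum(p == 0L & r == 0L),
    FP = sum(p == 1L & r == 0L), FN = sum(p == 0L & r == 1L))
}

#' Segmentation quality indicators
#'
#' Computes the five pixel-level indicators:
#' * `Qseg`: both-class consistency — agreeing pixels of each class omega
#'   in \{ear, background\} over the union, summed over both classes; equal to
#'   `a / (2T - a)` for `a` agreeing pixels out of `T`.
#' * `Sr`: ear-class completeness, `|pred_ear & ref_ear| / |ref_ear|`.
#' * `precision` = TP / (TP + FP) (0 when nothing is predicted),
#'   `recall` = TP / (TP + FN), and the F-measure
#'   `F = 2 P R / (P + R)` (0 when P + R = 0).
#'
#' The single-class (ear) Jaccard index is also reported as `jaccard_ear`
#' for comparison with the both-class `Qseg` reading.
#'
#' @inheritParams confusion
#' @return Named numeric vector with `qseg`, `sr`, `precision`, `recall`,
#'   `f`, `jaccard_ear` and the four confusion counts.
#' @export
pixel_metrics <- function(pred, ref) {
  cm <- confusion(pred, ref)
  TP <- cm[["TP"]]; TN <- cm[["TN"]]; FP <- cm[["FP"]]; FN <- cm[["FN"]]
  Tpx <- TP + TN + FP + FN
  if (TP + FN == 0)
    stop("reference mask has no ear pixels; Sr is undefined", call. = FALSE)
  a <- TP + TN
  qseg <- (TP + TN) / ((TP + FP + FN) + (TN + FP + FN))
  sr <- TP / (TP + FN)
  precision <- if (TP + FP == 0) 0 else TP / (TP + FP)
  recall <- TP / (TP + FN)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  jac <- if (TP + FP + FN == 0) 1 else TP / (TP + FP + FN)
  c(qseg = qseg, sr = sr, precision = precision, recall = recall, f = f,
    jaccard_ear = jac, TP = TP, TN = TN, FP = FP, FN = FN)
}

gaussian_kernel_1d <- function(window, sigma) {
  half <- (window - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g / sum(g)
}

#' Structural similarity between two masks
#'
#' Standard SSIM with an 11x11 Gaussian window (sigma 1.5) and stabilizing
#' constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`. Binary masks are scaled to
#' \{0, 255\} before computation (`L = 255`), local statistics use reflected
#' borders, and the mean over the SSIM map is returned.
#'
#' @param pred,ref Binary masks of equal size (values 0/1 or 0/255).
#' @param window Odd Gaussian window size (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param L Dynamic range (default 255).
#' @return SSIM value in \[-1, 1\] (1 iff the masks are identical).
#' @export
mask_ssim <- function(pred, ref, window = 11, sigma = 1.5, L = 255) {
  p <- as_binary_mask(pred, "pred") * L
  r <- as_binary_mask(ref, "ref") * L
  if (!all(dim(p) == dim(r))) stop("pred and ref sizes differ", call. = FALSE)
  if (nrow(p) < window || ncol(p) < window)
    stop("image smaller than the SSIM window", call. = FALSE)
  g <- gaussian_kernel_1d(window, sigma)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_p <- conv2_sep(p, g); mu_r <- conv2_sep(r, g)
  var_p <- conv2_sep(p * p, g) - mu_p^2
  var_r <- conv2_sep(r * r, g) - mu_r^2
  cov_pr <- conv2_sep(p * r, g) - mu_p * mu_r
  num <- (2 * mu_p * mu_r + C1) * (2 * cov_pr + C2)
  den <- (mu_p^2 + mu_r^2 + C1) * (var_p + var_r + C2)
  mean(num / den)
}

#' Linear regression of predicted against true ear counts
#'
#' Ordinary least squares of predicted counts on manual (true) counts; the
#' per-plot validation protocol for the counting pipeline.
#'
#' @param pred_counts,true_counts Equal-length numeric vectors (>= 3 plots).
#' @return An object of class `count_regression`: list with `slope`,
#'   `intercept`, `r_squared`, `sd_residuals`, `n` and the fitted data.
#' @export
count_regression <- function(pred_counts, true_counts) {
  if (length(pred_counts) != length(true_counts))
    stop("count vectors differ in length", call. = FALSE)
  if (length(pred_counts) < 3)
    stop("need at least 3 plots", call. = FALSE)
  fit <- stats::lm(pred ~ true,
                   data = data.frame(pred = pred_counts, true = true_counts))
  # R^2 computed directly (summary.lm warns on perfect fits)
  rss <- sum(residuals(fit)^2)
  tss <- sum((pred_counts - mean(pred_counts))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 sd_residuals = stats::sd(residuals(fit)),
                 n = length(pred_counts),
                 data = tibble::tibble(true = true_counts,
                                       pred = pred_counts)),
            class = "count_regression")
}

#' @export
print.count_regression <- function(x, ...) {
  cat(sprintf(
    "<count_regression> n = %d: slope %.3f, R^2 = %.3f, SD = %.2f\n",
    x$n, x$slope, x$r_squared, x$sd_residuals))
  invisible(x)
}

#' @rdname count_regression
#' @param x A `count_regression` object.
#' @param ... Unused.
#' @export
tidy.count_regression <- function(x, ...) x$data

#' @rdname count_regression
#' @export
glance.count_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, sd_residuals = x$sd_residuals,
                 n = x$n)
}

#' Evaluate a batch of segmentations
#'
#' Computes the six quality indicators for every (prediction, reference)
#' mask pair plus the per-indicator mean and standard deviation.
#'
#' @param pred_masks,ref_masks Equal-length non-empty lists of binary masks.
#' @param ids Optional image identifiers (default 1..n).
#' @return An object of class `ear_eval_report`: list with `per_image`
#'   (tibble, one row per pair) and `summary` (tibble with mean and sd rows).
#' @export
evaluate_batch <- function(pred_masks, ref_masks, ids = NULL) {
  if (!is.list(pred_masks) || !is.list(ref_masks) ||
      length(pred_masks) == 0 || length(pred_masks) != length(ref_masks))
    stop("need equal-length non-empty lists of masks", call. = FALSE)
  ids <- ids %||% as.character(seq_along(pred_masks))
  rows <- lapply(seq_along(pred_masks), function(i) {
    tryCatch({
      pm <- pixel_metrics(pred_masks[[i]], ref_masks[[i]])
      tibble::tibble(image = ids[i],
                     qseg = pm[["qseg"]], sr = pm[["sr"]],
                     ssim = mask_ssim(pred_masks[[i]], ref_masks[[i]]),
                     precision = pm[["precision"]], recall = pm[["recall"]],
                     f = pm[["f"]])
    }, error = function(e)
      stop(sprintf("image %s: %s", ids[i], conditionMessage(e)),
           call. = FALSE))
  })
  per_image <- dplyr::bind_rows(rows)
  metric_cols <- c("qseg", "sr", "ssim", "precision", "recall", "f")
  summary <- dplyr::bind_rows(
    c(list(statistic = "mean"),
      lapply(per_image[metric_cols], mean)),
    c(list(statistic = "sd"),
      lapply(per_image[metric_cols], stats::sd)))
  structure(list(per_image = per_image, summary = summary),
            class = "ear_eval_report")
}

#' @export
print.ear_eval_report <- function(x, ...) {
  cat(sprintf("<ear_eval_report> %d image(s)\n", nrow(x$per_image)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ear_eval_report <- function(x, ...) x$per_image

#' @export
glance.ear_eval_report <- function(x, ...) {
  m <- x$summary[x$summary$statistic == "mean", -1]
  names(m) <- paste0("mean_", names(m))
  tibble::as_tibble(c(m, n_images = nrow(x$per_image)))
}
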