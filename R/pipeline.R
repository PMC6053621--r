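#' Segment an image into an ear/background mask
#'
#' Runs the inference half of the workflow: SLIC superpixels, one 20x20 patch
#' per superpixel, CCV/GLCM/EHD features, the model's normalization,
#' importance weighting and (if fitted) KPCA projection, TWSVM patch
#' classification, and finally painting each superpixel's pixels with its
#' patch label.
#'
#' @param image H x W x 3 8-bit RGB array.
#' @param model A trained [train_ear_model()] bundle.
#' @param slic_config Optional [slic_config()] override; defaults to the one
#'   stored in the model.
#' @return H x W integer matrix, ear = 1, background = 0.
#' @export
segment_image <- function(image, model, slic_config = NULL) {
  assert_image(image)
  if (!inherits(model, "ear_model"))
    stop("`model` must be an ear_model", call. = FALSE)
  spmap <- slic_segment(image, slic_config %||% model$slic_config)
  patches <- extract_patches(image, spmap, model$patch_size)
  feats <- feature_matrix(patches, model$feature_config)
  labels <- predict(model, feats)
  lut <- labels[spmap$centers$id]
  matrix(as.integer(lut[as.vector(spmap$labels)]),
         nrow(spmap$labels), ncol(spmap$labels))
}

#' Median-filter a binary mask
#'
#' Slides a `window` x `window` median over the mask (for binary input this
#' is the neighbourhood majority), with reflected borders. The default 3-px
#' window removes isolated misclassified pixels and burrs before counting.
#'
#' @param mask Binary matrix (0/1 or 0/255).
#' @param window Odd window side length (>= 1).
#' @return Filtered integer 0/1 mask of the same size.
#' @export
median_filter_binary <- function(mask, window = 3) {
  m <- as_binary_mask(mask)
  if (window %% 2 != 1 || window < 1)
    stop("window must be odd and >= 1", call. = FALSE)
  if (window == 1) return(m)
  p <- (window - 1L) / 2L
  mp <- pad_reflect(m, p)
  H <- nrow(m); W <- ncol(m)
  acc <- matrix(0L, H, W)
  for (dr in -p:p)
    for (dc in -p:p)
      acc <- acc + mp[(p + 1 + dr):(p + H + dr), (p + 1 + dc):(p + W + dc)]
  matrix(as.integer(acc >= (window^2 + 1) / 2), H, W)
}

#' Median-filter an RGB image (denoising)
#'
#' Channel-wise sliding-window median with reflected borders. A 3x3 image
#' median is an effective pre-segmentation denoiser for impulse
#' (salt-and-pepper) contamination and, to a lesser degree, for additive
#' noise. Distinct from [median_filter_binary()], which smooths the
#' *classified mask*.
#'
#' @param image H x W x 3 8-bit RGB array.
#' @param window Odd window side length (>= 1).
#' @return Filtered 8-bit image of the same shape.
#' @export
median_filter_image <- function(image, window = 3) {
  assert_image(image)
  if (window %% 2 != 1 || window < 1)
    stop("window must be odd and >= 1", call. = FALSE)
  if (window == 1) return(image)
  out <- image
  for (ch in 1:3)
    out[, , ch] <- cpp_median_filter(image[, , ch], as.integer(window))
  storage.mode(out) <- "integer"
  out
}

#' Count ear regions in a binary mask
#'
#' Connected-component labeling of the foreground, optional minimum-area
#' filtering, and per-region statistics. Each surviving region is counted as
#' one ear.
#'
#' @param mask Binary matrix (0/1 or 0/255).
#' @param connectivity 8 (default) or 4.
#' @param min_area Regions smaller than this many pixels are dropped
#'   (default 0: keep all).
#' @return An object of class `segmentation_result`: list with the filtered
#'   `mask`, the `count`, and `regions`, a tibble (`region_id`, `area`,
#'   `centroid_row`, `centroid_col`, bounding box) sorted by area descending.
#' @export
count_regions <- function(mask, connectivity = 8, min_area = 0) {
  m <- as_binary_mask(mask)
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8", call. = FALSE)
  lab <- cpp_label_components(m, as.integer(connectivity), FALSE)
  K <- max(lab)
  if (K == 0) {
    return(structure(list(mask = m, count = 0L,
                          regions = tibble::tibble(
                            region_id = integer(0), area = integer(0),
                            centroid_row = numeric(0), centroid_col = numeric(0),
                            row_min = integer(0), row_max = integer(0),
                            col_min = integer(0), col_max = integer(0)),
                          connectivity = connectivity, min_area = min_area),
                     class = "segmentation_result"))
  }
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- ((idx - 1L) %% nrow(m)) + 1L
  cols <- ((idx - 1L) %/% nrow(m)) + 1L
  area <- tabulate(comp, K)
  reg <- tibble::tibble(
    region_id = seq_len(K), area = area,
    centroid_row = as.vector(rowsum(rows, comp)) / area,
    centroid_col = as.vector(rowsum(cols, comp)) / area,
    row_min = as.vector(tapply(rows, comp, min)),
    row_max = as.vector(tapply(rows, comp, max)),
    col_min = as.vector(tapply(cols, comp, min)),
    col_max = as.vector(tapply(cols, comp, max)))
  keep <- reg$area >= min_area
  if (any(!keep)) {
    drop_ids <- reg$region_id[!keep]
    m[idx[comp %in% drop_ids]] <- 0L
    reg <- reg[keep, ]
  }
  reg <- reg[order(-reg$area), ]
  reg$region_id <- seq_len(nrow(reg))
  structure(list(mask = m, count = nrow(reg), regions = reg,
                 connectivity = connectivity, min_area = min_area),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d region(s), %d foreground px\n",
              x$count, sum(x$mask)))
  invisible(x)
}

#' @export
tidy.segmentation_result <- function(x, ...) x$regions

#' @export
glance.segmentation_result <- function(x, ...) {
  tibble::tibble(count = x$count, foreground_px = sum(x$mask),
                 connectivity = x$connectivity, min_area = x$min_area)
}

#' Full inference pipeline: image to ear count
#'
#' Composes [segment_image()], [median_filter_binary()] and
#' [count_regions()]; per-stage wall-clock timings are attached as the
#' `timings` attribute.
#'
#' @inheritParams segment_image
#' @param median_window Median filter window (odd; 1 disables filtering).
#' @param connectivity,min_area Passed to [count_regions()].
#' @return A [count_regions()] `segmentation_result`.
#' @export
run_pipeline <- function(image, model, slic_config = NULL, median_window = 3,
                         connectivity = 8, min_area = 0) {
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
    list(out = out, t = proc.time()[["elapsed"]] - t0)
  }
  s1 <- stage("segment", segment_image(image, model, slic_config))
  s2 <- stage("median_filter", median_filter_binary(s1$out, median_window))
  s3 <- stage("count", count_regions(s2$out, connectivity, min_area))
  res <- s3$out
  attr(res, "timings") <- c(segment = s1$t, median_filter = s2$t,
                            count = s3$t)
  res
}
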