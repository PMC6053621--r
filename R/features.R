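#' Patch descriptor configuration
#'
#' Parameters of the three patch descriptors that make up the fused feature
#' vector \[f1C | f2G | f3E\]: colour coherence vectors (CCV), grey-level
#' co-occurrence matrix (GLCM) statistics and the MPEG-7 edge histogram
#' descriptor (EHD). Defaults give a 228-dimensional vector on a 20x20 patch:
#' 4 bins/channel CCV (2 x 64 = 128), 5 statistics x 4 offsets GLCM (20) and
#' a 4x4-subimage EHD (5 x 16 = 80).
#'
#' @param ccv_bins_per_channel Uniform quantization bins per RGB channel.
#' @param ccv_coherence_threshold Minimum 8-connected component size (pixels)
#'   for a pixel to count as coherent (CCV convention: ~1% of the area).
#' @param glcm_levels Grey levels for co-occurrence quantization (>= 2).
#' @param glcm_offsets List of `c(distance, angle_degrees)` pairs.
#' @param glcm_stats Statistics per offset, a subset of `"contrast"`,
#'   `"correlation"`, `"energy"`, `"homogeneity"`, `"entropy"`.
#' @param ehd_grid Subimages per side for EHD (grid^2 subimages).
#' @param ehd_edge_threshold Minimum edge-filter magnitude for a 2x2 block to
#'   vote (MPEG-7 convention: 11).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(ccv_bins_per_channel = 4,
                           ccv_coherence_threshold = 4,
                           glcm_levels = 16,
                           glcm_offsets = list(c(1, 0), c(1, 45),
                                               c(1, 90), c(1, 135)),
                           glcm_stats = c("contrast", "correlation", "energy",
                                          "homogeneity", "entropy"),
                           ehd_grid = 4, ehd_edge_threshold = 11) {
  stopifnot(ccv_bins_per_channel >= 1, ccv_coherence_threshold >= 1,
            glcm_levels >= 2, length(glcm_offsets) >= 1,
            length(glcm_stats) >= 1, ehd_grid >= 1, ehd_edge_threshold >= 0)
  glcm_stats <- match.arg(glcm_stats, c("contrast", "correlation", "energy",
                                        "homogeneity", "entropy"),
                          several.ok = TRUE)
  structure(list(ccv_bins_per_channel = as.integer(ccv_bins_per_channel),
                 ccv_coherence_threshold = as.integer(ccv_coherence_threshold),
                 glcm_levels = as.integer(glcm_levels),
                 glcm_offsets = glcm_offsets, glcm_stats = glcm_stats,
                 ehd_grid = as.integer(ehd_grid),
                 ehd_edge_threshold = as.numeric(ehd_edge_threshold)),
            class = "feature_config")
}

#' Colour coherence vector of a patch
#'
#' The patch is blurred with a 3x3 mean filter, each channel is quantized
#' into `ccv_bins_per_channel` uniform bins, and pixels of each quantized
#' colour are split into coherent (members of an 8-connected same-colour
#' component of at least `ccv_coherence_threshold` pixels) and incoherent.
#'
#' @param patch A `p x p x 3` 8-bit RGB array.
#' @param config A [feature_config()].
#' @return Named numeric vector of length `2 * bins^3`, interleaved
#'   `(coherent_b, incoherent_b)` pixel counts per colour bin `b`.
#' @export
ccv <- function(patch, config = feature_config()) {
  assert_image(patch, "patch")
  blurred <- mean_blur3(patch)
  B <- config$ccv_bins_per_channel
  q <- function(x) pmin(B - 1L, as.integer(floor(x * B / 256)))
  color <- q(blurred[, , 1]) * B * B + q(blurred[, , 2]) * B + q(blurred[, , 3])
  cm <- matrix(as.integer(color), dim(patch)[1], dim(patch)[2])
  comp <- cpp_label_components(cm, 8L, TRUE)
  sizes <- tabulate(as.vector(comp))
  coherent <- sizes[as.vector(comp)] >= config$ccv_coherence_threshold
  ncol_bins <- B^3
  bin <- as.vector(cm) + 1L
  coh <- tabulate(bin[coherent], ncol_bins)
  inc <- tabulate(bin[!coherent], ncol_bins)
  out <- as.numeric(rbind(coh, inc))
  names(out) <- paste0("ccv.", rep(seq_len(ncol_bins) - 1L, each = 2),
                       c(".coh", ".inc"))
  out
}

glcm_offset_shift <- function(distance, angle) {
  switch(as.character(angle %% 180),
         "0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("GLCM angle must be one of 0, 45, 90, 135 degrees",
              call. = FALSE)) * as.integer(distance)
}

# symmetric normalized co-occurrence matrix for one offset
glcm_matrix <- function(levels_img, n_levels, shift) {
  H <- nrow(levels_img); W <- ncol(levels_img)
  dr <- shift[1]; dc <- shift[2]
  r1 <- max(1, 1 - dr):min(H, H - dr)
  c1 <- max(1, 1 - dc):min(W, W - dc)
  a <- levels_img[r1, c1, drop = FALSE]
  b <- levels_img[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(tabulate(a + n_levels * b + 1L, n_levels^2),
                   n_levels, n_levels)
  counts <- counts + t(counts)   # symmetrize
  counts / sum(counts)
}

glcm_stat_values <- function(P, stats) {
  n <- nrow(P)
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  vapply(stats, function(s) switch(s,
    contrast = sum((i - j)^2 * P),
    correlation = if (sd_i == 0 || sd_j == 0) 0 else
      sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j),
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j))),
    entropy = { p <- P[P > 0]; -sum(p * log(p)) }), numeric(1))
}

#' GLCM texture statistics of a patch
#'
#' Converts the patch to BT.601 luminance, quantizes to `glcm_levels` grey
#' levels, builds the symmetric normalized co-occurrence matrix for each
#' configured offset and emits the configured Haralick-style statistics.
#' Correlation of a zero-variance patch is defined as 0. Entropy uses the
#' natural logarithm.
#'
#' @inheritParams ccv
#' @return Named numeric vector of length `length(stats) * length(offsets)`.
#' @export
glcm_features <- function(patch, config = feature_config()) {
  assert_image(patch, "patch")
  if (config$glcm_levels < 2) stop("glcm_levels must be >= 2", call. = FALSE)
  L <- config$glcm_levels
  lum <- luminance(patch)
  lev <- matrix(pmin(L - 1, floor(lum * L / 256)), nrow(lum), ncol(lum))
  out <- unlist(lapply(config$glcm_offsets, function(off) {
    P <- glcm_matrix(lev, L, glcm_offset_shift(off[1], off[2]))
    v <- glcm_stat_values(P, config$glcm_stats)
    names(v) <- sprintf("glcm.d%g.a%g.%s", off[1], off[2], config$glcm_stats)
    v
  }))
  out
}

# MPEG-7 edge operators on the four 2x2 block quadrant means (tl, tr, bl, br)
ehd_magnitudes <- function(tl, tr, bl, br) {
  cbind(vertical = abs(tl - tr + bl - br),
        horizontal = abs(tl + tr - bl - br),
        diag45 = sqrt(2) * abs(tl - br),
        diag135 = sqrt(2) * abs(tr - bl),
        nondir = 2 * abs(tl - tr - bl + br))
}

#' MPEG-7 edge histogram descriptor of a patch
#'
#' The luminance patch is partitioned into `grid x grid` subimages; each
#' subimage is tiled with non-overlapping 2x2 blocks (remainder rows/columns
#' dropped). For every block the five edge operators (vertical, horizontal,
#' 45 degree, 135 degree, non-directional) are evaluated on the block's four
#' pixels; if the maximum magnitude reaches `ehd_edge_threshold` the block
#' votes for that orientation. Each subimage's five bins are normalized by
#' its block count.
#'
#' @inheritParams ccv
#' @return Named numeric vector of length `5 * grid^2`, all entries in
#'   \[0, 1\].
#' @export
ehd <- function(patch, config = feature_config()) {
  assert_image(patch, "patch")
  g <- config$ehd_grid
  lum <- luminance(patch)
  H <- nrow(lum); W <- ncol(lum)
  sh <- H %/% g; sw <- W %/% g
  if (sh < 2 || sw < 2)
    stop("ehd_grid too fine for the patch", call. = FALSE)
  out <- numeric(5 * g * g)
  dirs <- c("vertical", "horizontal", "diag45", "diag135", "nondir")
  nm <- character(5 * g * g)
  idx <- 0L
  for (gr in seq_len(g)) {
    for (gc in seq_len(g)) {
      sub <- lum[((gr - 1) * sh + 1):(gr * sh),
                 ((gc - 1) * sw + 1):(gc * sw), drop = FALSE]
      nbr <- sh %/% 2; nbc <- sw %/% 2
      rr <- seq_len(nbr) * 2 - 1; cc <- seq_len(nbc) * 2 - 1
      tl <- sub[rr, cc, drop = FALSE]
      tr <- sub[rr, cc + 1, drop = FALSE]
      bl <- sub[rr + 1, cc, drop = FALSE]
      br <- sub[rr + 1, cc + 1, drop = FALSE]
      mags <- ehd_magnitudes(as.vector(tl), as.vector(tr),
                             as.vector(bl), as.vector(br))
      vote <- max.col(mags, ties.method = "first")
      mmax <- mags[cbind(seq_len(nrow(mags)), vote)]
      bins <- tabulate(vote[mmax >= config$ehd_edge_threshold], 5)
      out[idx + 1:5] <- bins / (nbr * nbc)
      nm[idx + 1:5] <- sprintf("ehd.s%d_%d.%s", gr, gc, dirs)
      idx <- idx + 5L
    }
  }
  names(out) <- nm
  out
}

#' Assemble the fused block feature matrix
#'
#' Extracts CCV, GLCM and EHD descriptors for every patch and stacks them row
#' per patch into the block matrix \[f1C | f2G | f3E\], recording the column
#' span of each block.
#'
#' @param patchset A [extract_patches()] (optionally [label_patches()]) result.
#' @param config A [feature_config()].
#' @return An object of class `feature_matrix`: list with `values`
#'   (n_patches x D numeric matrix with named columns), `blocks` (named list
#'   of column index ranges for `f1C`, `f2G`, `f3E`), `labels` (copied from
#'   the patch set, possibly `NULL`) and `config`.
#' @export
feature_matrix <- function(patchset, config = feature_config()) {
  if (!inherits(patchset, "patch_set") || length(patchset$patches) == 0)
    stop("`patchset` must be a non-empty patch_set", call. = FALSE)
  rows <- lapply(seq_along(patchset$patches), function(i) {
    tryCatch({
      p <- patchset$patches[[i]]
      c(ccv(p, config), glcm_features(p, config), ehd(p, config))
    }, error = function(e)
      stop(sprintf("patch %d: %s", i, conditionMessage(e)), call. = FALSE))
  })
  values <- do.call(rbind, rows)
  n_ccv <- 2 * config$ccv_bins_per_channel^3
  n_glcm <- length(config$glcm_stats) * length(config$glcm_offsets)
  n_ehd <- 5 * config$ehd_grid^2
  stopifnot(ncol(values) == n_ccv + n_glcm + n_ehd)
  blocks <- list(f1C = seq_len(n_ccv),
                 f2G = n_ccv + seq_len(n_glcm),
                 f3E = n_ccv + n_glcm + seq_len(n_ehd))
  new_feature_matrix(values, blocks, patchset$labels, config)
}

new_feature_matrix <- function(values, blocks, labels = NULL, config = NULL) {
  if (any(!is.finite(values)))
    stop("feature matrix contains non-finite values", call. = FALSE)
  structure(list(values = values, blocks = blocks, labels = labels,
                 config = config),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d dims (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(x$blocks),
                            lengths(x$blocks)), collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.feature_matrix <- function(x, ...) {
  tb <- tibble::as_tibble(as.data.frame(x$values))
  if (!is.null(x$labels)) tb$label <- x$labels
  tb
}
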