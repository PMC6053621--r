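#' SLIC configuration
#'
#' Parameters of the simple linear iterative clustering (SLIC) superpixel
#' stage: localized k-means over combined CIELAB colour + position space.
#' By default the number of superpixels is chosen so that the grid step
#' S = sqrt(N / k) is about 20 px, matching the 20x20 patch size.
#'
#' @param n_superpixels Requested number of superpixels `k`; `NULL` picks
#'   `round(N / 400)` for an N-pixel image (S ~ 20 px).
#' @param compactness SLIC compactness `m`; larger values weight spatial
#'   proximity more heavily, giving squarer superpixels.
#' @param max_iterations Assignment/update iterations.
#' @param min_region_fraction Connected fragments smaller than
#'   `min_region_fraction * S^2` pixels are merged into their largest
#'   adjacent region during connectivity enforcement.
#' @return An object of class `slic_config`.
#' @export
slic_config <- function(n_superpixels = NULL, compactness = 10,
                        max_iterations = 10, min_region_fraction = 0.25) {
  if (!is.null(n_superpixels) && n_superpixels < 1)
    stop("n_superpixels must be >= 1", call. = FALSE)
  stopifnot(compactness > 0, max_iterations >= 1, min_region_fraction >= 0)
  structure(list(n_superpixels = n_superpixels,
                 compactness = as.numeric(compactness),
                 max_iterations = as.integer(max_iterations),
                 min_region_fraction = as.numeric(min_region_fraction)),
            class = "slic_config")
}

rgb_to_lab <- function(image) {
  H <- dim(image)[1]; W <- dim(image)[2]
  rgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3])) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1], H, W), a = matrix(lab[, 2], H, W),
       b = matrix(lab[, 3], H, W))
}

#' SLIC superpixel segmentation
#'
#' Seeds are placed on a regular grid with step S = sqrt(N/k) and perturbed to
#' the lowest-gradient position in a 3x3 neighbourhood; pixels within a
#' 2S x 2S window of each centre are assigned by the combined distance
#' D^2 = d_lab^2 + (d_xy / S)^2 m^2, centres are updated to the mean of their
#' pixels, and the loop runs for a fixed iteration count (the procedure is
#' fully deterministic). Finally, connectivity is enforced by merging stray
#' fragments into their largest adjacent region, so every returned label is a
#' single 4-connected region and the labels partition the image.
#'
#' @param image H x W x 3 8-bit RGB array.
#' @param config A [slic_config()].
#' @return An object of class `superpixel_map`: list with `labels` (H x W
#'   integer matrix, values 1..K), `centers` (tibble: `id`, `row`, `col`,
#'   mean `r`, `g`, `b`, `n_pixels`), `K`, `S` and `config`. Centres are
#'   unweighted means over each region's pixels.
#' @export
slic_segment <- function(image, config = slic_config()) {
  assert_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]; N <- H * W
  k <- config$n_superpixels %||% max(1L, round(N / 400))
  if (k > N) stop("more superpixels requested than pixels", call. = FALSE)
  S <- sqrt(N / k)

  lab <- rgb_to_lab(image)

  # seed grid: nr x nc with spacing as close to S as possible
  nr <- max(1L, round(H / S))
  nc <- max(1L, round(k / nr))
  while (nr * nc < k && nr * nc < N) {
    if ((nr + 1) * nc <= k) nr <- nr + 1L else nc <- nc + 1L
    if (nr > H || nc > W) break
  }
  nr <- min(nr, H); nc <- min(nc, W)
  seed_r <- (seq_len(nr) - 0.5) * H / nr
  seed_c <- (seq_len(nc) - 0.5) * W / nc
  seeds <- cbind(rep(seed_r, times = nc), rep(seed_c, each = nr))

  # gradient image (squared CIELAB gradient magnitude)
  grad <- matrix(Inf, H, W)
  if (H > 2 && W > 2) {
    g <- matrix(0, H - 2, W - 2)
    for (chan in lab) {
      gx <- chan[2:(H - 1), 3:W] - chan[2:(H - 1), 1:(W - 2)]
      gy <- chan[3:H, 2:(W - 1)] - chan[1:(H - 2), 2:(W - 1)]
      g <- g + gx^2 + gy^2
    }
    grad[2:(H - 1), 2:(W - 1)] <- g
  } else grad[] <- 0

  centers <- matrix(0, nrow(seeds), 5)
  for (i in seq_len(nrow(seeds))) {
    r <- max(1L, min(H, round(seeds[i, 1])))
    c <- max(1L, min(W, round(seeds[i, 2])))
    rr <- max(1L, r - 1L):min(H, r + 1L)
    cc <- max(1L, c - 1L):min(W, c + 1L)
    sub <- grad[rr, cc, drop = FALSE]
    pos <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    r <- rr[pos[1]]; c <- cc[pos[2]]
    centers[i, ] <- c(r - 1, c - 1, lab$L[r, c], lab$a[r, c], lab$b[r, c])
  }

  lab0 <- cpp_slic_iterate(lab$L, lab$a, lab$b, centers, S,
                           config$compactness, config$max_iterations)
  min_size <- max(1L, as.integer(round(config$min_region_fraction * S^2)))
  labels <- cpp_enforce_connectivity(lab0, min_size)

  K <- max(labels)
  idx <- as.vector(labels)
  npx <- tabulate(idx, K)
  rows <- rep(seq_len(H), times = W)
  cols <- rep(seq_len(W), each = H)
  centers_tbl <- tibble::tibble(
    id = seq_len(K),
    row = as.vector(rowsum(rows, idx)) / npx,
    col = as.vector(rowsum(cols, idx)) / npx,
    r = as.vector(rowsum(as.vector(image[, , 1]), idx)) / npx,
    g = as.vector(rowsum(as.vector(image[, , 2]), idx)) / npx,
    b = as.vector(rowsum(as.vector(image[, , 3]), idx)) / npx,
    n_pixels = npx)

  structure(list(labels = labels, centers = centers_tbl, K = K, S = S,
                 config = config),
            class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map> %d x %d, K = %d (S = %.1f px)\n",
              nrow(x$labels), ncol(x$labels), x$K, x$S))
  invisible(x)
}

#' Extract one fixed-size patch per superpixel
#'
#' Cuts a `patch_size` x `patch_size` RGB window centred on the (rounded)
#' weighted centre of each superpixel. Windows that would overhang the image
#' boundary are shifted inward so that every patch contains real pixels only
#' (never padded).
#'
#' @param image H x W x 3 8-bit RGB array.
#' @param spmap A [slic_segment()] result for the same image.
#' @param patch_size Patch side length in pixels (default 20).
#' @return An object of class `patch_set`: list with `patches` (list of
#'   `patch_size`^2 x 3 arrays), `info` (tibble: `patch_id`, `superpixel_id`,
#'   `center_row`, `center_col`, `row0`, `col0`) and `labels` (`NULL` until
#'   [label_patches()] is applied).
#' @export
extract_patches <- function(image, spmap, patch_size = 20) {
  assert_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (patch_size > min(H, W))
    stop("patch_size exceeds the image", call. = FALSE)
  half <- patch_size %/% 2
  rc <- round(spmap$centers$row)
  cc <- round(spmap$centers$col)
  row0 <- pmin(pmax(rc - half + 1, 1), H - patch_size + 1)
  col0 <- pmin(pmax(cc - half + 1, 1), W - patch_size + 1)
  patches <- lapply(seq_along(row0), function(i) {
    image[row0[i]:(row0[i] + patch_size - 1),
          col0[i]:(col0[i] + patch_size - 1), , drop = FALSE]
  })
  structure(list(
    patches = patches,
    info = tibble::tibble(patch_id = seq_along(patches),
                          superpixel_id = spmap$centers$id,
                          center_row = spmap$centers$row,
                          center_col = spmap$centers$col,
                          row0 = row0, col0 = col0),
    labels = NULL, patch_size = as.integer(patch_size)),
    class = "patch_set")
}

#' Label patches by the superpixel ear-area ratio
#'
#' For each superpixel, the ratio of ear pixels (from the ground-truth mask)
#' to the region's total pixel count is computed; the patch is labeled 0
#' (background) exactly when that ratio is zero and 1 (ear) otherwise — a
#' single ear pixel in the region suffices for a positive label.
#'
#' @param patchset A [extract_patches()] result.
#' @param spmap The [slic_segment()] result the patches came from.
#' @param mask Ground-truth binary ear mask of the same size.
#' @return The `patch_set` with `labels` filled in (integer 0/1) and an
#'   `ear_ratio` column added to `info`.
#' @export
label_patches <- function(patchset, spmap, mask) {
  mask <- as_binary_mask(mask)
  if (!all(dim(mask) == dim(spmap$labels)))
    stop("mask and superpixel map sizes differ", call. = FALSE)
  K <- spmap$K
  ear <- rowsum(as.vector(mask), as.vector(spmap$labels))
  npx <- tabulate(as.vector(spmap$labels), K)
  ratio <- as.vector(ear) / npx
  ids <- patchset$info$superpixel_id
  patchset$labels <- as.integer(ratio[ids] > 0)
  patchset$info$ear_ratio <- ratio[ids]
  patchset
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d%s\n", length(x$patches),
              x$patch_size, x$patch_size,
              if (is.null(x$labels)) "" else
                sprintf(", %d ear / %d background",
                        sum(x$labels == 1L), sum(x$labels == 0L))))
  invisible(x)
}
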