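# Internal helpers shared across modules.

# clip to [0, 255] and round to integer-valued storage
clip8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  round(x)
}

assert_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 RGB array", arg), call. = FALSE)
  if (any(!is.finite(image)) || min(image) < 0 || max(image) > 255)
    stop(sprintf("`%s` must hold 8-bit values in [0, 255]", arg), call. = FALSE)
  invisible(TRUE)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask))
    stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  invisible(TRUE)
}

# coerce a mask in {0,1}, {0,255}, logical or numeric form to integer {0,1}
as_binary_mask <- function(mask, arg = "mask") {
  assert_mask(mask, arg)
  m <- mask
  storage.mode(m) <- "double"
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1, 255)))
    stop(sprintf("`%s` must be binary (values 0/1 or 0/255)", arg),
         call. = FALSE)
  out <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  out
}

# ITU-R BT.601 luminance of an 8-bit RGB array, as an H x W matrix
luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# reflect-pad a matrix by `p` pixels on every side (edge rows/cols mirrored,
# border pixel not repeated at itself when size allows)
pad_reflect <- function(x, p) {
  H <- nrow(x); W <- ncol(x)
  top <- rev(pmin(H, seq_len(p) + 1L))
  bot <- pmax(1L, H - seq_len(p))
  ridx <- c(top, seq_len(H), bot)
  left <- rev(pmin(W, seq_len(p) + 1L))
  right <- pmax(1L, W - seq_len(p))
  cidx <- c(left, seq_len(W), right)
  x[ridx, cidx, drop = FALSE]
}

# separable 2-D convolution with reflect padding; `f` is an odd-length kernel
conv2_sep <- function(x, f) {
  p <- (length(f) - 1L) / 2L
  xp <- pad_reflect(x, p)
  # stats::filter convolves each column
  y <- stats::filter(xp, f, sides = 2)
  y <- t(stats::filter(t(y), f, sides = 2))
  H <- nrow(x); W <- ncol(x)
  y[(p + 1L):(p + H), (p + 1L):(p + W), drop = FALSE]
}

# 3x3 mean blur of each channel, reflect borders (shift-add; cheaper than a
# generic convolution for the many small patches the pipeline touches)
mean_blur3 <- function(image) {
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- image
  for (ch in 1:3) {
    p <- pad_reflect(image[, , ch], 1)
    acc <- matrix(0, H, W)
    for (dr in 0:2)
      for (dc in 0:2)
        acc <- acc + p[(1 + dr):(H + dr), (1 + dc):(W + dc)]
    out[, , ch] <- acc / 9
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
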