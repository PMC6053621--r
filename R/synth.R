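#' Configuration for a synthetic wheat field scene
#'
#' Describes one simulated field plot: image geometry, the number of ears
#' (spikes) to place, their size range, the minimum separation between ear
#' centres, the illumination level and the background texture scale. A config
#' plus its seed fully determines the generated scene, byte for byte.
#'
#' Illumination emulates the three light-intensity categories field images are
#' triaged into: a brightness multiplier of 0.6 (`"low"`), 1.0 (`"medium"`) or
#' 1.4 (`"high"`) applied in linear RGB and clipped to 8 bits.
#'
#' @param height,width Scene size in pixels; each must be at least 40 so a
#'   20x20 patch fits.
#' @param ear_count Number of ears to place (>= 0).
#' @param ear_axis_range Length-2 numeric, minimum and maximum ellipse
#'   semi-axes in pixels.
#' @param min_separation Minimum pairwise distance between ear centres, in
#'   pixels. When positive, ears are additionally kept from touching so that
#'   connected components of the ground-truth mask recover `ear_count`
#'   exactly.
#' @param illumination One of `"low"`, `"medium"`, `"high"`.
#' @param background_texture_scale Correlation length, in pixels, of the
#'   soil/leaf background mottle.
#' @param seed Integer seed; identical configs generate identical scenes.
#' @return An object of class `scene_config`.
#' @seealso [generate_scene()], [scene_batch()]
#' @export
scene_config <- function(height = 360, width = 700, ear_count = 20,
                         ear_axis_range = c(6, 14), min_separation = 40,
                         illumination = c("medium", "low", "high"),
                         background_texture_scale = 24, seed = 1L) {
  illumination <- match.arg(illumination)
  stopifnot(length(height) == 1, length(width) == 1, length(ear_count) == 1)
  if (height < 40 || width < 40)
    stop("scene must be at least 40 x 40 pixels", call. = FALSE)
  if (ear_count < 0) stop("ear_count must be >= 0", call. = FALSE)
  if (min_separation < 0) stop("min_separation must be >= 0", call. = FALSE)
  if (length(ear_axis_range) != 2 || any(ear_axis_range <= 0) ||
      ear_axis_range[1] > ear_axis_range[2])
    stop("ear_axis_range must be increasing positive (min, max)", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 ear_count = as.integer(ear_count),
                 ear_axis_range = as.numeric(ear_axis_range),
                 min_separation = as.numeric(min_separation),
                 illumination = illumination,
                 background_texture_scale = as.numeric(background_texture_scale),
                 seed = as.integer(seed)),
            class = "scene_config")
}

illumination_multiplier <- c(low = 0.6, medium = 1.0, high = 1.4)

# smooth value-noise field in [0,1] with correlation length `scale`
value_noise_field <- function(H, W, scale) {
  nr <- max(2L, ceiling(H / scale) + 1L)
  nc <- max(2L, ceiling(W / scale) + 1L)
  g <- matrix(runif(nr * nc), nr, nc)
  # bilinear interpolation of the coarse grid onto the pixel lattice
  ry <- seq(1, nr, length.out = H)
  cx <- seq(1, nc, length.out = W)
  r0 <- pmin(floor(ry), nr - 1L); fr <- ry - r0
  c0 <- pmin(floor(cx), nc - 1L); fc <- cx - c0
  a <- g[cbind(rep(r0, W), rep(c0, each = H))]
  b <- g[cbind(rep(r0 + 1, W), rep(c0, each = H))]
  d <- g[cbind(rep(r0, W), rep(c0 + 1, each = H))]
  e <- g[cbind(rep(r0 + 1, W), rep(c0 + 1, each = H))]
  frm <- rep(fr, W); fcm <- rep(fc, each = H)
  v <- a * (1 - frm) * (1 - fcm) + b * frm * (1 - fcm) +
    d * (1 - frm) * fcm + e * frm * fcm
  matrix(v, H, W)
}

#' Generate one synthetic field scene with exact ground truth
#'
#' Renders elliptical wheat-ear blobs with a spikelet-like periodic texture
#' and a distinct golden hue on a mottled soil-and-leaf background, applies
#' the configured illumination multiplier, and returns the 8-bit RGB image
#' together with an exact binary ear mask, the true count and the ear
#' centroids. Ear positions are rejection-sampled until all pairwise centre
#' distances reach `min_separation` (and, when `min_separation > 0`, until no
#' two ellipses can touch); placement gives up with an informative error after
#' 1000 attempts per ear.
#'
#' @param config A [scene_config()].
#' @return An object of class `ear_scene`: a list with elements `image`
#'   (H x W x 3 integer array, 0-255), `mask` (H x W integer matrix, ear = 1),
#'   `count`, `centroids` (tibble with `row`, `col`) and `config`.
#' @examples
#' sc <- generate_scene(scene_config(height = 120, width = 160, ear_count = 4,
#'                                   min_separation = 30, seed = 7))
#' sc$count
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config"))
    stop("`config` must be a scene_config", call. = FALSE)
  withr::with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  H <- config$height; W <- config$width
  ax <- config$ear_axis_range

  # --- background: soil / leaf mottle plus fine grain ----------------------
  soil <- c(125, 98, 66)
  leaf <- c(62, 108, 48)
  t_field <- value_noise_field(H, W, config$background_texture_scale)
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3)
    img[, , ch] <- soil[ch] * t_field + leaf[ch] * (1 - t_field) +
      rnorm(H * W, 0, 6)

  # --- ear placement -------------------------------------------------------
  mask <- matrix(0L, H, W)
  n <- config$ear_count
  centres <- matrix(NA_real_, n, 2)
  majors <- numeric(n)
  if (n > 0) {
    margin <- ceiling(ax[2]) + 2
    if (H - 2 * margin < 1 || W - 2 * margin < 1)
      stop("scene too small for the configured ear size", call. = FALSE)
    mid <- mean(ax)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        r <- runif(1, margin + 1, H - margin)
        c <- runif(1, margin + 1, W - margin)
        a <- runif(1, mid, ax[2])       # semi-major
        if (i > 1) {
          d <- sqrt((centres[seq_len(i - 1), 1] - r)^2 +
                      (centres[seq_len(i - 1), 2] - c)^2)
          req <- config$min_separation
          if (req > 0)   # also forbid touching ellipses
            req <- pmax(req, a + majors[seq_len(i - 1)] + 3)
          if (any(d < req)) next
        }
        centres[i, ] <- c(r, c)
        majors[i] <- a
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(paste0("could not place ear %d of %d with ",
                            "min_separation = %g after 1000 attempts; ",
                            "the scene is too crowded"),
                     i, n, config$min_separation), call. = FALSE)
    }
    ear_base <- c(198, 178, 96)
    mid2 <- mean(ax)
    for (i in seq_len(n)) {
      r0 <- centres[i, 1]; c0 <- centres[i, 2]
      a <- majors[i]
      b <- runif(1, ax[1], min(a, mid2))  # semi-minor
      theta <- runif(1, 0, pi)
      jitter <- rnorm(3, 0, 10)
      period <- runif(1, 3.2, 4.8)        # spikelet band spacing, px
      rad <- ceiling(a) + 1
      rr <- max(1, floor(r0 - rad)):min(H, ceiling(r0 + rad))
      cc <- max(1, floor(c0 - rad)):min(W, ceiling(c0 + rad))
      rg <- matrix(rr - r0, length(rr), length(cc))
      cg <- matrix(cc - c0, length(rr), length(cc), byrow = TRUE)
      u <- cos(theta) * cg + sin(theta) * rg   # along major axis
      v <- -sin(theta) * cg + cos(theta) * rg
      inside <- (u / a)^2 + (v / b)^2 <= 1
      if (!any(inside)) next
      tex <- 1 + 0.35 * sin(2 * pi * u / period) * cos(pi * v / (2 * b))
      idx <- which(inside, arr.ind = TRUE)
      pr <- rr[idx[, 1]]; pc <- cc[idx[, 2]]
      lin <- cbind(pr, pc)
      for (ch in 1:3) {
        val <- (ear_base[ch] + jitter[ch]) * tex[inside]
        img[cbind(lin, ch)] <- val
      }
      mask[lin] <- 1L
    }
  }

  # --- illumination and quantization ---------------------------------------
  mult <- illumination_multiplier[[config$illumination]]
  img <- clip8(img * mult)
  storage.mode(img) <- "integer"

  centroids <- tibble::tibble(
    row = if (n > 0) round(centres[, 1]) else numeric(0),
    col = if (n > 0) round(centres[, 2]) else numeric(0))

  structure(list(image = img, mask = mask, count = n,
                 centroids = centroids, config = config),
            class = "ear_scene")
}

#' @export
print.ear_scene <- function(x, ...) {
  cat(sprintf("<ear_scene> %d x %d, %d ears, illumination %s, seed %d\n",
              nrow(x$mask), ncol(x$mask), x$count,
              x$config$illumination, x$config$seed))
  invisible(x)
}

#' Noise model specification
#'
#' Describes one of the four noise contaminations used to probe counting
#' robustness: additive Gaussian, Rayleigh or exponential noise (i.i.d. per
#' pixel and channel, clipped to 8 bits), or salt-and-pepper impulse noise
#' (each pixel set to black or white with probability `level/2` each).
#'
#' @param model One of `"gaussian"`, `"rayleigh"`, `"exponential"`,
#'   `"salt_pepper"`.
#' @param level Model parameter: the standard deviation sigma for Gaussian,
#'   the scale for Rayleigh/exponential, the flip density in \[0, 1\] for
#'   salt-and-pepper. `level = 0` leaves the image untouched.
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("gaussian", "rayleigh", "exponential",
                                 "salt_pepper"),
                       level, seed = 1L) {
  if (is.character(model) && length(model) == 1 &&
      !model %in% c("gaussian", "rayleigh", "exponential", "salt_pepper"))
    stop(sprintf("unknown noise model '%s'", model), call. = FALSE)
  model <- match.arg(model)
  if (length(level) != 1 || !is.finite(level) || level < 0)
    stop("`level` must be a single number >= 0", call. = FALSE)
  if (model == "salt_pepper" && level > 1)
    stop("salt_pepper density must be <= 1", call. = FALSE)
  structure(list(model = model, level = as.numeric(level),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Contaminate an image with a configured noise model
#'
#' @param image H x W x 3 8-bit RGB array.
#' @param spec A [noise_spec()].
#' @return A new image array of the same shape; the input is not modified.
#' @export
add_noise <- function(image, spec) {
  assert_image(image)
  if (!inherits(spec, "noise_spec"))
    stop("`spec` must be a noise_spec", call. = FALSE)
  if (spec$level == 0) return(image)
  withr::with_seed(spec$seed, {
    d <- dim(image)
    npx <- d[1] * d[2]
    out <- image
    if (spec$model == "salt_pepper") {
      u <- runif(npx)
      pepper <- u < spec$level / 2
      salt <- u >= spec$level / 2 & u < spec$level
      for (ch in 1:3) {
        plane <- out[, , ch]
        plane[pepper] <- 0
        plane[salt] <- 255
        out[, , ch] <- plane
      }
    } else {
      noise <- switch(spec$model,
        gaussian = rnorm(npx * 3, 0, spec$level),
        rayleigh = spec$level * sqrt(-2 * log(runif(npx * 3))),
        exponential = rexp(npx * 3, rate = 1 / spec$level))
      out <- clip8(image + array(noise, dim = d))
    }
    storage.mode(out) <- "integer"
    out
  })
}

#' Generate a batch of scenes
#'
#' @param configs Non-empty list of [scene_config()] objects, normally with
#'   distinct seeds.
#' @return A list of [generate_scene()] results, one per config.
#' @export
scene_batch <- function(configs) {
  if (!is.list(configs) || length(configs) == 0)
    stop("`configs` must be a non-empty list of scene_config objects",
         call. = FALSE)
  lapply(seq_along(configs), function(i) {
    tryCatch(generate_scene(configs[[i]]),
             error = function(e)
               stop(sprintf("scene %d: %s", i, conditionMessage(e)),
                    call. = FALSE))
  })
}
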