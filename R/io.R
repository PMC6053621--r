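#' Read and write 8-bit images and binary masks as PNG
#'
#' Thin wrappers around the `png` package using the package's array
#' conventions: images are H x W x 3 integer arrays in 0-255, masks are
#' H x W integer 0/1 matrices written as 0/255 grayscale PNGs.
#'
#' @param path PNG file path.
#' @param image H x W x 3 image array.
#' @param mask H x W binary matrix.
#' @return Readers return the array/matrix; writers return `path` invisibly.
#' @name image_io
NULL

#' @rdname image_io
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (dim(arr)[3] == 4) arr <- arr[, , 1:3, drop = FALSE]
  out <- round(arr * 255)
  storage.mode(out) <- "integer"
  out
}

#' @rdname image_io
#' @export
write_image <- function(image, path) {
  assert_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  matrix(as.integer(arr > 0.5), nrow(arr), ncol(arr))
}

#' @rdname image_io
#' @export
write_mask <- function(mask, path) {
  m <- as_binary_mask(mask)
  storage.mode(m) <- "double"
  png::writePNG(m, path)   # 0/1 in [0,1] scale -> 0/255 grayscale
  invisible(path)
}

#' Write / read a scene as PNG images plus a JSON sidecar
#'
#' Stores `NAME.png` (RGB image), `NAME_mask.png` (0/255 ground truth) and
#' `NAME.json` (count, centroids and the generating config).
#'
#' @param scene An [generate_scene()] `ear_scene`.
#' @param dir Output directory (created if needed).
#' @param name File stem.
#' @return `write_scene` returns the stem paths invisibly; `read_scene`
#'   returns an `ear_scene`.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  if (!inherits(scene, "ear_scene")) stop("`scene` must be an ear_scene",
                                          call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(name, ".png"))
  mask_path <- file.path(dir, paste0(name, "_mask.png"))
  json_path <- file.path(dir, paste0(name, ".json"))
  write_image(scene$image, img_path)
  write_mask(scene$mask, mask_path)
  cfg <- unclass(scene$config)
  jsonlite::write_json(list(count = scene$count,
                            centroids = scene$centroids,
                            config = cfg),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, mask = mask_path, json = json_path))
}

#' @rdname write_scene
#' @param dir,name Directory and stem previously passed to `write_scene`.
#' @export
read_scene <- function(dir, name = "scene") {
  json_path <- file.path(dir, paste0(name, ".json"))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  cfg <- do.call(scene_config, as.list(meta$config))
  centroids <- if (length(meta$centroids) == 0)
    tibble::tibble(row = numeric(0), col = numeric(0))
  else tibble::as_tibble(meta$centroids)
  structure(list(image = read_image(file.path(dir, paste0(name, ".png"))),
                 mask = read_mask(file.path(dir, paste0(name, "_mask.png"))),
                 count = meta$count,
                 centroids = centroids,
                 config = cfg),
            class = "ear_scene")
}
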