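#' Calibrated configuration for the counting study
#'
#' The SLIC tessellation and counting parameters the package uses for its
#' ear-counting experiments at the default scene geometry (700 x 360 px,
#' ears with 6-14 px semi-axes): a grid step of about 16 px with
#' compactness 5, so superpixels can follow ear boundaries (with the generic
#' 20-px compact tessellation a 200-400 px ear routinely fragments over many
#' superpixels, none ear-dominated, and is missed), and a minimum counted
#' region area of 100 px — half the smallest plausible ear, so no real ear
#' can be filtered while sub-ear debris is.
#'
#' @param height,width Scene geometry the configuration is calibrated for.
#' @return List with elements `slic` (a [slic_config()]) and `min_area`.
#' @export
default_study_config <- function(height = 360, width = 700) {
  list(slic = slic_config(n_superpixels = round(height * width / 250),
                          compactness = 5),
       min_area = 100)
}

subset_patchset <- function(patchset, idx) {
  structure(list(patches = patchset$patches[idx],
                 info = patchset$info[idx, ],
                 labels = patchset$labels[idx],
                 patch_size = patchset$patch_size),
            class = "patch_set")
}

#' Train the full ear segmentation model on ground-truthed scenes
#'
#' Off-line training half of the workflow. For every scene: SLIC superpixels
#' are generated, one 20x20 patch is cut at each superpixel centre, and
#' patches are labeled by the zero-ratio rule against the scene's ground
#' truth mask. A balanced per-scene subsample of labeled patches (ear and
#' background) forms the training set; its CCV/GLCM/EHD features are min-max
#' normalized, weighted by the per-class importance (combined weight vector)
#' and projected through RBF kernel PCA. TWSVM penalties and bandwidth are
#' selected by seeded stratified cross-validated grid search, and the final
#' twin SVM is fitted on the full training set.
#'
#' @param scenes List of [generate_scene()] scenes (or lists with `image` and
#'   `mask`).
#' @param slic_config,feature_config Stage configurations.
#' @param patch_size Patch side length (default 20).
#' @param patches_per_class Per-scene cap on sampled patches per class.
#' @param min_ear_ratio Minimum superpixel ear-area ratio for a patch to be
#'   sampled as a positive training example. Mirrors the manual curation of
#'   unambiguous ear patches in field practice: superpixels that merely graze
#'   an ear (ratio near zero) contain essentially background pixels and would
#'   poison the positive class. Inference and evaluation are unaffected —
#'   the zero-ratio labeling rule stays as is.
#' @param max_neg_window_ratio Maximum fraction of ear pixels allowed inside
#'   a patch *window* for it to be sampled as a negative example. A
#'   background superpixel right next to an ear yields a window lying partly
#'   on that ear; training on it as "background" teaches the classifier to
#'   reject genuinely eary windows and fragments detections. Set to 1 to
#'   make every rule-negative patch eligible ("hard negatives").
#' @param use_kpca Project features through kernel PCA before the TWSVM.
#' @param kpca_bandwidth,variance_retained Passed to [kpca_fit()].
#' @param c_grid,gamma_grid,folds Grid-search settings; give length-1 grids
#'   to skip the search.
#' @param grid_subsample Cap on training rows used during grid search.
#' @param eps TWSVM ridge.
#' @param seed Seed controlling patch subsampling and CV folds.
#' @return An object of class `ear_model` bundling every fitted component.
#' @export
train_ear_model <- function(scenes,
                            slic_config = earcount::slic_config(),
                            feature_config = earcount::feature_config(),
                            patch_size = 20,
                            patches_per_class = 40,
                            min_ear_ratio = 0.3,
                            max_neg_window_ratio = 0.02,
                            use_kpca = TRUE,
                            kpca_bandwidth = NULL,
                            variance_retained = 0.95,
                            c_grid = 2^c(-5, -3, -1),
                            gamma_grid = 2^c(-11, -9, -7),
                            folds = 3,
                            grid_subsample = 400,
                            eps = 1e-6,
                            seed = 1L) {
  if (!is.list(scenes) || length(scenes) == 0)
    stop("`scenes` must be a non-empty list", call. = FALSE)

  sampled <- withr::with_seed(seed, lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    spmap <- slic_segment(sc$image, slic_config)
    ps <- extract_patches(sc$image, spmap, patch_size)
    ps <- label_patches(ps, spmap, sc$mask)
    mask <- as_binary_mask(sc$mask)
    window_ear <- vapply(seq_along(ps$patches), function(j) {
      r0 <- ps$info$row0[j]; c0 <- ps$info$col0[j]
      mean(mask[r0:(r0 + patch_size - 1), c0:(c0 + patch_size - 1)])
    }, numeric(1))
    pick <- function(idx) {
      if (length(idx) > patches_per_class)
        idx <- sample(idx, patches_per_class)
      idx
    }
    subset_patchset(ps, c(pick(which(ps$labels == 1L &
                                       ps$info$ear_ratio >= min_ear_ratio)),
                          pick(which(ps$labels == 0L &
                                       window_ear <= max_neg_window_ratio))))
  }))

  patches <- do.call(c, lapply(sampled, `[[`, "patches"))
  labels <- unlist(lapply(sampled, `[[`, "labels"))
  if (length(unique(labels)) < 2)
    stop("training scenes yielded only one patch class", call. = FALSE)
  pool <- structure(list(patches = patches,
                         info = dplyr::bind_rows(lapply(sampled, `[[`, "info")),
                         labels = labels, patch_size = as.integer(patch_size)),
                    class = "patch_set")

  feats <- feature_matrix(pool, feature_config)
  normalizer <- fit_normalizer(feats)
  fn <- apply_normalizer(normalizer, feats)
  imp <- importance(fn, labels)
  fw <- apply_weights(fn, imp)
  kpca <- NULL
  ftrain <- fw
  if (use_kpca) {
    kpca <- kpca_fit(fw, bandwidth = kpca_bandwidth,
                     variance_retained = variance_retained)
    ftrain <- kpca_transform(kpca, fw)
  }

  x <- feature_values(ftrain)
  if (length(c_grid) > 1 || length(gamma_grid) > 1) {
    gs_idx <- seq_len(nrow(x))
    if (length(gs_idx) > grid_subsample)
      gs_idx <- withr::with_seed(seed + 1L, sort(sample(gs_idx, grid_subsample)))
    grid <- twsvm_grid_search(x[gs_idx, , drop = FALSE], labels[gs_idx],
                              c_grid = c_grid, gamma_grid = gamma_grid,
                              folds = folds, seed = seed, eps = eps)
    best_c <- grid$best_c; best_gamma <- grid$best_gamma
  } else {
    grid <- NULL
    best_c <- c_grid[1]; best_gamma <- gamma_grid[1]
  }

  fit <- twsvm_fit(x[labels == 1, , drop = FALSE],
                   x[labels == 0, , drop = FALSE],
                   c1 = best_c, c2 = best_c, gamma = best_gamma, eps = eps)

  structure(list(feature_config = feature_config,
                 slic_config = slic_config,
                 patch_size = as.integer(patch_size),
                 normalizer = normalizer, importance = imp, kpca = kpca,
                 twsvm = fit, grid = grid,
                 n_train = length(labels),
                 n_train_ear = sum(labels == 1L),
                 train_accuracy = mean(predict(fit, x) == labels),
                 seed = as.integer(seed)),
            class = "ear_model")
}

#' @export
print.ear_model <- function(x, ...) {
  cat(sprintf(paste0("<ear_model> trained on %d patches (%d ear); ",
                     "c = %g, gamma = %g%s; training accuracy %.3f\n"),
              x$n_train, x$n_train_ear, x$twsvm$c1, x$twsvm$gamma,
              if (is.null(x$kpca)) "" else
                sprintf("; KPCA %d comps", ncol(x$kpca$alpha)),
              x$train_accuracy))
  invisible(x)
}

#' Glance at a trained ear model
#'
#' @param x An [train_ear_model()] result.
#' @param ... Unused.
#' @export
glance.ear_model <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_train_ear = x$n_train_ear,
                 c = x$twsvm$c1, gamma = x$twsvm$gamma,
                 kpca_components = if (is.null(x$kpca)) NA_integer_ else
                   ncol(x$kpca$alpha),
                 train_accuracy = x$train_accuracy)
}

#' Classify raw patch features with a trained model
#'
#' Applies the stored normalization, importance weighting and KPCA
#' projection, then the TWSVM nearest-plane rule.
#'
#' @param object An `ear_model`.
#' @param features A raw [feature_matrix()] (same feature configuration as
#'   training) or plain matrix.
#' @param ... Unused.
#' @return Integer 0/1 labels, one per row.
#' @export
predict.ear_model <- function(object, features, ...) {
  f <- apply_normalizer(object$normalizer, features)
  f <- apply_weights(f, object$importance)
  if (!is.null(object$kpca)) f <- kpca_transform(object$kpca, f)
  predict(object$twsvm, feature_values(f))
}

#' Save / load a model archive
#'
#' The whole bundle (normalization parameters, importance table, KPCA
#' components, TWSVM planes and stage configurations) is stored in a single
#' portable JSON file, so inference needs exactly one artifact.
#'
#' @param model An `ear_model`.
#' @param path File path (conventionally `.earc.json`).
#' @return `write_ear_model` returns `path` invisibly; `read_ear_model`
#'   returns the restored `ear_model`.
#' @export
write_ear_model <- function(model, path) {
  if (!inherits(model, "ear_model"))
    stop("`model` must be an ear_model", call. = FALSE)
  writeLines(jsonlite::serializeJSON(model, digits = NA), path)
  invisible(path)
}

#' @rdname write_ear_model
#' @export
read_ear_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  model <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  if (!inherits(model, "ear_model"))
    stop(sprintf("%s does not contain an ear_model", path), call. = FALSE)
  model
}
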