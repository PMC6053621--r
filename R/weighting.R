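#' Fit a min-max feature normalizer
#'
#' Learns per-dimension minimum and maximum on the training features so that
#' the training data map into \[0, 1\]. Dimensions with `max == min` map to 0.
#'
#' @param train A [feature_matrix()] (or plain numeric matrix) with at least
#'   2 rows.
#' @return An object of class `ear_normalizer` with `min` and `max` vectors.
#' @export
fit_normalizer <- function(train) {
  x <- feature_values(train)
  if (nrow(x) < 2) stop("need at least 2 samples to fit", call. = FALSE)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "ear_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param normalizer A [fit_normalizer()] result.
#' @param features Features with the same dimensionality as the training set.
#' @return Object of the same kind as `features` with values rescaled by the
#'   training min/max (test values may fall outside \[0, 1\]).
#' @export
apply_normalizer <- function(normalizer, features) {
  x <- feature_values(features)
  if (ncol(x) != length(normalizer$min))
    stop("feature dimension does not match the normalizer", call. = FALSE)
  rng <- normalizer$max - normalizer$min
  rng[rng == 0] <- 1           # constant dims map to 0
  out <- sweep(sweep(x, 2, normalizer$min), 2, rng, "/")
  replace_values(features, out)
}

feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected a feature_matrix or numeric matrix", call. = FALSE)
}

replace_values <- function(template, values) {
  if (inherits(template, "feature_matrix")) {
    template$values <- values
    template
  } else values
}

#' Per-class feature importance and weights
#'
#' For each class j and feature dimension n, computes the within-class
#' population standard deviation `k`, the importance `I = 1 / (1 + k)` (a
#' more concentrated dimension is more important) and the weight
#' `W = I / sum(I)` so each class's weights sum to one. A single combined
#' per-dimension weight vector — the mean of the two class weight vectors,
#' renormalized to sum 1 — is what gets applied to (unlabeled) samples at
#' train and test time.
#'
#' @param train_normalized Normalized training features
#'   (a [feature_matrix()] or matrix).
#' @param labels 0/1 class labels, one per row; both classes must be present
#'   with at least 2 samples each.
#' @return An object of class `importance_table`: list with matrices `k`,
#'   `I`, `W` (2 x D, rows `class0`, `class1`) and vector `W_combined`.
#' @export
importance <- function(train_normalized, labels = NULL) {
  x <- feature_values(train_normalized)
  if (is.null(labels) && inherits(train_normalized, "feature_matrix"))
    labels <- train_normalized$labels
  if (is.null(labels) || length(labels) != nrow(x))
    stop("`labels` must give one 0/1 label per sample", call. = FALSE)
  for (cl in c(0, 1))
    if (sum(labels == cl) < 2)
      stop(sprintf("class %d has fewer than 2 samples", cl), call. = FALSE)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  k <- rbind(class0 = apply(x[labels == 0, , drop = FALSE], 2, pop_sd),
             class1 = apply(x[labels == 1, , drop = FALSE], 2, pop_sd))
  I <- 1 / (1 + k)
  W <- I / rowSums(I)
  W_combined <- colMeans(W)
  W_combined <- W_combined / sum(W_combined)
  structure(list(k = k, I = I, W = W, W_combined = W_combined),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("<importance_table> %d dims; top combined weights:\n",
              length(x$W_combined)))
  print(utils::head(sort(x$W_combined, decreasing = TRUE), 5))
  invisible(x)
}

#' Tidy an importance table
#'
#' @param x An [importance()] result.
#' @param ... Unused.
#' @return Tibble with one row per feature dimension: per-class standard
#'   deviation, importance and weight, plus the combined weight.
#' @export
tidy.importance_table <- function(x, ...) {
  D <- length(x$W_combined)
  nm <- colnames(x$k) %||% as.character(seq_len(D))
  tibble::tibble(dimension = nm,
                 k_class0 = x$k["class0", ], k_class1 = x$k["class1", ],
                 I_class0 = x$I["class0", ], I_class1 = x$I["class1", ],
                 W_class0 = x$W["class0", ], W_class1 = x$W["class1", ],
                 W_combined = x$W_combined)
}

#' Apply combined importance weights to features
#'
#' Multiplies every feature dimension by the combined weight vector; the same
#' transform is used for training and test samples.
#'
#' @param features A [feature_matrix()] or matrix.
#' @param table An [importance()] result with matching dimensionality.
#' @return Weighted features of the same kind as the input.
#' @export
apply_weights <- function(features, table) {
  x <- feature_values(features)
  if (ncol(x) != length(table$W_combined))
    stop("feature dimension does not match the importance table",
         call. = FALSE)
  replace_values(features, sweep(x, 2, table$W_combined, "*"))
}

#' Fit RBF kernel PCA
#'
#' Computes the RBF kernel matrix of the (weighted) training features,
#' double-centres it, and retains leading eigencomponents until the
#' cumulative eigenvalue fraction reaches `variance_retained`. Scores are
#' rescaled by one global factor so the leading component has unit variance
#' on the training set: relative eigenvalue decay is preserved while the
#' projected space becomes scale-free, keeping downstream kernel bandwidths
#' meaningful whatever the raw kernel magnitudes. Eigenvector sign is fixed
#' by making each component's largest-magnitude coefficient positive, so
#' fits are fully deterministic.
#'
#' @param train_weighted Weighted training features.
#' @param bandwidth RBF bandwidth gamma (> 0); `NULL` uses `1 / D`.
#' @param variance_retained Fraction of the centred kernel spectrum to keep,
#'   in (0, 1\].
#' @return An object of class `kpca_model` holding the reference samples,
#'   centring statistics and scaled projection coefficients.
#' @export
kpca_fit <- function(train_weighted, bandwidth = NULL,
                     variance_retained = 0.95) {
  x <- feature_values(train_weighted)
  gamma <- bandwidth %||% (1 / ncol(x))
  if (gamma <= 0) stop("bandwidth must be positive", call. = FALSE)
  if (variance_retained <= 0 || variance_retained > 1)
    stop("variance_retained must be in (0, 1]", call. = FALSE)
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  col_means <- colMeans(K)
  total_mean <- mean(K)
  Kc <- K - matrix(col_means, n, n, byrow = TRUE) -
    matrix(rowMeans(K), n, n) + total_mean
  eig <- eigen(Kc, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  tot <- sum(lambda)
  if (tot <= 0) stop("degenerate kernel: zero spectrum", call. = FALSE)
  cum <- cumsum(lambda) / tot
  ncomp <- which(cum >= variance_retained - 1e-12)[1]
  keep <- seq_len(ncomp)
  keep <- keep[lambda[keep] > tot * 1e-12]
  alpha <- eig$vectors[, keep, drop = FALSE]
  lam <- lambda[keep]
  # scale all scores by one global factor chosen so the leading component
  # has unit variance on the training set: the projected space keeps the
  # eigenvalue decay (later components stay small) but its overall scale --
  # and hence any downstream kernel bandwidth -- no longer depends on the
  # raw kernel magnitudes
  train_scores <- Kc %*% alpha
  lead_sd <- sqrt(mean((train_scores[, 1] - mean(train_scores[, 1]))^2))
  if (lead_sd > 0) alpha <- alpha / lead_sd
  # deterministic sign: largest-|coefficient| entry positive
  for (j in seq_len(ncol(alpha))) {
    i <- which.max(abs(alpha[, j]))
    if (alpha[i, j] < 0) alpha[, j] <- -alpha[, j]
  }
  structure(list(x_ref = x, gamma = gamma, alpha = alpha,
                 eigenvalues = lam, col_means = col_means,
                 total_mean = total_mean,
                 variance_retained = variance_retained,
                 achieved_fraction = cum[ncomp]),
            class = "kpca_model")
}

#' Project features through a fitted kernel PCA
#'
#' @param model A [kpca_fit()] result.
#' @param features Features with the reference dimensionality.
#' @return Features projected onto the retained components (a
#'   `feature_matrix` input keeps its class; its blocks are replaced by a
#'   single `kpca` block).
#' @export
kpca_transform <- function(model, features) {
  if (!inherits(model, "kpca_model"))
    stop("kpca_transform called before kpca_fit", call. = FALSE)
  x <- feature_values(features)
  if (ncol(x) != ncol(model$x_ref))
    stop("feature dimension does not match the KPCA model", call. = FALSE)
  Kt <- rbf_kernel(x, model$x_ref, model$gamma)
  n <- nrow(Kt); m <- ncol(Kt)
  Ktc <- Kt - matrix(model$col_means, n, m, byrow = TRUE) -
    matrix(rowMeans(Kt), n, m) + model$total_mean
  proj <- Ktc %*% model$alpha
  colnames(proj) <- sprintf("kpc%d", seq_len(ncol(proj)))
  if (inherits(features, "feature_matrix")) {
    features$values <- proj
    features$blocks <- list(kpca = seq_len(ncol(proj)))
    features
  } else proj
}
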