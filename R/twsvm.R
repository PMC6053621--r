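#' RBF kernel matrix
#'
#' `K[i, j] = exp(-gamma * ||x_i - y_j||^2)`.
#'
#' @param X,Y Sample matrices with matching column counts.
#' @param gamma Positive bandwidth.
#' @return `nrow(X)` x `nrow(Y)` kernel matrix.
#' @export
rbf_kernel <- function(X, Y, gamma) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("dimension mismatch", call. = FALSE)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

kernel_matrix <- function(X, Y, kernel, gamma) {
  switch(kernel,
         rbf = rbf_kernel(X, Y, gamma),
         linear = tcrossprod(as.matrix(X), as.matrix(Y)),
         stop(sprintf("unknown kernel '%s'", kernel), call. = FALSE))
}

# solve min 0.5 a'Qa - e'a, 0 <= a <= upper, to KKT residual <= tol
solve_box_qp <- function(Q, upper, tol = 1e-8, max_sweeps = 100000L) {
  res <- cpp_qp_box_cd(Q, rep(1, nrow(Q)), upper, tol, max_sweeps)
  if (res$kkt > 1e-6)
    stop(sprintf("dual QP did not converge (KKT residual %.2e)", res$kkt),
         call. = FALSE)
  res
}

#' Fit a twin support vector machine
#'
#' Learns the two non-parallel kernel hyperplanes of the TWSVM: plane 1 lies
#' close to the ear samples `A` while pushing the background samples `B` to
#' distance >= 1 (softly, at penalty `c1`), and plane 2 symmetrically close
#' to `B`. Each plane is obtained by solving the dual of its primal problem —
#' a box-constrained quadratic program
#' `max e'alpha - 0.5 alpha' G (H'H + eps I)^(-1) G' alpha`,
#' `0 <= alpha <= c1` (roles of the augmented kernel blocks
#' `H = [K(A, C') e]` and `G = [K(B, C') e]` swapped for plane 2) — by exact
#' coordinate descent to a KKT residual below 1e-6. The kernel expansion is
#' over all training samples `C = [A; B]`.
#'
#' @param A Matrix of class-1 (ear) samples, one per row.
#' @param B Matrix of class-0 (background) samples.
#' @param c1,c2 Positive penalty coefficients of the two primal problems.
#' @param gamma RBF bandwidth (ignored for `kernel = "linear"`).
#' @param eps Ridge added to `H'H` / `G'G` before inversion (also the floor
#'   of the distance-normalisation denominator).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @return An object of class `twsvm` with the reference matrix `C`, plane
#'   parameters `w1, b1, w2, b2`, kernel settings and the dual solutions.
#' @export
twsvm_fit <- function(A, B, c1 = 1, c2 = 1, gamma = 1, eps = 1e-6,
                      kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) < 1 || nrow(B) < 1)
    stop("both classes need at least one sample", call. = FALSE)
  if (ncol(A) != ncol(B)) stop("dimension mismatch", call. = FALSE)
  stopifnot(c1 > 0, c2 > 0, eps > 0)
  if (kernel == "rbf") stopifnot(gamma > 0)
  C <- rbind(A, B)
  m1 <- nrow(A); m2 <- nrow(B); m <- m1 + m2
  H <- cbind(kernel_matrix(A, C, kernel, gamma), 1)
  G <- cbind(kernel_matrix(B, C, kernel, gamma), 1)

  solve_plane <- function(P, Qb, penalty) {
    # plane close to the class giving P, pushed from the class giving Qb
    M <- crossprod(P) + diag(eps, ncol(P))
    Mi_Qt <- solve(M, t(Qb))
    Qmat <- Qb %*% Mi_Qt
    Qmat <- (Qmat + t(Qmat)) / 2
    sol <- solve_box_qp(Qmat, penalty)
    z <- -Mi_Qt %*% sol$alpha
    list(z = drop(z), alpha = sol$alpha, kkt = sol$kkt)
  }

  p1 <- solve_plane(H, G, c1)      # z1 = -(H'H + eI)^(-1) G' alpha
  p2 <- solve_plane(G, H, c2)
  z1 <- p1$z
  z2 <- -p2$z                      # sign: plane 2 lies on A's positive side

  Kcc <- kernel_matrix(C, C, kernel, gamma)
  norm_w <- function(w) sqrt(max(eps, drop(crossprod(w, Kcc %*% w))))

  structure(list(C = C, m1 = m1, m2 = m2,
                 w1 = z1[seq_len(m)], b1 = z1[m + 1],
                 w2 = z2[seq_len(m)], b2 = z2[m + 1],
                 norm1 = norm_w(z1[seq_len(m)]), norm2 = norm_w(z2[seq_len(m)]),
                 alpha1 = p1$alpha, alpha2 = p2$alpha,
                 kkt = c(plane1 = p1$kkt, plane2 = p2$kkt),
                 c1 = c1, c2 = c2, gamma = gamma, eps = eps, kernel = kernel),
            class = "twsvm")
}

#' @export
print.twsvm <- function(x, ...) {
  cat(sprintf(
    "<twsvm> %d + %d training samples, %s kernel (gamma = %g), c = (%g, %g)\n",
    x$m1, x$m2, x$kernel, x$gamma, x$c1, x$c2))
  invisible(x)
}

#' Glance at a fitted TWSVM
#'
#' @param x A [twsvm_fit()] result.
#' @param ... Unused.
#' @return One-row tibble with training sizes, hyperparameters, dual KKT
#'   residuals and support-vector counts.
#' @export
glance.twsvm <- function(x, ...) {
  tibble::tibble(m1 = x$m1, m2 = x$m2, kernel = x$kernel, gamma = x$gamma,
                 c1 = x$c1, c2 = x$c2,
                 kkt_plane1 = x$kkt[["plane1"]], kkt_plane2 = x$kkt[["plane2"]],
                 n_sv_plane1 = sum(x$alpha1 > 1e-8),
                 n_sv_plane2 = sum(x$alpha2 > 1e-8))
}

#' Kernel distances of samples to the two TWSVM hyperplanes
#'
#' `d_i(x) = |K(x, C') w_i + b_i| / sqrt(w_i' K(C, C') w_i)` with the
#' denominator floored at the model's ridge `eps`.
#'
#' @param model A fitted [twsvm_fit()] model.
#' @param X Sample matrix.
#' @return `nrow(X)` x 2 matrix with columns `d1` (ear plane) and `d2`
#'   (background plane).
#' @export
twsvm_decision <- function(model, X) {
  X <- as.matrix(X)
  Kx <- kernel_matrix(X, model$C, model$kernel, model$gamma)
  d1 <- abs(drop(Kx %*% model$w1) + model$b1) / model$norm1
  d2 <- abs(drop(Kx %*% model$w2) + model$b2) / model$norm2
  cbind(d1 = d1, d2 = d2)
}

#' Classify samples by the nearest hyperplane
#'
#' @param object A fitted [twsvm_fit()] model.
#' @param X Sample matrix.
#' @param ... Unused.
#' @return Integer vector of labels; 1 (ear) when `d1 <= d2` (ties go to
#'   class 1), else 0.
#' @export
predict.twsvm <- function(object, X, ...) {
  d <- twsvm_decision(object, X)
  as.integer(d[, "d1"] <= d[, "d2"])
}

#' Grid search of TWSVM penalties and kernel bandwidth
#'
#' Stratified k-fold cross-validation accuracy over a grid of `c` (used for
#' both penalties, `c1 = c2 = c`) and RBF `gamma`; returns the argmax, with
#' ties broken toward smaller `c` then smaller `gamma`. Duplicate grid values
#' are removed before searching, and fold assignment is seeded so results are
#' reproducible.
#'
#' @param train Training features (a [feature_matrix()] or matrix).
#' @param labels 0/1 labels, one per row.
#' @param c_grid,gamma_grid Candidate values (defaults 2^(-5), 2^(-3), ...,
#'   2^5).
#' @param folds Number of CV folds (>= 2).
#' @param seed Integer seed for fold assignment.
#' @param eps Ridge passed to [twsvm_fit()].
#' @return An object of class `twsvm_grid`: list with `best_c`, `best_gamma`,
#'   `best_accuracy` and the full `cv` tibble.
#' @export
twsvm_grid_search <- function(train, labels, c_grid = 2^seq(-5, 5, by = 2),
                              gamma_grid = 2^seq(-5, 5, by = 2), folds = 5,
                              seed = 1L, eps = 1e-6) {
  x <- feature_values(train)
  if (is.null(labels) && inherits(train, "feature_matrix"))
    labels <- train$labels
  if (length(labels) != nrow(x))
    stop("`labels` must give one label per sample", call. = FALSE)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (length(c_grid) == 0 || length(gamma_grid) == 0)
    stop("grids must be non-empty", call. = FALSE)
  c_grid <- sort(unique(c_grid))
  gamma_grid <- sort(unique(gamma_grid))

  fold_id <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- which(labels == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(labels[tr])) < 2 || !any(fold_id == f))
      stop("a fold lost a class; use fewer folds", call. = FALSE)
  }

  grid <- expand.grid(c = c_grid, gamma = gamma_grid)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    cc <- grid$c[i]; gg <- grid$gamma[i]
    fold_acc <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- twsvm_fit(x[tr & labels == 1, , drop = FALSE],
                       x[tr & labels == 0, , drop = FALSE],
                       c1 = cc, c2 = cc, gamma = gg, eps = eps)
      mean(predict(fit, x[!tr, , drop = FALSE]) == labels[!tr])
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))

  cv <- tibble::tibble(c = grid$c, gamma = grid$gamma, accuracy = acc)
  ord <- order(-cv$accuracy, cv$c, cv$gamma)
  best <- cv[ord[1], ]
  structure(list(best_c = best$c, best_gamma = best$gamma,
                 best_accuracy = best$accuracy, cv = cv,
                 folds = folds, seed = seed),
            class = "twsvm_grid")
}

#' @export
print.twsvm_grid <- function(x, ...) {
  cat(sprintf("<twsvm_grid> best c = %g, gamma = %g (CV accuracy %.3f)\n",
              x$best_c, x$best_gamma, x$best_accuracy))
  invisible(x)
}

#' @rdname twsvm_grid_search
#' @param x A `twsvm_grid` object.
#' @param ... Unused.
#' @export
tidy.twsvm_grid <- function(x, ...) x$cv

#' @rdname twsvm_grid_search
#' @export
glance.twsvm_grid <- function(x, ...) {
  tibble::tibble(best_c = x$best_c, best_gamma = x$best_gamma,
                 best_accuracy = x$best_accuracy,
                 n_grid = nrow(x$cv), folds = x$folds)
}
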