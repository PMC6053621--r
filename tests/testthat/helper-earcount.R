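# Shared fixtures and independent brute-force oracles used across the suite.
# Everything is generated in code under fixed seeds; no files are read.

constant_patch <- function(r, g = r, b = r, size = 20) {
  arr <- array(0L, dim = c(size, size, 3))
  arr[, , 1] <- as.integer(r); arr[, , 2] <- as.integer(g)
  arr[, , 3] <- as.integer(b)
  arr
}

random_patch <- function(seed, size = 20) {
  withr::with_seed(seed,
    array(sample(0:255, size * size * 3, replace = TRUE),
          dim = c(size, size, 3)))
}

# piecewise-constant two-region image (left/right halves)
two_region_image <- function(H = 40, W = 40,
                             left = c(200, 40, 40), right = c(40, 40, 200)) {
  img <- array(0L, dim = c(H, W, 3))
  for (ch in 1:3) {
    img[, 1:(W %/% 2), ch] <- left[ch]
    img[, (W %/% 2 + 1):W, ch] <- right[ch]
  }
  img
}

small_scene_config <- function(seed, ear_count = 5, illumination = "medium") {
  scene_config(height = 160, width = 240, ear_count = ear_count,
               ear_axis_range = c(5, 10), min_separation = 28,
               illumination = illumination, seed = seed)
}

# --- independent oracles --------------------------------------------------

# recursive-free flood fill component count on a binary matrix
oracle_component_count <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  if (connectivity == 8) {
    dr <- c(-1, 1, 0, 0, -1, -1, 1, 1); dc <- c(0, 0, -1, 1, -1, 1, -1, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  n <- 0
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (mask[r0, c0] == 0 || seen[r0, c0]) next
    n <- n + 1
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (t in seq_along(dr)) {
        r <- p[1] + dr[t]; c <- p[2] + dc[t]
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            !seen[r, c] && mask[r, c] != 0) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  n
}

# label equal-valued 8-connected components by repeated min-label propagation
oracle_equal_value_components <- function(values) {
  H <- nrow(values); W <- ncol(values)
  lab <- matrix(seq_len(H * W), H, W)
  repeat {
    new <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rs <- max(1, 1 + dr):min(H, H + dr); cs <- max(1, 1 + dc):min(W, W + dc)
      rt <- rs - dr; ct <- cs - dc
      same <- values[rs, cs, drop = FALSE] == values[rt, ct, drop = FALSE]
      cand <- lab[rs, cs, drop = FALSE]
      cur <- new[rt, ct, drop = FALSE]
      upd <- same & cand < cur
      cur[upd] <- cand[upd]
      new[rt, ct] <- cur
    }
    if (identical(new, lab)) break
    lab <- new
  }
  matrix(match(lab, sort(unique(as.vector(lab)))), H, W)
}

# brute-force CCV on a patch: blur + quantize exactly as the implementation
# defines, but with component labeling done by the independent propagation
# oracle above
oracle_ccv <- function(patch, config = feature_config()) {
  blurred <- earcount:::mean_blur3(patch)
  B <- config$ccv_bins_per_channel
  q <- function(x) pmin(B - 1, floor(x * B / 256))
  color <- matrix(q(blurred[, , 1]) * B * B + q(blurred[, , 2]) * B +
                    q(blurred[, , 3]), dim(patch)[1], dim(patch)[2])
  comp <- oracle_equal_value_components(color)
  sizes <- tabulate(as.vector(comp))
  out <- numeric(2 * B^3)
  for (px in seq_along(color)) {
    bin <- color[px]
    coherent <- sizes[comp[px]] >= config$ccv_coherence_threshold
    slot <- 2 * bin + (if (coherent) 1 else 2)
    out[slot] <- out[slot] + 1
  }
  out
}

# brute-force GLCM statistics by explicit pair enumeration
oracle_glcm <- function(patch, config = feature_config()) {
  L <- config$glcm_levels
  lum <- earcount:::luminance(patch)
  lev <- matrix(pmin(L - 1, floor(lum * L / 256)), nrow(lum), ncol(lum))
  H <- nrow(lev); W <- ncol(lev)
  unlist(lapply(config$glcm_offsets, function(off) {
    sh <- earcount:::glcm_offset_shift(off[1], off[2])
    P <- matrix(0, L, L)
    for (r in seq_len(H)) for (c in seq_len(W)) {
      r2 <- r + sh[1]; c2 <- c + sh[2]
      if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
        P[lev[r, c] + 1, lev[r2, c2] + 1] <- P[lev[r, c] + 1, lev[r2, c2] + 1] + 1
        P[lev[r2, c2] + 1, lev[r, c] + 1] <- P[lev[r2, c2] + 1, lev[r, c] + 1] + 1
      }
    }
    P <- P / sum(P)
    i <- matrix(0:(L - 1), L, L); j <- t(i)
    mu_i <- sum(i * P); mu_j <- sum(j * P)
    sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
    vapply(config$glcm_stats, function(s) switch(s,
      contrast = sum((i - j)^2 * P),
      correlation = if (sd_i == 0 || sd_j == 0) 0 else
        sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j),
      energy = sum(P^2),
      homogeneity = sum(P / (1 + abs(i - j))),
      entropy = -sum(P[P > 0] * log(P[P > 0]))), numeric(1))
  }))
}

# brute-force EHD by direct per-block filter evaluation
oracle_ehd <- function(patch, config = feature_config()) {
  g <- config$ehd_grid
  lum <- earcount:::luminance(patch)
  sh <- nrow(lum) %/% g; sw <- ncol(lum) %/% g
  out <- numeric(5 * g * g)
  idx <- 0
  for (gr in seq_len(g)) for (gc in seq_len(g)) {
    bins <- numeric(5); nblocks <- 0
    for (br in seq_len(sh %/% 2)) for (bc in seq_len(sw %/% 2)) {
      r <- (gr - 1) * sh + 2 * br - 1
      c <- (gc - 1) * sw + 2 * bc - 1
      a <- lum[r, c]; b <- lum[r, c + 1]
      d <- lum[r + 1, c]; e <- lum[r + 1, c + 1]
      m <- c(abs(a - b + d - e), abs(a + b - d - e),
             sqrt(2) * abs(a - e), sqrt(2) * abs(b - d),
             2 * abs(a - b - d + e))
      nblocks <- nblocks + 1
      if (max(m) >= config$ehd_edge_threshold)
        bins[which.max(m)] <- bins[which.max(m)] + 1
    }
    out[idx + 1:5] <- bins / nblocks
    idx <- idx + 5
  }
  out
}

# independent dual solve via kernlab's interior-point QP, on the identical
# dual:  min 0.5 a' Q a - e' a,  0 <= a <= penalty
oracle_box_qp <- function(Q, penalty) {
  n <- nrow(Q)
  # the box bounds are the real constraints; the linear constraint row is a
  # non-binding 0 <= sum(a) <= n * penalty so ipop's KKT system is full rank
  res <- kernlab::ipop(c = rep(-1, n), H = Q, A = matrix(1, 1, n), b = 0,
                       l = rep(0, n), u = rep(penalty, n), r = n * penalty,
                       sigf = 9, maxiter = 400)
  kernlab::primal(res)
}

# reference TWSVM plane parameters built from the oracle dual solution
oracle_twsvm_planes <- function(A, B, c1, c2, gamma, eps,
                                kernel = "rbf") {
  C <- rbind(A, B)
  H <- cbind(earcount:::kernel_matrix(A, C, kernel, gamma), 1)
  G <- cbind(earcount:::kernel_matrix(B, C, kernel, gamma), 1)
  M1 <- crossprod(H) + diag(eps, ncol(H))
  Q1 <- G %*% solve(M1, t(G)); Q1 <- (Q1 + t(Q1)) / 2
  a1 <- oracle_box_qp(Q1, c1)
  z1 <- -solve(M1, t(G) %*% a1)
  M2 <- crossprod(G) + diag(eps, ncol(G))
  Q2 <- H %*% solve(M2, t(H)); Q2 <- (Q2 + t(Q2)) / 2
  a2 <- oracle_box_qp(Q2, c2)
  z2 <- solve(M2, t(H) %*% a2)
  list(z1 = drop(z1), z2 = drop(z2))
}

# plain Lloyd k-means in (lab, xy/S * m) space, same init as slic_segment,
# full (unwindowed) assignment
oracle_slic_kmeans <- function(image, centers0, S, m, iters) {
  lab <- earcount:::rgb_to_lab(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  X <- cbind(as.vector(lab$L), as.vector(lab$a), as.vector(lab$b),
             rep(seq_len(H) - 1, W) * m / S,
             rep(seq_len(W) - 1, each = H) * m / S)
  C <- cbind(centers0[, 3], centers0[, 4], centers0[, 5],
             centers0[, 1] * m / S, centers0[, 2] * m / S)
  assign <- NULL
  for (it in seq_len(iters)) {
    d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
    assign <- max.col(-d2, ties.method = "first")
    for (k in seq_len(nrow(C)))
      if (any(assign == k)) C[k, ] <- colMeans(X[assign == k, , drop = FALSE])
  }
  matrix(assign, H, W)
}

# cached small trained model shared by pipeline-level tests
.test_cache <- new.env(parent = emptyenv())

get_small_model <- function() {
  if (is.null(.test_cache$model)) {
    scenes <- scene_batch(lapply(1:5, small_scene_config))
    .test_cache$model_scenes <- scenes
    .test_cache$model <- train_ear_model(
      scenes, c_grid = 1, gamma_grid = 2^-5, patches_per_class = 12,
      seed = 99)
  }
  .test_cache$model
}
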