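toy_problem <- function() {
  list(A = rbind(c(0, 0), c(0, 1)), B = rbind(c(5, 0), c(5, 1)))
}

test_that("the RBF kernel evaluates its closed form", {
  expect_equal(rbf_kernel(rbind(c(0, 0)), rbind(c(1, 1)), 0.5)[1, 1],
               exp(-1))
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(diag(rbf_kernel(x, x, 2)), rep(1, 5))
  expect_equal(rbf_kernel(x, x, 1e-12), matrix(1, 5, 5), tolerance = 1e-9)
  expect_error(rbf_kernel(x, x, 0), "positive")
  expect_error(rbf_kernel(x, matrix(0, 2, 3), 1), "mismatch")
})

test_that("plane parameters match the independent QP oracle", {
  skip_if_not_installed("kernlab")
  for (seed in 1:3) {
    set.seed(seed)
    A <- matrix(rnorm(10, 0, 1), 5, 2)
    B <- matrix(rnorm(10, 2, 1), 5, 2)
    fit <- twsvm_fit(A, B, c1 = 2, c2 = 2, gamma = 0.5, eps = 1e-3)
    ora <- oracle_twsvm_planes(A, B, 2, 2, 0.5, fit$eps)
    rel <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(b)))
    expect_lt(rel(c(fit$w1, fit$b1), ora$z1), 1e-4)
    expect_lt(rel(c(fit$w2, fit$b2), ora$z2), 1e-4)
    expect_true(all(fit$kkt <= 1e-6))
  }
})

test_that("the separable toy is classified perfectly", {
  tp <- toy_problem()
  fit <- twsvm_fit(tp$A, tp$B, c1 = 1, c2 = 1, kernel = "linear")
  expect_equal(predict(fit, tp$A), c(1L, 1L))
  expect_equal(predict(fit, tp$B), c(0L, 0L))
  # plane 1 hugs class 1: its mean |K w1 + b1| is far below class 0's
  H <- cbind(earcount:::kernel_matrix(tp$A, fit$C, "linear", 1), 1)
  G <- cbind(earcount:::kernel_matrix(tp$B, fit$C, "linear", 1), 1)
  v1 <- mean(abs(H %*% c(fit$w1, fit$b1)))
  v0 <- mean(abs(G %*% c(fit$w1, fit$b1)))
  expect_lt(v1, 1e-3 * v0)
  d <- twsvm_decision(fit, rbind(tp$A, tp$B))
  expect_true(all(d[1:2, "d1"] < d[1:2, "d2"]))
})

test_that("mirror-symmetric data yields mirror-image distance profiles", {
  set.seed(9)
  A <- matrix(rnorm(12), 6, 2)
  B <- -A                       # reflection through the origin
  fit <- twsvm_fit(A, B, c1 = 1.5, c2 = 1.5, gamma = 0.7)
  X <- matrix(rnorm(20), 10, 2)
  dX <- twsvm_decision(fit, X)
  dXm <- twsvm_decision(fit, -X)
  expect_equal(unname(dX[, "d1"]), unname(dXm[, "d2"]), tolerance = 1e-6)
  expect_equal(unname(dX[, "d2"]), unname(dXm[, "d1"]), tolerance = 1e-6)
})

test_that("tiny penalties on well-separated classes leave the duals slack", {
  set.seed(10)
  A <- matrix(rnorm(10, 0, 0.1), 5, 2)
  B <- matrix(rnorm(10, 50, 0.1), 5, 2)
  fit <- twsvm_fit(A, B, c1 = 1e-6, c2 = 1e-6, gamma = 0.01)
  expect_lt(sqrt(sum(fit$alpha1^2)), 1e-5)
  # with alpha ~ 0 the plane solves the ridge system H'H z = -G'a ~ 0-ish;
  # class-1 residuals must be near zero relative to class-0 residuals
  d <- twsvm_decision(fit, rbind(A, B))
  expect_lt(mean(d[1:5, "d1"]), 0.01 * mean(d[6:10, "d1"]))
})

test_that("distances are invariant to scaling plane parameters", {
  tp <- toy_problem()
  fit <- twsvm_fit(tp$A, tp$B, gamma = 0.3)
  X <- rbind(c(1, 0.5), c(4, 0))
  d0 <- twsvm_decision(fit, X)
  s <- 7.3
  fit$w1 <- fit$w1 * s; fit$b1 <- fit$b1 * s; fit$norm1 <- fit$norm1 * s
  expect_equal(twsvm_decision(fit, X)[, "d1"], d0[, "d1"], tolerance = 1e-12)
})

test_that("swapping the classes flips every prediction", {
  set.seed(12)
  A <- matrix(rnorm(14, 0, 1), 7, 2)
  B <- matrix(rnorm(14, 3, 1), 7, 2)
  X <- matrix(rnorm(30, 1.5, 2), 15, 2)
  f1 <- twsvm_fit(A, B, gamma = 0.5)
  f2 <- twsvm_fit(B, A, gamma = 0.5)
  expect_equal(predict(f2, X), 1L - predict(f1, X))
})

test_that("increasing c1 does not increase the total slack", {
  set.seed(13)
  A <- matrix(rnorm(16, 0, 1.5), 8, 2)
  B <- matrix(rnorm(16, 1, 1.5), 8, 2)
  slack_total <- function(cc) {
    fit <- twsvm_fit(A, B, c1 = cc, c2 = 1, gamma = 0.5)
    G <- cbind(earcount:::kernel_matrix(B, fit$C, "rbf", 0.5), 1)
    q <- pmax(0, 1 + drop(G %*% c(fit$w1, fit$b1)))  # violated margins
    sum(q)
  }
  s <- sapply(c(0.01, 0.1, 1, 10), slack_total)
  expect_true(all(diff(s) <= 1e-6))
})

test_that("grid search returns the argmax with deterministic tie-breaks", {
  tp <- toy_problem()
  x <- rbind(tp$A, tp$B)
  lab <- c(1, 1, 0, 0)
  set.seed(1)
  xx <- rbind(x, x, x, x) + matrix(rnorm(32, 0, 0.05), 16, 2)
  ll <- rep(lab, 4)
  g1 <- twsvm_grid_search(xx, ll, c_grid = 1, gamma_grid = 0.5, folds = 2)
  expect_equal(g1$best_c, 1)
  expect_equal(g1$best_gamma, 0.5)
  # duplicates deduplicated
  g2 <- twsvm_grid_search(xx, ll, c_grid = c(1, 1, 1), gamma_grid = c(0.5, 0.5),
                          folds = 2)
  expect_equal(nrow(tidy(g2)), 1)
  # a separable problem reaches CV accuracy 1 somewhere on the default-ish grid
  g3 <- twsvm_grid_search(xx, ll, c_grid = 2^c(-3, 0, 3),
                          gamma_grid = 2^c(-3, 0, 3), folds = 2, seed = 5)
  expect_equal(g3$best_accuracy, 1)
  # determinism under the seed
  g4 <- twsvm_grid_search(xx, ll, c_grid = 2^c(-3, 0, 3),
                          gamma_grid = 2^c(-3, 0, 3), folds = 2, seed = 5)
  expect_identical(tidy(g3), tidy(g4))
  expect_error(twsvm_grid_search(xx, ll, folds = 20), "fewer folds")
})

test_that("ties in plane distance go to the ear class", {
  tp <- toy_problem()
  fit <- twsvm_fit(tp$A, tp$B, gamma = 0.3)
  # force an exact tie by symmetrizing the model
  fit$w2 <- fit$w1; fit$b2 <- fit$b1; fit$norm2 <- fit$norm1
  expect_equal(predict(fit, rbind(c(2.5, 0.5))), 1L)
})
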