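test_that("confusion counts partition the image", {
  set.seed(1)
  pred <- matrix(rbinom(100, 1, 0.3), 10, 10)
  ref <- matrix(rbinom(100, 1, 0.3), 10, 10)
  cm <- confusion(pred, ref)
  expect_equal(sum(cm), 100)
  expect_equal(unname(confusion(ref, ref)[c("FP", "FN")]), c(0L, 0L))
  inv <- confusion(1 - ref, ref)
  expect_equal(unname(inv[c("TP", "TN")]), c(0L, 0L))
  expect_error(confusion(pred, ref[1:5, ]), "differ")
})

test_that("pixel metrics reproduce the hand-worked 2x2 example", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)   # [1,1; 0,0]
  ref <- matrix(c(1, 0, 0, 0), 2, 2)    # [1,0; 0,0]
  m <- pixel_metrics(pred, ref)
  expect_equal(unname(m[c("TP", "TN", "FP", "FN")]), c(1, 2, 1, 0))
  expect_equal(unname(m["precision"]), 0.5)
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["f"]), 2 / 3)
  expect_equal(unname(m["sr"]), 1)
  expect_equal(unname(m["qseg"]), 3 / 5)
})

test_that("all indicators are exactly 1 on identical masks", {
  set.seed(7)
  ref <- matrix(rbinom(30 * 40, 1, 0.4), 30, 40)
  m <- pixel_metrics(ref, ref)
  expect_identical(unname(m[c("qseg", "sr", "precision", "recall", "f")]),
                   rep(1, 5))
  expect_identical(mask_ssim(ref, ref), 1)
})

test_that("Qseg satisfies the a/(2T - a) identity on random mask pairs", {
  for (seed in 1:20) {
    set.seed(seed)
    pred <- matrix(rbinom(200, 1, runif(1, 0.2, 0.8)), 10, 20)
    ref <- matrix(rbinom(200, 1, runif(1, 0.2, 0.8)), 10, 20)
    if (sum(ref) == 0) ref[1, 1] <- 1
    a <- sum(pred == ref); T <- length(ref)
    expect_equal(unname(pixel_metrics(pred, ref)["qseg"]), a / (2 * T - a))
  }
})

test_that("complementary masks score Qseg = 0", {
  set.seed(3)
  ref <- matrix(rbinom(100, 1, 0.5), 10, 10)
  if (sum(ref) == 0) ref[1, 1] <- 1
  expect_equal(unname(pixel_metrics(1 - ref, ref)["qseg"]), 0)
})

test_that("F lies between min and max of precision and recall", {
  for (seed in 1:25) {
    set.seed(seed)
    pred <- matrix(rbinom(400, 1, runif(1, 0.1, 0.9)), 20, 20)
    ref <- matrix(rbinom(400, 1, runif(1, 0.1, 0.9)), 20, 20)
    if (sum(ref) == 0) ref[1, 1] <- 1
    m <- pixel_metrics(pred, ref)
    if (m["precision"] + m["recall"] > 0) {
      expect_gte(m[["f"]], min(m[["precision"]], m[["recall"]]) - 1e-12)
      expect_lte(m[["f"]], max(m[["precision"]], m[["recall"]]) + 1e-12)
      expect_equal(m[["f"]],
                   2 * m[["precision"]] * m[["recall"]] /
                     (m[["precision"]] + m[["recall"]]))
    }
  }
})

test_that("recall is non-increasing as a soft mask is thresholded higher", {
  set.seed(11)
  soft <- matrix(runif(30 * 30), 30, 30)
  ref <- matrix(as.integer(soft + rnorm(900, 0, 0.3) > 0.5), 30, 30)
  if (sum(ref) == 0) ref[1, 1] <- 1
  recalls <- sapply(seq(0.1, 0.9, by = 0.2), function(th)
    pixel_metrics(matrix(as.integer(soft > th), 30, 30), ref)[["recall"]])
  expect_true(all(diff(recalls) <= 1e-12))
})

test_that("an empty reference ear set is rejected for Sr", {
  expect_error(pixel_metrics(matrix(1, 12, 12), matrix(0, 12, 12)),
               "no ear pixels")
})

test_that("SSIM is symmetric and matches the zero-variance closed form", {
  set.seed(5)
  a <- matrix(rbinom(20 * 30, 1, 0.5), 20, 30)
  b <- matrix(rbinom(20 * 30, 1, 0.5), 20, 30)
  expect_equal(mask_ssim(a, b), mask_ssim(b, a))
  # constant all-ear vs constant all-background: variances vanish so
  # SSIM = (2 mu1 mu2 + C1) / (mu1^2 + mu2^2 + C1)
  ones <- matrix(1, 20, 30); zeros <- matrix(0, 20, 30)
  C1 <- (0.01 * 255)^2
  expected <- (2 * 255 * 0 + C1) / (255^2 + 0^2 + C1)
  expect_equal(mask_ssim(ones, zeros), expected, tolerance = 1e-10)
  expect_error(mask_ssim(a[1:5, 1:5], b[1:5, 1:5]), "window")
})

test_that("count regression recovers exact and shifted fits", {
  r <- count_regression(c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$sd_residuals, 0)
  r2 <- count_regression(c(12, 22, 32, 42), c(10, 20, 30, 40))
  expect_equal(r2$slope, 1)
  expect_equal(r2$r_squared, 1)
  expect_equal(r2$intercept, 2)
  # hand OLS of (1,2),(2,4),(3,6),(4,8)
  r3 <- count_regression(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(r3$slope, 2)
  expect_equal(r3$r_squared, 1)
  expect_error(count_regression(1:3, 1:4), "length")
  expect_error(count_regression(1:2, 1:2), "at least 3")
})

test_that("batch evaluation aggregates per-image rows correctly", {
  set.seed(9)
  ref <- matrix(rbinom(20 * 20, 1, 0.4), 20, 20)
  pred <- ref; pred[1:3, 1:3] <- 1 - pred[1:3, 1:3]
  rep5 <- evaluate_batch(rep(list(pred), 5), rep(list(ref), 5))
  expect_equal(unname(unlist(
    rep5$summary[rep5$summary$statistic == "sd", -1])), rep(0, 6))
  perfect <- evaluate_batch(list(ref, ref), list(ref, ref))
  expect_equal(unname(unlist(
    perfect$summary[perfect$summary$statistic == "mean", -1])), rep(1, 6))
  # means equal hand averages on a 3-pair fixture
  preds <- list(pred, ref, 1 - ref + 0L)
  preds[[3]][1, 1] <- 1  # keep some overlap defined
  refs <- list(ref, ref, ref)
  rep3 <- evaluate_batch(preds, refs)
  for (col in c("qseg", "precision", "f")) {
    hand <- mean(sapply(1:3, function(i)
      pixel_metrics(preds[[i]], refs[[i]])[[col]]))
    expect_equal(rep3$summary[[col]][rep3$summary$statistic == "mean"], hand)
  }
  expect_s3_class(tidy(rep3), "tbl_df")
  expect_equal(nrow(tidy(rep3)), 3)
})
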