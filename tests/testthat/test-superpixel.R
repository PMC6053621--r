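test_that("k = 1 yields a single superpixel covering the image", {
  img <- two_region_image(40, 40)
  sp <- slic_segment(img, slic_config(n_superpixels = 1))
  expect_equal(sp$K, 1)
  expect_true(all(sp$labels == 1))
})

test_that("labels always form a full partition of 4-connected regions", {
  scenes <- scene_batch(lapply(1:10, function(i)
    scene_config(height = 100, width = 140, ear_count = 3,
                 ear_axis_range = c(5, 9), min_separation = 22, seed = i)))
  for (s in scenes) {
    sp <- slic_segment(s$image)
    expect_equal(sort(unique(as.vector(sp$labels))), seq_len(sp$K))
    expect_equal(sum(tabulate(as.vector(sp$labels), sp$K)),
                 length(sp$labels))
    # each label is one 4-connected region
    for (k in sample(seq_len(sp$K), min(8, sp$K)))
      expect_equal(oracle_component_count(sp$labels == k, 4), 1)
    # superpixel count stays within 20% of the request
    requested <- max(1, round(100 * 140 / 400))
    expect_lt(abs(sp$K - requested) / requested, 0.2)
  }
})

test_that("a constant image with k = 4 splits into four equal quadrant cells", {
  img <- constant_patch(120, size = 40)
  sp <- slic_segment(img, slic_config(n_superpixels = 4))
  expect_equal(sp$K, 4)
  sizes <- sort(tabulate(as.vector(sp$labels), 4))
  expect_true(all(abs(sizes - 400) <= 80))  # ~400 px each
  # agreement with an unwindowed Lloyd k-means using the same init/distance
  S <- sqrt(40 * 40 / 4)
  seeds <- expand.grid(r = c(10, 30), c = c(10, 30))
  lab <- earcount:::rgb_to_lab(img)
  centers0 <- cbind(seeds$r - 1, seeds$c - 1,
                    lab$L[as.matrix(seeds)], lab$a[as.matrix(seeds)],
                    lab$b[as.matrix(seeds)])
  km <- oracle_slic_kmeans(img, centers0, S, 10, 10)
  agree <- max(sapply(1:4, function(k) {
    # best label matching between the two partitions
    tab <- table(km[sp$labels == k])
    max(tab) / sum(sp$labels == k)
  }))
  expect_gt(mean(sapply(1:4, function(k) {
    tab <- table(km[sp$labels == k]); max(tab) / sum(sp$labels == k)
  })), 0.95)
})

test_that("two colour regions are recovered almost exactly with k = 2", {
  img <- two_region_image(40, 60)
  sp <- slic_segment(img, slic_config(n_superpixels = 2))
  expect_equal(sp$K, 2)
  truth <- matrix(rep(c(1, 2), each = 40 * 30), 40, 60)
  agree <- max(mean((sp$labels == 1) == (truth == 1)),
               mean((sp$labels == 2) == (truth == 1)))
  expect_gte(agree, 0.99)
})

test_that("segmentation is deterministic and validates its inputs", {
  img <- two_region_image(40, 40)
  s1 <- slic_segment(img)
  s2 <- slic_segment(img)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$centers, s2$centers)
  expect_error(slic_segment(img, slic_config(n_superpixels = 40 * 40 + 1)),
               "more superpixels")
})

test_that("patch extraction cuts one clamped window per superpixel", {
  sc <- generate_scene(small_scene_config(4))
  sp <- slic_segment(sc$image)
  ps <- extract_patches(sc$image, sp)
  expect_length(ps$patches, sp$K)
  expect_true(all(vapply(ps$patches, function(p)
    all(dim(p) == c(20, 20, 3)), logical(1))))
  # windows stay inside the image
  expect_true(all(ps$info$row0 >= 1 & ps$info$row0 + 19 <= 160))
  expect_true(all(ps$info$col0 >= 1 & ps$info$col0 + 19 <= 240))
  # patch content matches the source image at the recorded offset
  i <- which.max(ps$info$row0)
  expect_identical(ps$patches[[i]],
                   sc$image[ps$info$row0[i]:(ps$info$row0[i] + 19),
                            ps$info$col0[i]:(ps$info$col0[i] + 19), ,
                            drop = FALSE])
})

test_that("a centroid near the border clamps the window to the edge", {
  img <- constant_patch(50, size = 60)
  sp <- slic_segment(img, slic_config(n_superpixels = 9))
  # forge a centroid 3 px from the left edge
  sp$centers$col[1] <- 3
  sp$centers$row[1] <- 30
  ps <- extract_patches(img, sp)
  expect_equal(ps$info$col0[1], 1)
  # a centered centroid gives the centered window
  sp$centers$col[2] <- 30; sp$centers$row[2] <- 30
  ps2 <- extract_patches(img, sp)
  expect_equal(ps2$info$row0[2], 21)
  expect_equal(ps2$info$col0[2], 21)
  expect_error(extract_patches(img, sp, patch_size = 61), "exceeds")
})

test_that("patch labels follow the zero-ratio rule", {
  sc <- generate_scene(small_scene_config(6))
  sp <- slic_segment(sc$image)
  ps <- extract_patches(sc$image, sp)
  # all-background mask: every label 0
  l0 <- label_patches(ps, sp, matrix(0L, 160, 240))
  expect_true(all(l0$labels == 0L))
  # all-ear mask: every label 1
  l1 <- label_patches(ps, sp, matrix(1L, 160, 240))
  expect_true(all(l1$labels == 1L))
  # a single ear pixel in one superpixel flips exactly that patch
  m <- matrix(0L, 160, 240)
  target <- which(sp$labels == 5)[1]
  m[target] <- 1L
  lx <- label_patches(ps, sp, m)
  expect_equal(which(lx$labels == 1L),
               which(ps$info$superpixel_id == 5))
  # the real mask labels agree with per-superpixel ear ratios
  lr <- label_patches(ps, sp, sc$mask)
  expect_equal(lr$labels, as.integer(lr$info$ear_ratio > 0))
  expect_error(label_patches(ps, sp, matrix(0L, 10, 10)), "sizes differ")
})
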