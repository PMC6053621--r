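test_that("an empty scene has no foreground and zero count", {
  sc <- generate_scene(scene_config(ear_count = 0, height = 80, width = 80,
                                    seed = 5))
  expect_equal(sc$count, 0)
  expect_equal(sum(sc$mask), 0)
  expect_equal(nrow(sc$centroids), 0)
})

test_that("well-separated ears appear as exactly ear_count mask components", {
  sc <- generate_scene(scene_config(ear_count = 20, seed = 11))
  expect_equal(oracle_component_count(sc$mask, 8), 20)
  expect_equal(count_regions(sc$mask)$count, 20)
  # centroids lie inside the foreground
  expect_true(all(sc$mask[cbind(sc$centroids$row, sc$centroids$col)] == 1))
})

test_that("scene generation is byte-deterministic in its config", {
  cfg <- scene_config(ear_count = 5, height = 120, width = 150,
                      min_separation = 30, seed = 123)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  s3 <- generate_scene(scene_config(ear_count = 5, height = 120, width = 150,
                                    min_separation = 30, seed = 124))
  expect_false(identical(s1$image, s3$image))
})

test_that("config validation rejects degenerate scenes", {
  expect_error(scene_config(height = 30), "40")
  expect_error(scene_config(ear_count = -1), "ear_count")
  expect_error(scene_config(ear_axis_range = c(5, 3)), "ear_axis_range")
  expect_error(scene_config(min_separation = -2), "min_separation")
})

test_that("impossible placements fail loudly instead of hanging", {
  expect_error(
    generate_scene(scene_config(height = 80, width = 80, ear_count = 50,
                                min_separation = 60, seed = 1)),
    "min_separation")
})

test_that("illumination levels order the mean scene luminance", {
  scenes <- scene_batch(lapply(c("low", "medium", "high"), function(ill)
    scene_config(height = 100, width = 120, ear_count = 3,
                 illumination = ill, seed = 77)))
  lum <- sapply(scenes, function(s) mean(earcount:::luminance(s$image)))
  expect_true(all(diff(lum) > 0))
})

test_that("scene batches propagate errors with the scene index", {
  expect_error(scene_batch(list()), "non-empty")
  cfgs <- list(scene_config(seed = 1, height = 80, width = 80, ear_count = 2),
               scene_config(height = 80, width = 80, ear_count = 50,
                            min_separation = 60, seed = 2))
  expect_error(scene_batch(cfgs), "scene 2")
})

test_that("distinct seeds give pairwise distinct images", {
  scenes <- scene_batch(lapply(1:10, function(i)
    scene_config(height = 60, width = 60, ear_count = 1,
                 ear_axis_range = c(4, 7), min_separation = 5, seed = i)))
  for (i in 1:9) for (j in (i + 1):10)
    expect_false(identical(scenes[[i]]$image, scenes[[j]]$image))
})

test_that("zero noise level is the identity", {
  img <- generate_scene(scene_config(height = 60, width = 60, ear_count = 1,
                                     ear_axis_range = c(4, 7),
                                     min_separation = 5, seed = 2))$image
  for (model in c("gaussian", "rayleigh", "exponential", "salt_pepper"))
    expect_identical(add_noise(img, noise_spec(model, 0)), img)
})

test_that("salt-and-pepper flips the configured pixel fraction", {
  img <- constant_patch(128, size = 100)
  out <- add_noise(img, noise_spec("salt_pepper", 0.1, seed = 4))
  changed <- mean(out[, , 1] != 128)
  p <- 0.1; n <- 100 * 100
  expect_lt(abs(changed - p), 3 * sqrt(p * (1 - p) / n))
  expect_true(all(out[out != 128] %in% c(0, 255)))
})

test_that("gaussian noise has the configured standard deviation", {
  img <- constant_patch(128, size = 100)
  out <- add_noise(img, noise_spec("gaussian", 10, seed = 6))
  delta <- as.numeric(out) - 128
  # at sigma = 10 around mid-gray essentially nothing clips
  expect_lt(abs(sd(delta) - 10) / 10, 0.05)
})

test_that("unknown noise models are rejected", {
  expect_error(noise_spec("poisson", 1), "unknown noise model")
  expect_error(noise_spec("salt_pepper", 1.5), "density")
  expect_error(noise_spec("gaussian", -1), "level")
})

test_that("mean deviation grows with the noise level for every model", {
  img <- generate_scene(scene_config(height = 80, width = 100, ear_count = 2,
                                     ear_axis_range = c(4, 7),
                                     min_separation = 20, seed = 9))$image
  levels <- list(gaussian = c(5, 15, 40), rayleigh = c(5, 15, 40),
                 exponential = c(5, 15, 40), salt_pepper = c(0.05, 0.2, 0.5))
  for (model in names(levels)) {
    mad <- sapply(levels[[model]], function(lv)
      mean(abs(as.numeric(add_noise(img, noise_spec(model, lv, seed = 3))) -
                 as.numeric(img))))
    expect_true(all(diff(mad) > 0), info = model)
  }
})

test_that("scenes round-trip through PNG + JSON on disk", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(scene_config(height = 80, width = 90, ear_count = 3,
                                    ear_axis_range = c(4, 7),
                                    min_separation = 25, seed = 31))
  write_scene(sc, dir, "s1")
  back <- read_scene(dir, "s1")
  expect_identical(back$image, sc$image)
  expect_identical(back$mask, sc$mask)
  expect_equal(back$count, sc$count)
  expect_equal(back$centroids$row, sc$centroids$row)
})
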