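# Full-scale counting study shared by the end-to-end recovery and
# noise-robustness tests: 30 training plots and 20 held-out 20-ear plots at
# the calibrated study configuration, plus 20 varying-count plots for the
# count regression. Built lazily and cached for the session.

get_study <- function() {
  if (!is.null(.test_cache$study)) return(.test_cache$study)
  base <- 42000L
  sep <- 48   # well-separated: inter-ear gap >= one patch width
  cfg <- default_study_config()
  train <- scene_batch(lapply(1:30, function(i)
    scene_config(min_separation = sep, seed = base + i)))
  test <- scene_batch(lapply(1:20, function(i)
    scene_config(min_separation = sep, seed = base + 500L + i)))
  reg_true <- round(seq(8, 30, length.out = 20))
  reg <- scene_batch(lapply(1:20, function(i)
    scene_config(ear_count = reg_true[i], min_separation = sep,
                 seed = base + 600L + i)))
  model <- train_ear_model(train, slic_config = cfg$slic, seed = base)
  res <- lapply(test, function(s)
    run_pipeline(s$image, model, min_area = cfg$min_area))
  reg_pred <- vapply(reg, function(s)
    run_pipeline(s$image, model, min_area = cfg$min_area)$count, integer(1))
  .test_cache$study <- list(
    model = model, cfg = cfg, test = test,
    pred_counts = vapply(res, `[[`, integer(1), "count"),
    pred_masks = lapply(res, `[[`, "mask"),
    true_counts = vapply(test, `[[`, integer(1), "count"),
    reg_true = reg_true, reg_pred = reg_pred, base = base)
  .test_cache$study
}

study_count_accuracy <- function(pred, truth) {
  1 - mean(abs(pred - truth) / truth)
}
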