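# Desk-scale trained models shared across the slower acceptance checks.
# Training is memoized so the paired-loss and cascade checks reuse the same
# seed-fixed cohorts and budgets, and the cascade reuses the paired check's
# stage-1 model.

.model_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function(seed, noise_sd = 0.05, n = 12, split = 0.75)
  generate_cohort(n, phantom_spec(noise_sd = noise_sd, seed = seed),
                  split = split)

acceptance_schedule <- function(max_epochs = 8)
  train_schedule(max_epochs = max_epochs, error_rate_stop = 0.05,
                 augment_rotate180 = TRUE)

# one small seed-fixed training; `kind` is "iou", "cross_entropy" or
# "cascade"
trained_model <- function(seed, kind) {
  key <- sprintf("%s_%d", kind, seed)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  co <- acceptance_cohort(100 + seed)
  obj <- if (kind == "cascade") {
    s1 <- trained_model(seed, "iou")$fit
    cascade_fit(co$train, cascade_config(sfcnn_config(base_filters = 4)),
                acceptance_schedule(), loss = "iou", val = co$test,
                seed = seed, stage1 = s1)
  } else {
    sfcnn_fit(co$train, sfcnn_config(base_filters = 4),
              acceptance_schedule(), loss = kind, val = co$test, seed = seed)
  }
  .model_cache[[key]] <- list(fit = obj, cohort = co)
  .model_cache[[key]]
}

heldout_whole_dice <- function(test, preds, field = "labels") {
  mean(vapply(seq_along(preds), function(i) {
    lab <- preds[[i]][[field]]
    lab <- if (inherits(lab, "labelmap")) lab$data else lab
    dice(test[[i]]$labels$data > 0, lab > 0)
  }, 0))
}
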