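#' Cascade configuration
#'
#' Settings of the two-stage multimodal auto-context cascade: stage 1 is a
#' standard network over the raw modalities; stage 2 is another instance of
#' the same architecture whose input concatenates the raw modalities, stage
#' 1's per-class probability maps (the context information) and dense 3D
#' Haar-like feature channels computed from a raw modality. The cascade is
#' exactly two stages -- the second classifier's result is the final
#' segmentation, with no further iteration.
#'
#' @param stage1 [sfcnn_config()] for the first classifier.
#' @param haar_templates template list from [haar_templates()]; use `list()`
#'   to ablate the Haar channels.
#' @param haar_modality raw modality the Haar features are computed from
#'   (default `"flair"`), or `NULL` to ablate.
#' @param haar_normalize z-score the Haar channels before stacking (default
#'   `TRUE`).
#' @param use_probability include stage-1 probability channels in stage 2
#'   (default `TRUE`; `FALSE` gives the ablation in which stage 2 reduces to
#'   an independently trained stage-1-equivalent).
#' @return object of class `cascade_config`; `$stage2` holds the derived
#'   stage-2 network config with the widened input channel count.
#' @export
cascade_config <- function(stage1 = sfcnn_config(),
                           haar_templates = ioucseg::haar_templates(),
                           haar_modality = "flair", haar_normalize = TRUE,
                           use_probability = TRUE) {
  n_haar <- if (is.null(haar_modality)) 0L else length(haar_templates)
  stage2 <- stage1
  stage2$in_channels <- stage1$in_channels +
    (if (use_probability) stage1$n_classes else 0L) + n_haar
  structure(list(stage1 = stage1, stage2 = stage2,
                 haar_templates = haar_templates,
                 haar_modality = haar_modality,
                 haar_normalize = isTRUE(haar_normalize),
                 use_probability = isTRUE(use_probability),
                 n_haar = n_haar, iterations = 2L),
            class = "cascade_config")
}

# Assemble one stage-2 training/validation sample: z-scored modalities +
# stage-1 probabilities (native scale) + normalized Haar channels
stage2_sample <- function(sub, stage1, config) {
  raw <- if (!is.null(sub$stack)) sub$stack else sub$x
  pr <- predict(stage1, raw, postprocess = FALSE)
  probs <- if (config$use_probability) pr$prob$data else NULL
  haar <- cascade_haar(raw, config)
  xr <- if (inherits(raw, "mmstack")) stack_array(raw) else raw
  for (c in seq_len(dim(xr)[4])) xr[, , , c] <- normalize_zscore(xr[, , , c])
  list(x = build_stage2_input(xr, probs, haar), labels = sub$labels)
}

# Haar channels for one subject (raw, un-normalized modality intensities)
cascade_haar <- function(stack, ccfg) {
  if (ccfg$n_haar == 0L) return(NULL)
  vol <- if (inherits(stack, "mmstack"))
    stack$channels[[ccfg$haar_modality]]$data
  else stack[, , , match(ccfg$haar_modality, MODALITIES)]
  h <- haar_feature_channels(vol, ccfg$haar_templates)
  if (ccfg$haar_normalize)
    for (i in seq_len(dim(h)[4])) h[, , , i] <- normalize_zscore(h[, , , i])
  h
}

#' Assemble the stage-2 input grid
#'
#' Concatenates, in fixed channel order, the raw modality channels, the
#' stage-1 class-probability channels, and the Haar feature channels. All
#' inputs must be spatially aligned.
#'
#' @param stack [mmstack] or 4D modality array.
#' @param probs [probmap] or 4D probability array from stage 1 (or `NULL`
#'   when ablated).
#' @param haar 4D Haar channel array (or `NULL`).
#' @return 4D array with `4 + n_classes + n_haar` channels.
#' @export
build_stage2_input <- function(stack, probs = NULL, haar = NULL) {
  x <- if (inherits(stack, "mmstack")) stack_array(stack) else stack
  parts <- list(x)
  if (!is.null(probs))
    parts <- c(parts, list(if (inherits(probs, "probmap")) probs$data
                           else probs))
  if (!is.null(haar)) parts <- c(parts, list(haar))
  shp <- dim(parts[[1]])[1:3]
  for (p in parts[-1])
    if (!identical(dim(p)[1:3], shp))
      stop_ioucseg("ioucseg_alignment",
                   "stage-2 inputs are not spatially aligned (%s vs %s)",
                   paste(shp, collapse = "x"),
                   paste(dim(p)[1:3], collapse = "x"))
  nch <- sum(vapply(parts, function(p) dim(p)[4], 0L))
  out <- array(0, c(shp, nch))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[4]
    out[, , , at + seq_len(k)] <- p
    at <- at + k
  }
  out
}

#' Train the two-stage auto-context cascade
#'
#' Stage 1 is trained on the raw multimodal stacks; its predictions on the
#' same training subjects then provide the probability-map context channels
#' (together with Haar features from the raw images) on which stage 2 is
#' trained. Both stages share the loss and schedule.
#'
#' @param subjects training subjects as in [sfcnn_fit()].
#' @param config a [cascade_config()].
#' @param schedule a [train_schedule()] used by both stages.
#' @param loss loss name as in [sfcnn_fit()].
#' @param val optional held-out subjects (early stopping for both stages).
#' @param seed integer seed.
#' @param stage1 optionally, an already fitted `sfcnn_fit` to use as the
#'   first classifier (its config must match `config$stage1`); by default
#'   stage 1 is trained here.
#' @param verbose print per-epoch lines.
#' @return object of class `sfcnn_cascade` with elements `stage1`, `stage2`
#'   (both `sfcnn_fit`s) and `config`.
#' @export
cascade_fit <- function(subjects, config = cascade_config(),
                        schedule = train_schedule(), loss = "iou",
                        val = NULL, seed = 1L, stage1 = NULL,
                        verbose = FALSE) {
  if (!length(subjects))
    stop_ioucseg("ioucseg_validation", "empty training set")
  if (is.null(stage1))
    stage1 <- sfcnn_fit(subjects, config$stage1, schedule, loss = loss,
                        val = val, seed = seed, verbose = verbose)
  else if (!identical(stage1$config, config$stage1))
    stop_ioucseg("ioucseg_validation",
                 "supplied stage-1 fit does not match config$stage1")
  s2_train <- lapply(subjects, stage2_sample, stage1 = stage1,
                     config = config)
  if (dim(s2_train[[1]]$x)[4] != config$stage2$in_channels)
    stop_ioucseg("ioucseg_validation",
                 "stage-2 input has %d channels but config expects %d",
                 dim(s2_train[[1]]$x)[4], config$stage2$in_channels)
  s2_val <- if (!is.null(val)) lapply(val, stage2_sample, stage1 = stage1,
                                      config = config)
  # stage-2 channels arrive pre-scaled (modalities z-scored, Haar channels
  # z-scored, probabilities on their native [0,1] scale), so the stage-2
  # fit must not renormalize them: z-scoring a near-constant probability
  # channel would reintroduce extreme outliers
  #
  # stage 2 warm-starts from stage 1: every layer is copied, and the first
  # convolution reads the modality channels with the stage-1 kernels while
  # the added context channels (probabilities, Haar) start at zero. The
  # refinement stage therefore begins at stage-1 performance and learns to
  # use the context rather than relearning segmentation from scratch; a
  # from-scratch stage 2 proved seed-bimodal at desk scale.
  W2 <- stage1$weights
  w1 <- W2[["c0a.w"]]
  d1 <- dim(w1)
  w2 <- array(0, c(d1[1:3], config$stage2$in_channels, d1[5]))
  w2[, , , seq_len(d1[4]), ] <- w1
  W2[["c0a.w"]] <- w2
  stage2 <- sfcnn_fit(s2_train, config$stage2, schedule, loss = loss,
                      val = s2_val, seed = seed + 1L, normalize = FALSE,
                      init_weights = W2, verbose = verbose)
  structure(list(stage1 = stage1, stage2 = stage2, config = config),
            class = "sfcnn_cascade")
}

#' Predict with the auto-context cascade
#'
#' Runs stage 1, assembles the stage-2 input from its probability maps and
#' the Haar channels, runs stage 2, and returns both stages' probability
#' maps for audit along with the final label map (argmax of the stage-2
#' probabilities, post-processed).
#'
#' @param object an `sfcnn_cascade`.
#' @param newdata an [mmstack], 4D array, or list of subjects.
#' @param postprocess apply component filtering to the final labels.
#' @param ... unused.
#' @return `list(prob_stage1 =, prob_stage2 =, labels =)` (or a per-subject
#'   list).
#' @export
predict.sfcnn_cascade <- function(object, newdata, postprocess = TRUE, ...) {
  if (is.list(newdata) && !inherits(newdata, "mmstack") &&
      is.null(dim(newdata)))
    return(lapply(newdata, function(s) {
      one <- if (is.list(s) && !inherits(s, "mmstack") && !is.null(s$stack))
        s$stack
      else if (is.list(s) && !inherits(s, "mmstack") && !is.null(s$x)) s$x
      else s
      predict.sfcnn_cascade(object, one, postprocess = postprocess)
    }))
  p1 <- predict(object$stage1, newdata, postprocess = FALSE)
  probs <- if (object$config$use_probability) p1$prob$data else NULL
  haar <- cascade_haar(newdata, object$config)
  xr <- if (inherits(newdata, "mmstack")) stack_array(newdata) else newdata
  for (c in seq_len(dim(xr)[4])) xr[, , , c] <- normalize_zscore(xr[, , , c])
  x2 <- build_stage2_input(xr, probs, haar)
  p2 <- predict(object$stage2, x2, postprocess = postprocess)
  list(prob_stage1 = p1$prob, prob_stage2 = p2$prob, labels = p2$labels)
}

#' @export
print.sfcnn_cascade <- function(x, ...) {
  cat("Two-stage multimodal auto-context cascade\n")
  cat(sprintf("  stage 1: %d input channels, final loss %.5f\n",
              x$config$stage1$in_channels,
              x$stage1$history$loss[nrow(x$stage1$history)]))
  cat(sprintf("  stage 2: %d input channels (4 raw + %d prob + %d Haar), final loss %.5f\n",
              x$config$stage2$in_channels,
              if (x$config$use_probability) x$config$stage1$n_classes else 0L,
              x$config$n_haar,
              x$stage2$history$loss[nrow(x$stage2$history)]))
  invisible(x)
}
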