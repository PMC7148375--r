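#' Training schedule
#'
#' The optimization contract used by [sfcnn_fit()]: adaptive-moment gradient
#' descent starting at learning rate 1e-4, halving the rate when the epoch
#' loss stops decreasing (after `lr_patience` epochs without a new best), a
#' maximum epoch count initialized at 100, and error-rate early stopping --
#' training stops once `1 - mean held-out whole-tumor Dice` (measured on
#' the full prediction pipeline, component filter included) drops to
#' `error_rate_stop`, and the best monitored iterate is the returned model.
#'
#' @param learning_rate initial learning rate (default 1e-4).
#' @param max_epochs maximum training epochs (default 100).
#' @param error_rate_stop held-out error-rate threshold for early stopping
#'   (default 0.05); only active when a validation set is supplied.
#' @param lr_halving halve the learning rate on a loss plateau (default
#'   `TRUE`).
#' @param lr_patience epochs without a new best loss before the rate is
#'   halved (default 3; plateau detection needs a window because the
#'   epoch loss of a stochastic schedule fluctuates).
#' @param min_lr floor below which the rate is not halved further.
#' @param batch_size sub-volumes per gradient step (default 1); the class
#'   weights of the IOU-constraint loss are computed over the whole batch,
#'   which tempers their variance when the rarest class has only a handful
#'   of voxels per sub-volume.
#' @param augment_rotate180 add 180-degree-rotated copies of the training
#'   samples (default `FALSE`).
#' @return object of class `train_schedule`.
#' @export
train_schedule <- function(learning_rate = 1e-4, max_epochs = 100L,
                           error_rate_stop = 0.05, lr_halving = TRUE,
                           lr_patience = 3L, min_lr = 1e-6,
                           batch_size = 1L, augment_rotate180 = FALSE) {
  if (learning_rate <= 0)
    stop_ioucseg("ioucseg_parameter", "learning_rate must be positive")
  if (max_epochs < 1)
    stop_ioucseg("ioucseg_parameter", "max_epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 error_rate_stop = error_rate_stop,
                 lr_halving = isTRUE(lr_halving),
                 lr_patience = as.integer(lr_patience),
                 min_lr = min_lr,
                 batch_size = as.integer(batch_size),
                 augment_rotate180 = isTRUE(augment_rotate180)),
            class = "train_schedule")
}

# turn a cohort subject into (x = normalized 4D array, y = one-hot, lab)
prepare_sample <- function(sub, cfg, normalize = TRUE) {
  x <- if (!is.null(sub$x)) sub$x else stack_array(sub$stack)
  if (normalize)
    for (c in seq_len(dim(x)[4])) x[, , , c] <- normalize_zscore(x[, , , c])
  lab <- if (inherits(sub$labels, "labelmap")) sub$labels$data else sub$labels
  list(x = x, y = one_hot(lab, seq_len(cfg$n_classes) - 1L), lab = lab)
}

loss_fun <- function(name) {
  switch(name,
    iou = function(X, Y) iou_constraint_loss(X, Y, "normalized",
                                             grad = TRUE, absent = "drop"),
    iou_literal = function(X, Y)
      iou_constraint_loss(X, Y, "literal", grad = TRUE, absent = "drop"),
    cross_entropy = function(X, Y) cross_entropy_loss(X, Y, grad = TRUE),
    stop_ioucseg("ioucseg_parameter", "unknown loss '%s'", name))
}

#' Fit the IOU-constrained 3D segmentation network
#'
#' Trains a single-stage symmetric 3D fully convolutional network on a list
#' of multimodal subjects with voxel-wise tissue labels, minimizing the
#' IOU-constraint (class-weighted soft-Jaccard) loss by default. Per-channel
#' z-score normalization is applied internally; training is deterministic
#' given `seed` under single-threaded execution.
#'
#' @param subjects list of `list(stack = mmstack, labels = labelmap)` (or
#'   `list(x = 4D array, labels =)`); spatial dims must be divisible by 32.
#' @param config an [sfcnn_config()].
#' @param schedule a [train_schedule()].
#' @param loss `"iou"` (normalized IOU-constraint, default), `"iou_literal"`
#'   (the printed form), or `"cross_entropy"` (unweighted baseline).
#' @param val optional held-out subjects, enabling error-rate early stopping.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @param normalize z-score each input channel (default `TRUE`).
#' @param logit_decay strength of the logit-norm regularizer added to the
#'   training gradient (default 1e-3). Ratio losses such as the
#'   IOU-constraint have bounded gradients in the probabilities, so a
#'   softmax that saturates early freezes permanently; this small pull
#'   toward zero scores keeps every class recoverable. Set to 0 to disable.
#' @param init_weights optional named weight list to start from (a warm
#'   start, e.g. the cascade's stage-2 initialization); must match the
#'   layer shapes of `config`. Default `NULL` draws fresh weights from
#'   [sfcnn_init()].
#' @param verbose print one line per epoch.
#' @return an object of class `sfcnn_fit` with elements `weights`, `config`,
#'   `schedule`, `loss`, `history` (epoch, loss, lr, error_rate), `seed`.
#' @seealso [predict.sfcnn_fit()], [cascade_fit()]
#' @export
sfcnn_fit <- function(subjects, config = sfcnn_config(),
                      schedule = train_schedule(),
                      loss = c("iou", "iou_literal", "cross_entropy"),
                      val = NULL, seed = 1L, normalize = TRUE,
                      logit_decay = 1e-3, init_weights = NULL,
                      verbose = FALSE) {
  loss <- match.arg(loss)
  if (!length(subjects))
    stop_ioucseg("ioucseg_validation", "empty training set")
  lf <- loss_fun(loss)
  samples <- lapply(subjects, prepare_sample, cfg = config,
                    normalize = normalize)
  if (schedule$augment_rotate180) {
    rot <- lapply(samples, function(s) {
      r <- augment_rotate180(s$x, s$lab)
      list(x = r$stack, y = one_hot(r$labels, seq_len(config$n_classes) - 1L),
           lab = r$labels)
    })
    samples <- c(samples, rot)
  }
  val_samples <- if (!is.null(val))
    lapply(val, prepare_sample, cfg = config, normalize = normalize)

  W <- if (is.null(init_weights)) sfcnn_init(config, seed = seed)
  else init_weights
  adam <- list(m = lapply(W, function(w) array(0, dim(w) %||% length(w))),
               v = lapply(W, function(w) array(0, dim(w) %||% length(w))),
               t = 0)
  lr <- schedule$learning_rate
  best_loss <- Inf
  since_best <- 0L
  best_err <- Inf
  best_W <- NULL
  hist <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                     error_rate = numeric())
  nC <- config$n_classes
  set.seed(seed + 1L)
  for (ep in seq_len(schedule$max_epochs)) {
    ord <- sample.int(length(samples))
    batches <- split(ord, ceiling(seq_along(ord) / schedule$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      bidx <- batches[[bi]]
      fws <- lapply(samples[bidx], function(s)
        sfcnn_forward(W, config, s$x, train = TRUE))
      # one loss over the pooled batch voxels: the class weights gamma are
      # per batch, not per sub-volume
      Xb <- do.call(rbind, lapply(fws, function(f)
        matrix(f$probs, ncol = nC)))
      Yb <- do.call(rbind, lapply(samples[bidx], function(s)
        matrix(s$y, ncol = nC)))
      lg <- lf(Xb, Yb)
      losses[bi] <- lg$loss
      # split the pooled gradient back to each sample and backpropagate,
      # seeding each graph with the loss gradient at the probabilities plus
      # a small logit-norm pull that keeps class scores from saturating
      # (ratio losses have bounded gradients and cannot recover a frozen
      # softmax on their own)
      GWs <- vector("list", length(fws))
      at <- 0L
      for (j in seq_along(fws)) {
        fw <- fws[[j]]
        V <- prod(dim(fw$probs)[1:3])
        gX <- array(lg$grad[at + seq_len(V), , drop = FALSE], dim(fw$probs))
        at <- at + V
        logits_id <- fw$graph$nodes[[fw$out]]$parents
        zval <- fw$graph$nodes[[logits_id]]$val
        GWs[[j]] <- graph_backward2(fw$graph, list(fw$out, logits_id),
                                    list(gX, logit_decay * zval /
                                           length(zval)))
      }
      adam$t <- adam$t + 1
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      for (k in names(W)) {
        g <- NULL
        for (j in seq_along(GWs)) {
          gj <- GWs[[j]][[k]]
          if (!is.null(gj)) g <- if (is.null(g)) gj else g + gj
        }
        if (is.null(g)) next
        adam$m[[k]] <- b1 * adam$m[[k]] + (1 - b1) * g
        adam$v[[k]] <- b2 * adam$v[[k]] + (1 - b2) * g^2
        mh <- adam$m[[k]] / (1 - b1^adam$t)
        vh <- adam$v[[k]] / (1 - b2^adam$t)
        W[[k]] <- W[[k]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    ep_loss <- mean(losses)
    err <- NA_real_
    if (!is.null(val_samples)) {
      # error rate is measured on the full prediction pipeline, including
      # the adaptive component filter
      dices <- vapply(val_samples, function(s) {
        probs <- sfcnn_forward(W, config, s$x, train = FALSE)
        pred <- filter_small_components(prob_argmax(probs,
                                                    seq_len(nC) - 1L))
        dice(s$lab > 0, pred > 0)
      }, 0)
      err <- 1 - mean(dices)
      if (err < best_err) { best_err <- err; best_W <- W }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss, lr = lr,
                                   error_rate = err))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  lr %.2e  err %s", ep, ep_loss,
                      lr, ifelse(is.na(err), "-", sprintf("%.3f", err))))
    if (ep_loss < best_loss) { best_loss <- ep_loss; since_best <- 0L }
    else since_best <- since_best + 1L
    if (schedule$lr_halving && since_best >= schedule$lr_patience &&
        lr > schedule$min_lr) {
      lr <- lr / 2
      since_best <- 0L
    }
    if (!is.na(err) && err <= schedule$error_rate_stop) break
  }
  # when a validation set monitors the error rate, keep the best iterate
  if (!is.null(best_W)) W <- best_W
  structure(list(weights = W, config = config, schedule = schedule,
                 loss = loss, history = hist, seed = seed,
                 normalize = normalize, best_error_rate = best_err,
                 class_order = seq_len(config$n_classes) - 1L),
            class = "sfcnn_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# voxel-wise argmax of a (D,H,W,C) probability array -> integer label grid
prob_argmax <- function(probs, class_order) {
  d <- dim(probs)
  m <- matrix(probs, prod(d[1:3]), d[4])
  lab <- class_order[max.col(m, ties.method = "first")]
  array(as.integer(lab), d[1:3])
}

#' Predict segmentations from a fitted network
#'
#' Runs sliding sub-volume inference: the input is cropped per
#' [plan_crops()] (a single pass when the volume already fits), each crop is
#' pushed through the network, overlapping probability crops are mean-fused
#' by [stitch_probability()], the voxel-wise argmax gives the label map, and
#' small spurious components are removed by [filter_small_components()]
#' unless `postprocess = FALSE`.
#'
#' @param object an `sfcnn_fit`.
#' @param newdata an [mmstack], a 4D array, or a list of subjects.
#' @param crop_size sub-volume size (default 32^3 when cropping is needed).
#' @param stride crop stride (default `crop_size - 16`, floored at 1).
#' @param postprocess apply adaptive component filtering (default `TRUE`).
#' @param spacing voxel spacing for the outputs.
#' @param ... unused.
#' @return `list(prob = probmap, labels = labelmap)`, or a list of such per
#'   subject.
#' @export
predict.sfcnn_fit <- function(object, newdata, crop_size = NULL,
                              stride = NULL, postprocess = TRUE,
                              spacing = NULL, ...) {
  if (is.list(newdata) && !inherits(newdata, "mmstack") &&
      is.null(dim(newdata)))
    return(lapply(newdata, function(s) {
      one <- if (is.list(s) && !inherits(s, "mmstack") && !is.null(s$stack))
        s$stack
      else if (is.list(s) && !inherits(s, "mmstack") && !is.null(s$x)) s$x
      else s
      predict.sfcnn_fit(object, one, crop_size = crop_size, stride = stride,
                        postprocess = postprocess, spacing = spacing)
    }))
  if (inherits(newdata, "mmstack")) {
    if (is.null(spacing)) spacing <- newdata$channels[[1]]$spacing
    x <- stack_array(newdata)
  } else x <- newdata
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  cfg <- object$config
  if (object$normalize)
    for (c in seq_len(dim(x)[4])) x[, , , c] <- normalize_zscore(x[, , , c])
  shp <- dim(x)[1:3]
  whole <- all(shp %% 32L == 0L) && is.null(crop_size)
  if (whole) {
    probs <- sfcnn_forward(object$weights, cfg, x, train = FALSE)
  } else {
    if (is.null(crop_size)) crop_size <- pmin(shp %/% 32L * 32L, 32L)
    crop_size <- as.integer(crop_size)
    if (any(crop_size %% 32L != 0L) || any(crop_size < 32L))
      crop_size <- pmax(crop_size %/% 32L * 32L, 32L)
    plan <- plan_crops(shp, crop_size, stride)
    crops <- extract_crops(x, plan)
    pcrops <- lapply(crops, function(cr)
      sfcnn_forward(object$weights, cfg, cr, train = FALSE))
    probs <- stitch_probability(pcrops, plan)
  }
  lab <- prob_argmax(probs, object$class_order)
  lm <- labelmap(lab, spacing)
  if (postprocess) lm <- filter_small_components(lm)
  list(prob = probmap(probs, spacing, object$class_order), labels = lm)
}

#' @export
print.sfcnn_fit <- function(x, ...) {
  cat(sprintf(
    "IOU-constrained 3D segmentation network (%d params, base filters %d)\n",
    sfcnn_n_params(x$config), x$config$base_filters))
  cat(sprintf("loss: %s   epochs run: %d   final loss: %.5f\n", x$loss,
              nrow(x$history), x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.sfcnn_fit <- function(object, ...) {
  h <- object$history
  cat(sprintf("Network: base_filters %d, %d classes, %d input channels\n",
              object$config$base_filters, object$config$n_classes,
              object$config$in_channels))
  cat(sprintf("Parameters: %d\n", sfcnn_n_params(object$config)))
  cat(sprintf("Loss (%s): %.5f -> %.5f over %d epochs\n", object$loss,
              h$loss[1], h$loss[nrow(h)], nrow(h)))
  cat(sprintf("Final learning rate: %.3g (initial %.3g)\n",
              h$lr[nrow(h)], object$schedule$learning_rate))
  if (any(!is.na(h$error_rate)))
    cat(sprintf("Final held-out error rate: %.4f\n",
                h$error_rate[nrow(h)]))
  invisible(object)
}

#' @export
coef.sfcnn_fit <- function(object, ...) object$weights

#' Plot the training history of a fit
#' @param x an `sfcnn_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sfcnn_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = sprintf("%s loss", x$loss), ...)
  invisible(x)
}
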