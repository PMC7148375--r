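#' One-hot encode a label map
#'
#' @param labels [labelmap] or integer 3D array.
#' @param class_order label value of each output channel (default `0:4`).
#' @return binary array (D, H, W, C).
#' @export
one_hot <- function(labels, class_order = 0:4) {
  x <- if (inherits(labels, "labelmap")) labels$data else labels
  class_order <- as.integer(class_order)
  d <- dim(x)
  out <- array(0, c(d, length(class_order)))
  for (i in seq_along(class_order))
    out[, , , i] <- as.numeric(x == class_order[i])
  out
}

#' IOU-constraint loss
#'
#' Class-weighted soft-Jaccard loss for segmentation under extreme class
#' imbalance. With per-voxel predicted probabilities `X` and one-hot ground
#' truth `Y` over `C` classes and `V` voxels, and per-class weights
#' `1 / (gamma_c^2 + epsilon)` where `gamma_c = sum_v Y_cv` is the class
#' size, the loss is
#'
#' `1 - s * [sum_c w_c sum_v X Y] / [sum_c w_c sum_v (X + Y - X Y)]`
#'
#' with `s = 1/C` for the `literal` variant (the printed form, whose value
#' at a perfect prediction is `1 - 1/C` because the ratio of sums is 1) and
#' `s = 1` for the `normalized` variant (perfect prediction scores 0; the
#' default for training). `epsilon` keeps the weight finite for classes
#' absent from the ground truth. At zero overlap both variants equal 1.
#' The loss is differentiable in `X`; `grad = TRUE` also returns the
#' analytic gradient.
#'
#' @param X probability array (D, H, W, C) or matrix (V, C); also accepts a
#'   [probmap].
#' @param Y one-hot array/matrix of the same shape.
#' @param variant `"normalized"` (default) or `"literal"`.
#' @param epsilon small positive stabilizer (default 1e-6).
#' @param grad if `TRUE`, return `list(loss =, grad =)` with the gradient
#'   with respect to `X`.
#' @param absent treatment of classes absent from the ground truth:
#'   `"stabilize"` (default) keeps them in both sums with weight
#'   `1/epsilon`, as the formula prescribes; `"drop"` removes them from
#'   both sums (weight 0), which is the behavior used during training,
#'   where a near-infinite weight on an empty class would otherwise let a
#'   single tumor-free sub-volume dominate every gradient step.
#' @return scalar loss, or a list when `grad = TRUE`.
#' @export
iou_constraint_loss <- function(X, Y, variant = c("normalized", "literal"),
                                epsilon = 1e-6, grad = FALSE,
                                absent = c("stabilize", "drop")) {
  variant <- match.arg(variant)
  absent <- match.arg(absent)
  if (epsilon <= 0)
    stop_ioucseg("ioucseg_parameter", "epsilon must be positive")
  if (inherits(X, "probmap")) X <- X$data
  dX <- dim(X)
  if (!identical(dX, dim(Y)))
    stop_ioucseg("ioucseg_validation", "X and Y shapes differ")
  C <- dX[length(dX)]
  V <- prod(dX) / C
  Xm <- matrix(X, V, C); Ym <- matrix(Y, V, C)
  gamma <- colSums(Ym)
  w <- 1 / (gamma^2 + epsilon)
  if (absent == "drop") w[gamma == 0] <- 0
  inter <- colSums(Xm * Ym)
  union <- colSums(Xm) + gamma - inter
  num <- sum(w * inter)
  den <- sum(w * union)
  s <- if (variant == "literal") 1 / C else 1
  loss <- 1 - s * num / den
  if (!grad) return(loss)
  # d(num)/dX = w_c Y, d(den)/dX = w_c (1 - Y)
  gm <- -s * (sweep(Ym, 2, w, "*") * den -
                num * sweep(1 - Ym, 2, w, "*")) / den^2
  list(loss = loss, grad = array(gm, dX))
}

#' Unweighted cross-entropy loss
#'
#' Mean per-voxel categorical cross-entropy, the conventional baseline that
#' degrades under extreme foreground/background imbalance.
#'
#' @inheritParams iou_constraint_loss
#' @param eps clamp for `log` stability.
#' @return scalar loss, or `list(loss =, grad =)`.
#' @export
cross_entropy_loss <- function(X, Y, eps = 1e-12, grad = FALSE) {
  dX <- dim(X)
  C <- dX[length(dX)]; V <- prod(dX) / C
  Xc <- pmax(X, eps)
  loss <- -sum(Y * log(Xc)) / V
  if (!grad) return(loss)
  list(loss = loss, grad = array(-(Y / Xc) / V, dX))
}

as_mask <- function(x) {
  if (inherits(x, "labelmap")) x <- x$data
  if (is.logical(x)) x else x != 0
}

#' Dice similarity coefficient
#'
#' `2 |T∩P| / (|T| + |P|)`; returns 1 when both masks are empty (the
#' defined limit).
#'
#' @param T,P logical arrays (or label maps; nonzero = foreground) of equal
#'   shape.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(T, P) {
  T <- as_mask(T); P <- as_mask(P)
  st <- sum(T); sp <- sum(P)
  if (st + sp == 0) return(1)
  2 * sum(T & P) / (st + sp)
}

#' Recall and precision of a binary segmentation
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`. When a
#' denominator is empty the value is 1 if both masks are empty and 0
#' otherwise, with a `degenerate` flag set.
#'
#' @inheritParams dice
#' @return named list `recall`, `precision`, `degenerate`.
#' @export
recall_precision <- function(T, P) {
  T <- as_mask(T); P <- as_mask(P)
  tp <- sum(T & P); fn <- sum(T & !P); fp <- sum(!T & P)
  both_empty <- sum(T) == 0 && sum(P) == 0
  degen <- FALSE
  rec <- if (tp + fn > 0) tp / (tp + fn) else { degen <- TRUE
    if (both_empty) 1 else 0 }
  prec <- if (tp + fp > 0) tp / (tp + fp) else { degen <- TRUE
    if (both_empty) 1 else 0 }
  list(recall = rec, precision = prec, degenerate = degen)
}

mask_points <- function(x, spacing) {
  w <- which(as_mask(x), arr.ind = TRUE)
  sweep(w - 1, 2, spacing, "*")
}

#' Hausdorff distance between two segmentations
#'
#' Symmetric Hausdorff distance `max(hd(P,T), hd(T,P))` with
#' `hd(P,T) = max_p min_t ||p - t||` in Euclidean distance, computed over
#' all foreground voxels (or over boundary voxels only when
#' `surface_only = TRUE`), with voxel coordinates scaled by `spacing` so the
#' result is in millimetres.
#'
#' @param T,P logical masks (or label maps), or point matrices (rows =
#'   points) which are then used as-is.
#' @param spacing voxel spacing in mm (ignored for point-matrix input).
#' @param surface_only if `TRUE`, restrict masks to voxels with at least one
#'   6-neighbor outside the mask.
#' @return distance in mm; empty input is an error of class
#'   `ioucseg_undefined_metric` (report as missing, never as 0).
#' @export
hausdorff <- function(T, P, spacing = c(1, 1, 1), surface_only = FALSE) {
  to_pts <- function(x) {
    if (is.matrix(x) && !is.logical(x)) return(x)
    m <- as_mask(x)
    if (surface_only) m <- m & !erode6(m)
    mask_points(m, spacing)
  }
  Tp <- to_pts(T); Pp <- to_pts(P)
  if (nrow(Tp) == 0 || nrow(Pp) == 0)
    stop_ioucseg("ioucseg_undefined_metric",
                 "Hausdorff distance is undefined for an empty set")
  cpp_hausdorff(Pp, Tp)
}

# 6-connected erosion (interior voxels)
erode6 <- function(m) {
  d <- dim(m)
  shift <- function(ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    n <- d[ax]
    if (by == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  m & shift(1, 1) & shift(1, -1) & shift(2, 1) & shift(2, -1) &
    shift(3, 1) & shift(3, -1)
}

#' Nested tumor evaluation regions
#'
#' Builds the standard nested evaluation masks from a label map: whole tumor
#' = labels \{1,2,3,4\}, tumor core = \{1,3,4\}, enhancing tumor = \{4\}
#' (so enhancing ⊆ core ⊆ whole).
#'
#' @param labels [labelmap] or integer array.
#' @param regions subset of `c("whole", "core", "enhancing")`.
#' @return named list of logical masks.
#' @export
region_masks <- function(labels, regions = c("whole", "core", "enhancing")) {
  x <- if (inherits(labels, "labelmap")) labels$data else labels
  defs <- list(whole = c(1, 2, 3, 4), core = c(1, 3, 4), enhancing = 4)
  regions <- match.arg(regions, names(defs), several.ok = TRUE)
  out <- lapply(defs[regions], function(v) array(x %in% v, dim(x)))
  names(out) <- regions
  out
}

#' Region-wise segmentation metrics for one subject
#'
#' @param truth,pred [labelmap]s (or integer arrays) of equal shape.
#' @param spacing voxel spacing in mm used for the Hausdorff distance.
#' @return data.frame with columns region, dice, recall, precision, hd_mm
#'   (hd_mm is `NA` when either mask is empty).
#' @export
segmentation_metrics <- function(truth, pred, spacing = c(1, 1, 1)) {
  mt <- region_masks(truth); mp <- region_masks(pred)
  rows <- lapply(names(mt), function(r) {
    rp <- recall_precision(mt[[r]], mp[[r]])
    hd <- tryCatch(hausdorff(mt[[r]], mp[[r]], spacing),
                   ioucseg_undefined_metric = function(e) NA_real_)
    data.frame(region = r, dice = dice(mt[[r]], mp[[r]]),
               recall = rp$recall, precision = rp$precision, hd_mm = hd)
  })
  do.call(rbind, rows)
}
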