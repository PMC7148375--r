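#' Z-score intensity normalization
#'
#' Normalizes one modality volume by subtracting the mean of all voxels and
#' dividing by the population standard deviation (the image is treated as
#' the full population). A constant volume maps to all zeros.
#'
#' @param vol a [volume] or bare 3D array.
#' @return same type as the input, normalized.
#' @export
normalize_zscore <- function(vol) {
  is_vol <- inherits(vol, "volume")
  x <- if (is_vol) vol$data else vol
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  y <- if (sdev < 1e-12) array(0, dim(x)) else (x - mu) / sdev
  if (is_vol) volume(y, spacing = vol$spacing, modality = vol$modality) else y
}

#' 180-degree rotation augmentation
#'
#' Rotates all modality channels and the label map by 180 degrees in the
#' axial (height, width) plane; label values are untouched, so the label
#' histogram is invariant and applying the rotation twice is the identity.
#'
#' @param stack an [mmstack] (or bare 4D array).
#' @param labels a [labelmap] (or bare 3D array), optional.
#' @param axes the two axes spanning the rotation plane (default `c(2, 3)`,
#'   the axial plane).
#' @return `list(stack =, labels =)` with both rotated consistently.
#' @export
augment_rotate180 <- function(stack, labels = NULL, axes = c(2, 3)) {
  rot3 <- function(a) {
    idx <- lapply(1:3, function(ax)
      if (ax %in% axes) rev(seq_len(dim(a)[ax])) else seq_len(dim(a)[ax]))
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  if (inherits(stack, "mmstack")) {
    chans <- lapply(stack$channels, function(v)
      volume(rot3(v$data), v$spacing, v$modality))
    stack <- structure(list(channels = chans, subject_id = stack$subject_id),
                       class = "mmstack")
  } else if (length(dim(stack)) == 4L) {
    for (c in seq_len(dim(stack)[4])) stack[, , , c] <- rot3(stack[, , , c])
  } else stack <- rot3(stack)
  if (!is.null(labels)) {
    if (inherits(labels, "labelmap"))
      labels <- labelmap(rot3(labels$data), labels$spacing)
    else labels <- rot3(labels)
  }
  list(stack = stack, labels = labels)
}

#' Plan sub-volume crops
#'
#' Computes sliding-window crop offsets covering a volume completely: offsets
#' advance by `stride` per axis, with a final offset flush to the far edge so
#' that the union of crops covers every voxel. Axes shorter than the crop
#' size are zero-padded symmetrically first.
#'
#' @param shape integer length-3 volume shape (D, H, W).
#' @param crop_size integer length-3 crop shape (default 128^3 at paper
#'   scale; desk-scale work uses 32^3).
#' @param stride integer length-3 stride (default `crop_size` minus a
#'   16-voxel overlap, floored at 1).
#' @return a `crop_plan`: crop size, per-axis padding, and the matrix of
#'   0-based crop corner offsets into the padded grid.
#' @export
plan_crops <- function(shape, crop_size = c(128, 128, 128), stride = NULL) {
  shape <- as.integer(shape); crop_size <- as.integer(crop_size)
  if (is.null(stride)) stride <- pmax(crop_size - 16L, 1L)
  stride <- as.integer(stride)
  if (any(stride <= 0L))
    stop_ioucseg("ioucseg_parameter", "stride must be positive")
  pad_before <- pad_after <- integer(3)
  padded <- shape
  for (ax in 1:3) {
    if (shape[ax] < crop_size[ax]) {
      tot <- crop_size[ax] - shape[ax]
      pad_before[ax] <- tot %/% 2L
      pad_after[ax] <- tot - pad_before[ax]
      padded[ax] <- crop_size[ax]
    }
  }
  offs <- lapply(1:3, function(ax) {
    last <- padded[ax] - crop_size[ax]
    o <- seq.int(0L, last, by = stride[ax])
    if (o[length(o)] != last) o <- c(o, last)
    as.integer(o)
  })
  grid <- as.matrix(expand.grid(d = offs[[1]], h = offs[[2]], w = offs[[3]]))
  structure(list(shape = shape, padded = padded, crop_size = crop_size,
                 pad_before = pad_before, pad_after = pad_after,
                 offsets = grid),
            class = "crop_plan")
}

# zero-pad a (D,H,W,[C]) array according to a crop plan
pad_to_plan <- function(x, plan) {
  d <- dim(x); nd <- length(d)
  out_dim <- d; out_dim[1:3] <- plan$padded
  if (all(out_dim == d)) return(x)
  out <- array(0, out_dim)
  ix <- lapply(1:3, function(ax) plan$pad_before[ax] + seq_len(d[ax]))
  if (nd == 3L) out[ix[[1]], ix[[2]], ix[[3]]] <- x
  else out[ix[[1]], ix[[2]], ix[[3]], ] <- x
  out
}

#' Extract the crops of a plan from an array
#'
#' @param x 3D or 4D (channel-last) array.
#' @param plan a `crop_plan` from [plan_crops()].
#' @return list of cropped arrays, in offset order.
#' @export
extract_crops <- function(x, plan) {
  x <- pad_to_plan(x, plan)
  nd <- length(dim(x))
  cs <- plan$crop_size
  lapply(seq_len(nrow(plan$offsets)), function(i) {
    o <- plan$offsets[i, ]
    if (nd == 3L)
      x[o[1] + seq_len(cs[1]), o[2] + seq_len(cs[2]), o[3] + seq_len(cs[3]),
        drop = FALSE]
    else
      x[o[1] + seq_len(cs[1]), o[2] + seq_len(cs[2]), o[3] + seq_len(cs[3]), ,
      drop = FALSE]
  })
}

#' Stitch cropped probability maps back together
#'
#' Inverse of cropping at inference time: each voxel of the output is the
#' arithmetic mean of all crop predictions covering it; the padding
#' introduced by the plan is removed and the per-voxel simplex property is
#' preserved (a mean of simplex points is on the simplex).
#'
#' @param crops list of 4D (d, h, w, C) probability arrays conforming to the
#'   plan.
#' @param plan the `crop_plan` the crops were taken with.
#' @return 4D probability array over the original (unpadded) shape.
#' @export
stitch_probability <- function(crops, plan) {
  if (length(crops) != nrow(plan$offsets))
    stop_ioucseg("ioucseg_composition",
                 "plan has %d crops but %d maps were given",
                 nrow(plan$offsets), length(crops))
  C <- dim(crops[[1]])[4]
  acc <- array(0, c(plan$padded, C))
  cnt <- array(0, plan$padded)
  cs <- plan$crop_size
  for (i in seq_along(crops)) {
    o <- plan$offsets[i, ]
    id <- o[1] + seq_len(cs[1]); ih <- o[2] + seq_len(cs[2])
    iw <- o[3] + seq_len(cs[3])
    acc[id, ih, iw, ] <- acc[id, ih, iw, , drop = FALSE] + crops[[i]]
    cnt[id, ih, iw] <- cnt[id, ih, iw] + 1
  }
  for (c in seq_len(C)) acc[, , , c] <- acc[, , , c] / cnt
  ix <- lapply(1:3, function(ax) plan$pad_before[ax] + seq_len(plan$shape[ax]))
  acc[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
}

#' External bias-field correction hook
#'
#' Intensity inhomogeneity correction (e.g. N4) is an established external
#' algorithm; this package only provides the plumbing to call one. `hook`
#' may be an R function `volume -> volume`, or a shell command template
#' containing `{in}` and `{out}` placeholders that is run on a temporary
#' NIfTI pair. With `hook = NULL` (the default, `off`) the volume passes
#' through unchanged.
#'
#' @param vol a [volume].
#' @param hook `NULL`, a function, or a command template string.
#' @return the corrected [volume].
#' @export
bias_correction_hook <- function(vol, hook = NULL) {
  if (is.null(hook)) return(vol)
  if (is.function(hook)) return(hook(vol))
  tin <- tempfile(fileext = ".nii.gz"); tout <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  write_nifti(vol, tin)
  cmd <- gsub("{out}", tout, gsub("{in}", tin, hook, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd)
  if (status != 0 || !file.exists(tout))
    stop_ioucseg("ioucseg_io", "bias-correction hook failed: %s", cmd)
  read_nifti(tout, "intensity", modality = vol$modality)
}
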