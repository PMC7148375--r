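#' Voxel-grid containers
#'
#' Lightweight S3 containers shared by the whole pipeline. A `volume` holds
#' one modality's real-valued 3D grid with voxel spacing in millimetres; a
#' `labelmap` holds an integer grid over the tissue labels 0--4 (healthy,
#' necrotic, edema, non-enhancing, enhancing); a `probmap` holds per-class
#' probabilities as a 4D grid (depth, height, width, class) that must lie on
#' the probability simplex at every voxel; an `mmstack` bundles the four
#' co-registered modalities (flair, t1, t1gd, t2) of one subject.
#'
#' Grids are indexed (depth, height, width); the class axis of a `probmap`
#' comes last, matching both R's column-major arrays and the 4D NIfTI layout
#' used for serialization.
#'
#' @param data numeric 3D array (`volume`), integer-valued 3D array
#'   (`labelmap`), or numeric 4D array (`probmap`).
#' @param spacing positive numeric length-3 voxel spacing in mm.
#' @param modality one of `"flair"`, `"t1"`, `"t1gd"`, `"t2"`, `"derived"`.
#' @param class_order integer vector giving the label value of each class
#'   channel (default `0:4`).
#' @return An object of the corresponding class.
#' @name voxel-containers
NULL

#' @rdname voxel-containers
#' @export
volume <- function(data, spacing = c(1, 1, 1), modality = "derived") {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop_ioucseg("ioucseg_validation", "volume data must be a 3D array")
  if (anyNA(data) || any(!is.finite(data)))
    stop_ioucseg("ioucseg_validation", "volume contains NaN/Inf values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_ioucseg("ioucseg_validation", "spacing must be 3 positive numbers")
  modality <- match.arg(modality, c(MODALITIES, "derived"))
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "volume")
}

#' @rdname voxel-containers
#' @export
labelmap <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop_ioucseg("ioucseg_validation", "labelmap data must be a 3D array")
  vals <- unique(as.vector(data))
  bad <- vals[!(vals %in% LABEL_VALUES) | vals != round(vals)]
  if (length(bad))
    stop_ioucseg("ioucseg_validation",
                 "labelmap contains values outside {0..4}: {%s}",
                 paste(sort(bad), collapse = ", "))
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "labelmap")
}

#' @rdname voxel-containers
#' @export
probmap <- function(data, spacing = c(1, 1, 1), class_order = 0:4) {
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop_ioucseg("ioucseg_validation", "probmap data must be a 4D array")
  if (dim(data)[4] != length(class_order))
    stop_ioucseg("ioucseg_validation",
                 "probmap has %d channels but class_order names %d",
                 dim(data)[4], length(class_order))
  if (any(data < -1e-7) || any(data > 1 + 1e-7))
    stop_ioucseg("ioucseg_validation", "probabilities outside [0, 1]")
  sums <- rowSums(matrix(data, ncol = dim(data)[4]))
  if (max(abs(sums - 1)) > 1e-5)
    stop_ioucseg("ioucseg_validation",
                 "per-voxel class probabilities do not sum to 1 (max dev %.2e)",
                 max(abs(sums - 1)))
  structure(list(data = data, spacing = as.numeric(spacing),
                 class_order = as.integer(class_order)),
            class = "probmap")
}

#' @rdname voxel-containers
#' @param vols list of exactly four `volume` objects, one per modality, in
#'   any order.
#' @param subject_id opaque subject identifier.
#' @export
stack_modalities <- function(vols, subject_id = "subject") {
  if (length(vols) != 4L)
    stop_ioucseg("ioucseg_composition", "expected 4 modality volumes, got %d",
                 length(vols))
  mods <- vapply(vols, function(v) v$modality, "")
  if (anyDuplicated(mods))
    stop_ioucseg("ioucseg_composition", "duplicate modality: %s",
                 mods[duplicated(mods)][1])
  if (!setequal(mods, MODALITIES))
    stop_ioucseg("ioucseg_composition", "missing modality: %s",
                 paste(setdiff(MODALITIES, mods), collapse = ", "))
  vols <- vols[match(MODALITIES, mods)]
  shp <- dim(vols[[1]]$data)
  spc <- vols[[1]]$spacing
  for (v in vols[-1]) {
    if (!identical(dim(v$data), shp))
      stop_ioucseg("ioucseg_alignment", "channel shapes differ: %s vs %s",
                   paste(shp, collapse = "x"),
                   paste(dim(v$data), collapse = "x"))
    if (max(abs(v$spacing - spc)) > 1e-6)
      stop_ioucseg("ioucseg_alignment", "channel spacings differ")
  }
  names(vols) <- MODALITIES
  structure(list(channels = vols, subject_id = subject_id), class = "mmstack")
}

#' Convert a multimodal stack to a 4D input array
#'
#' Channels are stacked in the canonical (flair, t1, t1gd, t2) order along
#' the 4th dimension.
#' @param stack an `mmstack`.
#' @return numeric array (D, H, W, 4).
#' @export
stack_array <- function(stack) {
  arrs <- lapply(stack$channels, function(v) v$data)
  shp <- dim(arrs[[1]])
  out <- array(0, c(shp, length(arrs)))
  for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
  out
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file as either an intensity volume, an integer label map
#' (values verified to be whole numbers in 0--4), or a 4D probability map.
#' Voxel spacing is taken from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param expected_kind `"intensity"`, `"label"` or `"probability"`.
#' @param modality modality tag attached to an intensity volume.
#' @return a [volume], [labelmap] or [probmap].
#' @export
read_nifti <- function(path, expected_kind = c("intensity", "label",
                                               "probability"),
                       modality = "derived") {
  expected_kind <- match.arg(expected_kind)
  if (!file.exists(path))
    stop_ioucseg("ioucseg_io", "file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_ioucseg("ioucseg_io", "cannot read NIfTI %s: %s",
                                 path, conditionMessage(e)))
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))     # drop NIfTI header attributes
  spc <- RNifti::pixdim(img)[seq_len(min(3L, length(RNifti::pixdim(img))))]
  if (length(spc) < 3L) spc <- c(spc, rep(1, 3L - length(spc)))
  switch(expected_kind,
    intensity = volume(arr, spacing = spc, modality = modality),
    label = {
      if (any(arr != round(arr)))
        stop_ioucseg("ioucseg_validation",
                     "label file %s contains non-integer values", path)
      labelmap(arr, spacing = spc)
    },
    probability = probmap(arr, spacing = spc,
                          class_order = seq_len(dim(arr)[4]) - 1L))
}

#' Write a volume, label map or probability map as NIfTI
#'
#' Label maps are stored as unsigned 8-bit integers; probability maps as 4D
#' volumes with class as the 4th dimension. Round-trips through
#' [read_nifti()] preserve integer grids exactly and real grids and spacing
#' to within 1e-6.
#'
#' @param vol a [volume], [labelmap] or [probmap].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_nifti <- function(vol, path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_ioucseg("ioucseg_io", "directory does not exist: %s", dir)
  dt <- if (inherits(vol, "labelmap")) "uint8" else "float64"
  img <- RNifti::asNifti(vol$data)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- vol$spacing
  RNifti::pixdim(img) <- pd
  tryCatch(RNifti::writeNifti(img, path, datatype = dt),
           error = function(e)
             stop_ioucseg("ioucseg_io", "cannot write %s: %s", path,
                          conditionMessage(e)))
  invisible(path)
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s  %s voxels  spacing %s mm  range [%.3g, %.3g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.labelmap <- function(x, ...) {
  tb <- table(factor(as.vector(x$data), levels = LABEL_VALUES))
  cat(sprintf("<labelmap> %s voxels  labels: %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(sprintf("%s:%d", names(tb), tb), collapse = " ")))
  invisible(x)
}

#' @export
print.mmstack <- function(x, ...) {
  cat(sprintf("<mmstack> subject %s  %s voxels  channels: %s\n",
              x$subject_id, paste(dim(x$channels[[1]]$data), collapse = "x"),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
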