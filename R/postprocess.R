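#' Label connected components of a binary mask
#'
#' Breadth-first connected-component labeling under 6-, 18- or
#' 26-neighborhood adjacency. Component ids are contiguous from 1.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return `list(labels = integer array, sizes = voxel count per component)`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_ioucseg("ioucseg_parameter", "connectivity must be 6, 18 or 26")
  mask <- as_mask(mask)
  lab <- cpp_label_components(mask, as.integer(connectivity))
  n <- max(lab)
  list(labels = lab,
       sizes = if (n > 0) tabulate(lab[lab > 0], n) else integer(0))
}

#' Remove small spurious tumor components
#'
#' Treats all tumor labels (1--4) as one foreground, labels its connected
#' components, and deletes (sets to 0) every component whose voxel count is
#' below `ratio` times the largest component's size -- the adaptive
#' threshold rule, one tenth of the maximum connected volume by default.
#' Surviving voxels keep their original class labels. The filter only
#' deletes, never adds, and is idempotent; the largest component always
#' survives; an empty prediction passes through unchanged.
#'
#' @param pred predicted [labelmap] (or integer array).
#' @param connectivity component adjacency: 6, 18 or 26 (default 26).
#' @param ratio adaptive threshold fraction in (0, 1\] (default 0.1).
#' @return filtered prediction, same type as the input.
#' @export
filter_small_components <- function(pred, connectivity = 26L, ratio = 0.1) {
  if (ratio <= 0 || ratio > 1)
    stop_ioucseg("ioucseg_parameter", "ratio must be in (0, 1]")
  is_lm <- inherits(pred, "labelmap")
  x <- if (is_lm) pred$data else pred
  fg <- x > 0
  if (!any(fg)) return(pred)
  cc <- label_components(fg, connectivity)
  thr <- ratio * max(cc$sizes)
  drop_ids <- which(cc$sizes < thr)
  if (length(drop_ids)) x[cc$labels %in% drop_ids] <- 0L
  if (is_lm) labelmap(x, pred$spacing) else x
}
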