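#' Integral volume (3D summed-area table)
#'
#' Entry (i, j, k) holds the sum of the source over the box
#' `[1..i] x [1..j] x [1..k]`, so any axis-aligned box sum is recoverable
#' from 8 lookups by inclusion-exclusion (see [box_sum()]).
#'
#' @param vol [volume] or 3D array.
#' @return 3D array of cumulative sums.
#' @export
integral_volume <- function(vol) {
  x <- if (inherits(vol, "volume")) vol$data else vol
  csum_axis <- function(a, ax) {          # dimension-preserving cumsum
    d <- dim(a)
    if (d[ax] == 1L) return(a)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    m <- matrix(ap, d[ax])
    m <- apply(m, 2, cumsum)
    aperm(array(m, dim(ap)), order(perm))
  }
  csum_axis(csum_axis(csum_axis(x, 1L), 2L), 3L)
}

# integral volume padded with a zero slab in front of each axis, so that
# lookups at index 0 are valid
pad_iv <- function(iv) {
  d <- dim(iv)
  out <- array(0, d + 1L)
  out[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- iv
  out
}

#' Box sum from an integral volume
#'
#' Sum of the source over the inclusive 1-based box `lo..hi`, from 8 lookups.
#'
#' @param iv integral volume from [integral_volume()].
#' @param lo,hi integer length-3 inclusive corners.
#' @return scalar sum.
#' @export
box_sum <- function(iv, lo, hi) {
  ivp <- pad_iv(iv)
  l <- as.integer(lo)          # lo - 1, in padded (1-based) coordinates
  h <- as.integer(hi) + 1L     # hi, in padded coordinates
  ivp[h[1], h[2], h[3]] - ivp[l[1], h[2], h[3]] - ivp[h[1], l[2], h[3]] -
    ivp[h[1], h[2], l[3]] + ivp[l[1], l[2], h[3]] + ivp[l[1], h[2], l[3]] +
    ivp[h[1], l[2], l[3]] - ivp[l[1], l[2], l[3]]
}

#' Canonical 3D Haar-like template catalogue
#'
#' Eight cuboid-block templates extending the classic 2D family to 3D:
#' three two-block edge templates (one per axis), three three-block line
#' templates (middle third black), one center-surround, and one eight-octant
#' checkerboard. Blocks are stored in unit-window coordinates and tile the
#' window without overlap; the feature value of a template is the difference
#' between the summed intensities of its white (+1) and black (-1) blocks.
#' Templates whose white and black blocks cover equal volume are flagged
#' `balanced` (their response on any constant volume is exactly 0).
#'
#' @param window integer length-3 window size in voxels (default `c(8,8,8)`).
#' @return named list of `haar_template` objects with materialized voxel
#'   blocks.
#' @export
haar_templates <- function(window = c(8, 8, 8)) {
  window <- as.integer(window)
  blk <- function(lo, hi, sign) list(lo = lo, hi = hi, sign = sign)
  unit <- list()
  halves <- function(ax) {
    b1 <- rep(0, 3); e1 <- rep(1, 3); b2 <- rep(0, 3); e2 <- rep(1, 3)
    e1[ax] <- 0.5; b2[ax] <- 0.5
    list(blk(b1, e1, +1), blk(b2, e2, -1))
  }
  thirds <- function(ax) {
    mk <- function(a, b, s) {
      lo <- rep(0, 3); hi <- rep(1, 3); lo[ax] <- a; hi[ax] <- b
      blk(lo, hi, s)
    }
    list(mk(0, 1/3, +1), mk(1/3, 2/3, -1), mk(2/3, 1, +1))
  }
  unit$edge_x <- halves(1); unit$edge_y <- halves(2); unit$edge_z <- halves(3)
  unit$line_x <- thirds(1); unit$line_y <- thirds(2); unit$line_z <- thirds(3)
  # center-surround: inner half-extent box black, the 26 surrounding cuboids
  # white (tiled by splitting each axis at 1/4 and 3/4)
  cs <- list()
  cuts <- c(0, 0.25, 0.75, 1)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    lo <- c(cuts[i], cuts[j], cuts[k]); hi <- c(cuts[i + 1], cuts[j + 1],
                                                cuts[k + 1])
    cs[[length(cs) + 1]] <- blk(lo, hi, if (i == 2 && j == 2 && k == 2) -1
                                        else +1)
  }
  unit$center_surround <- cs
  dg <- list()
  for (i in 0:1) for (j in 0:1) for (k in 0:1)
    dg[[length(dg) + 1]] <- blk(c(i, j, k) / 2, c(i + 1, j + 1, k + 1) / 2,
                                if ((i + j + k) %% 2 == 0) +1 else -1)
  unit$diagonal <- dg

  materialize <- function(name, blocks) {
    vb <- lapply(blocks, function(b) {
      lo <- round(b$lo * window) + 1L
      hi <- round(b$hi * window)
      list(lo = as.integer(lo), hi = as.integer(hi), sign = b$sign)
    })
    vb <- Filter(function(b) all(b$hi >= b$lo), vb)
    vols <- vapply(vb, function(b) prod(b$hi - b$lo + 1L) * b$sign, 0)
    structure(list(name = name, blocks = vb, window = window,
                   balanced = sum(vols) == 0),
              class = "haar_template")
  }
  out <- lapply(names(unit), function(nm) materialize(nm, unit[[nm]]))
  names(out) <- names(unit)
  out
}

#' Haar-like feature response at one window placement
#'
#' Sum of white-block sums minus black-block sums for a template window whose
#' low corner sits at `anchor` (1-based), each block sum taken from the
#' integral volume in 8 lookups.
#'
#' @param iv integral volume.
#' @param template a `haar_template` from [haar_templates()].
#' @param anchor integer length-3 window corner (1-based).
#' @return scalar response.
#' @export
haar_response <- function(iv, template, anchor) {
  anchor <- as.integer(anchor)
  d <- dim(iv)
  if (any(anchor < 1L) || any(anchor + template$window - 1L > d))
    stop_ioucseg("ioucseg_bounds", "window at (%s) exceeds volume (%s)",
                 paste(anchor, collapse = ","), paste(d, collapse = "x"))
  ivp <- pad_iv(iv)
  acc <- 0
  for (b in template$blocks) {
    l <- anchor + b$lo - 1L          # padded-iv index of lo-1
    h <- anchor + b$hi - 1L + 1L     # padded-iv index of hi
    s <- ivp[h[1], h[2], h[3]] - ivp[l[1], h[2], h[3]] -
      ivp[h[1], l[2], h[3]] - ivp[h[1], h[2], l[3]] +
      ivp[l[1], l[2], h[3]] + ivp[l[1], h[2], l[3]] +
      ivp[h[1], l[2], l[3]] - ivp[l[1], l[2], l[3]]
    acc <- acc + b$sign * s
  }
  acc
}

# dense responses over all valid anchors, vectorized via shifted slices of
# the padded integral volume
dense_responses <- function(ivp, template, vd) {
  win <- template$window
  n <- vd - win + 1L
  out <- array(0, n)
  ix <- function(off) list(off[1] + seq_len(n[1]), off[2] + seq_len(n[2]),
                           off[3] + seq_len(n[3]))
  for (b in template$blocks) {
    l <- b$lo - 1L        # 0-based offsets into padded iv for anchor 1
    h <- b$hi
    t1 <- ix(h); t2 <- ix(c(l[1], h[2], h[3])); t3 <- ix(c(h[1], l[2], h[3]))
    t4 <- ix(c(h[1], h[2], l[3])); t5 <- ix(c(l[1], l[2], h[3]))
    t6 <- ix(c(l[1], h[2], l[3])); t7 <- ix(c(h[1], l[2], l[3])); t8 <- ix(l)
    s <- ivp[t1[[1]], t1[[2]], t1[[3]]] - ivp[t2[[1]], t2[[2]], t2[[3]]] -
      ivp[t3[[1]], t3[[2]], t3[[3]]] - ivp[t4[[1]], t4[[2]], t4[[3]]] +
      ivp[t5[[1]], t5[[2]], t5[[3]]] + ivp[t6[[1]], t6[[2]], t6[[3]]] +
      ivp[t7[[1]], t7[[2]], t7[[3]]] - ivp[t8[[1]], t8[[2]], t8[[3]]]
    out <- out + b$sign * s
  }
  out
}

#' Dense Haar-like feature channels
#'
#' Computes one feature channel per template: the response of the template
#' window centered at each voxel, zero-filled where the window would
#' overflow the volume. With `stride > 1` responses are evaluated on a
#' strided anchor grid and brought back to input resolution by trilinear
#' interpolation.
#'
#' @param vol [volume] or 3D array.
#' @param templates list from [haar_templates()].
#' @param stride integer sampling stride (default 1, fully dense).
#' @return 4D array (D, H, W, n_templates).
#' @export
haar_feature_channels <- function(vol, templates = haar_templates(),
                                  stride = 1L) {
  x <- if (inherits(vol, "volume")) vol$data else vol
  vd <- dim(x)
  win <- templates[[1]]$window
  if (any(win > vd))
    stop_ioucseg("ioucseg_parameter",
                 "window (%s) larger than volume (%s)",
                 paste(win, collapse = "x"), paste(vd, collapse = "x"))
  ivp <- pad_iv(integral_volume(x))
  out <- array(0, c(vd, length(templates)))
  ctr <- win %/% 2L            # anchor = center - ctr
  for (ti in seq_along(templates)) {
    dense <- dense_responses(ivp, templates[[ti]], vd)
    nd <- dim(dense)
    if (stride > 1L) {
      sub <- dense[seq(1, nd[1], by = stride), seq(1, nd[2], by = stride),
                   seq(1, nd[3], by = stride), drop = FALSE]
      dense <- trilinear_upsample(sub, nd)
    }
    # place anchor-grid responses at the window-center voxel
    out[ctr[1] + seq_len(nd[1]), ctr[2] + seq_len(nd[2]),
        ctr[3] + seq_len(nd[3]), ti] <- dense
  }
  out
}

#' Serialize a Haar template catalogue as JSON
#'
#' Writes the materialized blocks (name, per-block corners and signs,
#' window, balance flag) so a catalogue can be stored alongside a model
#' checkpoint and reloaded exactly.
#'
#' @param templates list from [haar_templates()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_haar_templates <- function(templates, path) {
  payload <- lapply(templates, function(t)
    list(name = t$name, window = t$window, balanced = t$balanced,
         blocks = lapply(t$blocks, function(b)
           list(lo = b$lo, hi = b$hi, sign = b$sign))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Haar template catalogue from JSON
#' @param path JSON file written by [write_haar_templates()].
#' @return named list of `haar_template` objects.
#' @export
read_haar_templates <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(payload, function(t)
    structure(list(name = t$name, window = as.integer(unlist(t$window)),
                   balanced = isTRUE(t$balanced),
                   blocks = lapply(t$blocks, function(b)
                     list(lo = as.integer(unlist(b$lo)),
                          hi = as.integer(unlist(b$hi)),
                          sign = b$sign))),
              class = "haar_template"))
  names(out) <- vapply(out, function(t) t$name, "")
  out
}
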