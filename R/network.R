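#' Network configuration
#'
#' Describes a buildable instance of the symmetric 3D fully convolutional
#' segmentation network: a coarse block layer (two 3^3 convolutions), five
#' 2x2x2 max-pooling stages interleaved with four bottlenecked 3D residual
#' groups, a two-convolution bottleneck with dropout, and a decoder
#' (refinement block layer) that restores resolution by separable trilinear
#' upsampling with adapter-layer (1^3 convolution + pixel-wise addition)
#' fusion of the matching encoder features. Channel widths double at each
#' level starting from `base_filters` (paper scale 32; desk scale 4), so the
#' same topology spans CPU-friendly and full-size instances.
#'
#' @param in_channels input channels (4 modalities by default).
#' @param n_classes output classes (5 tissue labels by default).
#' @param base_filters channels of the first convolution; widths double per
#'   level.
#' @param depth number of pooling stages; fixed at 5 (the five-layer
#'   cohesion architecture).
#' @param blocks_per_group residual blocks per group (default 3).
#' @param bottleneck_ratio channel reduction m -> m/ratio inside each
#'   residual block (default 2).
#' @param dropout dropout probability applied after the two deepest encoder
#'   convolution stacks during training (default 0.5).
#' @param normalization `"none"` (default, the architecture as published
#'   carries no normalization layers) or `"instance"`, which inserts
#'   per-channel instance normalization between every hidden convolution
#'   and its activation in the style of the wider 3D U-Net family.
#'   Normalized features train more placidly but need far more optimizer
#'   steps at the published learning rate, so the raw architecture is the
#'   default at desk scale.
#' @return an object of class `sfcnn_config`.
#' @export
sfcnn_config <- function(in_channels = 4L, n_classes = 5L, base_filters = 4L,
                         depth = 5L, blocks_per_group = 3L,
                         bottleneck_ratio = 2L, dropout = 0.5,
                         normalization = c("none", "instance")) {
  normalization <- match.arg(normalization)
  if (depth != 5L)
    stop_ioucseg("ioucseg_parameter",
                 "depth is fixed at 5 (five pooling stages); got %d", depth)
  if (base_filters < 1L)
    stop_ioucseg("ioucseg_parameter", "base_filters must be >= 1")
  if (dropout < 0 || dropout >= 1)
    stop_ioucseg("ioucseg_parameter", "dropout must be in [0, 1)")
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 base_filters = as.integer(base_filters), depth = 5L,
                 blocks_per_group = as.integer(blocks_per_group),
                 bottleneck_ratio = as.integer(bottleneck_ratio),
                 dropout = dropout, normalization = normalization),
            class = "sfcnn_config")
}

# Enumerate every convolution layer (name, kernel size, channels in/out).
sfcnn_layers <- function(cfg) {
  f <- cfg$base_filters
  L <- list()
  add <- function(name, k, cin, cout)
    L[[name]] <<- list(name = name, k = k, cin = cin, cout = cout)
  add("c0a", 3L, cfg$in_channels, f)
  add("c0b", 3L, f, 2L * f)
  for (g in 1:4) {
    m <- 2L * f * 2L^(g - 1L)
    n <- max(1L, m %/% cfg$bottleneck_ratio)
    for (b in seq_len(cfg$blocks_per_group)) {
      add(sprintf("g%d.b%d.c1", g, b), 1L, m, n)
      add(sprintf("g%d.b%d.c2", g, b), 3L, n, n)
      add(sprintf("g%d.b%d.c3", g, b), 1L, n, m)
    }
    add(sprintf("t%d", g), 3L, m, 2L * m)
  }
  bc <- 32L * f
  add("b1", 3L, bc, bc)
  add("b2", 3L, bc, bc)
  up_ch <- c(32L, 16L, 8L, 4L, 2L) * f          # channels arriving at level 5..1
  for (i in 1:5) {
    l <- 6L - i
    add(sprintf("a%d", l), 1L, up_ch[i], up_ch[i])
    add(sprintf("r%d", l), 3L, up_ch[i], up_ch[i] %/% 2L)
  }
  add("head", 1L, f, cfg$n_classes)
  L
}

#' Initialize network weights
#'
#' Variance-scaling (He) initialization: each kernel entry is drawn from
#' N(0, 2 / fan_in); biases start at zero. Deterministic given `seed`.
#'
#' @param cfg an [sfcnn_config()].
#' @param seed integer RNG seed.
#' @return named list of weight arrays (`<layer>.w`, `<layer>.b`).
#' @export
sfcnn_init <- function(cfg, seed = 1L) {
  set.seed(seed)
  W <- list()
  for (ly in sfcnn_layers(cfg)) {
    n <- ly$k^3 * ly$cin
    sd <- if (grepl("\\.c3$", ly$name)) 0        # identity-start residuals
    else if (ly$name == "head") 0.01             # gentle scores at start
    else sqrt(2 / n)
    W[[paste0(ly$name, ".w")]] <-
      array(rnorm(n * ly$cout, 0, sd), c(ly$k, ly$k, ly$k, ly$cin, ly$cout))
    W[[paste0(ly$name, ".b")]] <- numeric(ly$cout)
  }
  W
}

#' Count trainable parameters
#' @param cfg an [sfcnn_config()].
#' @return integer parameter count.
#' @export
sfcnn_n_params <- function(cfg) {
  sum(vapply(sfcnn_layers(cfg),
             function(ly) ly$k^3 * ly$cin * ly$cout + ly$cout, 0))
}

## ---- reference primitives (exported, oracle-friendly) ----------------------

#' Reference 3D convolution (triple-sum form)
#'
#' Direct evaluation of the 3D convolution as the triple sum
#' `Y(m,n,l) = sum_i sum_j sum_k M(m+i, n+j, l+k) F(i,j,k)` (cross-correlation
#' form, no kernel flip), with zero padding so the output has the input's
#' spatial size. This plain-R path is the oracle the fast production
#' convolution is tested against.
#'
#' @param input 3D numeric array.
#' @param kernel 3D numeric array with odd dimensions.
#' @return 3D array of the input's shape.
#' @export
conv3d_reference <- function(input, kernel) {
  kd <- dim(kernel)
  if (any(kd %% 2 == 0))
    stop_ioucseg("ioucseg_parameter", "kernel dimensions must be odd")
  p <- (kd - 1L) %/% 2L
  d <- dim(input)
  padded <- array(0, d + 2L * p)
  padded[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3])] <-
    input
  out <- array(0, d)
  for (m in seq_len(d[1])) for (n in seq_len(d[2])) for (l in seq_len(d[3])) {
    acc <- 0
    for (i in seq_len(kd[1])) for (j in seq_len(kd[2])) for (k in seq_len(kd[3]))
      acc <- acc + padded[m + i - 1L, n + j - 1L, l + k - 1L] * kernel[i, j, k]
    out[m, n, l] <- acc
  }
  out
}

#' Fast 3D convolution (production path)
#'
#' Same-padded multi-channel 3D convolution via im2col + BLAS matrix
#' multiplication. Restricted to a single channel it agrees with
#' [conv3d_reference()].
#'
#' @param x 4D array (D, H, W, Cin) or 3D array (treated as one channel).
#' @param w 5D kernel array (k, k, k, Cin, Cout) or 3D kernel.
#' @param b bias vector of length Cout (default zeros).
#' @return 4D array (D, H, W, Cout), or 3D if both inputs were 3D.
#' @export
conv3d <- function(x, w, b = NULL) {
  drop3 <- FALSE
  if (length(dim(x)) == 3L) { dim(x) <- c(dim(x), 1L); drop3 <- TRUE }
  if (length(dim(w)) == 3L) dim(w) <- c(dim(w), 1L, 1L)
  if (dim(w)[1] %% 2 == 0)
    stop_ioucseg("ioucseg_parameter", "kernel dimensions must be odd")
  if (is.null(b)) b <- numeric(dim(w)[5])
  y <- cpp_conv3d(x, w, b)
  if (drop3 && dim(y)[4] == 1L) { d <- dim(y)[1:3]; dim(y) <- d }
  y
}

#' Rectified linear activation, f(x) = max(0, x)
#' @param x numeric array.
#' @return array of the same shape.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' 2x2x2 max pooling
#'
#' Each output voxel is the maximum over its 2x2x2 block; spatial dimensions
#' halve, channels are unchanged. Odd spatial dimensions are an error (the
#' caller must pad).
#'
#' @param x 3D or 4D (channel-last) array with even spatial dims.
#' @return pooled array.
#' @export
maxpool3d <- function(x) {
  drop3 <- length(dim(x)) == 3L
  if (drop3) dim(x) <- c(dim(x), 1L)
  if (any(dim(x)[1:3] %% 2L != 0L))
    stop_ioucseg("ioucseg_shape",
                 "spatial dims (%s) must be even for 2x2x2 pooling",
                 paste(dim(x)[1:3], collapse = ","))
  y <- cpp_maxpool3d(x)$y
  if (drop3) dim(y) <- dim(y)[1:3]
  y
}

#' Separable trilinear upsampling
#'
#' Corner-aligned linear interpolation along each axis in turn; restricted
#' to one slice it reproduces the bilinear matrix form
#' `F(Sx,Sy) = [1-Sx, Sx] %*% F %*% c(1-Sy, Sy)` exactly, and grid points
#' aligned with input voxels keep their values.
#'
#' @param x 3D or 4D (channel-last) array.
#' @param target_shape integer length-3 target spatial shape, >= the input
#'   shape per axis.
#' @return upsampled array.
#' @export
trilinear_upsample <- function(x, target_shape) {
  drop3 <- length(dim(x)) == 3L
  if (drop3) dim(x) <- c(dim(x), 1L)
  target_shape <- as.integer(target_shape)
  if (any(target_shape < dim(x)[1:3]))
    stop_ioucseg("ioucseg_parameter",
                 "target shape must be >= input shape per axis")
  y <- cpp_upsample3d(x, target_shape[1], target_shape[2], target_shape[3])
  if (drop3) dim(y) <- dim(y)[1:3]
  y
}

#' Bottlenecked 3D residual block
#'
#' Computes `relu(F(x) + x)` where F is the 1^3 -> 3^3 -> 1^3 convolution
#' stack reducing m channels to n and restoring them to m, with ReLU after
#' the first two convolutions. Spatial shape is preserved.
#'
#' @param x 4D (D, H, W, m) array.
#' @param weights list with elements `c1`, `c2`, `c3`, each a `list(w =, b =)`
#'   kernel/bias pair.
#' @return 4D array of the input's shape.
#' @export
residual_block <- function(x, weights) {
  h <- relu(conv3d(x, weights$c1$w, weights$c1$b))
  h <- relu(conv3d(h, weights$c2$w, weights$c2$b))
  h <- conv3d(h, weights$c3$w, weights$c3$b)
  if (!identical(dim(h), dim(x)))
    stop_ioucseg("ioucseg_shape",
                 "residual branch shape %s does not match skip %s",
                 paste(dim(h), collapse = "x"), paste(dim(x), collapse = "x"))
  relu(h + x)
}

#' Adapter-layer feature fusion
#'
#' Brings a low-resolution feature map to the target map's grid by trilinear
#' upsampling, optionally matches channels through a 1^3 adapter convolution
#' applied to `high`, and adds the two maps pixel-wise.
#'
#' @param low feature map to upsample (4D array).
#' @param high feature map at the target resolution (4D array).
#' @param adapter optional `list(w =, b =)` 1^3 convolution applied to `high`
#'   before the addition, to reconcile channel counts.
#' @return fused 4D array at `high`'s spatial shape.
#' @export
abl_fuse <- function(low, high, adapter = NULL) {
  low <- trilinear_upsample(low, dim(high)[1:3])
  if (!is.null(adapter)) high <- conv3d(high, adapter$w, adapter$b)
  if (dim(low)[4] != dim(high)[4])
    stop_ioucseg("ioucseg_configuration",
                 "channel counts %d and %d differ and no adapter was given",
                 dim(low)[4], dim(high)[4])
  low + high
}

softmax_channels <- function(z) {
  d <- dim(z); V <- prod(d[1:3]); C <- d[4]
  m <- matrix(z, V, C)
  m <- m - m[cbind(seq_len(V), max.col(m, ties.method = "first"))]
  e <- exp(m)
  p <- e / rowSums(e)
  array(p, d)
}

## ---- computation graph (reverse-mode) --------------------------------------

new_graph <- function(weights) {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$W <- weights
  g
}

nd <- function(g, op, parents, val, extra = NULL) {
  force(parents)        # parents must register their nodes before this one
  force(val)
  force(extra)
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- list(op = op, parents = parents, val = val, extra = extra)
  id
}

g_input <- function(g, x) nd(g, "input", integer(0), x)
g_conv <- function(g, x, name) {
  force(x)
  v <- g$nodes[[x]]$val
  if (isTRUE(g$train)) {
    r <- cpp_conv3d_cached(v, g$W[[paste0(name, ".w")]],
                           g$W[[paste0(name, ".b")]])
    nd(g, "conv", x, r$y, list(name = name, col = r$col, xdim = dim(v)))
  } else {
    y <- cpp_conv3d(v, g$W[[paste0(name, ".w")]], g$W[[paste0(name, ".b")]])
    nd(g, "conv", x, y, list(name = name))
  }
}
g_relu <- function(g, x) {
  force(x)
  nd(g, "relu", x, relu(g$nodes[[x]]$val))
}
g_pool <- function(g, x) {
  force(x)
  r <- cpp_maxpool3d(g$nodes[[x]]$val)
  nd(g, "pool", x, r$y, list(idx = r$idx, xdim = dim(g$nodes[[x]]$val)))
}
g_up <- function(g, x, tgt) {
  force(x)
  nd(g, "up", x,
     cpp_upsample3d(g$nodes[[x]]$val, tgt[1], tgt[2], tgt[3]),
     list(xdim = dim(g$nodes[[x]]$val)))
}
g_add <- function(g, a, b) {
  force(a); force(b)
  nd(g, "add", c(a, b), g$nodes[[a]]$val + g$nodes[[b]]$val)
}
# per-channel instance normalization over the spatial dims (no affine);
# degenerate single-voxel grids pass through unchanged
g_inorm <- function(g, x, eps = 1e-5) {
  force(x)
  v <- g$nodes[[x]]$val
  d <- dim(v); V <- prod(d[1:3]); C <- d[4]
  if (V < 2) return(x)
  m <- matrix(v, V, C)
  mu <- colMeans(m)
  ctr <- sweep(m, 2, mu)
  s <- sqrt(colMeans(ctr^2) + eps)
  xhat <- sweep(ctr, 2, s, "/")
  nd(g, "inorm", x, array(xhat, d), list(xhat = xhat, s = s, V = V, C = C))
}
g_dropout <- function(g, x, p) {
  force(x)
  v <- g$nodes[[x]]$val
  keep <- 1 - p
  mask <- array(rbinom(length(v), 1L, keep) / keep, dim(v))
  nd(g, "dropout", x, v * mask, list(mask = mask))
}
g_softmax <- function(g, x) {
  force(x)
  nd(g, "softmax", x, softmax_channels(g$nodes[[x]]$val))
}

# Backpropagate from node `out` seeded with gradient `gout`; returns an
# environment of weight gradients keyed like the weight list.
graph_backward <- function(g, out, gout) {
  graph_backward2(g, list(out), list(gout))
}

# multi-seed variant: gradients injected at several nodes (used to add the
# logit-regularization term during training)
graph_backward2 <- function(g, outs, gouts) {
  n <- length(g$nodes)
  grads <- vector("list", n)
  for (i in seq_along(outs)) {
    id <- outs[[i]]
    grads[[id]] <- if (is.null(grads[[id]])) gouts[[i]]
    else grads[[id]] + gouts[[i]]
  }
  GW <- new.env(parent = emptyenv())
  for (id in n:1) {
    gy <- grads[[id]]
    if (is.null(gy)) next
    node <- g$nodes[[id]]
    addg <- function(pid, gval) {
      if (is.null(grads[[pid]])) grads[[pid]] <<- gval
      else grads[[pid]] <<- grads[[pid]] + gval
    }
    switch(node$op,
      input = NULL,
      conv = {
        nm <- node$extra$name
        bw <- if (is.null(node$extra$col))
          cpp_conv3d_backward(g$nodes[[node$parents]]$val,
                              g$W[[paste0(nm, ".w")]], gy)
        else
          cpp_conv3d_backward_col(node$extra$col,
                                  g$W[[paste0(nm, ".w")]], gy,
                                  node$extra$xdim)
        wkey <- paste0(nm, ".w"); bkey <- paste0(nm, ".b")
        GW[[wkey]] <- if (is.null(GW[[wkey]])) bw$gw else GW[[wkey]] + bw$gw
        GW[[bkey]] <- if (is.null(GW[[bkey]])) bw$gb else GW[[bkey]] + bw$gb
        addg(node$parents, bw$gx)
      },
      relu = addg(node$parents, gy * (g$nodes[[node$parents]]$val > 0)),
      pool = addg(node$parents,
                  cpp_maxpool3d_backward(gy, node$extra$idx, node$extra$xdim)),
      up = {
        xd <- node$extra$xdim
        addg(node$parents, cpp_upsample3d_backward(gy, xd[1], xd[2], xd[3]))
      },
      add = { addg(node$parents[1], gy); addg(node$parents[2], gy) },
      inorm = {
        ex <- node$extra
        gm <- matrix(gy, ex$V, ex$C)
        gcent <- sweep(gm, 2, colMeans(gm))
        proj <- colMeans(gm * ex$xhat)
        gx <- sweep(gcent - sweep(ex$xhat, 2, proj, "*"), 2, ex$s, "/")
        addg(node$parents, array(gx, dim(gy)))
      },
      dropout = addg(node$parents, gy * node$extra$mask),
      softmax = {
        p <- node$val
        d <- dim(p); V <- prod(d[1:3]); C <- d[4]
        pm <- matrix(p, V, C); gm <- matrix(gy, V, C)
        gz <- pm * (gm - rowSums(pm * gm))
        addg(node$parents, array(gz, d))
      },
      stop("unknown op ", node$op))
    grads[id] <- list(NULL)            # free as we go
  }
  GW
}

## ---- full forward pass -----------------------------------------------------

#' Run the segmentation network forward
#'
#' Builds the full coarse/adapter/refinement pass over one multi-channel
#' sub-volume and returns per-voxel class probabilities (normalized
#' exponential over the class axis). Spatial dimensions must be divisible by
#' 2^5 = 32 for the five pooling stages. With dropout disabled the pass is
#' deterministic given fixed weights.
#'
#' @param weights named weight list from [sfcnn_init()] (or a trained fit's
#'   `$weights`).
#' @param cfg the matching [sfcnn_config()].
#' @param x input array (D, H, W, in_channels).
#' @param train logical; if `TRUE`, dropout is active and the computation
#'   graph is returned for backpropagation.
#' @return probability array (D, H, W, n_classes); when `train = TRUE`, a
#'   list with the graph and the output node id.
#' @export
sfcnn_forward <- function(weights, cfg, x, train = FALSE) {
  d <- dim(x)
  if (length(d) != 4L || d[4] != cfg$in_channels)
    stop_ioucseg("ioucseg_shape", "input must be (D,H,W,%d)", cfg$in_channels)
  if (any(d[1:3] %% 32L != 0L))
    stop_ioucseg("ioucseg_shape",
                 "spatial dims (%s) must be divisible by 2^5 = 32",
                 paste(d[1:3], collapse = ","))
  g <- new_graph(weights)
  g$train <- train
  norm <- if (identical(cfg$normalization, "none")) function(g, x) x
  else g_inorm
  res_group <- function(x, grp, blocks) {
    for (b in seq_len(blocks)) {
      nm <- sprintf("g%d.b%d", grp, b)
      h <- g_relu(g, norm(g, g_conv(g, x, paste0(nm, ".c1"))))
      h <- g_relu(g, norm(g, g_conv(g, h, paste0(nm, ".c2"))))
      h <- norm(g, g_conv(g, h, paste0(nm, ".c3")))
      x <- g_relu(g, g_add(g, h, x))
    }
    x
  }
  xin <- g_input(g, x)
  x0 <- g_relu(g, norm(g, g_conv(g, xin, "c0a")))
  x0b <- g_relu(g, norm(g, g_conv(g, x0, "c0b")))
  skips <- vector("list", 5)
  skips[[1]] <- x0b
  cur <- x0b
  for (grp in 1:4) {
    cur <- g_pool(g, cur)
    cur <- res_group(cur, grp, cfg$blocks_per_group)
    cur <- g_relu(g, norm(g, g_conv(g, cur, sprintf("t%d", grp))))
    skips[[grp + 1L]] <- cur
  }
  cur <- g_pool(g, cur)
  cur <- g_relu(g, norm(g, g_conv(g, cur, "b1")))
  if (train && cfg$dropout > 0) cur <- g_dropout(g, cur, cfg$dropout)
  cur <- g_relu(g, norm(g, g_conv(g, cur, "b2")))
  if (train && cfg$dropout > 0) cur <- g_dropout(g, cur, cfg$dropout)
  for (l in 5:1) {
    skip <- skips[[l]]
    tgt <- dim(g$nodes[[skip]]$val)[1:3]
    up <- g_up(g, cur, tgt)
    ad <- norm(g, g_conv(g, skip, sprintf("a%d", l)))
    fused <- g_add(g, up, ad)
    cur <- g_relu(g, norm(g, g_conv(g, fused, sprintf("r%d", l))))
  }
  logits <- g_conv(g, cur, "head")
  out <- g_softmax(g, logits)
  probs <- g$nodes[[out]]$val
  if (train) list(graph = g, out = out, probs = probs) else probs
}
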