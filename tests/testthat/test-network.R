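test_that("production convolution equals the triple-sum reference", {
  # constant input, all-ones kernel: interior voxels sum 27 ones
  ones <- array(1, c(5, 5, 5))
  k1 <- array(1, c(3, 3, 3))
  expect_equal(conv3d(ones, k1)[3, 3, 3], 27)
  # delta kernel is the identity
  dk <- array(0, c(3, 3, 3)); dk[2, 2, 2] <- 1
  x <- array(rnorm(125), c(5, 5, 5))
  expect_equal(conv3d(x, dk), x)
  # 20+ random instances against the reference path
  set.seed(20)
  for (i in 1:20) {
    d <- sample(3:6, 3, replace = TRUE)
    x <- array(rnorm(prod(d)), d)
    k <- array(rnorm(27), c(3, 3, 3))
    expect_equal(conv3d(x, k), conv3d_reference(x, k), tolerance = 1e-5)
  }
  # 1^3 kernels too
  k0 <- array(2.5, c(1, 1, 1))
  expect_equal(conv3d(x, k0), conv3d_reference(x, k0), tolerance = 1e-12)
  expect_error(conv3d(x, array(1, c(2, 2, 2))), class = "ioucseg_parameter")
  expect_error(conv3d_reference(x, array(1, c(4, 3, 3))),
               class = "ioucseg_parameter")
})

test_that("relu clamps negatives and is idempotent", {
  expect_equal(relu(array(-3, c(1, 1, 1))), array(0, c(1, 1, 1)))
  expect_equal(relu(array(2, c(1, 1, 1))), array(2, c(1, 1, 1)))
  x <- array(rnorm(60), c(3, 4, 5))
  expect_equal(relu(relu(x)), relu(x))
})

test_that("max pooling matches the brute-force blockwise maximum", {
  expect_equal(maxpool3d(array(5, c(4, 4, 4))), array(5, c(2, 2, 2)))
  expect_equal(as.vector(maxpool3d(array(1:8, c(2, 2, 2)))), 8)
  set.seed(8)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  br <- array(0, c(4, 4, 4, 2))
  for (cc in 1:2) for (d in 1:4) for (h in 1:4) for (w in 1:4)
    br[d, h, w, cc] <- max(x[2 * d - 1:0, 2 * h - 1:0, 2 * w - 1:0, cc])
  expect_equal(maxpool3d(x), br)
  expect_error(maxpool3d(array(0, c(3, 4, 4))), class = "ioucseg_error")
})

test_that("trilinear upsampling reproduces the bilinear matrix form", {
  # knots keep their values; 1D midpoint of (0,1) is 0.5
  e <- array(c(0, 1), c(1, 1, 2))
  up <- trilinear_upsample(e, c(1, 1, 3))
  expect_equal(as.vector(up), c(0, 0.5, 1))
  # random 2x2 slices at fractional (Sx, Sy) against the matrix product
  set.seed(13)
  for (i in 1:20) {
    sl <- array(rnorm(4), c(1, 2, 2))
    Fm <- matrix(sl[1, , ], 2, 2)
    oh <- sample(3:6, 1); ow <- sample(3:6, 1)
    up <- trilinear_upsample(sl, c(1, oh, ow))
    for (a in seq_len(oh)) for (b in seq_len(ow)) {
      sx <- (a - 1) / (oh - 1); sy <- (b - 1) / (ow - 1)
      eq3 <- drop(c(1 - sx, sx) %*% Fm %*% c(1 - sy, sy))
      expect_equal(up[1, a, b], eq3, tolerance = 1e-6)
    }
  }
  # corner alignment in full 3D
  x <- array(rnorm(8), c(2, 2, 2))
  u2 <- trilinear_upsample(x, c(3, 3, 3))
  expect_equal(u2[c(1, 3), c(1, 3), c(1, 3)], x)
  expect_error(trilinear_upsample(x, c(1, 2, 2)), class = "ioucseg_parameter")
})

test_that("residual blocks preserve shape and compose the primitive oracles", {
  mk_w <- function(k, cin, cout, zero = FALSE) {
    w <- if (zero) array(0, c(k, k, k, cin, cout))
    else array(rnorm(k^3 * cin * cout, 0, 0.3), c(k, k, k, cin, cout))
    list(w = w, b = numeric(cout))
  }
  # zero branch weights + non-negative input = identity
  x <- abs(array(rnorm(4^3 * 4), c(4, 4, 4, 4)))
  wz <- list(c1 = mk_w(1, 4, 2, TRUE), c2 = mk_w(3, 2, 2, TRUE),
             c3 = mk_w(1, 2, 4, TRUE))
  expect_equal(residual_block(x, wz), x)

  # shape preservation across the residual-group geometries (scaled down)
  for (d in c(8, 4, 2)) {
    xi <- array(rnorm(d^3 * 4), c(d, d, d, 4))
    wr <- list(c1 = mk_w(1, 4, 2), c2 = mk_w(3, 2, 2), c3 = mk_w(1, 2, 4))
    expect_identical(dim(residual_block(xi, wr)), dim(xi))
  }

  # equals the composition of single-channel reference convolutions
  set.seed(31)
  xi <- array(rnorm(5^3 * 2), c(5, 5, 5, 2))
  wr <- list(c1 = mk_w(1, 2, 1), c2 = mk_w(3, 1, 1), c3 = mk_w(1, 1, 2))
  ref_conv <- function(x, w) {
    cout <- dim(w$w)[5]
    out <- array(0, c(dim(x)[1:3], cout))
    for (co in seq_len(cout)) {
      acc <- array(0, dim(x)[1:3])
      for (ci in seq_len(dim(x)[4])) {
        xi1 <- x[, , , ci, drop = FALSE]; dim(xi1) <- dim(x)[1:3]
        k1 <- w$w[, , , ci, co, drop = FALSE]; dim(k1) <- dim(w$w)[1:3]
        acc <- acc + conv3d_reference(xi1, k1)
      }
      out[, , , co] <- acc + w$b[co]
    }
    out
  }
  h <- relu(ref_conv(xi, wr$c1))
  h <- relu(ref_conv(h, wr$c2))
  h <- ref_conv(h, wr$c3)
  expect_equal(residual_block(xi, wr), relu(h + xi), tolerance = 1e-5)

  # channel mismatch between branch and skip
  wb <- list(c1 = mk_w(1, 2, 1), c2 = mk_w(3, 1, 1), c3 = mk_w(1, 1, 3))
  expect_error(residual_block(xi, wb), class = "ioucseg_error")
})

test_that("adapter fusion upsamples, matches channels and adds", {
  x <- array(rnorm(8^3 * 3), c(8, 8, 8, 3))
  z <- array(0, c(8, 8, 8, 3))
  expect_equal(abl_fuse(z, x), x)
  a <- array(2, c(4, 4, 4, 3)); b <- array(5, c(8, 8, 8, 3))
  expect_equal(abl_fuse(a, b), array(7, c(8, 8, 8, 3)))
  # 4^3 map upsampled against an 8^3 map gives an 8^3 result
  expect_identical(dim(abl_fuse(a, b))[1:3], c(8L, 8L, 8L))
  # channel mismatch without adapter weights
  expect_error(abl_fuse(array(0, c(4, 4, 4, 2)), b),
               class = "ioucseg_configuration")
  # a 1^3 adapter reconciles them
  ad <- list(w = array(rnorm(2 * 3), c(1, 1, 1, 3, 2)), b = numeric(2))
  expect_identical(dim(abl_fuse(array(0, c(4, 4, 4, 2)), b, ad))[4], 2L)
})

test_that("forward pass honors shape, simplex and determinism contracts", {
  cfg <- sfcnn_config(base_filters = 2, blocks_per_group = 1)
  W <- sfcnn_init(cfg, seed = 2)
  x <- array(rnorm(32^3 * 4), c(32, 32, 32, 4))
  p <- sfcnn_forward(W, cfg, x)
  expect_identical(dim(p), c(32L, 32L, 32L, 5L))
  expect_lt(max(abs(apply(p, 1:3, sum) - 1)), 1e-5)
  # deterministic with dropout off at inference
  p2 <- sfcnn_forward(W, cfg, x)
  expect_identical(ioucseg:::prob_argmax(p, 0:4), ioucseg:::prob_argmax(p2, 0:4))
  # indivisible spatial dims are refused with a named divisibility
  err <- expect_error(
    sfcnn_forward(W, cfg, array(0, c(30, 30, 30, 4))),
    class = "ioucseg_shape")
  expect_match(conditionMessage(err), "32")
})

test_that("parameter count grows with base_filters and paper scale builds", {
  n2 <- sfcnn_n_params(sfcnn_config(base_filters = 2))
  n4 <- sfcnn_n_params(sfcnn_config(base_filters = 4))
  n8 <- sfcnn_n_params(sfcnn_config(base_filters = 8))
  expect_true(n2 < n4 && n4 < n8)
  # paper-scale width instantiates without error (no training required)
  Wp <- sfcnn_init(sfcnn_config(base_filters = 32), seed = 1)
  expect_true(length(Wp) > 0)
  expect_identical(dim(Wp[["c0a.w"]]), c(3L, 3L, 3L, 4L, 32L))
})

test_that("network gradients match finite differences end-to-end", {
  cfg <- sfcnn_config(base_filters = 1, blocks_per_group = 1, dropout = 0)
  W <- sfcnn_init(cfg, seed = 3)
  set.seed(4)
  x <- array(rnorm(32^3 * 4), c(32, 32, 32, 4))
  lab <- array(sample(0:4, 32^3, TRUE, prob = c(.96, .01, .01, .01, .01)),
               c(32, 32, 32))
  Y <- one_hot(lab)
  fw <- sfcnn_forward(W, cfg, x, train = TRUE)
  lg <- iou_constraint_loss(fw$probs, Y, "normalized", grad = TRUE)
  GW <- ioucseg:::graph_backward(fw$graph, fw$out, lg$grad)
  lossW <- function(W) iou_constraint_loss(sfcnn_forward(W, cfg, x), Y,
                                           "normalized")
  for (nm in c("c0a.w", "g3.b1.c2.w", "b2.w", "r2.w", "head.b")) {
    g <- GW[[nm]]
    i <- which.max(abs(g))          # probe the largest-gradient entry
    h <- 1e-5
    Wp <- W; Wp[[nm]][i] <- Wp[[nm]][i] + h
    Wm <- W; Wm[[nm]][i] <- Wm[[nm]][i] - h
    fd <- (lossW(Wp) - lossW(Wm)) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})
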