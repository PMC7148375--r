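test_that("z-score normalization matches the population-sd oracle", {
  # hand-computed: (1,2,3) has mean 2 and population sd sqrt(2/3)
  v <- array(c(1, 2, 3), c(1, 1, 3))
  got <- normalize_zscore(v)
  expect_equal(as.vector(got), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-4)

  out <- normalize_zscore(rand_volume(c(6, 5, 4), seed = 3))
  expect_lt(abs(mean(out$data)), 1e-6)
  expect_lt(abs(sqrt(mean(out$data^2)) - 1), 1e-6)

  expect_equal(normalize_zscore(array(7, c(3, 3, 3))), array(0, c(3, 3, 3)))
  # idempotence
  x <- rand_volume(c(5, 5, 5), seed = 4)$data
  expect_equal(normalize_zscore(normalize_zscore(x)), normalize_zscore(x),
               tolerance = 1e-5)
})

test_that("rotation augmentation is an involution that permutes indices", {
  co <- tiny_cohort(n = 2, seed = 3)
  s <- co$train[[1]]
  r1 <- augment_rotate180(s$stack, s$labels)
  r2 <- augment_rotate180(r1$stack, r1$labels)
  expect_equal(r2$stack, s$stack)
  expect_equal(r2$labels, s$labels)
  # histogram invariance
  expect_identical(table(r1$labels$data), table(s$labels$data))

  # single marked voxel moves to (i, H-1-j, W-1-k), brute-force index map
  a <- array(0, c(3, 4, 5)); a[2, 1, 2] <- 1
  r <- augment_rotate180(a)$stack
  expect_equal(which(r == 1, arr.ind = TRUE)[1, ],
               c(dim1 = 2, dim2 = 4 + 1 - 1, dim3 = 5 + 1 - 2))
})

test_that("crop planning covers the grid with flush final offsets", {
  p1 <- plan_crops(c(128, 128, 128), c(128, 128, 128))
  expect_equal(nrow(p1$offsets), 1)
  expect_equal(unname(p1$offsets[1, ]), c(0, 0, 0))
  expect_equal(p1$pad_before, c(0L, 0L, 0L))

  # the full-size case: per-axis offsets {0,112} for 240 and {0,27} for 155
  p2 <- plan_crops(c(240, 240, 155), c(128, 128, 128), c(112, 112, 112))
  expect_equal(sort(unique(p2$offsets[, 1])), c(0, 112))
  expect_equal(sort(unique(p2$offsets[, 3])), c(0, 27))
  expect_equal(nrow(p2$offsets), 8)
  # brute-force coverage check
  covered <- array(FALSE, p2$padded)
  for (i in seq_len(nrow(p2$offsets))) {
    o <- p2$offsets[i, ]
    covered[o[1] + 1:128, o[2] + 1:128, o[3] + 1:128] <- TRUE
  }
  expect_true(all(covered))

  # short axis is padded symmetrically
  p3 <- plan_crops(c(100, 128, 128), c(128, 128, 128))
  expect_equal(p3$padded, c(128L, 128L, 128L))
  expect_equal(p3$pad_before[1] + p3$pad_after[1], 28L)
  expect_lte(abs(p3$pad_before[1] - p3$pad_after[1]), 1L)
  expect_equal(nrow(p3$offsets), 1)

  expect_error(plan_crops(c(64, 64, 64), c(32, 32, 32), c(0, 1, 1)),
               class = "ioucseg_parameter")
})

test_that("stitching averages overlaps and inverts cropping", {
  # single full-size crop is the identity
  p <- rand_probs(c(8, 8, 8), 3)
  plan <- plan_crops(c(8, 8, 8), c(8, 8, 8))
  expect_equal(stitch_probability(list(p), plan), p)

  # two half-overlapping constant maps -> overlap is their mean
  plan2 <- plan_crops(c(8, 8, 12), c(8, 8, 8), c(4, 4, 4))
  cp <- array(rep(c(0.2, 0.8), each = 512), c(8, 8, 8, 2))
  cq <- array(rep(c(0.6, 0.4), each = 512), c(8, 8, 8, 2))
  st <- stitch_probability(list(cp, cq), plan2)
  expect_equal(st[1, 1, 2, 1], 0.2)              # only first crop
  expect_equal(st[1, 1, 6, 1], (0.2 + 0.6) / 2)  # overlap region
  expect_equal(st[1, 1, 11, 1], 0.6)             # only second crop

  # random crops against a voxel-wise accumulate-and-divide oracle
  shape <- c(8, 10, 12); C <- 3
  plan3 <- plan_crops(shape, c(8, 8, 8), c(4, 4, 4))
  set.seed(5)
  crops <- lapply(seq_len(nrow(plan3$offsets)), function(i)
    rand_probs(c(8, 8, 8), C, seed = i))
  acc <- array(0, c(plan3$padded, C)); cnt <- array(0, plan3$padded)
  for (i in seq_len(nrow(plan3$offsets))) {
    o <- plan3$offsets[i, ]
    for (cc in 1:C)
      acc[o[1] + 1:8, o[2] + 1:8, o[3] + 1:8, cc] <-
        acc[o[1] + 1:8, o[2] + 1:8, o[3] + 1:8, cc] + crops[[i]][, , , cc]
    cnt[o[1] + 1:8, o[2] + 1:8, o[3] + 1:8] <-
      cnt[o[1] + 1:8, o[2] + 1:8, o[3] + 1:8] + 1
  }
  oracle <- array(0, c(plan3$padded, C))
  for (cc in 1:C) oracle[, , , cc] <- acc[, , , cc] / cnt
  oracle <- oracle[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), ,
                   drop = FALSE]
  expect_equal(stitch_probability(crops, plan3), oracle, tolerance = 1e-6)
  # simplex restored
  st3 <- stitch_probability(crops, plan3)
  expect_lt(max(abs(apply(st3, 1:3, sum) - 1)), 1e-5)

  expect_error(stitch_probability(crops[-1], plan3),
               class = "ioucseg_composition")
})

test_that("crop-then-stitch is the identity for non-overlapping tilings", {
  p <- rand_probs(c(8, 8, 16), 2, seed = 9)
  plan <- plan_crops(c(8, 8, 16), c(8, 8, 8), c(8, 8, 8))
  crops <- extract_crops(p, plan)
  expect_equal(stitch_probability(crops, plan), p)
})

test_that("rotation commutes with z-score normalization", {
  x <- rand_volume(c(6, 6, 6), seed = 11)$data
  a <- normalize_zscore(augment_rotate180(x)$stack)
  b <- augment_rotate180(normalize_zscore(x))$stack
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("bias-correction hook is off by default and pluggable", {
  v <- rand_volume(c(4, 4, 4), seed = 1)
  expect_identical(bias_correction_hook(v), v)
  halve <- function(vol) volume(vol$data / 2, vol$spacing, vol$modality)
  expect_equal(bias_correction_hook(v, halve)$data, v$data / 2)
})
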