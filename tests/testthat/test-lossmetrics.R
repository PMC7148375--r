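test_that("IOU-constraint loss has the forced values at its extremes", {
  # perfect one-hot prediction: ratio of sums is 1 algebraically, so the
  # literal form gives 1 - 1/C and the normalized form gives 0
  for (C in 2:5) {
    Y <- rand_onehot(c(4, 4, 4), C, seed = C)
    expect_equal(iou_constraint_loss(Y, Y, "literal"), 1 - 1 / C,
                 tolerance = 1e-9)
    expect_equal(iou_constraint_loss(Y, Y, "normalized"), 0,
                 tolerance = 1e-9)
  }
  # disjoint binary prediction with both classes present: loss exactly 1
  Y <- array(0, c(1, 1, 4, 2)); Y[1, 1, 1:2, 1] <- 1; Y[1, 1, 3:4, 2] <- 1
  X <- array(0, c(1, 1, 4, 2)); X[1, 1, 1:2, 2] <- 1; X[1, 1, 3:4, 1] <- 1
  expect_equal(iou_constraint_loss(X, Y, "literal"), 1)
  expect_equal(iou_constraint_loss(X, Y, "normalized"), 1)
})

test_that("loss equals the brute-force double sum on random instances", {
  set.seed(100)
  for (i in 1:25) {
    C <- sample(2:5, 1)
    V3 <- sample(3:5, 3, replace = TRUE)
    X <- rand_probs(V3, C, seed = i)
    Y <- rand_onehot(V3, C, seed = i + 1000)
    for (variant in c("literal", "normalized"))
      expect_equal(iou_constraint_loss(X, Y, variant),
                   loss_bruteforce(X, Y, variant), tolerance = 1e-8)
  }
})

test_that("loss is monotone in overlap and bounded", {
  # growing the intersection with the denominator held fixed lowers the loss
  Y <- array(0, c(1, 1, 8, 2)); Y[1, 1, 1:4, 1] <- 1; Y[1, 1, 5:8, 2] <- 1
  mk <- function(p) {
    X <- array(0, c(1, 1, 8, 2))
    X[, , , 1] <- p * Y[, , , 1] + (1 - p) * Y[, , , 2]
    X[, , , 2] <- 1 - X[, , , 1]
    X
  }
  losses <- sapply(seq(0.1, 0.9, by = 0.2), function(p)
    iou_constraint_loss(mk(p), Y, "normalized"))
  expect_true(all(diff(losses) < 0))
  expect_true(all(losses >= 0 & losses <= 1))
})

test_that("analytic loss gradient matches finite differences", {
  for (seed in 1:3) {
    X <- rand_probs(c(3, 3, 3), 4, seed = seed)
    Y <- rand_onehot(c(3, 3, 3), 4, seed = seed + 50)
    for (variant in c("literal", "normalized")) {
      lg <- iou_constraint_loss(X, Y, variant, grad = TRUE)
      set.seed(seed)
      for (probe in sample(length(X), 12)) {
        h <- 1e-6
        Xp <- X; Xp[probe] <- Xp[probe] + h
        Xm <- X; Xm[probe] <- Xm[probe] - h
        fd <- (iou_constraint_loss(Xp, Y, variant) -
                 iou_constraint_loss(Xm, Y, variant)) / (2 * h)
        expect_equal(lg$grad[probe], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("for binary problems 1 - normalized loss is weighted Jaccard <= Dice", {
  set.seed(60)
  for (i in 1:5) {
    lab <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
    pred <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
    if (!any(lab) || !any(pred)) next
    X <- one_hot(pred, 0:1); Y <- one_hot(lab, 0:1)
    jac_w <- 1 - iou_constraint_loss(X, Y, "normalized")
    # gamma-weighted Jaccard, computed directly
    g <- c(sum(lab == 0), sum(lab == 1)); w <- 1 / (g^2 + 1e-6)
    inter <- c(sum(lab == 0 & pred == 0), sum(lab == 1 & pred == 1))
    uni <- c(sum(lab == 0 | pred == 0), sum(lab == 1 | pred == 1))
    expect_equal(jac_w, sum(w * inter) / sum(w * uni), tolerance = 1e-6)
    # plain per-class Jaccard never exceeds Dice
    expect_lte(inter[2] / uni[2], dice(lab == 1, pred == 1) + 1e-12)
  }
})

test_that("dice handles identity, disjoint and counted cases", {
  m <- array(c(rep(TRUE, 10), rep(FALSE, 17)), c(3, 3, 3))
  expect_equal(dice(m, m), 1)
  expect_equal(dice(m, !m), 0)
  # |T∩P| = 50, |T| = |P| = 100
  T <- array(FALSE, c(10, 10, 2)); P <- T
  T[1:100] <- TRUE; P[51:150] <- TRUE
  expect_equal(dice(T, P), 0.5)
  expect_equal(dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), 1)
  expect_equal(dice(T, P), dice(P, T))
})

test_that("recall/precision cover degenerate denominators and duality", {
  T <- array(FALSE, c(10, 1, 1)); P <- T
  T[1:10] <- TRUE; P[1:8] <- TRUE     # TP=8, FN=2
  expect_equal(recall_precision(T, P)$recall, 0.8)
  rp <- recall_precision(T, T)
  expect_equal(rp$recall, 1); expect_equal(rp$precision, 1)
  # empty prediction with non-empty truth: recall 0, precision flagged 0
  rp2 <- recall_precision(T, array(FALSE, dim(T)))
  expect_equal(rp2$recall, 0)
  expect_equal(rp2$precision, 0)
  expect_true(rp2$degenerate)
  # recall(T, P) == precision(P, T)
  set.seed(3)
  A <- array(rbinom(27, 1, .4) > 0, c(3, 3, 3))
  B <- array(rbinom(27, 1, .4) > 0, c(3, 3, 3))
  expect_equal(recall_precision(A, B)$recall, recall_precision(B, A)$precision)
})

test_that("Hausdorff matches brute force, scales by spacing, and is symmetric", {
  # 3-4-5 triangle
  expect_equal(hausdorff(matrix(c(3, 4, 0), 1), matrix(c(0, 0, 0), 1)), 5)
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  expect_equal(hausdorff(m, m), 0)
  set.seed(40)
  for (i in 1:10) {
    P <- matrix(runif(3 * sample(5:30, 1), 0, 10), ncol = 3)
    T <- matrix(runif(3 * sample(5:30, 1), 0, 10), ncol = 3)
    expect_equal(hausdorff(T, P), hausdorff_bruteforce(P, T),
                 tolerance = 1e-9)
    expect_equal(hausdorff(T, P), hausdorff(P, T))
  }
  # voxel masks with anisotropic spacing: distance in mm
  a <- array(FALSE, c(5, 1, 1)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, c(5, 1, 1)); b[5, 1, 1] <- TRUE
  expect_equal(hausdorff(a, b, spacing = c(2, 1, 1)), 8)
  expect_error(hausdorff(a, array(FALSE, c(5, 1, 1))),
               class = "ioucseg_undefined_metric")
})

test_that("region masks follow the nested whole/core/enhancing convention", {
  all4 <- array(4L, c(3, 3, 3))
  m <- region_masks(all4)
  expect_true(all(m$whole) && all(m$core) && all(m$enhancing))
  one2 <- array(0L, c(3, 3, 3)); one2[2, 2, 2] <- 2L
  m2 <- region_masks(one2)
  expect_equal(sum(m2$whole), 1)
  expect_equal(sum(m2$core), 0)
  expect_equal(sum(m2$enhancing), 0)
  m0 <- region_masks(array(0L, c(2, 2, 2)))
  expect_true(!any(m0$whole) && !any(m0$core) && !any(m0$enhancing))
  # nesting on a phantom with all labels present
  ph <- generate_phantom(phantom_spec(seed = 2))
  mm <- region_masks(ph$labels)
  expect_true(all(mm$enhancing <= mm$core))
  expect_true(all(mm$core <= mm$whole))
})

test_that("per-subject metrics report all regions with NA for undefined HD", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  rep1 <- segmentation_metrics(ph$labels, ph$labels)
  expect_equal(rep1$dice, rep(1, 3))
  expect_equal(rep1$hd_mm, rep(0, 3))
  empty <- labelmap(array(0L, dim(ph$labels$data)))
  rep2 <- segmentation_metrics(ph$labels, empty)
  expect_equal(rep2$dice, rep(0, 3))
  expect_true(all(is.na(rep2$hd_mm)))
})
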