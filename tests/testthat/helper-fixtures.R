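# Shared fixture builders and brute-force oracles used across the suite.

rand_volume <- function(shape = c(8, 8, 8), spacing = c(1, 1, 1),
                        modality = "derived", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  volume(array(rnorm(prod(shape)), shape), spacing, modality)
}

rand_stack <- function(shape = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  vols <- lapply(c("flair", "t1", "t1gd", "t2"), function(m)
    volume(array(rnorm(prod(shape)), shape), modality = m))
  stack_modalities(vols)
}

# random point on the probability simplex per voxel
rand_probs <- function(shape = c(4, 4, 4), C = 5, seed = 1) {
  set.seed(seed)
  z <- matrix(rexp(prod(shape) * C), ncol = C)
  array(z / rowSums(z), c(shape, C))
}

rand_onehot <- function(shape = c(4, 4, 4), C = 5, seed = 1) {
  set.seed(seed)
  lab <- array(sample.int(C, prod(shape), replace = TRUE) - 1L, shape)
  one_hot(lab, 0:(C - 1))
}

# brute-force evaluation of the class-weighted soft-Jaccard loss as a double
# sum, independent of the vectorized implementation
loss_bruteforce <- function(X, Y, variant = "normalized", epsilon = 1e-6) {
  d <- dim(X); C <- d[length(d)]; V <- prod(d) / C
  Xm <- matrix(X, V, C); Ym <- matrix(Y, V, C)
  num <- 0; den <- 0
  for (cc in seq_len(C)) {
    gamma <- 0
    for (v in seq_len(V)) gamma <- gamma + Ym[v, cc]
    w <- 1 / (gamma^2 + epsilon)
    si <- 0; su <- 0
    for (v in seq_len(V)) {
      si <- si + Xm[v, cc] * Ym[v, cc]
      su <- su + Xm[v, cc] + Ym[v, cc] - Xm[v, cc] * Ym[v, cc]
    }
    num <- num + w * si
    den <- den + w * su
  }
  s <- if (variant == "literal") 1 / C else 1
  1 - s * num / den
}

# brute-force symmetric Hausdorff distance (double loop over point rows)
hausdorff_bruteforce <- function(P, T) {
  directed <- function(A, B) {
    mx <- 0
    for (i in seq_len(nrow(A))) {
      mn <- Inf
      for (j in seq_len(nrow(B)))
        mn <- min(mn, sqrt(sum((A[i, ] - B[j, ])^2)))
      mx <- max(mx, mn)
    }
    mx
  }
  max(directed(P, T), directed(T, P))
}

# recursive flood-fill component labeling oracle (26-connectivity)
floodfill_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    if (lab[idx[r, 1], idx[r, 2], idx[r, 3]] > 0L) next
    nxt <- nxt + 1L
    stack <- list(idx[r, ])
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (any(p < 1) || any(p > d)) next
      if (!mask[p[1], p[2], p[3]] || lab[p[1], p[2], p[3]] > 0L) next
      lab[p[1], p[2], p[3]] <- nxt
      for (dd in -1:1) for (dh in -1:1) for (dw in -1:1)
        if (dd || dh || dw)
          stack[[length(stack) + 1L]] <- p + c(dd, dh, dw)
    }
  }
  lab
}

# tiny training cohort used by the slower pipeline tests
tiny_cohort <- function(n = 4, seed = 7, noise_sd = 0.05)
  generate_cohort(n, phantom_spec(noise_sd = noise_sd, seed = seed),
                  split = 0.5)
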