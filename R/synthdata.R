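#' Default per-label modality contrasts for phantoms
#'
#' Mean intensity of each tissue label (rows: healthy 0, necrotic 1, edema
#' 2, non-enhancing 3, enhancing 4) in each modality channel, chosen to
#' mimic the qualitative appearance of the real contrasts: edema is bright
#' on flair and t2, enhancing tumor lights up on t1gd, and t1 carries
#' deliberately weak tumor contrast (the least informative channel).
#'
#' @return 5 x 4 numeric matrix (labels x modalities).
#' @export
default_contrasts <- function() {
  m <- rbind(
    healthy   = c(flair = 0.20, t1 = 0.50, t1gd = 0.40, t2 = 0.30),
    necrotic  = c(flair = 0.50, t1 = 0.35, t1gd = 0.25, t2 = 0.70),
    edema     = c(flair = 0.90, t1 = 0.45, t1gd = 0.45, t2 = 0.85),
    nonenh    = c(flair = 0.70, t1 = 0.40, t1gd = 0.55, t2 = 0.55),
    enhancing = c(flair = 0.60, t1 = 0.45, t1gd = 1.00, t2 = 0.45))
  colnames(m) <- MODALITIES
  m
}

#' Phantom specification
#'
#' Parameters of one synthetic multimodal subject: a nested-ellipsoid tumor
#' (edema shell ⊃ non-enhancing ⊃ enhancing rim ⊃ necrotic center) placed at
#' a random location in an otherwise homogeneous background, rendered into
#' four modality channels by contrast lookup, an optional smooth
#' multiplicative bias field, and additive Gaussian noise. The default
#' foreground fraction of one thousandth reproduces the extreme
#' tumor/background imbalance of real volumes. The bias amplitude defaults
#' to 0, emulating data whose inhomogeneity was already corrected upstream
#' (as the real preprocessing pipeline assumes); set it positive to give the
#' bias-correction hook something to act on.
#'
#' @param shape integer length-3 grid shape (default 32^3).
#' @param foreground_fraction target tumor fraction in (0, 0.5) (default
#'   1e-3).
#' @param n_subregions number of nested tumor labels, 1--4 (default 4).
#' @param modality_contrasts 5 x 4 label-by-modality mean intensities.
#' @param noise_sd additive Gaussian noise sd (default 0.05).
#' @param bias_amplitude log-amplitude of the multiplicative low-order
#'   polynomial bias field (default 0 = off).
#' @param spacing voxel spacing in mm.
#' @param seed integer seed; phantoms are bit-reproducible given the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), foreground_fraction = 1e-3,
                         n_subregions = 4L,
                         modality_contrasts = default_contrasts(),
                         noise_sd = 0.05, bias_amplitude = 0,
                         spacing = c(1, 1, 1), seed = 1L) {
  if (foreground_fraction <= 0 || foreground_fraction >= 0.5)
    stop_ioucseg("ioucseg_parameter",
                 "foreground_fraction must be in (0, 0.5)")
  if (!n_subregions %in% 1:4)
    stop_ioucseg("ioucseg_parameter", "n_subregions must be 1..4")
  if (!identical(dim(modality_contrasts), c(5L, 4L)))
    stop_ioucseg("ioucseg_parameter",
                 "modality_contrasts must be a 5 x 4 matrix")
  structure(list(shape = as.integer(shape),
                 foreground_fraction = foreground_fraction,
                 n_subregions = as.integer(n_subregions),
                 modality_contrasts = modality_contrasts,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth multiplicative field exp(a * p(x)) with p a random quadratic
# polynomial normalized to max |p| = 1
bias_field <- function(shape, amplitude) {
  cd <- lapply(shape, function(n) seq(-1, 1, length.out = n))
  x <- array(cd[[1]], shape)
  y <- aperm(array(cd[[2]], shape[c(2, 1, 3)]), c(2, 1, 3))
  z <- aperm(array(cd[[3]], shape[c(3, 2, 1)]), c(3, 2, 1))
  co <- runif(9, -1, 1)
  p <- co[1] * x + co[2] * y + co[3] * z + co[4] * x * y + co[5] * x * z +
    co[6] * y * z + co[7] * x^2 + co[8] * y^2 + co[9] * z^2
  p <- p / max(abs(p))
  exp(amplitude * p)
}

#' Generate one multimodal phantom subject
#'
#' @param spec a [phantom_spec()].
#' @param subject_id identifier attached to the stack.
#' @return `list(stack = mmstack, labels = labelmap)`.
#' @export
generate_phantom <- function(spec, subject_id = "phantom") {
  set.seed(spec$seed)
  shp <- spec$shape
  n_vox <- prod(shp)
  target <- spec$foreground_fraction * n_vox
  if (target < 1)
    stop_ioucseg("ioucseg_parameter",
                 "foreground_fraction %.2g yields < 1 voxel on a %s grid",
                 spec$foreground_fraction, paste(shp, collapse = "x"))
  r0 <- (3 * target / (4 * pi))^(1 / 3)
  u <- runif(3, 0.8, 1.25)
  radii <- r0 * u / prod(u)^(1 / 3)
  margin <- ceiling(radii) + 1
  if (any(shp - 2 * margin < 0))
    stop_ioucseg("ioucseg_parameter",
                 "tumor of fraction %.2g does not fit in a %s grid",
                 spec$foreground_fraction, paste(shp, collapse = "x"))
  center <- vapply(1:3, function(ax)
    runif(1, margin[ax] + 1, shp[ax] - margin[ax]), 0)

  cd <- lapply(1:3, function(ax) (seq_len(shp[ax]) - center[ax]) / radii[ax])
  q2 <- outer(outer(cd[[1]]^2, cd[[2]]^2, "+"), cd[[3]]^2, "+")
  q <- sqrt(q2)
  # nested shells, outside-in: edema(2), non-enhancing(3), enhancing(4),
  # necrotic(1); with fewer subregions the innermost shells are merged away
  cuts <- c(1, 0.80, 0.62, 0.40, 0)[seq_len(spec$n_subregions + 1L)]
  cuts[length(cuts)] <- 0
  shell_labels <- c(2L, 3L, 4L, 1L)[seq_len(spec$n_subregions)]
  lab <- array(0L, shp)
  for (i in seq_along(shell_labels)) {
    inner <- i == length(shell_labels)
    sel <- q <= cuts[i] & (q > cuts[i + 1L] | inner)
    lab[sel] <- shell_labels[i]
  }
  labels <- labelmap(lab, spec$spacing)

  vols <- lapply(seq_along(MODALITIES), function(mi) {
    base <- spec$modality_contrasts[lab + 1L, mi]
    dim(base) <- shp
    if (spec$bias_amplitude > 0)
      base <- base * bias_field(shp, spec$bias_amplitude)
    if (spec$noise_sd > 0)
      base <- base + array(rnorm(n_vox, 0, spec$noise_sd), shp)
    volume(base, spacing = spec$spacing, modality = MODALITIES[mi])
  })
  list(stack = stack_modalities(vols, subject_id = subject_id),
       labels = labels)
}

#' Generate a train/test phantom cohort
#'
#' Subject-level split (no subject appears in both sets); each subject's
#' seed is derived deterministically from the master seed, so a cohort is
#' reproducible from `spec$seed` alone.
#'
#' @param n number of subjects (>= 2).
#' @param spec a [phantom_spec()]; its seed is the master seed.
#' @param split training fraction in (0, 1) (default 0.8).
#' @return `list(train =, test =)`, each a list of
#'   `list(stack =, labels =, id =)`.
#' @export
generate_cohort <- function(n, spec = phantom_spec(), split = 0.8) {
  if (n < 2)
    stop_ioucseg("ioucseg_parameter", "cohort needs n >= 2 subjects")
  if (split <= 0 || split >= 1)
    stop_ioucseg("ioucseg_parameter", "split must be in (0, 1)")
  n_train <- floor(n * split + 1e-9)
  if (n_train < 1 || n_train >= n)
    stop_ioucseg("ioucseg_parameter",
                 "split %.2f leaves an empty partition for n = %d", split, n)
  subjects <- lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- (spec$seed * 7919L + i * 104729L) %% 2147483647L
    id <- sprintf("sub%03d", i)
    ph <- generate_phantom(s, subject_id = id)
    list(stack = ph$stack, labels = ph$labels, id = id)
  })
  set.seed(spec$seed)
  ord <- sample.int(n)
  list(train = subjects[sort(ord[seq_len(n_train)])],
       test = subjects[sort(ord[(n_train + 1L):n])])
}
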