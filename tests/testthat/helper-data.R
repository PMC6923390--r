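# Small constructors shared across tests.

vol <- function(values, d = NULL, spacing = c(1, 1, 1), ...) {
  if (!is.null(d)) values <- array(values, dim = d)
  VolumeImage(values, spacing = spacing, ...)
}

msk <- function(values, d = NULL, spacing = c(1, 1, 1)) {
  if (!is.null(d)) values <- array(values, dim = d)
  RoiMask(values, spacing = spacing)
}

# Solid digital ball mask of a given radius (voxels), centered.
ballMask <- function(radius, spacing = c(1, 1, 1), pad = 2) {
  n <- 2 * (radius + pad) + 1
  ctr <- (n + 1) / 2
  co <- seq_len(n) - ctr
  rr <- sqrt(outer(outer(co^2, co^2, "+"), co^2, "+"))
  msk((rr <= radius) * 1, spacing = spacing)
}

quantFromLevels <- function(lev, ng) {
  # wrap a precomputed level array in the public QuantizedRoi type
  new("QuantizedRoi", levels = lev, nLevels = as.integer(ng),
      mask = msk((lev > 0) * 1))
}

# A small synthetic feature table: pure-noise features plus optionally
# planted informative columns (mean shift between grades).
syntheticTable <- function(n1 = 30, n2 = 30, p = 500, informative = 0,
                           shift = 2, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  X <- matrix(rnorm(n * p), n, p)
  grade <- c(rep("III", n1), rep("IV", n2))
  if (informative > 0)
    X[grade == "IV", seq_len(informative)] <-
      X[grade == "IV", seq_len(informative)] + shift
  colnames(X) <- sprintf("f%04d", seq_len(p))
  rownames(X) <- sprintf("s%03d", seq_len(n))
  featureTable(t(X), grade = grade)
}

# A tiny preprocessed subject on a small grid for extraction tests.
tinySubject <- function(seed = 1, d = c(24, 24, 24), shiftTumor = 0) {
  set.seed(seed)
  sp <- c(1, 1, 1)
  brain <- array(1, dim = d)
  tumor <- array(0, dim = d)
  tumor[9:15, 9:15, 9:15] <- 1
  base <- array(rnorm(prod(d)), dim = d)
  base[tumor > 0] <- base[tumor > 0] + 1 + shiftTumor
  ce <- zscoreNormalize(vol(base, spacing = sp), msk(brain, spacing = sp))
  t2v <- zscoreNormalize(vol(base * 0.8 + array(rnorm(prod(d), sd = 0.3),
                                                dim = d), spacing = sp),
                         msk(brain, spacing = sp))
  new("PhantomSubject", subjectId = sprintf("tiny%d", seed), grade = "III",
      ceT1 = ce, t2 = t2v, tumorMask = msk(tumor, spacing = sp),
      brainMask = msk(brain, spacing = sp))
}
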