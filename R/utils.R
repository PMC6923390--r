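# Internal helpers: classed errors, separable filtering, connectivity,
# stratified folds, seed substreams.

gliostop <- function(class, msg, ...) {
  stop(structure(class = c(class, "gliorad_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

gliowarn <- function(class, msg, ...) {
  warning(structure(class = c(class, "gliorad_warning", "warning",
                              "condition"),
                    list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Symmetric (edge-repeating, half-sample) boundary index: 0 -> 1, -1 -> 2,
# n+1 -> n, n+2 -> n-1, applied iteratively for deep overruns.
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  i <- (i - 1L) %% period
  ifelse(i < n, i + 1L, period - i)
}

# "Same"-size 1D convolution of a 3D array along one axis with symmetric
# boundary extension: out[m] = sum_k w[k] * x[m - k + ceil(L/2)].
convAxis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  L <- length(kernel)
  off <- as.integer(ceiling(L / 2))
  out <- array(0, dim = d)
  for (k in seq_len(L)) {
    if (kernel[k] == 0) next
    src <- reflectIndex(seq_len(n) - k + off, n)
    shifted <- switch(axis,
                      arr[src, , , drop = FALSE],
                      arr[, src, , drop = FALSE],
                      arr[, , src, drop = FALSE])
    out <- out + kernel[k] * shifted
  }
  out
}

separableConv3 <- function(arr, kx, ky, kz) {
  convAxis(convAxis(convAxis(arr, kx, 1L), ky, 2L), kz, 3L)
}

gaussianKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gaussianSmooth3 <- function(arr, sigma) {
  k <- gaussianKernel1d(sigma)
  separableConv3(arr, k, k, k)
}

# 26-connected component labels of a logical 3D array; 0 outside.
# Implemented as iterative stack-based flood fill over voxel indices.
connComp26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nxt <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cur0 <- cur - 1L
      x <- cur0 %% d[1]
      y <- (cur0 %/% d[1]) %% d[2]
      z <- cur0 %/% (d[1] * d[2])
      nx <- x + offs[, 1]; ny <- y + offs[, 2]; nz <- z + offs[, 3]
      ok <- nx >= 0 & nx < d[1] & ny >= 0 & ny < d[2] & nz >= 0 & nz < d[3]
      nb <- 1L + nx[ok] + d[1] * (ny[ok] + d[2] * nz[ok])
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- nxt
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

is26Connected <- function(mask) {
  lab <- connComp26(mask)
  max(lab) == 1L
}

# Stratified k-fold assignment: within each class, shuffled subjects are
# dealt round-robin so every fold holds both classes whenever each class
# has at least `k` members.
stratifiedFolds <- function(labels, k) {
  classes <- unique(labels)
  if (any(table(labels) < k))
    gliostop("gliorad_stratification",
             "cannot build %d stratified folds: smallest class has %d subjects",
             k, min(table(labels)))
  fold <- integer(length(labels))
  for (cl in classes) {
    ids <- which(labels == cl)
    ids <- ids[sample.int(length(ids))]
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

# Deterministic 31-bit substream seed from a base seed and an index.
subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 11) %%
               2147483647)
}

standardizeTrain <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(X = scale(X, center = ctr, scale = scl), center = ctr, scale = scl)
}

applyStandardization <- function(X, center, scale) {
  scale(X, center = center, scale = scale)
}
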