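# Independent brute-force oracles, written as direct transcriptions of the
# matrix definitions (plain R loops, no shared code with the package
# internals).

DIRS13 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dx > 0 | (g$dx == 0 & g$dy > 0) |
    (g$dx == 0 & g$dy == 0 & g$dz > 0)
  as.matrix(g[keep, ])
})

DIRS26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

inBounds <- function(v, d) all(v >= 1) && all(v <= d)

bfGlcm <- function(lev, ng) {
  d <- dim(lev)
  m <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lev[x, y, z]
    if (li == 0) next
    for (r in seq_len(nrow(DIRS13))) {
      v <- c(x, y, z) + DIRS13[r, ]
      if (!inBounds(v, d)) next
      lj <- lev[v[1], v[2], v[3]]
      if (lj == 0) next
      m[li, lj] <- m[li, lj] + 1
      m[lj, li] <- m[lj, li] + 1
    }
  }
  if (sum(m) > 0) m <- m / sum(m)
  m
}

bfGlrlm <- function(lev, ng) {
  d <- dim(lev)
  maxlen <- max(d)
  m <- matrix(0, ng, maxlen)
  for (r in seq_len(nrow(DIRS13))) {
    dir <- DIRS13[r, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      li <- lev[x, y, z]
      if (li == 0) next
      prev <- c(x, y, z) - dir
      if (inBounds(prev, d) && lev[prev[1], prev[2], prev[3]] == li) next
      len <- 1
      cur <- c(x, y, z) + dir
      while (inBounds(cur, d) && lev[cur[1], cur[2], cur[3]] == li) {
        len <- len + 1
        cur <- cur + dir
      }
      m[li, len] <- m[li, len] + 1
    }
  }
  m[, seq_len(max(1, max(which(colSums(m) > 0)))), drop = FALSE]
}

bfGlszm <- function(lev, ng) {
  d <- dim(lev)
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lev[x, y, z]
    if (li == 0 || seen[x, y, z]) next
    size <- 0
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(DIRS26))) {
        v <- cur + DIRS26[r, ]
        if (!inBounds(v, d)) next
        if (!seen[v[1], v[2], v[3]] && lev[v[1], v[2], v[3]] == li) {
          seen[v[1], v[2], v[3]] <- TRUE
          stack[[length(stack) + 1]] <- v
        }
      }
    }
    zones[[length(zones) + 1]] <- c(li, size)
  }
  maxz <- max(vapply(zones, `[`, numeric(1), 2))
  m <- matrix(0, ng, maxz)
  for (zn in zones) m[zn[1], zn[2]] <- m[zn[1], zn[2]] + 1
  m
}

bfNgldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  m <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lev[x, y, z]
    if (li == 0) next
    k <- 0
    for (r in seq_len(nrow(DIRS26))) {
      v <- c(x, y, z) + DIRS26[r, ]
      if (!inBounds(v, d)) next
      lj <- lev[v[1], v[2], v[3]]
      if (lj != 0 && abs(lj - li) <= alpha) k <- k + 1
    }
    m[li, k + 1] <- m[li, k + 1] + 1
  }
  m
}

bfNgtdm <- function(lev, ng) {
  d <- dim(lev)
  m <- matrix(0, ng, 2)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lev[x, y, z]
    if (li == 0) next
    nb <- c()
    for (r in seq_len(nrow(DIRS26))) {
      v <- c(x, y, z) + DIRS26[r, ]
      if (!inBounds(v, d)) next
      lj <- lev[v[1], v[2], v[3]]
      if (lj != 0) nb <- c(nb, lj)
    }
    if (!length(nb)) next
    m[li, 1] <- m[li, 1] + 1
    m[li, 2] <- m[li, 2] + abs(li - mean(nb))
  }
  m
}

# Random quantized ROI: levels in 1..ng on a random subset, 0 elsewhere.
randomLevels <- function(d, ng, density = 0.6) {
  lev <- array(0L, dim = d)
  mask <- array(runif(prod(d)) < density, dim = d)
  lev[mask] <- sample.int(ng, sum(mask), replace = TRUE)
  lev
}

# Direct (non-separable) 3D "same" convolution with symmetric extension,
# for the wavelet impulse-response check.
bfConv3 <- function(arr, k3) {
  d <- dim(arr)
  L <- dim(k3)
  off <- ceiling(L / 2)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 1 - i, i)
      i <- ifelse(i > n, 2 * n + 1 - i, i)
    }
    i
  }
  out <- array(0, dim = d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    acc <- 0
    for (a in 1:L[1]) for (b in 1:L[2]) for (cc in 1:L[3]) {
      sx <- refl(x - a + off[1], d[1])
      sy <- refl(y - b + off[2], d[2])
      sz <- refl(z - cc + off[3], d[3])
      acc <- acc + k3[a, b, cc] * arr[sx, sy, sz]
    }
    out[x, y, z] <- acc
  }
  out
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (tie-free data).
bfWmwP <- function(x1, x2) {
  n1 <- length(x1)
  all <- c(x1, x2)
  u <- sum(rank(all)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n1n2 <- n1 * length(x2)
  dev <- abs(u - n1n2 / 2)
  sets <- utils::combn(length(all), n1)
  us <- apply(sets, 2, function(idx)
    sum(rank(all)[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - n1n2 / 2) >= dev - 1e-12)
}

# Brute-force pairwise AUC with half credit for ties.
bfAuc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}
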