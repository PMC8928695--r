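# Small construction helpers and independent oracles used across tests.

vg <- function(data, spacing = c(1, 1, 1)) VolumeGrid(data, spacing)

# a TissueProbabilitySet from per-class values (scalars or arrays) on a
# common small grid
makeProbSet <- function(dims = c(4, 4, 4), grey = 0, white = 0, csf = 0,
                        soft = 0, bone = 0, air = 0) {
  mk <- function(x) vg(array(x, dims))
  TissueProbabilitySet(grey = mk(grey), white = mk(white), csf = mk(csf),
                       soft = mk(soft), bone = mk(bone), air = mk(air))
}

# queue-based breadth-first flood fill, written independently of the
# package's vectorized dilation implementation
bfFloodFill <- function(mask, seeds, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L)
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  seen <- array(FALSE, d)
  queue <- lapply(seq_len(nrow(seeds)), function(r) seeds[r, ])
  for (s in queue) seen[s[1], s[2], s[3]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (r in seq_len(nrow(offs))) {
      nb <- cur + offs[r, ]
      if (any(nb < 1) || any(nb > d)) next
      if (mask[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
        seen[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1L]] <- nb
      }
    }
  }
  seen
}

# exhaustive brute-force cuboid search: every sub-cuboid, direct summation,
# same tie rules as the search contract (goodness, then volume, then
# lexicographic)
bfBestCuboid <- function(p, minDim = 3L, penalty = "edges") {
  d <- dim(p)
  best <- NULL
  for (l3 in 1:d[3]) for (h3 in l3:d[3]) {
    if (h3 - l3 + 1 < minDim) next
    for (l2 in 1:d[2]) for (h2 in l2:d[2]) {
      if (h2 - l2 + 1 < minDim) next
      for (l1 in 1:d[1]) for (h1 in l1:d[1]) {
        if (h1 - l1 + 1 < minDim) next
        ps <- sum(p[l1:h1, l2:h2, l3:h3])
        dims <- c(h1 - l1 + 1, h2 - l2 + 1, h3 - l3 + 1)
        pen <- if (penalty == "edges") sum(dims)^2
               else ((dims[1] + dims[2]) / 2)^2
        cg <- ps / pen
        cand <- list(lo = c(l1, l2, l3), hi = c(h1, h2, h3), cg = cg,
                     vol = prod(dims))
        if (is.null(best) || cg > best$cg ||
            (cg == best$cg && (cand$vol < best$vol ||
              (cand$vol == best$vol &&
               lexLess(c(cand$lo, cand$hi), c(best$lo, best$hi))))))
          best <- cand
      }
    }
  }
  best
}

lexLess <- function(a, b) {
  for (t in seq_along(a)) {
    if (a[t] < b[t]) return(TRUE)
    if (a[t] > b[t]) return(FALSE)
  }
  FALSE
}

# dense-sampling oracle for the distance from a point to the normalized
# three-segment conversion polyline
curveDistOracle <- function(point, mLow, mHigh, scales, nSamp = 1e5,
                            plateauLen = 5) {
  a <- mLow / scales[["mri"]]; b <- mHigh / scales[["mri"]]
  x <- point[1] / scales[["mri"]]; y <- point[2] / scales[["hu"]]
  yAir <- -1000 / scales[["hu"]]
  t1 <- seq(a - plateauLen, a, length.out = nSamp)
  t2 <- seq(a, b, length.out = nSamp)
  t3 <- seq(b, b + plateauLen, length.out = nSamp)
  cx <- c(t1, t2, t3)
  cy <- c(rep(yAir, nSamp), yAir + (t2 - a) / (b - a) * (0 - yAir),
          rep(0, nSamp))
  sqrt(min((cx - x)^2 + (cy - y)^2))
}
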