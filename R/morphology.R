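# Internal binary-morphology helpers on logical 3-D arrays.
#
# All routines work on a 1-voxel zero-padded copy so that linear-index
# neighbour offsets never wrap across array edges.

padArray <- function(a) {
  d <- dim(a)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- a
  p
}

unpadArray <- function(p) {
  d <- dim(p) - 2L
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
}

# linear-index offsets of a neighbourhood in a padded array
neighbourOffsets <- function(dimPadded, connectivity = 26L) {
  d1 <- dimPadded[1]; d2 <- dimPadded[2]
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1L, ]
  else if (connectivity == 18L)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) <= 2L, ]
  else if (connectivity != 26L)
    stop("connectivity must be 6, 18 or 26")
  offs$dx + offs$dy * d1 + offs$dz * d1 * d2
}

# one dilation step restricted to a mask (both padded); frontier given as
# linear indices; returns newly reached indices
spreadStep <- function(reached, frontier, maskIdx, offsets) {
  cand <- unique(as.vector(outer(frontier, offsets, `+`)))
  cand <- cand[maskIdx[cand] & !reached[cand]]
  cand
}

# flood fill within `mask` starting from seed linear indices (padded space
# handled internally); returns a logical array of the reached set
floodFill <- function(mask, seedsIdx, connectivity = 26L) {
  d <- dim(mask)
  p <- padArray(mask)
  offs <- neighbourOffsets(dim(p), connectivity)
  # map unpadded linear indices to padded ones
  co <- arrayInd(seedsIdx, d)
  padIdx <- (co[, 1] + 1L) + (co[, 2]) * dim(p)[1] +
    (co[, 3]) * dim(p)[1] * dim(p)[2]
  reached <- array(FALSE, dim(p))
  reached[padIdx] <- TRUE
  frontier <- padIdx
  while (length(frontier)) {
    frontier <- spreadStep(reached, frontier, p, offs)
    reached[frontier] <- TRUE
  }
  unpadArray(reached)
}

# connected-component labelling of a logical array; returns integer array
labelComponents <- function(mask, connectivity = 26L) {
  lab <- array(0L, dim(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    seed <- which(remaining)[1]
    comp <- floodFill(remaining, seed, connectivity)
    lab[comp] <- k
    remaining <- remaining & !comp
  }
  lab
}

# 2-D component labelling of a slice (8- or 4-connectivity) by embedding
labelComponents2D <- function(slice, connectivity = 8L) {
  m3 <- array(slice, c(dim(slice), 1L))
  conn3 <- if (connectivity == 8L) 26L else 6L
  lab3 <- labelComponents(m3, conn3)
  lab3[, , 1]
}

# binary dilation / erosion with the 3x3x3 (26-neighbourhood) structuring
# element, repeated `iter` times
dilate3 <- function(mask, iter = 1L) {
  p <- padArray(mask)
  offs <- c(0L, neighbourOffsets(dim(p), 26L))
  for (i in seq_len(iter)) {
    idx <- which(p)
    hit <- unique(as.vector(outer(idx, offs, `+`)))
    p[hit] <- TRUE
    # clear the pad border so growth cannot creep along it
    p <- padArray(unpadArray(p))
  }
  unpadArray(p)
}

erode3 <- function(mask, iter = 1L) !dilate3(!mask, iter)

# fill interior holes: background is what is 6-connected to the array border
fillHoles <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  seeds <- which(bg & border)
  if (!length(seeds)) return(array(TRUE, d))
  outside <- floodFill(bg, seeds, connectivity = 6L)
  mask | (bg & !outside)
}
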