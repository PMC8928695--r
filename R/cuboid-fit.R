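# Cuboid fitting: summed-volume tables for constant-time box sums, the
# cuboid-goodness score, and the lattice search with local refinement.

#' SummedVolume: 3-D inclusion-exclusion prefix table
#'
#' Cumulative sums of a scalar volume along all three axes, enabling O(1)
#' sums over any axis-aligned box.
#'
#' @slot table 3-D numeric array of prefix sums.
#' @export
setClass("SummedVolume", representation(table = "array"))

#' Build a summed-volume table
#'
#' @param p a \linkS4class{VolumeGrid} (or plain 3-D array) of finite
#'   values, typically the bone probability map.
#' @return A \linkS4class{SummedVolume}.
#' @export
buildSummedVolume <- function(p) {
  a <- if (is(p, "VolumeGrid")) p@data else as.array(p)
  if (any(!is.finite(a))) stop("summed volume requires finite values")
  s <- apply(a, c(2, 3), cumsum)                     # along axis 1
  s <- aperm(apply(s, c(1, 3), cumsum), c(2, 1, 3))  # along axis 2
  s <- aperm(apply(s, c(1, 2), cumsum), c(2, 3, 1))  # along axis 3
  new("SummedVolume", table = s)
}

#' O(1) box sum from a summed-volume table
#'
#' @param svt a \linkS4class{SummedVolume}.
#' @param lo,hi inclusive 1-based corner indices; vectors of length 3 or
#'   n x 3 matrices for vectorized evaluation.
#' @return Numeric vector of box sums.
#' @export
boxSum <- function(svt, lo, hi) {
  S <- svt@table
  d <- dim(S)
  lo <- matrix(as.integer(lo), ncol = 3)
  hi <- matrix(as.integer(hi), ncol = 3)
  at <- function(i, j, k) {
    v <- numeric(length(i))
    ok <- i >= 1L & j >= 1L & k >= 1L
    v[ok] <- S[cbind(i[ok], j[ok], k[ok])]
    v
  }
  at(hi[, 1], hi[, 2], hi[, 3]) -
    at(lo[, 1] - 1L, hi[, 2], hi[, 3]) -
    at(hi[, 1], lo[, 2] - 1L, hi[, 3]) -
    at(hi[, 1], hi[, 2], lo[, 3] - 1L) +
    at(lo[, 1] - 1L, lo[, 2] - 1L, hi[, 3]) +
    at(lo[, 1] - 1L, hi[, 2], lo[, 3] - 1L) +
    at(hi[, 1], lo[, 2] - 1L, lo[, 3] - 1L) -
    at(lo[, 1] - 1L, lo[, 2] - 1L, lo[, 3] - 1L)
}

#' Cuboid goodness: bone coverage against box size
#'
#' \eqn{CG = \sum_{i \in C} p_i / (c/4)^2} where \eqn{c} is the cuboid
#' perimeter. A 3-D solid has no canonical perimeter; the default reading
#' takes \eqn{c} as the total edge length \eqn{4(a+b+h)} of the box, hence
#' \eqn{CG = p_{sum} / (a+b+h)^2}. The alternative \code{"slice"} reading
#' uses the per-slice rectangle perimeter \eqn{2(a+b)}.
#'
#' @param pSum nonnegative sum of bone probability inside the cuboid.
#' @param dims voxel extents (a, b, h), each >= 1.
#' @param penalty \code{"edges"} (default) or \code{"slice"}.
#' @return The goodness value.
#' @export
cuboidGoodness <- function(pSum, dims, penalty = c("edges", "slice")) {
  penalty <- match.arg(penalty)
  if (any(dims < 1)) stop("cuboid dimensions must be >= 1")
  if (penalty == "edges") pSum / sum(dims)^2
  else pSum / ((dims[1] + dims[2]) / 2)^2
}

#' Initial cuboid search region around the air cavities
#'
#' A large box in the front half of the head extending above and below the
#' air cavities: the anterior half of the head's anterior-posterior extent
#' (anterior = low index on axis 2), with the lateral and axial extents
#' given by the air-cavity bounding box padded by \code{marginSlices} and
#' clipped to the head box. Bounding the lateral extent to the cavity
#' neighbourhood keeps the search anchored on the sinus; an unrestricted
#' lateral window lets the goodness optimum latch onto the temporal skull
#' shell instead.
#'
#' @param headMask binary \linkS4class{VolumeGrid} of the head.
#' @param airCavities binary \linkS4class{VolumeGrid} of delineated
#'   cavities.
#' @param marginSlices padding around the cavity bounds, in voxels
#'   (default 5).
#' @return A \linkS4class{CuboidRegion}.
#' @export
initialSearchRegion <- function(headMask, airCavities, marginSlices = 5L) {
  stopIfGridMismatch(headMask, airCavities)
  hb <- boundingBox(asMaskArray(headMask))
  ab <- boundingBox(asMaskArray(airCavities))
  if (is.null(hb) || is.null(ab)) stop("empty mask")
  lo <- c(max(hb$lo[1], ab$lo[1] - marginSlices), hb$lo[2],
          max(hb$lo[3], ab$lo[3] - marginSlices))
  hi <- c(min(hb$hi[1], ab$hi[1] + marginSlices),
          floor((hb$lo[2] + hb$hi[2]) / 2),
          min(hb$hi[3], ab$hi[3] + marginSlices))
  CuboidRegion(lo, hi)
}

#' Search for the best cuboid by goodness
#'
#' Maximises \code{\link{cuboidGoodness}} over axis-aligned sub-cuboids of
#' \code{region} whose corners lie on a stride lattice, then refines the
#' optimum at stride 1 within one stride of each corner. Ties resolve to
#' the smaller volume, then to the lexicographically smallest corner
#' coordinates.
#'
#' @param boneProb \linkS4class{VolumeGrid} of bone probability.
#' @param region \linkS4class{CuboidRegion} to search within.
#' @param stride lattice spacing in voxels (>= 1).
#' @param minDim minimum cuboid extent per axis (default 3).
#' @param penalty see \code{\link{cuboidGoodness}}.
#' @param refine run the stride-1 local refinement (default TRUE).
#' @return List with \code{region} (a \linkS4class{CuboidRegion} in
#'   full-volume coordinates) and \code{cg} (its goodness).
#' @export
searchBestCuboid <- function(boneProb, region, stride = 2L, minDim = 3L,
                             penalty = c("edges", "slice"), refine = TRUE) {
  penalty <- match.arg(penalty)
  if (stride < 1L) stop("stride must be >= 1")
  d <- dim(boneProb@data)
  if (any(region@hi > d)) stop("region exceeds volume bounds")
  n <- cuboidDims(region)
  if (any(n < minDim))
    stop("search region smaller than the minimum cuboid")
  crop <- boneProb@data[region@lo[1]:region@hi[1],
                        region@lo[2]:region@hi[2],
                        region@lo[3]:region@hi[3], drop = FALSE]
  svt <- buildSummedVolume(crop)
  mode <- if (penalty == "edges") 0L else 1L
  cand <- lapply(1:3, function(ax) as.integer(seq(1L, n[ax], by = stride)))
  best <- .bestCuboidCpp(as.numeric(svt@table), dim(svt@table),
                         cand[[1]], cand[[1]], cand[[2]], cand[[2]],
                         cand[[3]], cand[[3]], as.integer(minDim), mode)
  if (refine && stride > 1L) {
    win <- function(ax, centre) {
      as.integer(max(1L, centre - stride):min(n[ax], centre + stride))
    }
    best <- .bestCuboidCpp(as.numeric(svt@table), dim(svt@table),
                           win(1, best$lo[1]), win(1, best$hi[1]),
                           win(2, best$lo[2]), win(2, best$hi[2]),
                           win(3, best$lo[3]), win(3, best$hi[3]),
                           as.integer(minDim), mode)
  }
  list(region = CuboidRegion(best$lo + region@lo - 1L,
                             best$hi + region@lo - 1L),
       cg = best$cg)
}
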