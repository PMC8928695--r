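# Sinus air-cavity delineation: interior air mask, axial slice profile,
# seed-slice selection, centre-of-mass seeding and 3-D region growing.

#' Initial mask of air inside the head
#'
#' Air-classified voxels restricted to the interior of the head envelope.
#' The envelope is the morphological fill (binary closing followed by
#' hole-filling) of the union of the soft, brain and bone masks, so the
#' mask keeps interior air -- sinus cavities, throat, stray pockets --
#' while excluding the background air around the head.
#'
#' @param probmaps a \linkS4class{TissueProbabilitySet}.
#' @param thresholds from \code{\link{classThresholds}}.
#' @return Binary \linkS4class{VolumeGrid}.
#' @export
initialAirMask <- function(probmaps, thresholds = classThresholds()) {
  interior <- headMask(probmaps, thresholds)
  airSel <- probmaps@air@data >= thresholds[["air"]] &
    asMaskArray(interior)
  maskVolume(probmaps@air, airSel)
}

#' Head envelope from probability maps
#'
#' The filled head: union of the thresholded soft, bone and brain masks,
#' closed morphologically (bridging pinholes) and hole-filled, so interior
#' air (sinus cavities, throat) lies inside the envelope while background
#' air does not.
#'
#' @param probmaps a \linkS4class{TissueProbabilitySet}.
#' @param thresholds from \code{\link{classThresholds}}.
#' @return Binary \linkS4class{VolumeGrid}.
#' @export
headMask <- function(probmaps, thresholds = classThresholds()) {
  stopIfGridMismatch(probmaps@soft, probmaps@bone, probmaps@air)
  brainP <- probmaps@grey@data + probmaps@white@data + probmaps@csf@data
  body <- probmaps@soft@data >= thresholds[["soft"]] |
    probmaps@bone@data >= thresholds[["bone"]] |
    brainP >= thresholds[["brain"]]
  closed <- erode3(dilate3(body, 1L), 1L)
  maskVolume(probmaps@air, fillHoles(closed))
}

#' Per-slice voxel counts of a binary mask along the axial axis
#'
#' @param mask binary \linkS4class{VolumeGrid}.
#' @return Integer vector of per-axial-slice sums (length = number of
#'   slices).
#' @export
sliceProfile <- function(mask) {
  as.integer(apply(asMaskArray(mask), 3, sum))
}

#' Select the seed slice from a slice profile
#'
#' Scanning in ascending slice order, the largest single inter-slice
#' decrease \code{sums[i] - sums[i+1]} is located (ties broken toward the
#' smallest index). The seed slice is the largest local maximum of the
#' profile at or before that index; among equal maxima the one closest to
#' the drop wins. Boundary slices count as local maxima against a virtual
#' -Inf neighbour.
#'
#' @param profile integer vector from \code{\link{sliceProfile}}.
#' @return 1-based slice index.
#' @export
selectSeedSlice <- function(profile) {
  if (all(profile == 0)) stop("slice profile is all zero")
  n <- length(profile)
  if (n == 1L) return(1L)
  drops <- profile[-n] - profile[-1]
  iDrop <- which.max(drops)            # ties -> smallest index
  ext <- c(-Inf, profile, -Inf)
  isMax <- profile >= ext[seq_len(n)] & profile >= ext[seq_len(n) + 2L]
  cand <- which(isMax & seq_len(n) <= iDrop)
  cand[which(profile[cand] == max(profile[cand]))] |> max()
}

#' Seed voxels of a slice by centre of mass per 2-D component
#'
#' Each 8-connected 2-D component of the mask slice contributes one seed:
#' its centre of mass snapped to the nearest in-component voxel (ties
#' broken lexicographically).
#'
#' @param mask binary \linkS4class{VolumeGrid}.
#' @param sliceIdx 1-based axial slice index.
#' @return Integer matrix of seed voxel coordinates (columns i, j, k).
#' @export
selectSeeds <- function(mask, sliceIdx) {
  sl <- asMaskArray(mask)[, , sliceIdx]
  if (!any(sl)) stop("selected slice contains no mask voxels")
  lab <- labelComponents2D(sl, connectivity = 8L)
  seeds <- t(vapply(seq_len(max(lab)), function(k) {
    co <- which(lab == k, arr.ind = TRUE)
    com <- colMeans(co)
    d2 <- (co[, 1] - com[1])^2 + (co[, 2] - com[2])^2
    best <- which(d2 == min(d2))
    ord <- order(co[best, 1], co[best, 2])
    as.integer(co[best[ord[1]], ])
  }, integer(2)))
  cbind(seeds, sliceIdx)
}

#' Grow air cavities from seed voxels
#'
#' Union of the 26-connected 3-D components of the mask that contain at
#' least one seed; pockets not connected to any seed (e.g. the throat) are
#' excluded.
#'
#' @param mask binary \linkS4class{VolumeGrid}.
#' @param seeds integer matrix of voxel coordinates (rows), as returned by
#'   \code{\link{selectSeeds}}.
#' @return Binary \linkS4class{VolumeGrid}, a subset of \code{mask}.
#' @export
growAirCavities <- function(mask, seeds) {
  m <- asMaskArray(mask)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  lin <- seeds[, 1] + (seeds[, 2] - 1L) * dim(m)[1] +
    (seeds[, 3] - 1L) * dim(m)[1] * dim(m)[2]
  if (any(!m[lin])) stop("seed outside mask")
  maskVolume(mask, floodFill(m, lin, connectivity = 26L))
}

#' Full air-cavity delineation pipeline
#'
#' Runs initial mask, slice profile, seed-slice selection, seeding and
#' region growing in sequence. Deterministic given its inputs.
#'
#' @param probmaps a \linkS4class{TissueProbabilitySet}.
#' @param thresholds from \code{\link{classThresholds}}.
#' @return List with \code{mask} (grown cavities), \code{initialMask},
#'   \code{profile}, \code{seedSlice} and \code{seeds}.
#' @export
delineateAirCavities <- function(probmaps, thresholds = classThresholds()) {
  init <- initialAirMask(probmaps, thresholds)
  prof <- sliceProfile(init)
  k <- selectSeedSlice(prof)
  seeds <- selectSeeds(init, k)
  grown <- growAirCavities(init, seeds)
  list(mask = grown, initialMask = init, profile = prof,
       seedSlice = k, seeds = seeds)
}
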