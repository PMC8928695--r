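# Quantitative comparison of attenuation maps and attenuation-corrected
# PET volumes: Dice overlap, correlation sampling, sinus VOI statistics,
# VOI relative differences and voxelwise bias atlases.

#' Dice overlap coefficient of two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}. Two empty masks agree perfectly on
#' absence and score 1 by convention (configurable).
#'
#' @param a,b aligned binary \linkS4class{VolumeGrid}s.
#' @param emptyValue value when both masks are empty (default 1).
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b, emptyValue = 1) {
  stopIfGridMismatch(a, b)
  ma <- asMaskArray(a); mb <- asMaskArray(b)
  denom <- sum(ma) + sum(mb)
  if (denom == 0) return(emptyValue)
  2 * sum(ma & mb) / denom
}

#' Bone masks for Dice analysis
#'
#' CT mask: voxels with HU strictly above the bone threshold (157 HU by
#' convention, corresponding to 0.105 cm^-1). MRAC mask: attenuation-map
#' voxels strictly above the matching coefficient -- with discrete class
#' values this selects exactly the bone class (0.151 cm^-1).
#'
#' @param ct \linkS4class{VolumeGrid} in HU.
#' @param mrac a \linkS4class{MuMap}.
#' @param huThreshold bone threshold in HU (default 157).
#' @param muThreshold matching attenuation threshold in cm^-1
#'   (default 0.105).
#' @return List with binary \code{ct} and \code{mrac} masks.
#' @export
boneMasksForDice <- function(ct, mrac, huThreshold = 157,
                             muThreshold = 0.105) {
  stopIfGridMismatch(ct, mrac@mu)
  list(ct = maskVolume(ct, !is.nan(ct@data) & ct@data > huThreshold),
       mrac = maskVolume(mrac@mu, mrac@mu@data > muThreshold))
}

#' Axial sub-volume of the sinus evaluation window
#'
#' Inclusive 1-based axial crop; the default (50, 70) spans 21 slices,
#' i.e. 4.2 cm at 2 mm voxels.
#'
#' @param v a \linkS4class{VolumeGrid}.
#' @param sliceRange inclusive (first, last) 1-based slice pair.
#' @return Cropped \linkS4class{VolumeGrid} (affine translated
#'   accordingly).
#' @export
sinusSubvolume <- function(v, sliceRange = c(50L, 70L)) {
  d <- dim(v@data)
  if (sliceRange[1] > sliceRange[2])
    stop("slice range must be increasing")
  if (sliceRange[1] < 1 || sliceRange[2] > d[3])
    stop("slice range outside the volume")
  aff <- v@affine
  aff[, 4] <- aff[, 4] + aff[, 3] * (sliceRange[1] - 1)
  VolumeGrid(v@data[, , sliceRange[1]:sliceRange[2], drop = FALSE],
             spacing = v@spacing, affine = aff)
}

#' Repeated Pearson correlation between paired attenuation volumes
#'
#' Each repeat draws \code{nVox} voxel locations without replacement from
#' the inclusion mask and computes the Pearson correlation between the
#' paired values of the two volumes there. Repeats with zero variance in
#' either draw record NA.
#'
#' @param ctMu,mracMu aligned \linkS4class{VolumeGrid}s (cm^-1).
#' @param includeMask aligned binary mask of eligible voxels (by
#'   convention the CT bone mask, HU > 157); needs >= \code{nVox} voxels.
#' @param nVox voxels per repeat (default 200).
#' @param nReps repeats (default 100).
#' @param seed RNG seed.
#' @return Numeric vector of \code{nReps} correlations.
#' @export
sampleCorrelations <- function(ctMu, mracMu, includeMask, nVox = 200L,
                               nReps = 100L, seed = 1L) {
  stopIfGridMismatch(ctMu, mracMu, includeMask)
  pool <- which(asMaskArray(includeMask))
  if (length(pool) < nVox)
    stop("inclusion mask has fewer voxels than nVox")
  withSeed(seed, {
    vapply(seq_len(nReps), function(r) {
      idx <- pool[sample.int(length(pool), nVox)]
      x <- ctMu@data[idx]; y <- mracMu@data[idx]
      if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
      cor(x, y)
    }, numeric(1))
  })
}

#' Mean attenuation coefficient over a volume of interest
#'
#' @param mu a \linkS4class{MuMap} or \linkS4class{VolumeGrid} (cm^-1).
#' @param voi aligned nonempty binary \linkS4class{VolumeGrid}.
#' @return Mean attenuation in cm^-1.
#' @export
voiMeanMu <- function(mu, voi) {
  v <- if (is(mu, "MuMap")) mu@mu else mu
  stopIfGridMismatch(v, voi)
  sel <- asMaskArray(voi)
  if (!any(sel)) stop("empty VOI")
  mean(v@data[sel])
}

#' Per-VOI relative difference between two PET volumes
#'
#' For each label of the atlas, restricted to voxels whose grey-matter
#' probability passes the threshold, computes
#' \eqn{(mean(PET_{MRAC}) - mean(PET_{CTAC})) / mean(PET_{CTAC})}.
#' Labels whose masked region is empty are reported absent; VOIs with a
#' zero reference mean record NA.
#'
#' @param petMrac,petCtac aligned PET \linkS4class{VolumeGrid}s.
#' @param labels aligned integer atlas \linkS4class{VolumeGrid}
#'   (0 = outside).
#' @param gmProb aligned grey-matter probability \linkS4class{VolumeGrid}.
#' @param gmThreshold inclusion threshold (default 0.8).
#' @return data.frame with columns \code{voi}, \code{nVoxels},
#'   \code{relDiff}.
#' @export
voiRelDiff <- function(petMrac, petCtac, labels, gmProb, gmThreshold = 0.8) {
  stopIfGridMismatch(petMrac, petCtac, labels, gmProb)
  lab <- labels@data
  if (any(lab < 0)) stop("atlas labels must be nonnegative")
  gmSel <- gmProb@data >= gmThreshold
  present <- sort(unique(lab[lab > 0 & gmSel]))
  rows <- lapply(present, function(L) {
    sel <- lab == L & gmSel
    mMrac <- mean(petMrac@data[sel])
    mCtac <- mean(petCtac@data[sel])
    data.frame(voi = L, nVoxels = sum(sel),
               relDiff = if (mCtac == 0) NA_real_
                         else (mMrac - mCtac) / mCtac)
  })
  if (!length(rows))
    return(data.frame(voi = integer(), nVoxels = integer(),
                      relDiff = numeric()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Voxelwise mean bias atlas across a cohort
#'
#' Per subject the voxelwise relative difference
#' \eqn{(PET_{MRAC} - PET_{CTAC}) / PET_{CTAC}} is computed, then averaged
#' voxelwise across subjects and masked by the brain mask. Voxels with a
#' zero reference in any subject propagate NA (never silently dropped);
#' voxels outside the mask are NA.
#'
#' @param pairs list of two-element lists \code{list(mrac =, ctac =)} of
#'   co-registered \linkS4class{VolumeGrid}s.
#' @param brainMask binary \linkS4class{VolumeGrid} in the common space.
#' @return \linkS4class{VolumeGrid} of mean relative differences.
#' @export
biasAtlas <- function(pairs, brainMask) {
  if (!length(pairs)) stop("empty subject list")
  acc <- array(0, dim(brainMask@data))
  for (p in pairs) {
    stopIfGridMismatch(p$mrac, p$ctac, brainMask)
    ref <- p$ctac@data
    rel <- (p$mrac@data - ref) / ref
    rel[ref == 0] <- NA_real_
    acc <- acc + rel
  }
  acc <- acc / length(pairs)
  acc[!asMaskArray(brainMask)] <- NA_real_
  withData(brainMask, acc)
}
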