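# Four-class MR-based attenuation maps, the CT-based reference map, and the
# bulk / model-based sinus assignments.

#' Class-probability thresholds for tissue classification
#'
#' Defaults follow the established segmentation recipe: 0.25 for air, 0.50
#' for soft tissue, 0.25 for bone and 0.5 for brain tissue (grey + white +
#' CSF combined).
#'
#' @param air,soft,bone,brain probabilities in (0,1).
#' @return Named numeric vector of thresholds.
#' @export
classThresholds <- function(air = 0.25, soft = 0.50, bone = 0.25,
                            brain = 0.5) {
  th <- c(air = air, soft = soft, bone = bone, brain = brain)
  if (any(th <= 0) || any(th >= 1)) stop("thresholds must lie in (0,1)")
  th
}

#' Linear attenuation coefficients (511 keV) per tissue class
#'
#' Defaults: 0.0 cm^-1 air, 0.096 cm^-1 soft tissue, 0.0985 cm^-1 brain,
#' 0.151 cm^-1 bone, and 0.100 cm^-1 for the fixed bulk sinus assignment.
#' (A brain coefficient an order of magnitude above water is physically
#' impossible at 511 keV; 0.0985 cm^-1 is the intended value, but the slot
#' is configurable.)
#'
#' @param air,soft,brain,bone,bulkSinus coefficients in cm^-1, each in
#'   \[0, 0.2\].
#' @return Named numeric vector of coefficients.
#' @export
muCoefficients <- function(air = 0.0, soft = 0.096, brain = 0.0985,
                           bone = 0.151, bulkSinus = 0.100) {
  mu <- c(air = air, soft = soft, brain = brain, bone = bone,
          bulkSinus = bulkSinus)
  if (any(mu < 0) || any(mu > 0.2))
    stop("attenuation coefficients must lie in [0, 0.2] cm^-1")
  mu
}

#' Classify voxels into air / soft / brain / bone from probability maps
#'
#' Grey matter, white matter and CSF are pooled into a single brain
#' probability. Each class mask is thresholded, then the masks are combined
#' innermost-out with precedence brain > bone > soft > air; voxels passing
#' no threshold default to air.
#'
#' @param probmaps a \linkS4class{TissueProbabilitySet}.
#' @param thresholds from \code{\link{classThresholds}}.
#' @return Integer label \linkS4class{VolumeGrid}
#'   (codes of \code{\link{tissueLabels}}).
#' @export
classifyTissues <- function(probmaps, thresholds = classThresholds()) {
  stopIfGridMismatch(probmaps@grey, probmaps@soft, probmaps@bone,
                     probmaps@air)
  lb <- tissueLabels()
  brainP <- probmaps@grey@data + probmaps@white@data + probmaps@csf@data
  lab <- array(lb[["air"]], dim(brainP))
  lab[probmaps@soft@data >= thresholds[["soft"]]] <- lb[["soft"]]
  lab[probmaps@bone@data >= thresholds[["bone"]]] <- lb[["bone"]]
  lab[brainP >= thresholds[["brain"]]] <- lb[["brain"]]
  withData(probmaps@grey, lab)
}

#' Map class labels to attenuation coefficients
#'
#' Lookup-table assignment of the four base classes; sinus labels
#' (\code{bulkSinus}, \code{convertedSinus}) are produced later by
#' \code{\link{applyBulkSinus}} / \code{\link{applyConvertedSinus}} and are
#' rejected here.
#'
#' @param labels integer label \linkS4class{VolumeGrid}.
#' @param coeffs from \code{\link{muCoefficients}}.
#' @return A \linkS4class{MuMap}.
#' @export
assignMu <- function(labels, coeffs = muCoefficients()) {
  lb <- tissueLabels()
  lut <- c(coeffs[["air"]], coeffs[["soft"]], coeffs[["brain"]],
           coeffs[["bone"]])
  lab <- labels@data
  if (any(!(lab %in% lb[c("air", "soft", "brain", "bone")])))
    stop("unknown label code in label volume")
  mu <- array(lut[lab + 1L], dim(lab))
  MuMap(mu = withData(labels, mu), labels = labels)
}

#' Fixed bulk assignment for the sinus region
#'
#' Sets every voxel of the sinus mask to the fixed bulk coefficient
#' (default 0.100 cm^-1) and relabels it \code{bulkSinus}; all other voxels
#' are untouched.
#'
#' @param m a \linkS4class{MuMap}.
#' @param sinusMask aligned binary \linkS4class{VolumeGrid}.
#' @param coeffs from \code{\link{muCoefficients}}.
#' @return Updated \linkS4class{MuMap}.
#' @export
applyBulkSinus <- function(m, sinusMask, coeffs = muCoefficients()) {
  stopIfGridMismatch(m@mu, sinusMask)
  sel <- asMaskArray(sinusMask)
  mu <- m@mu@data; lab <- m@labels@data
  mu[sel] <- coeffs[["bulkSinus"]]
  lab[sel] <- tissueLabels()[["bulkSinus"]]
  MuMap(withData(m@mu, mu), withData(m@labels, lab))
}

#' Model-based conversion of bone voxels inside the sinus region
#'
#' Only voxels labelled bone inside the region are modified: the conversion
#' model predicts a CT number from the voxel's MRI intensity, which is then
#' expressed as an air/soft-tissue mix,
#' \eqn{\mu = \mu_{soft} (HU + 1000)/1000}, clamped to
#' \eqn{[0, \mu_{soft}]}. Modified voxels are relabelled
#' \code{convertedSinus}.
#'
#' @param m a \linkS4class{MuMap}.
#' @param region a \linkS4class{CuboidRegion} or an aligned binary mask
#'   \linkS4class{VolumeGrid} (e.g. a warped template).
#' @param mri aligned MRI \linkS4class{VolumeGrid}.
#' @param model a fitted \linkS4class{ConversionModel}.
#' @param coeffs from \code{\link{muCoefficients}}.
#' @return Updated \linkS4class{MuMap}.
#' @export
applyConvertedSinus <- function(m, region, mri, model,
                                coeffs = muCoefficients()) {
  stopIfGridMismatch(m@mu, mri)
  validObject(model)
  regMask <- if (is(region, "CuboidRegion"))
    asMaskArray(cuboidMask(region, m@mu)) else {
      stopIfGridMismatch(m@mu, region)
      asMaskArray(region)
    }
  sel <- regMask & m@labels@data == tissueLabels()[["bone"]]
  mu <- m@mu@data; lab <- m@labels@data
  hu <- predictHu(model, mri@data[sel])
  mu[sel] <- pmin(pmax(coeffs[["soft"]] * (hu + 1000) / 1000, 0),
                  coeffs[["soft"]])
  lab[sel] <- tissueLabels()[["convertedSinus"]]
  MuMap(withData(m@mu, mu), withData(m@labels, lab))
}

#' Bilinear HU to attenuation-coefficient parameters
#'
#' Two-segment linear scaling for a 120 kVp acquisition: below the break at
#' 0 HU the slope maps -1000 HU (air) to 0 and 0 HU (water) to the
#' soft-tissue coefficient; above the break the slope is fixed by the
#' boundary correspondence 157 HU = 0.105 cm^-1 between non-bone and bone.
#' The transform is continuous at the break and clamps at -1000 HU.
#'
#' @param muSoft soft-tissue coefficient at 0 HU (cm^-1).
#' @param breakHu HU value of the slope break.
#' @param muAtBoneThreshold,boneThresholdHu the bone-boundary
#'   correspondence fixing the upper slope.
#' @return List of bilinear parameters.
#' @export
bilinearParams <- function(muSoft = 0.096, breakHu = 0,
                           muAtBoneThreshold = 0.105,
                           boneThresholdHu = 157) {
  slopeLow <- muSoft / 1000
  muBreak <- slopeLow * (breakHu + 1000)
  slopeHigh <- (muAtBoneThreshold - muBreak) /
    (boneThresholdHu - breakHu)
  list(slopeLow = slopeLow, breakHu = breakHu, muBreak = muBreak,
       slopeHigh = slopeHigh)
}

#' Convert CT numbers to 511 keV attenuation coefficients
#'
#' @param hu numeric vector/array or \linkS4class{VolumeGrid} of CT numbers.
#' @param params from \code{\link{bilinearParams}}.
#' @return Same container type as \code{hu}, in cm^-1. NaN inputs (coverage
#'   sentinel) propagate as NaN.
#' @export
huToMu <- function(hu, params = bilinearParams()) {
  if (is(hu, "VolumeGrid")) return(withData(hu, huToMu(hu@data, params)))
  h <- pmax(hu, -1000)
  ifelse(h <= params$breakHu,
         params$slopeLow * (h + 1000),
         params$muBreak + params$slopeHigh * (h - params$breakHu))
}

#' CT-based reference attenuation map
#'
#' Bilinear conversion of the CT volume. Voxels where the CT acquisition
#' lacks coverage are flagged NaN in the input; where the MR-based map
#' marks soft tissue they are filled with the soft coefficient, elsewhere
#' with air (0). Labels record HU bands: air below -500 HU, bone above the
#' bone threshold, soft between.
#'
#' @param ct \linkS4class{VolumeGrid} in HU, NaN marking unscanned voxels.
#' @param mracSoftMask aligned binary mask of MRAC soft-tissue voxels used
#'   to complement missing coverage.
#' @param coeffs from \code{\link{muCoefficients}}.
#' @param params from \code{\link{bilinearParams}}.
#' @return A \linkS4class{MuMap}.
#' @export
ctReferenceMuMap <- function(ct, mracSoftMask, coeffs = muCoefficients(),
                             params = bilinearParams()) {
  stopIfGridMismatch(ct, mracSoftMask)
  mu <- huToMu(ct@data, params)
  lb <- tissueLabels()
  lab <- array(lb[["soft"]], dim(mu))
  lab[ct@data < -500] <- lb[["air"]]
  lab[ct@data > 157] <- lb[["bone"]]
  missing <- is.nan(ct@data)
  fillSoft <- missing & asMaskArray(mracSoftMask)
  mu[fillSoft] <- coeffs[["soft"]]
  lab[fillSoft] <- lb[["soft"]]
  mu[missing & !fillSoft] <- 0
  lab[missing & !fillSoft] <- lb[["air"]]
  MuMap(withData(ct, mu), withData(ct, lab))
}
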