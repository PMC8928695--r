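#' @import methods
#' @importFrom stats quantile rnorm runif sd median cor setNames dnorm
NULL

# ---------------------------------------------------------------------------
# VolumeGrid
# ---------------------------------------------------------------------------

#' VolumeGrid: a 3-D scalar field on a regular voxel grid
#'
#' The common carrier for all volumes handled by the package: anatomical MRI
#' (arbitrary intensity units), CT (Hounsfield units), attenuation maps
#' (cm^-1), tissue probabilities (in \[0,1\]) and binary masks (\{0,1\}).
#' A volume knows its voxel spacing in mm and a 4x4 voxel-to-world affine.
#' Axis convention: (x, y, z) with axis 1 = left-right, axis 2 =
#' anterior-posterior (anterior at low index) and axis 3 = axial slice,
#' indexed 1-based as usual in R.
#'
#' @slot data 3-D numeric array.
#' @slot spacing numeric(3), voxel size in mm per axis; strictly positive.
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("VolumeGrid",
         representation(data = "array", spacing = "numeric", affine = "matrix"))

setValidity("VolumeGrid", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)) || any(!is.finite(object@affine)))
    msg <- c(msg, "affine must be a finite 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' Construct a VolumeGrid
#'
#' @param data 3-D numeric array (coerced to double).
#' @param spacing voxel size in mm per axis.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by \code{spacing} with the origin at the first voxel.
#' @return A \linkS4class{VolumeGrid}.
#' @export
VolumeGrid <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  new("VolumeGrid", data = data, spacing = spacing, affine = affine)
}

#' @describeIn VolumeGrid extract the raw 3-D array
#' @param x a VolumeGrid
#' @export
volData <- function(x) x@data

#' @describeIn VolumeGrid voxel spacing in mm
#' @export
voxelSpacing <- function(x) x@spacing

#' @describeIn VolumeGrid 4x4 voxel-to-world affine
#' @export
worldAffine <- function(x) x@affine

#' Replace the data array of a VolumeGrid, keeping its grid
#'
#' @param x a VolumeGrid supplying spacing and affine.
#' @param data replacement array of identical dimensions.
#' @return A VolumeGrid on the same grid.
#' @export
withData <- function(x, data) {
  stopifnot(identical(dim(as.array(data)), dim(x@data)))
  VolumeGrid(data, spacing = x@spacing, affine = x@affine)
}

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeGrid %dx%dx%d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = "x"),
              min(object@data), max(object@data)))
})

# ---------------------------------------------------------------------------
# TissueProbabilitySet
# ---------------------------------------------------------------------------

#' TissueProbabilitySet: six aligned tissue probability volumes
#'
#' Per-voxel class-membership probabilities as produced by unified MR
#' segmentation: grey matter, white matter, CSF, scalp/soft tissue,
#' skull/bone and air. All six share one grid and are bounded in \[0,1\].
#'
#' @slot grey,white,csf,soft,bone,air \linkS4class{VolumeGrid} probabilities.
#' @export
setClass("TissueProbabilitySet",
         representation(grey = "VolumeGrid", white = "VolumeGrid",
                        csf = "VolumeGrid", soft = "VolumeGrid",
                        bone = "VolumeGrid", air = "VolumeGrid"))

setValidity("TissueProbabilitySet", function(object) {
  msg <- character()
  vols <- list(object@grey, object@white, object@csf,
               object@soft, object@bone, object@air)
  for (v in vols[-1])
    if (!isTRUE(sameGrid(vols[[1]], v)))
      msg <- c(msg, "all probability volumes must share one grid")
  for (v in vols) {
    rng <- range(v@data)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
      msg <- c(msg, "probabilities must lie in [0,1]")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TissueProbabilitySet
#'
#' @param grey,white,csf,soft,bone,air aligned \linkS4class{VolumeGrid}s.
#' @return A \linkS4class{TissueProbabilitySet}.
#' @export
TissueProbabilitySet <- function(grey, white, csf, soft, bone, air) {
  new("TissueProbabilitySet", grey = grey, white = white, csf = csf,
      soft = soft, bone = bone, air = air)
}

#' @describeIn TissueProbabilitySet one probability volume by name
#' @param x a TissueProbabilitySet
#' @param class one of "grey", "white", "csf", "soft", "bone", "air"
#' @export
probMap <- function(x, class) slot(x, match.arg(class, probClasses()))

#' @describeIn TissueProbabilitySet the six class names in slot order
#' @export
probClasses <- function() c("grey", "white", "csf", "soft", "bone", "air")

setMethod("show", "TissueProbabilitySet", function(object) {
  d <- dim(object@grey@data)
  cat(sprintf("TissueProbabilitySet (%s) %dx%dx%d\n",
              paste(probClasses(), collapse = ", "), d[1], d[2], d[3]))
})

# ---------------------------------------------------------------------------
# MuMap
# ---------------------------------------------------------------------------

#' MuMap: attenuation-coefficient volume with per-voxel provenance labels
#'
#' Pairs a 511 keV linear-attenuation-coefficient volume (cm^-1) with an
#' integer label volume recording which tissue class (or sinus treatment)
#' produced each voxel's value. See \code{\link{tissueLabels}} for the codes.
#'
#' @slot mu \linkS4class{VolumeGrid} in cm^-1.
#' @slot labels \linkS4class{VolumeGrid} of integer class codes.
#' @export
setClass("MuMap", representation(mu = "VolumeGrid", labels = "VolumeGrid"))

setValidity("MuMap", function(object) {
  msg <- character()
  if (!isTRUE(sameGrid(object@mu, object@labels)))
    msg <- c(msg, "mu and labels must share one grid")
  if (any(!is.finite(object@mu@data)))
    msg <- c(msg, "mu must be finite")
  lab <- object@labels@data
  if (any(lab != round(lab)) || any(lab < 0) || any(lab > 5))
    msg <- c(msg, "labels must be integer codes in 0..5")
  if (length(msg)) msg else TRUE
})

#' Construct a MuMap
#' @param mu attenuation volume (cm^-1).
#' @param labels aligned integer label volume (codes of
#'   \code{\link{tissueLabels}}).
#' @return A \linkS4class{MuMap}.
#' @export
MuMap <- function(mu, labels) new("MuMap", mu = mu, labels = labels)

#' @describeIn MuMap the attenuation VolumeGrid
#' @param x a MuMap
#' @export
muValues <- function(x) x@mu

#' @describeIn MuMap the label VolumeGrid
#' @export
muLabels <- function(x) x@labels

#' Integer label codes used in MuMap label volumes
#'
#' \code{air} 0, \code{soft} 1, \code{brain} 2, \code{bone} 3,
#' \code{bulkSinus} 4 (fixed 0.100 cm^-1 sinus assignment) and
#' \code{convertedSinus} 5 (model-converted sinus voxels).
#' @return Named integer vector.
#' @export
tissueLabels <- function() {
  c(air = 0L, soft = 1L, brain = 2L, bone = 3L,
    bulkSinus = 4L, convertedSinus = 5L)
}

setMethod("show", "MuMap", function(object) {
  d <- dim(object@mu@data)
  tab <- table(factor(object@labels@data, levels = tissueLabels(),
                      labels = names(tissueLabels())))
  cat(sprintf("MuMap %dx%dx%d, mu range [%.4f, %.4f] cm^-1\n",
              d[1], d[2], d[3], min(object@mu@data), max(object@mu@data)))
  cat("  voxels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
})

# ---------------------------------------------------------------------------
# CuboidRegion
# ---------------------------------------------------------------------------

#' CuboidRegion: axis-aligned box of voxel indices
#'
#' Inclusive 1-based voxel bounds delimiting the sinus conversion region.
#'
#' @slot lo integer(3), inclusive lower corner.
#' @slot hi integer(3), inclusive upper corner; \code{lo <= hi} componentwise.
#' @export
setClass("CuboidRegion", representation(lo = "integer", hi = "integer"))

setValidity("CuboidRegion", function(object) {
  if (length(object@lo) != 3L || length(object@hi) != 3L)
    return("lo and hi must have length 3")
  if (any(object@lo < 1L)) return("lo must be >= 1")
  if (any(object@lo > object@hi)) return("lo must be <= hi componentwise")
  TRUE
})

#' Construct a CuboidRegion
#' @param lo,hi inclusive 1-based voxel corner indices (length-3).
#' @return A \linkS4class{CuboidRegion}.
#' @export
CuboidRegion <- function(lo, hi)
  new("CuboidRegion", lo = as.integer(lo), hi = as.integer(hi))

#' @describeIn CuboidRegion voxel extents hi - lo + 1
#' @param x a CuboidRegion
#' @export
cuboidDims <- function(x) x@hi - x@lo + 1L

#' Rasterize a CuboidRegion as a binary mask on a reference grid
#' @param region a \linkS4class{CuboidRegion}.
#' @param like a \linkS4class{VolumeGrid} supplying the grid.
#' @return Binary \linkS4class{VolumeGrid}.
#' @export
cuboidMask <- function(region, like) {
  d <- dim(like@data)
  if (any(region@hi > d)) stop("cuboid exceeds volume bounds")
  m <- array(0, d)
  m[region@lo[1]:region@hi[1], region@lo[2]:region@hi[2],
    region@lo[3]:region@hi[3]] <- 1
  withData(like, m)
}

setMethod("show", "CuboidRegion", function(object) {
  cat(sprintf("CuboidRegion [%s] .. [%s] (%s voxels)\n",
              paste(object@lo, collapse = ","),
              paste(object@hi, collapse = ","),
              paste(cuboidDims(object), collapse = "x")))
})

# ---------------------------------------------------------------------------
# ConversionModel
# ---------------------------------------------------------------------------

#' ConversionModel: three-segment piecewise-linear MRI to CT conversion
#'
#' The sinus conversion curve: CT = -1000 HU (air) for MRI intensities at or
#' below \code{mLow}, 0 HU (soft tissue) at or above \code{mHigh}, and linear
#' in between. Fitting metadata (bootstrap repeats, per-repeat estimates,
#' axis scales, seed, any held-out subject) travels in \code{fitMeta}.
#'
#' @slot mLow numeric, MRI intensity mapped to -1000 HU.
#' @slot mHigh numeric, MRI intensity mapped to 0 HU; \code{mLow < mHigh}.
#' @slot fitMeta list of fitting provenance.
#' @export
setClass("ConversionModel",
         representation(mLow = "numeric", mHigh = "numeric", fitMeta = "list"))

setValidity("ConversionModel", function(object) {
  if (length(object@mLow) != 1L || length(object@mHigh) != 1L ||
      !is.finite(object@mLow) || !is.finite(object@mHigh))
    return("mLow and mHigh must be finite scalars")
  if (object@mLow >= object@mHigh)
    return("mLow must be strictly below mHigh")
  TRUE
})

#' Construct a ConversionModel
#' @param mLow,mHigh the two MRI-intensity breakpoints (mLow < mHigh).
#' @param fitMeta optional list of fitting provenance.
#' @return A \linkS4class{ConversionModel}.
#' @export
ConversionModel <- function(mLow, mHigh, fitMeta = list()) {
  new("ConversionModel", mLow = as.numeric(mLow), mHigh = as.numeric(mHigh),
      fitMeta = fitMeta)
}

#' @describeIn ConversionModel the (mLow, mHigh) breakpoints
#' @param x a ConversionModel
#' @export
breakpoints <- function(x) c(mLow = x@mLow, mHigh = x@mHigh)

setMethod("show", "ConversionModel", function(object) {
  cat(sprintf("ConversionModel: -1000 HU at MRI <= %.4g, 0 HU at MRI >= %.4g\n",
              object@mLow, object@mHigh))
  if (length(object@fitMeta)) {
    fm <- object@fitMeta
    if (!is.null(fm$nReps))
      cat(sprintf("  bootstrap: %d repeats x %d voxels, seed %s\n",
                  fm$nReps, fm$nVox, format(fm$seed)))
    if (!is.null(fm$heldOut))
      cat(sprintf("  leave-one-out: subject %d excluded\n", fm$heldOut))
  }
})

# ---------------------------------------------------------------------------
# DeformationField
# ---------------------------------------------------------------------------

#' DeformationField: 3-component voxelwise displacement in mm
#'
#' Pull-back convention: for a voxel of the grid the field lives on, adding
#' the displacement (mm) to the voxel's world coordinates gives the
#' corresponding world point in the other space.
#'
#' @slot ux,uy,uz \linkS4class{VolumeGrid} displacement components (mm).
#' @export
setClass("DeformationField",
         representation(ux = "VolumeGrid", uy = "VolumeGrid",
                        uz = "VolumeGrid"))

setValidity("DeformationField", function(object) {
  if (!isTRUE(sameGrid(object@ux, object@uy)) ||
      !isTRUE(sameGrid(object@ux, object@uz)))
    return("field components must share one grid")
  TRUE
})

#' Construct a DeformationField
#' @param ux,uy,uz aligned displacement-component VolumeGrids (mm).
#' @return A \linkS4class{DeformationField}.
#' @export
DeformationField <- function(ux, uy, uz)
  new("DeformationField", ux = ux, uy = uy, uz = uz)

setMethod("show", "DeformationField", function(object) {
  mag <- sqrt(object@ux@data^2 + object@uy@data^2 + object@uz@data^2)
  cat(sprintf("DeformationField %s, |u| mean %.2f mm, max %.2f mm\n",
              paste(dim(object@ux@data), collapse = "x"),
              mean(mag), max(mag)))
})

# ---------------------------------------------------------------------------
# PhantomSpec / PhantomSubject
# ---------------------------------------------------------------------------

#' PhantomSpec: study conditions for the digital head-phantom generator
#'
#' See \code{\link{phantomSpec}} for field semantics and defaults.
#'
#' @export
setClass("PhantomSpec",
         representation(shape = "integer", spacingMm = "numeric",
                        seed = "integer", mLow = "numeric", mHigh = "numeric",
                        mriMargin = "numeric", mriNoiseSd = "numeric",
                        huNoiseSd = "numeric", airFraction = "numeric",
                        softFraction = "numeric", boneFraction = "numeric",
                        segmenterConfusion = "numeric",
                        deformationAmplitudeMm = "numeric",
                        probNoise = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (any(object@shape < 16L))
    msg <- c(msg, "all grid dimensions must be >= 16")
  fr <- c(object@airFraction, object@softFraction, object@boneFraction)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    msg <- c(msg, "composition fractions must be nonnegative and sum to 1")
  if (object@mLow >= object@mHigh)
    msg <- c(msg, "mLow must be strictly below mHigh")
  if (object@mriNoiseSd < 0 || object@huNoiseSd < 0)
    msg <- c(msg, "noise standard deviations must be nonnegative")
  if (object@segmenterConfusion < 0 || object@segmenterConfusion > 1)
    msg <- c(msg, "segmenterConfusion must be a probability")
  if (length(msg)) msg else TRUE
})

#' PhantomSubject: one synthetic subject
#'
#' Holds the paired MRI and CT volumes, the six tissue probability maps, the
#' ground-truth masks (per tissue class, the sinus air cavities, the sinus
#' compartment box, a throat decoy pocket), a sinus volume-of-interest
#' standing in for a manual delineation, and forward/inverse deformation
#' fields relating subject space to the canonical template space.
#'
#' @slot mri,ct \linkS4class{VolumeGrid} volumes.
#' @slot probmaps \linkS4class{TissueProbabilitySet}.
#' @slot truthMasks named list of binary \linkS4class{VolumeGrid}s.
#' @slot sinusVoi binary \linkS4class{VolumeGrid}.
#' @slot fwdDeformation,invDeformation \linkS4class{DeformationField}s.
#' @slot meta list: subject seed, true breakpoints, composition.
#' @export
setClass("PhantomSubject",
         representation(mri = "VolumeGrid", ct = "VolumeGrid",
                        probmaps = "TissueProbabilitySet",
                        truthMasks = "list", sinusVoi = "VolumeGrid",
                        fwdDeformation = "DeformationField",
                        invDeformation = "DeformationField",
                        meta = "list"))

setMethod("show", "PhantomSubject", function(object) {
  d <- dim(object@mri@data)
  cat(sprintf("PhantomSubject %dx%dx%d (seed %d)\n", d[1], d[2], d[3],
              object@meta$subjectSeed))
  cat(sprintf("  sinus compartment: %d voxels, air cavities: %d voxels\n",
              sum(object@truthMasks$sinusCompartment@data),
              sum(object@truthMasks$sinusAir@data)))
})
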