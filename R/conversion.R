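# The three-segment MRI->CT conversion model: orthogonal-distance grid
# fitting, the 100-voxel x 100-repeat bootstrap, cohort averaging and
# leave-one-out validation.

#' Predict CT numbers from MRI intensities
#'
#' Piecewise-linear evaluation: -1000 HU at or below \code{mLow}, 0 HU at
#' or above \code{mHigh}, linear between. Non-decreasing everywhere; range
#' is \[-1000, 0\].
#'
#' @param model a \linkS4class{ConversionModel}.
#' @param mri numeric vector/array or \linkS4class{VolumeGrid}.
#' @return Same container type as \code{mri}, in HU.
#' @export
predictHu <- function(model, mri) {
  validObject(model)
  if (is(mri, "VolumeGrid"))
    return(withData(mri, predictHu(model, mri@data)))
  t <- (mri - model@mLow) / (model@mHigh - model@mLow)
  pmin(pmax(t, 0), 1) * 1000 - 1000
}

#' Orthogonal distance from a data point to a candidate conversion curve
#'
#' Both axes are normalized (HU by \code{scales["hu"]}, MRI by
#' \code{scales["mri"]}) so the shortest-distance criterion weighs them
#' comparably; the distance is the Euclidean distance from the normalized
#' point to the nearest point of the normalized three-segment polyline
#' (half-infinite plateaus at -1000 and 0 HU, diagonal between the
#' breakpoints).
#'
#' @param point numeric length-2 (mri, hu).
#' @param candidate numeric length-2 (mLow, mHigh), mLow < mHigh.
#' @param scales named numeric: positive normalization divisors
#'   \code{mri} and \code{hu}.
#' @return The distance (in normalized units).
#' @export
pointCurveDistance <- function(point, candidate,
                               scales = c(mri = 1, hu = 1000)) {
  if (any(scales <= 0)) stop("scales must be positive")
  sqrt(as.numeric(
    curveDistanceSq(point[1] / scales[["mri"]], point[2] / scales[["hu"]],
                    candidate[1] / scales[["mri"]],
                    candidate[2] / scales[["mri"]],
                    huScale = scales[["hu"]])))
}

# internal: squared distances of normalized points (x, y) to the normalized
# curve with breakpoints a <= b (all already divided by their scales).
# Vectorized over points and candidates: x, y are n-vectors, a, b are
# m-vectors; returns an n x m matrix.
curveDistanceSq <- function(x, y, a, b, huScale = 1000) {
  yAir <- -1000 / huScale
  ySoft <- 0
  X <- matrix(x, length(x), length(a))
  Y <- matrix(y, length(x), length(a))
  A <- matrix(a, length(x), length(a), byrow = TRUE)
  B <- matrix(b, length(x), length(a), byrow = TRUE)
  # left plateau: y = yAir, x <= a
  d1 <- pmax(X - A, 0)^2 + (Y - yAir)^2
  # right plateau: y = ySoft, x >= b
  d2 <- pmax(B - X, 0)^2 + (Y - ySoft)^2
  # diagonal segment (a, yAir) -> (b, ySoft)
  vx <- B - A
  vy <- ySoft - yAir
  tt <- ((X - A) * vx + (Y - yAir) * vy) / (vx^2 + vy^2)
  tt <- pmin(pmax(tt, 0), 1)
  d3 <- (X - A - tt * vx)^2 + (Y - yAir - tt * vy)^2
  pmin(d1, d2, d3)
}

# internal: sum of squared distances for every candidate pair; sample is a
# data.frame(mri, hu); cands a data.frame(a, b) in raw MRI units
candidateLoss <- function(sample, cands, scales) {
  dsq <- curveDistanceSq(sample$mri / scales[["mri"]],
                         sample$hu / scales[["hu"]],
                         cands$a / scales[["mri"]],
                         cands$b / scales[["mri"]],
                         huScale = scales[["hu"]])
  colSums(dsq)
}

#' Default axis normalization for conversion fitting
#'
#' HU divided by 1000 and MRI by the sample's 99th-percentile intensity,
#' so both axes are O(1); without normalization the HU axis would dominate
#' the shortest-distance criterion.
#'
#' @param mri numeric vector of MRI intensities.
#' @return Named numeric vector with elements \code{mri} and \code{hu}.
#' @export
conversionScales <- function(mri) {
  s <- quantile(mri, 0.99, names = FALSE)
  if (!is.finite(s) || s <= 0) s <- max(abs(mri), 1)
  c(mri = s, hu = 1000)
}

#' Fit the conversion breakpoints to one sample
#'
#' Exhaustive minimisation of the summed squared point-to-curve distance
#' over a candidate lattice for (mLow, mHigh): \code{gridN} x \code{gridN}
#' over the sample's MRI range, followed by one refinement at 8x finer
#' spacing around the optimum. Ties resolve to the smallest
#' \code{mHigh - mLow}, then the smallest \code{mLow}. Samples without
#' points between the plateaus make the problem ill-posed and raise a
#' warning.
#'
#' @param sample data.frame with columns \code{mri} and \code{hu}
#'   (>= 10 rows).
#' @param gridN lattice resolution per axis (default 64).
#' @param scales from \code{\link{conversionScales}}; computed from the
#'   sample when NULL.
#' @return Named numeric vector (mLow, mHigh) with attribute \code{loss}.
#' @export
fitOnce <- function(sample, gridN = 64L, scales = NULL) {
  if (is.null(sample) || nrow(sample) == 0) stop("empty sample")
  if (nrow(sample) < 10) stop("need at least 10 (mri, hu) pairs")
  if (is.null(scales)) scales <- conversionScales(sample$mri)
  if (!any(sample$hu > -950 & sample$hu < -50))
    warning("no points between the plateaus; breakpoint fit is ill-posed")
  rng <- range(sample$mri)
  vals <- seq(rng[1], rng[2], length.out = gridN)
  best <- gridArgmin(sample, vals, vals, scales)
  step <- if (gridN > 1) diff(vals[1:2]) else diff(rng)
  fine <- function(centre)
    seq(centre - step, centre + step, length.out = 17L)
  best <- gridArgmin(sample, fine(best[["mLow"]]), fine(best[["mHigh"]]),
                     scales)
  best
}

# internal: argmin over the cross of candidate values with a < b, applying
# the tie rules (loss, span, mLow)
gridArgmin <- function(sample, aVals, bVals, scales) {
  cands <- expand.grid(a = aVals, b = bVals)
  cands <- cands[cands$a < cands$b, , drop = FALSE]
  if (!nrow(cands)) stop("no valid (mLow < mHigh) candidates on the lattice")
  loss <- candidateLoss(sample, cands, scales)
  ord <- order(loss, cands$b - cands$a, cands$a)
  sel <- ord[1]
  out <- c(mLow = cands$a[sel], mHigh = cands$b[sel])
  attr(out, "loss") <- loss[sel]
  out
}

#' Bootstrap fit of the conversion model for one subject
#'
#' \code{nReps} independent draws of \code{nVox} voxels without
#' replacement; \code{\link{fitOnce}} on each; the final model is the
#' arithmetic mean of the per-repeat (mLow, mHigh) estimates.
#'
#' @param voxels data.frame with columns \code{mri} and \code{hu}; at
#'   least \code{nVox} rows.
#' @param nVox voxels per repeat (default 100).
#' @param nReps repeats (default 100).
#' @param seed RNG seed for the resampling.
#' @param replace sample with replacement instead (default FALSE).
#' @param gridN lattice resolution passed to \code{\link{fitOnce}}.
#' @return A \linkS4class{ConversionModel}; per-repeat estimates, scales
#'   and the seed are kept in \code{fitMeta}.
#' @export
fitBootstrap <- function(voxels, nVox = 100L, nReps = 100L, seed = 1L,
                         replace = FALSE, gridN = 64L) {
  if (nrow(voxels) < nVox)
    stop("fewer voxels (", nrow(voxels), ") than nVox (", nVox, ")")
  scales <- conversionScales(voxels$mri)
  est <- withSeed(seed, {
    t(vapply(seq_len(nReps), function(r) {
      idx <- sample.int(nrow(voxels), nVox, replace = replace)
      suppressWarnings(fitOnce(voxels[idx, , drop = FALSE],
                               gridN = gridN, scales = scales))
    }, numeric(2)))
  })
  colnames(est) <- c("mLow", "mHigh")
  ConversionModel(mean(est[, 1]), mean(est[, 2]),
                  fitMeta = list(nVox = nVox, nReps = nReps, seed = seed,
                                 perRepeat = est, scales = scales,
                                 replace = replace))
}

#' Cohort conversion model
#'
#' Per-subject bootstrap models averaged with equal subject weight: the
#' final breakpoints are the means of the per-subject breakpoints.
#'
#' @param subjectVoxels list of per-subject data.frames (\code{mri},
#'   \code{hu}).
#' @param seed base seed; subject s uses \code{seed + 7919 * s}.
#' @param ... passed to \code{\link{fitBootstrap}}.
#' @return A \linkS4class{ConversionModel} with per-subject models in
#'   \code{fitMeta$subjectModels}.
#' @export
fitCohort <- function(subjectVoxels, seed = 1L, ...) {
  if (!length(subjectVoxels)) stop("empty cohort")
  models <- lapply(seq_along(subjectVoxels), function(s)
    fitBootstrap(subjectVoxels[[s]], seed = seed + 7919L * s, ...))
  bp <- t(vapply(models, breakpoints, numeric(2)))
  ConversionModel(mean(bp[, 1]), mean(bp[, 2]),
                  fitMeta = list(seed = seed, subjectModels = models,
                                 subjectBreakpoints = bp))
}

#' Leave-one-out conversion model
#'
#' The cohort model fitted with one subject excluded; used to convert that
#' subject out-of-sample.
#'
#' @param subjectVoxels list of per-subject data.frames.
#' @param heldOut 1-based index of the excluded subject.
#' @param seed base seed (see \code{\link{fitCohort}}).
#' @param ... passed to \code{\link{fitBootstrap}}.
#' @return A \linkS4class{ConversionModel}; \code{fitMeta$heldOut} records
#'   the exclusion.
#' @export
leaveOneOut <- function(subjectVoxels, heldOut, seed = 1L, ...) {
  n <- length(subjectVoxels)
  if (n < 2) stop("leave-one-out needs a cohort of at least 2")
  if (heldOut < 1 || heldOut > n) stop("held-out index out of range")
  m <- fitCohort(subjectVoxels[-heldOut], seed = seed, ...)
  m@fitMeta$heldOut <- as.integer(heldOut)
  m
}

#' Serialize / deserialize a ConversionModel as JSON
#'
#' @param model a \linkS4class{ConversionModel}.
#' @param path output (input) file path.
#' @return \code{path} invisibly; \code{readConversionModel} returns the
#'   model.
#' @export
writeConversionModel <- function(model, path) {
  fm <- model@fitMeta
  fm$subjectModels <- NULL
  if (!is.null(fm$perRepeat)) fm$perRepeat <- unname(as.matrix(fm$perRepeat))
  jsonlite::write_json(list(mLow = model@mLow, mHigh = model@mHigh,
                            fitMeta = fm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeConversionModel
#' @export
readConversionModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ConversionModel(x$mLow, x$mHigh, fitMeta = as.list(x$fitMeta))
}
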