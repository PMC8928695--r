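# Seeded digital head phantoms: paired MRI/CT, tissue probability maps,
# ground-truth masks and deformation fields, so every pipeline stage is
# testable without patient data.

#' Phantom study conditions
#'
#' Defines the synthetic cohort the generator emulates: an ellipsoidal head
#' (background air at -1000 HU, scalp near 0 HU, skull shell near 1000 HU,
#' brain interior near 30 HU) with an anterior sinus compartment whose
#' voxels are a mixture of air cavities, fine bone and soft tissue. Inside
#' the sinus, CT numbers are generated from MRI intensity through a known
#' three-segment piecewise-linear law (plateau at -1000 HU below
#' \code{mLow}, plateau at 0 HU above \code{mHigh}) plus noise, mirroring
#' the scatter structure real sinus voxels show. The probability maps
#' mislabel sinus mixture voxels as bone with probability
#' \code{segmenterConfusion}, reproducing the upstream segmenter's known
#' failure mode in this region.
#'
#' @param shape grid dimensions (default 96 x 96 x 96).
#' @param spacingMm isotropic voxel size in mm (default 2, the anatomical
#'   MRI resolution the pipeline targets).
#' @param seed base RNG seed; per-subject seeds derive from it.
#' @param mLow,mHigh true MRI-intensity breakpoints mapping to -1000 and
#'   0 HU (arbitrary MRI units).
#' @param mriMargin half-width of the plateau coverage beyond the
#'   breakpoints in the sinus MRI draw.
#' @param mriNoiseSd additive Gaussian noise on observed MRI intensities.
#' @param huNoiseSd additive Gaussian noise on CT numbers (HU).
#' @param airFraction,softFraction,boneFraction target composition of the
#'   sinus compartment; must sum to 1. Defaults describe a majority-air
#'   sinus with substantial fine-bone admixture.
#' @param segmenterConfusion probability that a sinus mixture voxel is
#'   labelled bone in the probability maps.
#' @param deformationAmplitudeMm amplitude of the smooth sinusoidal
#'   component of the subject-template deformation fields.
#' @param probNoise amplitude of the uniform perturbation applied to the
#'   probability maps (renormalized per voxel).
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(shape = c(96L, 96L, 96L), spacingMm = 2,
                        seed = 1L, mLow = 120, mHigh = 320, mriMargin = 80,
                        mriNoiseSd = 10, huNoiseSd = 40,
                        airFraction = 0.55, softFraction = 0.12,
                        boneFraction = 0.33, segmenterConfusion = 0.9,
                        deformationAmplitudeMm = 3, probNoise = 0.02) {
  new("PhantomSpec", shape = as.integer(shape),
      spacingMm = as.numeric(spacingMm), seed = as.integer(seed),
      mLow = mLow, mHigh = mHigh, mriMargin = mriMargin,
      mriNoiseSd = mriNoiseSd, huNoiseSd = huNoiseSd,
      airFraction = airFraction, softFraction = softFraction,
      boneFraction = boneFraction, segmenterConfusion = segmenterConfusion,
      deformationAmplitudeMm = deformationAmplitudeMm, probNoise = probNoise)
}

# internal: the true piecewise conversion law of a spec
phantomLaw <- function(spec, m) {
  pmin(pmax((m - spec@mLow) / (spec@mHigh - spec@mLow), 0), 1) * 1000 - 1000
}

# internal: canonical (template-space) sinus compartment box for a spec
canonicalSinusBox <- function(spec) {
  d <- spec@shape
  c1 <- (d[1] + 1) / 2
  CuboidRegion(
    lo = c(round(c1 - 10 * d[1] / 96), round(0.15 * d[2]), round(0.54 * d[3])),
    hi = c(round(c1 + 10 * d[1] / 96), round(0.30 * d[2]), round(0.71 * d[3])))
}

# internal: normalized ellipsoidal radius field of the head
headRadiusField <- function(d) {
  cc <- (d + 1) / 2
  semi <- c(0.38 * d[1], 0.44 * d[2], 0.42 * d[3])
  xs <- ((seq_len(d[1]) - cc[1]) / semi[1])^2
  ys <- ((seq_len(d[2]) - cc[2]) / semi[2])^2
  zs <- ((seq_len(d[3]) - cc[3]) / semi[3])^2
  r2 <- array(outer(xs, ys, `+`), d) + rep(zs, each = d[1] * d[2])
  sqrt(r2)
}

#' Generate one synthetic subject
#'
#' Deterministic given \code{spec} and \code{subjectIdx}: the per-subject
#' seed is \code{seed * 10007 + subjectIdx}. Subjects of a cohort share the
#' true conversion law but differ in sinus-compartment placement, air-cavity
#' shapes, deformation fields and noise realization.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param subjectIdx positive integer subject index.
#' @return A \linkS4class{PhantomSubject}.
#' @export
generateSubject <- function(spec, subjectIdx = 1L) {
  validObject(spec)
  subjectSeed <- spec@seed * 10007L + as.integer(subjectIdx)
  withSeed(subjectSeed, {
    d <- spec@shape
    sp <- rep(spec@spacingMm, 3)
    like <- VolumeGrid(array(0, d), spacing = sp)
    r <- headRadiusField(d)

    # tissue codes: 0 bg air, 1 scalp, 2 skull, 3 brain, 4 sinus air,
    # 5 sinus soft, 6 sinus mixture, 7 throat air
    cls <- array(0L, d)
    cls[r <= 1] <- 1L
    cls[r <= 0.92] <- 2L
    cls[r <= 0.84] <- 3L
    # facial sector: the anterior-inferior skeleton is far thinner than the
    # calvarium; keep only a 1-voxel-scale bone sheet there and give the
    # rest of the shell to soft tissue
    jArr <- array(rep(rep(seq_len(d[2]), each = d[1]), d[3]), d)
    kArr <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
    facial <- jArr < 0.32 * d[2] & kArr < 0.78 * d[3]
    cls[cls == 2L & facial & r <= 0.905] <- 1L

    # throat decoy: an enclosed air pocket posterior to the sinus, not
    # connected to the sinus cavities
    cc <- (d + 1) / 2
    i1 <- seq_len(d[1]); j1 <- seq_len(d[2])
    jThroat <- 0.38 * d[2]
    radTh <- 2.8 * d[1] / 96
    cyl2d <- outer((i1 - cc[1])^2, (j1 - jThroat)^2, `+`) <= radTh^2
    kTh <- round(0.25 * d[3]):round(0.52 * d[3])
    throat <- array(FALSE, d)
    throat[, , kTh] <- cyl2d
    throat <- throat & cls == 3L
    cls[throat] <- 7L

    # sinus compartment: canonical box shifted by a per-subject jitter
    canon <- canonicalSinusBox(spec)
    jAmp <- pmax(1L, round(c(2, 2, 1) * d / 96))
    jit <- vapply(jAmp, function(a) sample(seq(-a, a), 1), integer(1))
    box <- CuboidRegion(canon@lo + jit, canon@hi + jit)
    boxSel <- array(FALSE, d)
    boxSel[box@lo[1]:box@hi[1], box@lo[2]:box@hi[2], box@lo[3]:box@hi[3]] <- TRUE
    # keep the carve strictly inside the head so cavities stay enclosed by
    # scalp even at coarse grids or extreme jitter
    boxSel <- boxSel & r <= 0.94
    # mucosal lining: the compartment is separated from adjacent facial
    # bone by a thin soft-tissue rind, as real sinus walls are
    lining <- dilate3(boxSel, 2L) & !boxSel & cls == 2L
    cls[lining] <- 1L
    bIdx <- which(boxSel, arr.ind = TRUE)

    # cavity potential: two roughened ellipsoidal wells; sublevel quantiles
    # carve air cores, then a fine-bone band around them, then soft tissue
    ctr <- (box@lo + box@hi) / 2
    halfSpan <- (box@hi[1] - box@lo[1]) / 4
    b1 <- ctr + c(-halfSpan, 0, 0) + runif(3, -1.5, 1.5)
    b2 <- ctr + c(+halfSpan, 0, 0) + runif(3, -1.5, 1.5)
    sax <- pmax((box@hi - box@lo + 1) * c(0.26, 0.42, 0.46), 1.5)
    phi1 <- sqrt(((bIdx[, 1] - b1[1]) / sax[1])^2 +
                 ((bIdx[, 2] - b1[2]) / sax[2])^2 +
                 ((bIdx[, 3] - b1[3]) / sax[3])^2)
    phi2 <- sqrt(((bIdx[, 1] - b2[1]) / sax[1])^2 +
                 ((bIdx[, 2] - b2[2]) / sax[2])^2 +
                 ((bIdx[, 3] - b2[3]) / sax[3])^2)
    phi <- pmin(phi1, phi2) + rnorm(nrow(bIdx), sd = 0.06)
    qs <- quantile(phi, c(spec@airFraction,
                          spec@airFraction + spec@boneFraction),
                   names = FALSE, type = 1)
    boxCls <- ifelse(phi <= qs[1], 4L, ifelse(phi <= qs[2], 6L, 5L))
    cls[boxSel] <- boxCls

    # MRI: class-dependent means; inside the sinus a uniform draw whose
    # range covers both plateaus and the diagonal of the conversion law
    mriBase <- array(0, d)
    mriBase[cls == 0L | cls == 7L] <- 30
    mriBase[cls == 1L] <- 400
    mriBase[cls == 2L] <- 80
    mriBase[cls == 3L] <- 360
    nAir <- sum(cls == 4L); nSoft <- sum(cls == 5L); nMix <- sum(cls == 6L)
    mriBase[cls == 4L] <- runif(nAir, spec@mLow - spec@mriMargin, spec@mLow)
    mriBase[cls == 5L] <- runif(nSoft, spec@mHigh, spec@mHigh + spec@mriMargin)
    mriBase[cls == 6L] <- runif(nMix, spec@mLow - spec@mriMargin,
                                spec@mHigh + spec@mriMargin)
    mri <- mriBase + rnorm(length(mriBase), sd = spec@mriNoiseSd)

    # CT: fixed class values outside the sinus, the conversion law inside
    hu <- array(-1000, d)
    hu[cls == 1L] <- 0
    hu[cls == 2L] <- 1000
    hu[cls == 3L] <- 30
    sinusSel <- cls >= 4L & cls <= 6L
    hu[sinusSel] <- phantomLaw(spec, mriBase[sinusSel])
    noisy <- cls >= 1L & cls != 7L
    hu[noisy] <- hu[noisy] + rnorm(sum(noisy), sd = spec@huNoiseSd)
    hu <- pmin(pmax(hu, -1000), 3000)

    # probability maps: one-hot on the true class, except that sinus
    # mixture voxels are mislabelled bone with the configured probability
    pm <- lapply(probClasses(), function(z) array(0, d))
    names(pm) <- probClasses()
    pm$air[cls == 0L | cls == 4L | cls == 7L] <- 1
    pm$soft[cls == 1L | cls == 5L] <- 1
    pm$bone[cls == 2L] <- 1
    pm$grey[cls == 3L] <- 0.6
    pm$white[cls == 3L] <- 0.3
    pm$csf[cls == 3L] <- 0.1
    mixIdx <- which(cls == 6L)
    confused <- runif(length(mixIdx)) < spec@segmenterConfusion
    lawMix <- phantomLaw(spec, mriBase[mixIdx])
    pm$bone[mixIdx[confused]] <- 1
    elseAir <- mixIdx[!confused][lawMix[!confused] < -500]
    elseSoft <- mixIdx[!confused][lawMix[!confused] >= -500]
    pm$air[elseAir] <- 1
    pm$soft[elseSoft] <- 1
    if (spec@probNoise > 0) {
      tot <- array(0, d)
      for (z in probClasses()) {
        pm[[z]] <- pm[[z]] + runif(length(pm[[z]]), 0, spec@probNoise)
        tot <- tot + pm[[z]]
      }
      for (z in probClasses()) pm[[z]] <- pm[[z]] / tot
    }
    probmaps <- TissueProbabilitySet(
      grey = withData(like, pm$grey), white = withData(like, pm$white),
      csf = withData(like, pm$csf), soft = withData(like, pm$soft),
      bone = withData(like, pm$bone), air = withData(like, pm$air))

    # deformation fields: constant pull-back matching the compartment
    # jitter plus a smooth sinusoidal perturbation with a known approximate
    # inverse (its negation)
    wx <- (seq_len(d[1]) - 1) * sp[1]
    wy <- (seq_len(d[2]) - 1) * sp[2]
    wz <- (seq_len(d[3]) - 1) * sp[3]
    A <- spec@deformationAmplitudeMm
    freq <- 1 / 250
    inv <- list()
    for (cmp in 1:3) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      ph <- runif(1, 0, 2 * pi)
      arg <- array(outer(2 * pi * freq * dir[1] * wx,
                         2 * pi * freq * dir[2] * wy, `+`), d) +
        rep(2 * pi * freq * dir[3] * wz, each = d[1] * d[2])
      inv[[cmp]] <- -jit[cmp] * sp[cmp] + A * sin(arg + ph)
    }
    invField <- DeformationField(withData(like, inv[[1]]),
                                 withData(like, inv[[2]]),
                                 withData(like, inv[[3]]))
    fwdField <- DeformationField(withData(like, -inv[[1]]),
                                 withData(like, -inv[[2]]),
                                 withData(like, -inv[[3]]))

    truth <- list(
      backgroundAir = maskVolume(like, cls == 0L),
      scalp = maskVolume(like, cls == 1L),
      skull = maskVolume(like, cls == 2L),
      brain = maskVolume(like, cls == 3L),
      sinusAir = maskVolume(like, cls == 4L),
      sinusSoft = maskVolume(like, cls == 5L),
      sinusMixture = maskVolume(like, cls == 6L),
      throat = maskVolume(like, cls == 7L),
      sinusCompartment = maskVolume(like, boxSel),
      head = maskVolume(like, r <= 1))

    new("PhantomSubject",
        mri = withData(like, mri), ct = withData(like, hu),
        probmaps = probmaps, truthMasks = truth,
        sinusVoi = maskVolume(like, boxSel),
        fwdDeformation = fwdField, invDeformation = invField,
        meta = list(subjectSeed = subjectSeed, subjectIdx = subjectIdx,
                    mLow = spec@mLow, mHigh = spec@mHigh,
                    sinusBox = box, canonicalBox = canon, jitter = jit))
  })
}

#' Generate a phantom cohort
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param n number of subjects; at least 2 (leave-one-out validation is
#'   undefined for a single subject).
#' @return List of \linkS4class{PhantomSubject}s with derived per-subject
#'   seeds; all share the true conversion law.
#' @export
generateCohort <- function(spec, n) {
  if (n < 2) stop("a cohort needs at least 2 subjects")
  lapply(seq_len(n), function(i) generateSubject(spec, i))
}

#' Extract the sinus (MRI, HU) voxel pairs of a subject
#'
#' The fitting pool for the conversion model: voxels labelled bone by
#' \code{\link{classifyTissues}} inside the given sinus region, paired as
#' observed MRI intensity and CT number.
#'
#' @param subject a \linkS4class{PhantomSubject} (or any list-like with
#'   \code{mri} and \code{ct} retrievable), here the S4 phantom.
#' @param regionMask binary \linkS4class{VolumeGrid} of the sinus region.
#' @param labels label volume from \code{\link{classifyTissues}}.
#' @return data.frame with columns \code{mri} and \code{hu}.
#' @export
sinusVoxelPairs <- function(subject, regionMask, labels) {
  stopIfGridMismatch(subject@mri, regionMask, labels)
  sel <- asMaskArray(regionMask) & labels@data == tissueLabels()["bone"]
  data.frame(mri = subject@mri@data[sel], hu = subject@ct@data[sel])
}

#' Write a phantom subject to a directory as NIfTI volumes
#'
#' Writes \code{mri.nii.gz}, \code{ct.nii.gz}, the six probability maps,
#' the sinus VOI and truth masks (uint8), the deformation-field components,
#' and a JSON manifest of the ground-truth parameters.
#'
#' @param subject a \linkS4class{PhantomSubject}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeSubject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(subject@mri, file.path(dir, "mri.nii.gz"))
  writeVolume(subject@ct, file.path(dir, "ct.nii.gz"))
  for (z in probClasses())
    writeVolume(probMap(subject@probmaps, z),
                file.path(dir, paste0("prob_", z, ".nii.gz")))
  writeVolume(subject@sinusVoi, file.path(dir, "sinus_voi.nii.gz"),
              datatype = "uint8")
  for (nm in names(subject@truthMasks))
    writeVolume(subject@truthMasks[[nm]],
                file.path(dir, paste0("truth_", nm, ".nii.gz")),
                datatype = "uint8")
  writeVolume(subject@invDeformation@ux, file.path(dir, "inv_ux.nii.gz"))
  writeVolume(subject@invDeformation@uy, file.path(dir, "inv_uy.nii.gz"))
  writeVolume(subject@invDeformation@uz, file.path(dir, "inv_uz.nii.gz"))
  manifest <- subject@meta
  manifest$sinusBox <- list(lo = manifest$sinusBox@lo,
                            hi = manifest$sinusBox@hi)
  manifest$canonicalBox <- list(lo = manifest$canonicalBox@lo,
                                hi = manifest$canonicalBox@hi)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
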