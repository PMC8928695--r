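# End-to-end orchestration: phantom cohort -> attenuation maps for each
# sinus-delineation method -> conversion models -> evaluation reports.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: tissue
#' thresholds, class attenuation coefficients, bilinear CT scaling, the
#' sinus evaluation slice window, cuboid-search options, conversion-fit
#' options, the PET-resolution smoothing width and the base seed. The
#' object round-trips losslessly through YAML
#' (\code{\link{writeRunConfig}} / \code{\link{readRunConfig}}).
#'
#' @param thresholds from \code{\link{classThresholds}}.
#' @param coefficients from \code{\link{muCoefficients}}.
#' @param bilinear from \code{\link{bilinearParams}}.
#' @param sliceRange inclusive axial window for sinus evaluation.
#' @param cuboid list: \code{stride}, \code{minDim}, \code{marginSlices},
#'   \code{penalty}.
#' @param conversion list: \code{nVox}, \code{nReps}, \code{gridN}.
#' @param correlation list: \code{nVox}, \code{nReps}.
#' @param petFwhmMm PET-resolution smoothing FWHM in mm.
#' @param seed base RNG seed.
#' @return A list of class \code{mracConfig}.
#' @export
mracConfig <- function(thresholds = classThresholds(),
                       coefficients = muCoefficients(),
                       bilinear = bilinearParams(),
                       sliceRange = c(50L, 70L),
                       cuboid = list(stride = 2L, minDim = 3L,
                                     marginSlices = 5L, penalty = "edges"),
                       conversion = list(nVox = 100L, nReps = 100L,
                                         gridN = 64L),
                       correlation = list(nVox = 200L, nReps = 100L),
                       petFwhmMm = 5, seed = 1L) {
  structure(list(thresholds = thresholds, coefficients = coefficients,
                 bilinear = bilinear, sliceRange = as.integer(sliceRange),
                 cuboid = cuboid, conversion = conversion,
                 correlation = correlation, petFwhmMm = petFwhmMm,
                 seed = as.integer(seed)),
            class = "mracConfig")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config an \code{mracConfig} list.
#' @param path YAML file path.
#' @return \code{path} invisibly; \code{readRunConfig} returns the config.
#' @export
writeRunConfig <- function(config, path) {
  # named atomic vectors must become maps, or YAML drops their names
  yamlable <- function(x) {
    if (is.list(x)) lapply(x, yamlable)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(yamlable(unclass(config)), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- mracConfig()
  for (nm in names(cfg)) {
    v <- x[[nm]]
    cfg[[nm]] <- if (is.list(cfg[[nm]]) || is.null(names(cfg[[nm]]))) v
    else unlist(v)[names(cfg[[nm]])]
  }
  cfg$sliceRange <- as.integer(unlist(x$sliceRange))
  structure(cfg, class = "mracConfig")
}

# internal: the sinus region mask for one subject under a given method
sinusRegionForMethod <- function(subject, method, config, template,
                                 labels) {
  switch(method,
    bulk = list(mask = subject@sinusVoi, info = list()),
    cuboid = {
      del <- delineateAirCavities(subject@probmaps, config$thresholds)
      reg0 <- initialSearchRegion(headMask(subject@probmaps,
                                           config$thresholds),
                                  del$mask, config$cuboid$marginSlices)
      fit <- searchBestCuboid(probMap(subject@probmaps, "bone"), reg0,
                              stride = config$cuboid$stride,
                              minDim = config$cuboid$minDim,
                              penalty = config$cuboid$penalty)
      list(mask = cuboidMask(fit$region, subject@mri),
           info = list(region = fit$region, cg = fit$cg,
                       airCavities = del$mask))
    },
    template = {
      if (is.null(template))
        stop("template method requires a TemplateCuboid")
      list(mask = warpMask(template, subject@invDeformation, subject@mri),
           info = list())
    },
    stop("unknown method: ", method))
}

#' Run the full sinus-MRAC pipeline on a cohort
#'
#' For each subject: classify tissues, build the four-class attenuation
#' map, delineate the sinus region with the chosen method, and either
#' assign the fixed bulk coefficient or convert bone voxels through the
#' MRI-CT model. Conversion models are fitted by per-subject bootstrap,
#' averaged over the cohort, and each subject is converted with its
#' leave-one-out model (fitted without that subject). The CT-based
#' reference map, Dice coefficients (sinus window and whole volume),
#' correlation samples and sinus-VOI attenuation means are computed per
#' subject. Per-subject failures are recorded and the run continues.
#'
#' @param cohort list of \linkS4class{PhantomSubject}s (or equivalent).
#' @param method \code{"bulk"}, \code{"cuboid"} or \code{"template"}.
#' @param config from \code{\link{mracConfig}}.
#' @param template a \linkS4class{TemplateCuboid}; required for the
#'   template method.
#' @return List with \code{method}, per-subject \code{table}
#'   (data.frame), \code{muMaps}, \code{referenceMaps}, \code{regions},
#'   \code{cohortModel}, \code{looModels}, \code{correlations} and
#'   \code{errors}.
#' @export
runPipeline <- function(cohort, method = c("bulk", "cuboid", "template"),
                        config = mracConfig(), template = NULL) {
  method <- match.arg(method)
  n <- length(cohort)
  errors <- list()
  labelsList <- vector("list", n)
  baseMaps <- vector("list", n)
  regions <- vector("list", n)
  pools <- vector("list", n)
  for (s in seq_len(n)) {
    res <- tryCatch({
      subj <- cohort[[s]]
      lab <- classifyTissues(subj@probmaps, config$thresholds)
      base <- assignMu(lab, config$coefficients)
      reg <- sinusRegionForMethod(subj, method, config, template, lab)
      list(lab = lab, base = base, reg = reg$mask, info = reg$info,
           pool = sinusVoxelPairs(subj, reg$mask, lab))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(s)]] <- conditionMessage(res)
    } else {
      labelsList[[s]] <- res$lab
      baseMaps[[s]] <- res$base
      regions[[s]] <- res$reg
      pools[[s]] <- res$pool
    }
  }
  ok <- which(!vapply(baseMaps, is.null, logical(1)))

  cohortModel <- NULL
  looModels <- vector("list", n)
  if (method != "bulk" && length(ok) >= 2) {
    okPools <- pools[ok]
    cohortModel <- fitCohort(okPools, seed = config$seed,
                             nVox = config$conversion$nVox,
                             nReps = config$conversion$nReps,
                             gridN = config$conversion$gridN)
    for (k in seq_along(ok))
      looModels[[ok[k]]] <- leaveOneOut(okPools, k, seed = config$seed,
                                        nVox = config$conversion$nVox,
                                        nReps = config$conversion$nReps,
                                        gridN = config$conversion$gridN)
  }

  muMaps <- vector("list", n)
  refMaps <- vector("list", n)
  corSamples <- vector("list", n)
  rows <- list()
  for (s in ok) {
    subj <- cohort[[s]]
    m <- if (method == "bulk") {
      applyBulkSinus(baseMaps[[s]], regions[[s]], config$coefficients)
    } else {
      applyConvertedSinus(baseMaps[[s]], regions[[s]], subj@mri,
                          looModels[[s]], config$coefficients)
    }
    softMask <- maskVolume(subj@mri,
                           labelsList[[s]]@data ==
                             tissueLabels()[["soft"]])
    ref <- ctReferenceMuMap(subj@ct, softMask, config$coefficients,
                            config$bilinear)
    masks <- boneMasksForDice(subj@ct, m)
    sl <- pmin(config$sliceRange, dim(subj@ct@data)[3])
    dSin <- dice(sinusSubvolume(masks$ct, sl),
                 sinusSubvolume(masks$mrac, sl))
    dAll <- dice(masks$ct, masks$mrac)
    rs <- sampleCorrelations(ref@mu, m@mu, masks$ct,
                             nVox = config$correlation$nVox,
                             nReps = config$correlation$nReps,
                             seed = config$seed + s)
    muRef <- voiMeanMu(ref, subj@sinusVoi)
    muMethod <- voiMeanMu(m, subj@sinusVoi)
    muMaps[[s]] <- m
    refMaps[[s]] <- ref
    corSamples[[s]] <- rs
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, diceSinus = dSin, diceWhole = dAll,
      corMedian = median(rs, na.rm = TRUE),
      muRefVoi = muRef, muMethodVoi = muMethod,
      muAbsErr = abs(muMethod - muRef))
  }
  list(method = method, config = config,
       table = do.call(rbind, rows),
       muMaps = muMaps, referenceMaps = refMaps, regions = regions,
       cohortModel = cohortModel, looModels = looModels,
       correlations = corSamples, errors = errors)
}

#' Write pipeline reports to a directory
#'
#' Writes the per-subject table as TSV, a JSON summary (cohort medians,
#' conversion breakpoints, errors) and the resolved configuration as YAML.
#' Output is deterministic given the config seeds.
#'
#' @param result from \code{\link{runPipeline}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writePipelineReport <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- result$table
  write.table(format(tab, digits = 10, trim = TRUE),
              file.path(dir, paste0(result$method, "_subjects.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    method = result$method,
    nSubjects = if (is.null(tab)) 0L else nrow(tab),
    medianDiceSinus = if (is.null(tab)) NULL else median(tab$diceSinus),
    medianDiceWhole = if (is.null(tab)) NULL else median(tab$diceWhole),
    medianMuMethodVoi = if (is.null(tab)) NULL
                        else median(tab$muMethodVoi),
    medianMuRefVoi = if (is.null(tab)) NULL else median(tab$muRefVoi),
    cohortModel = if (is.null(result$cohortModel)) NULL
                  else as.list(breakpoints(result$cohortModel)),
    errors = result$errors)
  jsonlite::write_json(summary, file.path(dir,
                                          paste0(result$method,
                                                 "_summary.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeRunConfig(result$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @importFrom utils write.table
NULL
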