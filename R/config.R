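#' Construct a cohort configuration
#'
#' Defaults encode the study conditions the analysis assumes: 96 donors
#' (61 male : 35 female, ages 18-60 so the median is near 39), technical
#' duplicates per condition, about 10,000 recorded CD42b-positive events
#' per measurement, baseline platelet-complex means of 8400 singlets, 200
#' doublets, 10 triplets and 1 multiplet, and ADP stimulation multiplying
#' the doublet/triplet/multiplet means by 2.5/7/5 while depleting singlets
#' by the platelets consumed.  The inter-donor dispersion default (phi =
#' 1/460) puts the cohort SD of baseline WPA near 0.8 percentage points.
#' About 99 percent of whole-blood objects are CD42b-negative (mainly
#' erythrocytes), controlled by \code{wholeBloodPlateletFraction}.
#'
#' @param nDonors,sexFractionMale,ageRange donor demographics.
#' @param baselineMeans,adpMultipliers,dispersion class-count model.
#' @param maleAgeSlope,ageTotalSlope planted covariate effects (0 = none).
#' @param cd42bMeanlog,cd42bSdlog,cd62pMeanlog,cd62pSdlog,adpCd62pShift
#'   log-normal fluorescence model; ADP shifts the CD62P log-location.
#' @param cd62pMasking optional linear CD62P attenuation per extra platelet
#'   in an aggregate (epitope masking); disabled by default.
#' @param rbcCd42bMeanlog,rbcCd42bSdlog erythrocyte autofluorescence.
#' @param donorMfiSd inter-donor log-scale MFI random effect.
#' @param eventsPerMeasurement,coincidenceFraction,wholeBloodPlateletFraction
#'   acquisition composition.
#' @param outOfFocusFraction,batchSize,seed acquisition logistics and
#'   master seed.
#' @return a \linkS4class{CohortConfig}.
#' @examples
#' cfg <- cohortConfig(nDonors = 8, seed = 1)
#' @export
cohortConfig <- function(nDonors = 96L, sexFractionMale = 61 / 96,
                         ageRange = c(18, 60),
                         baselineMeans = c(8400, 200, 10, 1),
                         adpMultipliers = c(2.5, 7, 5),
                         dispersion = 1 / 460,
                         maleAgeSlope = 0, ageTotalSlope = 0,
                         cd42bMeanlog = log(200), cd42bSdlog = 0.35,
                         cd62pMeanlog = log(8), cd62pSdlog = 0.5,
                         adpCd62pShift = log(6), cd62pMasking = 0,
                         rbcCd42bMeanlog = 0, rbcCd42bSdlog = 0.4,
                         donorMfiSd = 0.1,
                         eventsPerMeasurement = 10000L,
                         coincidenceFraction = 0.139,
                         wholeBloodPlateletFraction = 0.01,
                         outOfFocusFraction = 0.02, batchSize = 12L,
                         seed = 1L) {
    new("CohortConfig", nDonors = as.integer(nDonors),
        sexFractionMale = sexFractionMale, ageRange = ageRange,
        baselineMeans = baselineMeans, adpMultipliers = adpMultipliers,
        dispersion = dispersion, maleAgeSlope = maleAgeSlope,
        ageTotalSlope = ageTotalSlope, cd42bMeanlog = cd42bMeanlog,
        cd42bSdlog = cd42bSdlog, cd62pMeanlog = cd62pMeanlog,
        cd62pSdlog = cd62pSdlog, adpCd62pShift = adpCd62pShift,
        cd62pMasking = cd62pMasking, rbcCd42bMeanlog = rbcCd42bMeanlog,
        rbcCd42bSdlog = rbcCd42bSdlog, donorMfiSd = donorMfiSd,
        eventsPerMeasurement = as.integer(eventsPerMeasurement),
        coincidenceFraction = coincidenceFraction,
        wholeBloodPlateletFraction = wholeBloodPlateletFraction,
        outOfFocusFraction = outOfFocusFraction,
        batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' Construct a gating configuration
#'
#' @param cd42bThreshold CD42b MFI gate; \code{"auto"} places a bimodal
#'   Otsu split on the log MFIs.
#' @param focusThreshold focus-score gate; \code{"auto"} uses the 5th
#'   percentile of focus scores among CD42b-positive events.
#' @param coincidenceExclusion drop events co-imaging a platelet and an
#'   erythrocyte.
#' @return a \linkS4class{GatingConfig}.
#' @export
gatingConfig <- function(cd42bThreshold = "auto", focusThreshold = "auto",
                         coincidenceExclusion = TRUE) {
    new("GatingConfig", cd42bThreshold = cd42bThreshold,
        focusThreshold = focusThreshold,
        coincidenceExclusion = coincidenceExclusion)
}

#' Construct a classifier configuration
#'
#' The default topology is the smallest network that convolves and pools
#' twice before a fully connected layer: 48x48 single-channel (CD42b)
#' input, conv 3x3x16, 2x2 max-pool, conv 3x3x32, 2x2 max-pool, flatten,
#' fully connected 64, 4-way softmax, trained with Adam on cross-entropy.
#'
#' @param inputSize,convFilters,kernelSize,poolSize,fcWidth topology.
#' @param epochs,learningRate,batchSize training schedule.
#' @param balanceClasses resample batches to uniform class frequency.
#' @param validationFraction stratified held-out fraction.
#' @param seed training seed.
#' @return a \linkS4class{ClassifierConfig}.
#' @export
classifierConfig <- function(inputSize = 48L, convFilters = c(16L, 32L),
                             kernelSize = 3L, poolSize = 2L,
                             fcWidth = 64L, epochs = 12L,
                             learningRate = 1e-3, batchSize = 32L,
                             balanceClasses = TRUE,
                             validationFraction = 0.2, seed = 1L) {
    new("ClassifierConfig", inputSize = as.integer(inputSize),
        convFilters = as.integer(convFilters),
        kernelSize = as.integer(kernelSize),
        poolSize = as.integer(poolSize), fcWidth = as.integer(fcWidth),
        nClasses = 4L, epochs = as.integer(epochs),
        learningRate = learningRate, batchSize = as.integer(batchSize),
        balanceClasses = balanceClasses,
        validationFraction = validationFraction, seed = as.integer(seed))
}

#' Construct a quality-control configuration
#'
#' @param bandLower,bandUpper replicate-concordance band as fractions of
#'   the pair mean (closed interval; values exactly at the bound are kept).
#' @param routQ ROUT false-discovery level.
#' @param minGroupSize smallest group size ROUT is applied to.
#' @param stage2Condition condition whose per-date mean WPA feeds ROUT.
#' @param stage2Mode exclude the whole flagged date (\code{"date"}) or
#'   only donors whose own date mean is flagged (\code{"donor"}).
#' @return a \linkS4class{QCConfig}.
#' @export
qcConfig <- function(bandLower = 0.70, bandUpper = 1.30, routQ = 0.01,
                     minGroupSize = 3L, stage2Condition = "baseline",
                     stage2Mode = "date") {
    new("QCConfig", bandLower = bandLower, bandUpper = bandUpper,
        routQ = routQ, minGroupSize = as.integer(minGroupSize),
        stage2Condition = stage2Condition, stage2Mode = stage2Mode)
}

#' Construct an end-to-end pipeline configuration
#'
#' Validation is aggregated: every invalid nested field is reported in a
#' single error.
#'
#' @param cohort,gating,classifier,qc,render module configurations.
#' @param nTrainingImages labelled synthetic training images (balanced
#'   over the four classes).
#' @param outDir output directory for tables, reports and the manifest.
#' @param logLevel one of debug, info, warning, error.
#' @return a \linkS4class{RunConfig}.
#' @export
runConfig <- function(cohort = cohortConfig(), gating = gatingConfig(),
                      classifier = classifierConfig(), qc = qcConfig(),
                      render = renderParams(), nTrainingImages = 2000L,
                      outDir = tempfile("plateletIFC_run_"),
                      logLevel = "info") {
    problems <- character()
    for (nm in c("cohort", "gating", "classifier", "qc", "render")) {
        obj <- get(nm)
        v <- validObject(obj, test = TRUE)
        if (!isTRUE(v)) {
            problems <- c(problems, sprintf("%s: %s", nm,
                                            paste(v, collapse = "; ")))
        }
    }
    if (length(problems)) {
        stop("invalid pipeline configuration:\n  ",
             paste(problems, collapse = "\n  "))
    }
    new("RunConfig", cohort = cohort, gating = gating,
        classifier = classifier, qc = qc, render = render,
        nTrainingImages = as.integer(nTrainingImages),
        outDir = outDir, logLevel = logLevel)
}
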