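#' @import methods
NULL

setClassUnion("numericOrCharacter", c("numeric", "character"))
setClassUnion("dataframeOrNULL", c("data.frame", "NULL"))

#' EventImage: one imaging-flow-cytometry event
#'
#' Container for the multi-channel pixel grid of a single acquired event.
#' Channels are \code{brightfield}, \code{cd42b} (constitutive platelet
#' marker GPIb-alpha) and \code{cd62p} (P-selectin, activation marker), all
#' sharing the same dimensions.  Synthetic events carry a ground-truth
#' annotation with the number of platelets, their pixel centres and a flag
#' for a co-imaged erythrocyte.
#'
#' @slot channels named list of non-negative intensity matrices.
#' @slot pixelSize physical pixel size in micrometres per pixel.
#' @slot annotation list with elements \code{nPlatelets}, \code{centers}
#'   (matrix with columns x, y) and \code{containsErythrocyte}; empty for
#'   unannotated (real) events.
#' @exportClass EventImage
setClass("EventImage",
    representation(channels = "list", pixelSize = "numeric",
                   annotation = "list"),
    prototype(pixelSize = 0.33, annotation = list()))

setValidity("EventImage", function(object) {
    ch <- object@channels
    if (length(ch) == 0L || !all(vapply(ch, is.matrix, logical(1)))) {
        return("channels must be a non-empty list of matrices")
    }
    dims <- vapply(ch, dim, integer(2))
    if (any(dims != dims[, 1])) {
        return("all channels must share identical dimensions")
    }
    if (any(vapply(ch, function(m) any(m < 0), logical(1)))) {
        return("pixel intensities must be non-negative")
    }
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0) {
        return("pixelSize must be a single positive number")
    }
    a <- object@annotation
    if (length(a) > 0L && !is.null(a$nPlatelets)) {
        nc <- if (is.null(a$centers)) 0L else nrow(a$centers)
        if (a$nPlatelets != nc) {
            return("annotation nPlatelets must equal the number of centers")
        }
    }
    TRUE
})

#' ClassCounts: per-measurement aggregation class counts
#'
#' Event counts m1..m4 of singlets, doublets, triplets and multiplets for
#' one measurement; the total N = m1 + m2 + m3 + m4 is the number of
#' platelet complexes acquired.
#'
#' @slot counts named integer vector of length 4 (m1..m4), all non-negative.
#' @exportClass ClassCounts
setClass("ClassCounts", representation(counts = "integer"))

setValidity("ClassCounts", function(object) {
    if (length(object@counts) != 4L) {
        return("counts must have length 4 (m1..m4)")
    }
    if (any(is.na(object@counts)) || any(object@counts < 0L)) {
        return("counts must be non-negative integers")
    }
    TRUE
})

#' Construct a ClassCounts object
#'
#' @param m1,m2,m3,m4 non-negative integer counts of singlet, doublet,
#'   triplet and multiplet events.
#' @return a \linkS4class{ClassCounts} object.
#' @examples
#' cc <- ClassCounts(8400, 200, 10, 0)
#' totalEvents(cc)
#' @export
ClassCounts <- function(m1, m2, m3, m4) {
    new("ClassCounts",
        counts = c(m1 = as.integer(m1), m2 = as.integer(m2),
                   m3 = as.integer(m3), m4 = as.integer(m4)))
}

#' RenderParams: settings for the synthetic event renderer
#'
#' @slot imageSize image edge length in pixels.
#' @slot pixelSize micrometres per pixel.
#' @slot plateletDiameter min/max platelet diameter in micrometres.
#' @slot blurSigma point-spread width in pixels; out-of-focus events are
#'   rendered at \code{outOfFocusFactor} times this width.
#' @slot outOfFocusFactor blur multiplier for out-of-focus rendering.
#' @slot centerJitter fractional jitter on tangent-disk centre distance.
#' @slot cd42bAmplitude mean per-platelet CD42b peak intensity (counts).
#' @slot cd62pAmplitude mean per-platelet CD62P peak intensity (counts).
#' @slot brightfieldLevel brightfield background level (counts).
#' @slot brightfieldAbsorption fractional transmission loss over a cell.
#' @slot rbcDiameter erythrocyte outer diameter in micrometres.
#' @slot readNoiseSd additive Gaussian read noise (counts).
#' @slot shotNoise logical; apply Poisson shot noise to each channel.
#' @exportClass RenderParams
setClass("RenderParams",
    representation(imageSize = "integer", pixelSize = "numeric",
                   plateletDiameter = "numeric", blurSigma = "numeric",
                   outOfFocusFactor = "numeric", centerJitter = "numeric",
                   cd42bAmplitude = "numeric", cd62pAmplitude = "numeric",
                   brightfieldLevel = "numeric",
                   brightfieldAbsorption = "numeric",
                   rbcDiameter = "numeric", readNoiseSd = "numeric",
                   shotNoise = "logical"))

setValidity("RenderParams", function(object) {
    if (object@imageSize < 8L) return("imageSize must be at least 8 px")
    if (any(object@plateletDiameter <= 0)) {
        return("platelet diameter must be positive")
    }
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    TRUE
})

#' Default renderer settings
#'
#' 48 x 48 px at 0.33 um/px emulates the appearance of platelets at 60x
#' magnification on an imaging flow cytometer.  Platelet diameters are drawn
#' uniformly from 2-3 um; aggregates are built from mutually tangent disks.
#' Noise follows the standard microscopy forward model: Poisson shot noise
#' on the signal plus additive Gaussian read noise, after isotropic Gaussian
#' blur.
#'
#' @param imageSize,pixelSize,plateletDiameter,blurSigma,outOfFocusFactor
#'   geometry and optics settings; see \linkS4class{RenderParams}.
#' @param centerJitter,cd42bAmplitude,cd62pAmplitude,brightfieldLevel
#'   placement jitter and channel intensities.
#' @param brightfieldAbsorption,rbcDiameter,readNoiseSd,shotNoise remaining
#'   forward-model settings; \code{shotNoise = FALSE} with
#'   \code{readNoiseSd = 0} gives a deterministic noiseless rendering.
#' @return a \linkS4class{RenderParams} object.
#' @export
renderParams <- function(imageSize = 48L, pixelSize = 0.33,
                         plateletDiameter = c(2, 3), blurSigma = 0.7,
                         outOfFocusFactor = 3, centerJitter = 0.1,
                         cd42bAmplitude = 180, cd62pAmplitude = 30,
                         brightfieldLevel = 600,
                         brightfieldAbsorption = 0.35,
                         rbcDiameter = 7, readNoiseSd = 2,
                         shotNoise = TRUE) {
    new("RenderParams", imageSize = as.integer(imageSize),
        pixelSize = pixelSize, plateletDiameter = plateletDiameter,
        blurSigma = blurSigma, outOfFocusFactor = outOfFocusFactor,
        centerJitter = centerJitter, cd42bAmplitude = cd42bAmplitude,
        cd62pAmplitude = cd62pAmplitude,
        brightfieldLevel = brightfieldLevel,
        brightfieldAbsorption = brightfieldAbsorption,
        rbcDiameter = rbcDiameter, readNoiseSd = readNoiseSd,
        shotNoise = shotNoise)
}

#' CohortConfig: parameters of the synthetic donor cohort
#'
#' Defines the statistical structure of a simulated study: donor
#' demographics, per-measurement class composition at baseline, the effect
#' of ADP stimulation, inter-donor dispersion, fluorescence-intensity
#' models, and acquisition logistics.  Defaults reproduce a cohort of 96
#' generally healthy donors (61 male, 35 female, median age 39) measured in
#' technical duplicate at baseline and after ADP stimulation, with about
#' 10,000 CD42b-positive events recorded per measurement of which the
#' platelet complexes split approximately 8400/200/10/1 into
#' singlets/doublets/triplets/multiplets.
#'
#' @slot nDonors number of donors.
#' @slot sexFractionMale fraction of male donors in [0, 1].
#' @slot ageRange min/max donor age in years (uniform draw; the default
#'   18-60 yields a median near 39).
#' @slot baselineMeans expected baseline per-measurement counts mu1..mu4.
#' @slot adpMultipliers multipliers applied by ADP stimulation to the
#'   doublet, triplet and multiplet means; singlets are depleted by the
#'   platelets consumed (2*dm2 + 3*dm3 + 4*dm4).
#' @slot dispersion inter-donor Dirichlet dispersion phi: donor class
#'   probabilities ~ Dirichlet(p/phi); 0 disables all count sampling and
#'   makes counts deterministic.
#' @slot maleAgeSlope per-year multiplicative increase of the male
#'   doublet/triplet/multiplet means, centred at age 39 (planted effect;
#'   0 = none).
#' @slot ageTotalSlope per-year multiplicative change of total platelet
#'   events with age, centred at 39 (planted effect; 0 = none).
#' @slot cd42bMeanlog,cd42bSdlog log-normal per-event platelet CD42b MFI.
#' @slot cd62pMeanlog,cd62pSdlog log-normal per-event CD62P MFI.
#' @slot adpCd62pShift additive shift of the CD62P log-location under ADP.
#' @slot cd62pMasking optional linear attenuation of CD62P per additional
#'   platelet in an aggregate (epitope masking); 0 disables.
#' @slot rbcCd42bMeanlog,rbcCd42bSdlog log-normal erythrocyte CD42b
#'   autofluorescence.
#' @slot donorMfiSd inter-donor random effect (SD on the log scale) shared
#'   by both markers.
#' @slot eventsPerMeasurement recorded CD42b-positive events per
#'   measurement (platelet complexes plus coincidence images).
#' @slot coincidenceFraction fraction of recorded events that co-image a
#'   platelet with an erythrocyte and are excluded downstream.
#' @slot wholeBloodPlateletFraction fraction of all whole-blood objects
#'   that are platelet events (the remainder are CD42b-negative, mainly
#'   erythrocytes).
#' @slot outOfFocusFraction fraction of recorded events out of camera
#'   focus.
#' @slot batchSize donors measured per acquisition date.
#' @slot seed master seed; all sub-streams derive from it.
#' @exportClass CohortConfig
setClass("CohortConfig",
    representation(nDonors = "integer", sexFractionMale = "numeric",
                   ageRange = "numeric", baselineMeans = "numeric",
                   adpMultipliers = "numeric", dispersion = "numeric",
                   maleAgeSlope = "numeric", ageTotalSlope = "numeric",
                   cd42bMeanlog = "numeric", cd42bSdlog = "numeric",
                   cd62pMeanlog = "numeric", cd62pSdlog = "numeric",
                   adpCd62pShift = "numeric", cd62pMasking = "numeric",
                   rbcCd42bMeanlog = "numeric", rbcCd42bSdlog = "numeric",
                   donorMfiSd = "numeric",
                   eventsPerMeasurement = "integer",
                   coincidenceFraction = "numeric",
                   wholeBloodPlateletFraction = "numeric",
                   outOfFocusFraction = "numeric", batchSize = "integer",
                   seed = "integer"))

setValidity("CohortConfig", function(object) {
    if (object@nDonors < 1L) return("nDonors must be at least 1")
    if (object@sexFractionMale < 0 || object@sexFractionMale > 1) {
        return("sexFractionMale must lie in [0, 1]")
    }
    if (length(object@baselineMeans) != 4L || any(object@baselineMeans < 0)) {
        return("baselineMeans must be 4 non-negative class means")
    }
    if (length(object@adpMultipliers) != 3L || any(object@adpMultipliers < 0)) {
        return("adpMultipliers must be 3 non-negative multipliers")
    }
    if (object@dispersion < 0) return("dispersion must be non-negative")
    if (object@eventsPerMeasurement < 1L) {
        return("eventsPerMeasurement must be at least 1")
    }
    if (object@coincidenceFraction < 0 || object@coincidenceFraction >= 1) {
        return("coincidenceFraction must lie in [0, 1)")
    }
    if (object@wholeBloodPlateletFraction <= 0 ||
        object@wholeBloodPlateletFraction > 1) {
        return("wholeBloodPlateletFraction must lie in (0, 1]")
    }
    if (object@outOfFocusFraction < 0 || object@outOfFocusFraction >= 1) {
        return("outOfFocusFraction must lie in [0, 1)")
    }
    if (object@batchSize < 1L) return("batchSize must be at least 1")
    TRUE
})

#' GatingConfig: conditional-gating settings
#'
#' @slot cd42bThreshold CD42b MFI gate, numeric or \code{"auto"} (bimodal
#'   Otsu split on log MFI).
#' @slot focusThreshold focus-score gate, numeric or \code{"auto"} (5th
#'   percentile among CD42b-positive events).
#' @slot coincidenceExclusion drop events co-imaging a platelet with an
#'   erythrocyte.
#' @exportClass GatingConfig
setClass("GatingConfig",
    representation(cd42bThreshold = "numericOrCharacter",
                   focusThreshold = "numericOrCharacter",
                   coincidenceExclusion = "logical"))

setValidity("GatingConfig", function(object) {
    for (nm in c("cd42bThreshold", "focusThreshold")) {
        v <- slot(object, nm)
        if (is.character(v)) {
            if (!identical(v, "auto")) {
                return(sprintf("%s must be numeric or \"auto\"", nm))
            }
        } else if (length(v) != 1L || !is.finite(v) || v <= 0) {
            return(sprintf("%s must be a single positive number", nm))
        }
    }
    TRUE
})

#' GatingReport: partition of an event stream by the gate
#'
#' @slot nInput,nOutsideCd42bGate,nOutOfFocus,nCoincidenceExcluded,nRetained
#'   event counts; the exclusion counts plus \code{nRetained} always equal
#'   \code{nInput}.
#' @slot fractionExcluded proportion of events excluded.
#' @slot resolvedCd42bThreshold,resolvedFocusThreshold numeric thresholds
#'   actually applied (after resolving \code{"auto"}).
#' @exportClass GatingReport
setClass("GatingReport",
    representation(nInput = "integer", nOutsideCd42bGate = "integer",
                   nOutOfFocus = "integer",
                   nCoincidenceExcluded = "integer", nRetained = "integer",
                   fractionExcluded = "numeric",
                   resolvedCd42bThreshold = "numeric",
                   resolvedFocusThreshold = "numeric"))

setValidity("GatingReport", function(object) {
    tot <- object@nOutsideCd42bGate + object@nOutOfFocus +
        object@nCoincidenceExcluded + object@nRetained
    if (tot != object@nInput) {
        return("exclusion counts plus retained count must equal input count")
    }
    if (object@fractionExcluded < 0 || object@fractionExcluded > 1) {
        return("fractionExcluded must lie in [0, 1]")
    }
    TRUE
})

#' ClassifierConfig: topology and training settings of the event classifier
#'
#' The network convolves and max-pools the input twice, flattens the last
#' convolution output, and feeds a fully connected layer ending in a 4-way
#' softmax over singlet/doublet/triplet/multiplet.
#'
#' @slot inputSize input edge length in pixels.
#' @slot convFilters filter counts of the two convolution stages.
#' @slot kernelSize convolution kernel edge (square kernels).
#' @slot poolSize max-pooling window edge.
#' @slot fcWidth width of the fully connected hidden layer.
#' @slot nClasses number of output classes (fixed at 4).
#' @slot epochs,learningRate,batchSize training schedule (Adam).
#' @slot balanceClasses resample training batches to uniform class
#'   frequency (singlets dominate raw data roughly 40:1).
#' @slot validationFraction held-out fraction for the stratified split.
#' @slot seed training seed (weight init and batch order).
#' @exportClass ClassifierConfig
setClass("ClassifierConfig",
    representation(inputSize = "integer", convFilters = "integer",
                   kernelSize = "integer", poolSize = "integer",
                   fcWidth = "integer", nClasses = "integer",
                   epochs = "integer", learningRate = "numeric",
                   batchSize = "integer", balanceClasses = "logical",
                   validationFraction = "numeric", seed = "integer"))

setValidity("ClassifierConfig", function(object) {
    if (length(object@convFilters) != 2L) {
        return("exactly two convolution + pooling stages are required")
    }
    if (object@nClasses != 4L) return("nClasses must be 4")
    if (object@validationFraction <= 0 || object@validationFraction >= 1) {
        return("validationFraction must lie in (0, 1)")
    }
    TRUE
})

#' ClassifierModel: a trained event classifier
#'
#' @slot params list of trained weight and bias arrays (opaque).
#' @slot config the \linkS4class{ClassifierConfig} used for training.
#' @slot metrics list with the training loss curve and held-out accuracy.
#' @exportClass ClassifierModel
setClass("ClassifierModel",
    representation(params = "list", config = "ClassifierConfig",
                   metrics = "list"))

#' QCConfig: two-stage quality-control settings
#'
#' Stage 1 excludes a donor when either technical replicate of the WPA
#' falls outside 70-130 percent of the replicate-pair mean (closed
#' interval).  Stage 2 applies the ROUT outlier test at FDR level Q to the
#' per-acquisition-date mean WPA of the retained donors.
#'
#' @slot bandLower,bandUpper concordance band as fractions of the pair mean.
#' @slot routQ ROUT false-discovery level Q.
#' @slot minGroupSize smallest group ROUT is applied to.
#' @slot stage2Condition condition whose WPA feeds stage 2
#'   (\code{"baseline"} or \code{"ADP"}).
#' @slot stage2Mode \code{"date"} removes every donor on a flagged date;
#'   \code{"donor"} removes only donors whose own date mean is flagged.
#' @exportClass QCConfig
setClass("QCConfig",
    representation(bandLower = "numeric", bandUpper = "numeric",
                   routQ = "numeric", minGroupSize = "integer",
                   stage2Condition = "character", stage2Mode = "character"))

setValidity("QCConfig", function(object) {
    if (!(object@bandLower > 0 && object@bandLower < 1 &&
          object@bandUpper > 1)) {
        return("need 0 < bandLower < 1 < bandUpper")
    }
    if (object@routQ < 0 || object@routQ >= 1) {
        return("routQ must lie in [0, 1)")
    }
    if (!object@stage2Condition %in% c("baseline", "ADP")) {
        return("stage2Condition must be \"baseline\" or \"ADP\"")
    }
    if (!object@stage2Mode %in% c("date", "donor")) {
        return("stage2Mode must be \"date\" or \"donor\"")
    }
    TRUE
})

#' QCReport: record of quality-control exclusions
#'
#' @slot stage1Excluded data.frame of donors failing replicate concordance
#'   (donor, condition, replicate values, offending ratio).
#' @slot incompleteDonors donors with a missing replicate, excluded and
#'   counted separately.
#' @slot stage2FlaggedDates acquisition dates flagged by ROUT.
#' @slot stage2Excluded donors excluded at stage 2.
#' @slot retainedDonors donors surviving both stages.
#' @exportClass QCReport
setClass("QCReport",
    representation(stage1Excluded = "data.frame",
                   incompleteDonors = "character",
                   stage2FlaggedDates = "character",
                   stage2Excluded = "character",
                   retainedDonors = "character"))

#' SyntheticCohort: a simulated study with ground truth
#'
#' @slot donors data.frame with one row per donor (id, age, sex, date).
#' @slot measurements data.frame with one row per measurement: true class
#'   counts, true WPA, measurement-level MFIs and event totals.
#' @slot events per-event table (\code{NULL} when simulated at measurement
#'   level only).
#' @slot config the \linkS4class{CohortConfig} used.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
    representation(donors = "data.frame", measurements = "data.frame",
                   events = "dataframeOrNULL", config = "CohortConfig"))

#' RunConfig: nested configuration of the end-to-end pipeline
#'
#' @slot cohort,gating,classifier,qc module configurations.
#' @slot render renderer settings used for event images.
#' @slot nTrainingImages labelled synthetic images used to train the
#'   classifier (balanced across the four classes).
#' @slot outDir output directory.
#' @slot logLevel one of debug, info, warning, error.
#' @exportClass RunConfig
setClass("RunConfig",
    representation(cohort = "CohortConfig", gating = "GatingConfig",
                   classifier = "ClassifierConfig", qc = "QCConfig",
                   render = "RenderParams", nTrainingImages = "integer",
                   outDir = "character", logLevel = "character"))

setValidity("RunConfig", function(object) {
    if (!object@logLevel %in% c("debug", "info", "warning", "error")) {
        return("logLevel must be debug, info, warning or error")
    }
    if (object@nTrainingImages < 4L) {
        return("nTrainingImages must cover all four classes")
    }
    TRUE
})
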