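#' Accessors for plateletIFC classes
#'
#' @param x an object of the documented class.
#' @param name channel name for \code{channel}.
#' @name accessors
NULL

#' @describeIn accessors total number of platelet complexes N.
#' @export
setGeneric("totalEvents", function(x) standardGeneric("totalEvents"))

#' @describeIn accessors class counts as a named integer vector m1..m4.
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @describeIn accessors one channel matrix of an event image.
#' @export
setGeneric("channel", function(x, name) standardGeneric("channel"))

#' @describeIn accessors ground-truth annotation of a synthetic event.
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))

#' @describeIn accessors physical pixel size (micrometres per pixel).
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @describeIn accessors donor table of a synthetic cohort.
#' @export
setGeneric("donors", function(x) standardGeneric("donors"))

#' @describeIn accessors measurement table of a synthetic cohort.
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' @describeIn accessors per-event table of a synthetic cohort (or NULL).
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setMethod("totalEvents", "ClassCounts", function(x) sum(x@counts))

#' @rdname accessors
#' @export
setMethod("classCounts", "ClassCounts", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("channel", "EventImage", function(x, name) {
    if (!name %in% names(x@channels)) {
        stop("unknown channel: ", name)
    }
    x@channels[[name]]
})

#' @rdname accessors
#' @export
setMethod("annotation", "EventImage", function(x) x@annotation)

#' @rdname accessors
#' @export
setMethod("pixelSize", "EventImage", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("donors", "SyntheticCohort", function(x) x@donors)

#' @rdname accessors
#' @export
setMethod("measurements", "SyntheticCohort", function(x) x@measurements)

#' @rdname accessors
#' @export
setMethod("events", "SyntheticCohort", function(x) x@events)

setMethod("show", "ClassCounts", function(object) {
    cc <- object@counts
    cat("ClassCounts: ", paste(names(cc), cc, sep = "=", collapse = " "),
        " (N=", sum(cc), ")\n", sep = "")
})

setMethod("show", "EventImage", function(object) {
    d <- dim(object@channels[[1]])
    cat(sprintf("EventImage: %dx%d px (%.2f um/px), channels: %s\n",
                d[1], d[2], object@pixelSize,
                paste(names(object@channels), collapse = ", ")))
    a <- object@annotation
    if (length(a) > 0L) {
        cat(sprintf("  annotated: %d platelet(s)%s\n", a$nPlatelets,
                    if (isTRUE(a$containsErythrocyte))
                        " + erythrocyte" else ""))
    }
})

setMethod("show", "GatingReport", function(object) {
    cat("GatingReport\n")
    cat(sprintf("  input:                 %d\n", object@nInput))
    cat(sprintf("  outside CD42b gate:    %d\n", object@nOutsideCd42bGate))
    cat(sprintf("  out of focus:          %d\n", object@nOutOfFocus))
    cat(sprintf("  coincidence excluded:  %d\n",
                object@nCoincidenceExcluded))
    cat(sprintf("  retained:              %d (%.1f%% excluded)\n",
                object@nRetained, 100 * object@fractionExcluded))
})

setMethod("show", "SyntheticCohort", function(object) {
    d <- object@donors
    cat(sprintf("SyntheticCohort: %d donors (%d male, %d female), %d measurements\n",
                nrow(d), sum(d$sex == "M"), sum(d$sex == "F"),
                nrow(object@measurements)))
    if (!is.null(object@events)) {
        cat(sprintf("  per-event table: %d events\n", nrow(object@events)))
    }
})

setMethod("show", "ClassifierModel", function(object) {
    cfg <- object@config
    cat(sprintf("ClassifierModel: %dx%d input, conv %d/%d, fc %d, 4 classes\n",
                cfg@inputSize, cfg@inputSize, cfg@convFilters[1],
                cfg@convFilters[2], cfg@fcWidth))
    if (!is.null(object@metrics$heldOutAccuracy)) {
        cat(sprintf("  held-out accuracy: %.3f\n",
                    object@metrics$heldOutAccuracy))
    }
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport\n")
    cat(sprintf("  stage 1 (replicate concordance) excluded: %d donor(s)\n",
                length(unique(object@stage1Excluded$donor_id))))
    cat(sprintf("  incomplete donors: %d\n",
                length(object@incompleteDonors)))
    cat(sprintf("  stage 2 (ROUT) flagged dates: %s\n",
                if (length(object@stage2FlaggedDates))
                    paste(object@stage2FlaggedDates, collapse = ", ")
                else "none"))
    cat(sprintf("  stage 2 excluded donors: %d\n",
                length(object@stage2Excluded)))
    cat(sprintf("  retained donors: %d\n", length(object@retainedDonors)))
})
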