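#' Focus score of an event image
#'
#' Root-mean-square of the discrete intensity-gradient magnitude over the
#' brightfield channel, normalised by the mean intensity.  Sharp images
#' score high; Gaussian blur lowers the score monotonically; the score is
#' invariant under rescaling all intensities by a positive constant.
#'
#' @param image an \linkS4class{EventImage} (brightfield channel required)
#'   or a plain intensity matrix.
#' @return a non-negative scalar.
#' @export
focusScore <- function(image) {
    m <- if (is(image, "EventImage")) channel(image, "brightfield")
         else image
    if (!is.matrix(m) || length(m) == 0L) {
        stop("focusScore requires a non-empty image")
    }
    mu <- mean(m)
    if (mu <= 0) {
        return(0)
    }
    gx <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    gy <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
    sqrt(mean(c(gx^2, gy^2))) / mu
}

## Resolve "auto" thresholds against the observed stream.
.resolveGate <- function(events, config) {
    cd42b <- config@cd42bThreshold
    if (identical(cd42b, "auto")) {
        if (nrow(events) < 50L) {
            stop("auto threshold needs at least 50 events to place ",
                 "a bimodal split")
        }
        cd42b <- exp(otsuThreshold(log(pmax(events$cd42b_mfi, 1e-12))))
    }
    focus <- config@focusThreshold
    if (identical(focus, "auto")) {
        pos <- events$focus[events$cd42b_mfi >= cd42b]
        if (length(pos) < 50L) {
            stop("auto focus threshold needs at least 50 CD42b-positive ",
                 "events")
        }
        focus <- unname(quantile(pos, 0.05, type = 7))
    }
    list(cd42b = cd42b, focus = focus)
}

#' Conditional gating of an event stream
#'
#' Reproduces the acquisition-side gate: keep events that are
#' CD42b-positive (MFI at or above the threshold), in camera focus, and --
#' when coincidence exclusion is on -- not co-imaging an erythrocyte.
#' Exclusions are counted in that order, so each event appears in exactly
#' one partition and the counts always sum to the input count.  The order
#' of retained events is preserved.
#'
#' Auto thresholds are resolved against the stream (Otsu bimodal split on
#' log CD42b MFI; 5th percentile of focus among CD42b-positive events) and
#' reported back, so a resolved configuration can be re-applied to other
#' streams or to the gate's own output.
#'
#' @param events data.frame with columns \code{cd42b_mfi} and \code{focus}
#'   (focus computed from images beforehand if absent), plus
#'   \code{contains_erythrocyte} when coincidence exclusion is on.
#' @param config a \linkS4class{GatingConfig}.
#' @return list with \code{events} (retained rows) and \code{report}
#'   (a \linkS4class{GatingReport} including the resolved thresholds).
#' @examples
#' cfg <- cohortConfig(nDonors = 1, seed = 3)
#' stream <- simulateWholeBlood(cfg, nEvents = 20000)
#' g <- gateEvents(stream, gatingConfig())
#' g$report
#' @export
gateEvents <- function(events, config = gatingConfig()) {
    validObject(config)
    n <- nrow(events)
    if (n == 0L) {
        rep0 <- new("GatingReport", nInput = 0L, nOutsideCd42bGate = 0L,
                    nOutOfFocus = 0L, nCoincidenceExcluded = 0L,
                    nRetained = 0L, fractionExcluded = 0,
                    resolvedCd42bThreshold = NA_real_,
                    resolvedFocusThreshold = NA_real_)
        return(list(events = events, report = rep0))
    }
    if (!all(c("cd42b_mfi", "focus") %in% names(events))) {
        stop("events must carry cd42b_mfi and focus columns")
    }
    thr <- .resolveGate(events, config)
    outCd42b <- events$cd42b_mfi < thr$cd42b
    outFocus <- !outCd42b & events$focus < thr$focus
    coin <- if (config@coincidenceExclusion &&
                "contains_erythrocyte" %in% names(events)) {
        !outCd42b & !outFocus & events$contains_erythrocyte
    } else {
        rep(FALSE, n)
    }
    keep <- !outCd42b & !outFocus & !coin
    report <- new("GatingReport", nInput = n,
                  nOutsideCd42bGate = sum(outCd42b),
                  nOutOfFocus = sum(outFocus),
                  nCoincidenceExcluded = sum(coin),
                  nRetained = sum(keep),
                  fractionExcluded = 1 - sum(keep) / n,
                  resolvedCd42bThreshold = thr$cd42b,
                  resolvedFocusThreshold = thr$focus)
    list(events = events[keep, , drop = FALSE], report = report)
}

#' Gating configuration with resolved thresholds
#'
#' Convenience: turn the thresholds a gate actually applied into a
#' numeric \linkS4class{GatingConfig}, e.g. to re-gate further streams with
#' the same cut-offs or to verify idempotence.
#'
#' @param report a \linkS4class{GatingReport}.
#' @param coincidenceExclusion see \code{\link{gatingConfig}}.
#' @return a \linkS4class{GatingConfig} with numeric thresholds.
#' @export
resolvedGatingConfig <- function(report, coincidenceExclusion = TRUE) {
    gatingConfig(cd42bThreshold = report@resolvedCd42bThreshold,
                 focusThreshold = report@resolvedFocusThreshold,
                 coincidenceExclusion = coincidenceExclusion)
}
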