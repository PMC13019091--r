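## Two-stage prefiltering: technical-replicate concordance on the WPA,
## then ROUT outlier removal (robust fit + FDR) on acquisition-date means.

#' Stage 1: technical-replicate concordance filter
#'
#' A donor is excluded when, for any condition, either technical replicate
#' of the WPA falls outside the configured band around the replicate-pair
#' mean (default 70-130 percent, closed interval: a replicate exactly at
#' the bound is kept).  Donors with a missing replicate are flagged
#' incomplete, excluded, and counted separately.
#'
#' @param summaries data.frame with columns \code{donor_id},
#'   \code{condition}, \code{replicate}, \code{wpa}.
#' @param config a \linkS4class{QCConfig}.
#' @return list with \code{excluded} (data.frame: donor_id, condition,
#'   wpa1, wpa2, worst ratio), \code{incomplete} (donor ids),
#'   \code{retained} (donor ids).
#' @export
replicateConcordanceFilter <- function(summaries, config = qcConfig()) {
    validObject(config)
    donorsAll <- unique(summaries$donor_id)
    excl <- list()
    incomplete <- character()
    for (d in donorsAll) {
        dd <- summaries[summaries$donor_id == d, ]
        for (cond in unique(dd$condition)) {
            w <- dd$wpa[dd$condition == cond][order(
                dd$replicate[dd$condition == cond])]
            if (length(w) != 2L || any(is.na(w))) {
                incomplete <- union(incomplete, d)
                next
            }
            mu <- mean(w)
            ratio <- if (mu > 0) w / mu else c(1, 1)
            if (any(ratio < config@bandLower - 1e-12) ||
                any(ratio > config@bandUpper + 1e-12)) {
                bad <- ratio[which.max(abs(ratio - 1))]
                excl[[length(excl) + 1L]] <- data.frame(
                    donor_id = d, condition = cond, wpa1 = w[1],
                    wpa2 = w[2], ratio = bad, stringsAsFactors = FALSE)
            }
        }
    }
    excluded <- if (length(excl)) do.call(rbind, excl) else
        data.frame(donor_id = character(0), condition = character(0),
                   wpa1 = numeric(0), wpa2 = numeric(0),
                   ratio = numeric(0), stringsAsFactors = FALSE)
    out <- setdiff(donorsAll, c(excluded$donor_id, incomplete))
    list(excluded = excluded, incomplete = incomplete, retained = out)
}

#' ROUT outlier detection for a constant model
#'
#' The published ROUT procedure (robust fit followed by a stepwise
#' false-discovery-rate test) specialised to a constant model with K = 1
#' parameter: the robust centre is the median; the robust standard
#' deviation of the residuals (RSDR) is the 68.27th percentile of the
#' absolute residuals scaled by n/(n-K); residuals are then tested from
#' most to least extreme against two-tailed t-tail probabilities with n-K
#' degrees of freedom at stepwise levels alpha_i = Q (n-i+1)/n, flagging
#' until the first non-significant residual.
#'
#' @param values numeric vector.
#' @param Q false-discovery level (Q = 0 flags nothing).
#' @param minGroupSize below this length no flags are returned (with a
#'   warning).
#' @return logical vector marking outliers.
#' @examples
#' routOutliers(c(2.0, 2.1, 1.9, 2.05, 10.0), Q = 0.01)
#' @export
routOutliers <- function(values, Q = 0.01, minGroupSize = 3L) {
    n <- length(values)
    flags <- rep(FALSE, n)
    if (Q <= 0) {
        return(flags)
    }
    if (n < minGroupSize) {
        warning("ROUT skipped: fewer than ", minGroupSize, " values")
        return(flags)
    }
    K <- 1L
    res <- values - median(values)
    rsdr <- unname(quantile(abs(res), 0.6827, type = 7)) * n / (n - K)
    if (rsdr <= 0) {
        return(flags)
    }
    ord <- order(abs(res), decreasing = TRUE)
    df <- n - K
    for (i in seq_len(n)) {
        j <- ord[i]
        p <- 2 * pt(-abs(res[j]) / rsdr, df)
        alpha <- Q * (n - i + 1) / n
        if (p < alpha) {
            flags[j] <- TRUE
        } else {
            break
        }
    }
    flags
}

#' Apply the full two-stage quality control
#'
#' Stage 1 removes donors failing replicate concordance; stage 2 computes
#' the per-acquisition-date mean WPA (of the configured reference
#' condition) over the retained donors and applies ROUT at level Q.  In
#' \code{"date"} mode every donor measured on a flagged date is excluded;
#' in \code{"donor"} mode the per-donor date means are tested instead.
#' Applying the QC to its own output excludes nothing further on clean
#' data (idempotence).
#'
#' @param summaries measurement-level data.frame with columns
#'   \code{donor_id}, \code{condition}, \code{replicate},
#'   \code{acquisition_date}, \code{wpa}.
#' @param config a \linkS4class{QCConfig}.
#' @return list with \code{summaries} (filtered, plus a \code{qc_pass}
#'   column on the input rows) and \code{report} (a
#'   \linkS4class{QCReport}).
#' @export
applyQC <- function(summaries, config = qcConfig()) {
    validObject(config)
    s1 <- replicateConcordanceFilter(summaries, config)
    kept <- summaries[summaries$donor_id %in% s1$retained, , drop = FALSE]
    condName <- if (config@stage2Condition == "baseline") "baseline"
                else "ADP"
    ref <- kept[kept$condition == condName, , drop = FALSE]
    flaggedDates <- character()
    stage2Donors <- character()
    if (nrow(ref) > 0L) {
        if (config@stage2Mode == "date") {
            agg <- aggregate(wpa ~ acquisition_date, data = ref,
                             FUN = mean)
            fl <- routOutliers(agg$wpa, config@routQ, config@minGroupSize)
            flaggedDates <- agg$acquisition_date[fl]
            stage2Donors <- unique(kept$donor_id[
                kept$acquisition_date %in% flaggedDates])
        } else {
            ## donor mode: test per-donor reference-condition means
            agg <- aggregate(wpa ~ donor_id, data = ref, FUN = mean)
            fl <- routOutliers(agg$wpa, config@routQ, config@minGroupSize)
            stage2Donors <- agg$donor_id[fl]
            flaggedDates <- unique(kept$acquisition_date[
                kept$donor_id %in% stage2Donors])
        }
    }
    retained <- setdiff(s1$retained, stage2Donors)
    filtered <- summaries[summaries$donor_id %in% retained, ,
                          drop = FALSE]
    annotated <- summaries
    annotated$qc_pass <- annotated$donor_id %in% retained
    report <- new("QCReport", stage1Excluded = s1$excluded,
                  incompleteDonors = s1$incomplete,
                  stage2FlaggedDates = as.character(flaggedDates),
                  stage2Excluded = as.character(stage2Donors),
                  retainedDonors = as.character(retained))
    list(summaries = filtered, annotated = annotated, report = report)
}
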