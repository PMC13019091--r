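#' Weighted platelet aggregation (WPA) score
#'
#' Weights each event class by the number of platelets it contains, sums,
#' divides by the total number of platelet events acquired, and subtracts
#' the singlet baseline:
#' \deqn{WPA = \left(\frac{1 m_1 + 2 m_2 + 3 m_3 + 4 m_4}{N} - 1\right)
#'   \times 100\%}
#' A measurement of exclusively singlets scores 0\%; exclusively multiplets
#' scores 300\%.  The multiplet weight is fixed at 4: aggregates of four or
#' more platelets are indistinguishable in the four-class output, and the
#' stated 300\% maximum forces the weight.
#'
#' @param counts a \linkS4class{ClassCounts} object (or a numeric vector
#'   m1..m4 of length 4).
#' @return the WPA in percent, in [0, 300].
#' @examples
#' computeWPA(ClassCounts(8400, 200, 10, 0))  # ~2.56
#' computeWPA(ClassCounts(0, 0, 0, 7))        # 300
#' @export
computeWPA <- function(counts) {
    m <- if (is(counts, "ClassCounts")) classCounts(counts) else counts
    if (length(m) != 4L || any(m < 0)) {
        stop("counts must be four non-negative class counts m1..m4")
    }
    N <- sum(m)
    if (N == 0) {
        stop("WPA is undefined for a measurement with zero events")
    }
    (sum(m * 1:4) / N - 1) * 100
}

#' Summarize one measurement from labelled events
#'
#' Tallies class labels into \linkS4class{ClassCounts}, computes the WPA,
#' and averages the per-event marker intensities.
#'
#' @param events data.frame of gated, classified events with columns
#'   \code{class} (1-4), \code{cd42b_mfi}, \code{cd62p_mfi}, and the
#'   identifying columns \code{donor_id}, \code{condition},
#'   \code{replicate}, \code{acquisition_date} (first value used).
#' @return one-row data.frame: donor_id, condition, replicate,
#'   acquisition_date, m1..m4, N, wpa, cd42b_mfi, cd62p_mfi.
#' @export
summarizeMeasurement <- function(events) {
    if (is.null(events) || nrow(events) == 0L) {
        stop("WPA is undefined for a measurement with zero gated events")
    }
    if (!"class" %in% names(events) || any(is.na(events$class))) {
        stop("every event must carry a class label")
    }
    m <- tabulate(events$class, 4L)
    first <- function(col, default = NA) {
        if (col %in% names(events)) events[[col]][1] else default
    }
    data.frame(donor_id = first("donor_id"),
               condition = first("condition"),
               replicate = first("replicate"),
               acquisition_date = first("acquisition_date"),
               m1 = m[1], m2 = m[2], m3 = m[3], m4 = m[4], N = sum(m),
               wpa = computeWPA(m),
               cd42b_mfi = mean(events$cd42b_mfi),
               cd62p_mfi = mean(events$cd62p_mfi),
               stringsAsFactors = FALSE)
}
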