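## Cohort-level statistical layer: condition and sex contrasts, age
## regressions.  Tests follow the reporting convention of the study
## design: Welch's t for normal data, Mann-Whitney otherwise, Pearson
## (ordinary least squares) regression for age trends, no
## multiple-testing correction.

.statRow <- function(test, estimate, statistic, p, ciLow = NA, ciHigh = NA,
                     r2 = NA, n1 = NA, n2 = NA, reporting = NA_character_) {
    data.frame(test = test, estimate = estimate, statistic = statistic,
               p = p, ci_low = ciLow, ci_high = ciHigh, r2 = r2,
               n1 = n1, n2 = n2, reporting = reporting,
               stringsAsFactors = FALSE)
}

#' Two-group contrast with normality-dependent test choice
#'
#' In \code{"auto"} mode each group is checked for normality
#' (Shapiro-Wilk at alpha = 0.05); Welch's t-test is used when both groups
#' pass, the Mann-Whitney test otherwise.  The Mann-Whitney null is exact
#' for combined n of at most 20 without ties, and a tie-corrected normal
#' approximation otherwise.  The reporting mode follows the same check:
#' mean with SD for normal data, median with a distribution-free
#' (order-statistic) 95 percent confidence interval otherwise.
#'
#' @param x,y numeric group vectors (each n >= 3).
#' @param mode \code{"auto"}, \code{"welch"} or \code{"mannwhitney"}.
#' @return a one-row data.frame (test, estimate, statistic, p, CI, group
#'   sizes, reporting mode).
#' @examples
#' contrastGroups(c(1, 2, 3), c(4, 5, 6), mode = "mannwhitney")
#' @export
contrastGroups <- function(x, y, mode = c("auto", "welch",
                                          "mannwhitney")) {
    mode <- match.arg(mode)
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 3L || length(y) < 3L) {
        stop("each group needs at least 3 values")
    }
    normal <- function(v) {
        length(unique(v)) > 1L && shapiro.test(v)$p.value >= 0.05
    }
    bothNormal <- normal(x) && normal(y)
    if (mode == "auto") {
        mode <- if (bothNormal) "welch" else "mannwhitney"
    }
    reporting <- if (bothNormal) "mean_sd" else "median_ci"
    if (mode == "welch") {
        tt <- t.test(x, y, var.equal = FALSE)
        .statRow("welch_t", estimate = mean(x) - mean(y),
                 statistic = unname(tt$statistic), p = tt$p.value,
                 ciLow = tt$conf.int[1], ciHigh = tt$conf.int[2],
                 n1 = length(x), n2 = length(y), reporting = reporting)
    } else {
        exact <- (length(x) + length(y)) <= 20L &&
            !anyDuplicated(c(x, y))
        wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                           correct = !exact))
        ciX <- medianCI(x)
        .statRow("mann_whitney", estimate = median(x) - median(y),
                 statistic = unname(wt$statistic), p = wt$p.value,
                 ciLow = ciX[1], ciHigh = ciX[2],
                 n1 = length(x), n2 = length(y), reporting = reporting)
    }
}

#' Age regression of an outcome
#'
#' Ordinary least squares of \code{y} on age within the requested stratum:
#' slope, intercept, squared Pearson correlation, and the two-sided p-value
#' from the t distribution with n - 2 degrees of freedom.
#'
#' @param age numeric ages in years.
#' @param y outcome vector.
#' @param sex optional factor/character used for stratification.
#' @param stratum \code{"all"}, \code{"male"} or \code{"female"}.
#' @return a one-row data.frame with the slope as estimate.
#' @export
ageRegression <- function(age, y, sex = NULL,
                          stratum = c("all", "male", "female")) {
    stratum <- match.arg(stratum)
    if (stratum != "all") {
        if (is.null(sex)) {
            stop("sex is required for a stratified regression")
        }
        keep <- sex == (if (stratum == "male") "M" else "F")
        age <- age[keep]
        y <- y[keep]
    }
    ok <- is.finite(age) & is.finite(y)
    age <- age[ok]
    y <- y[ok]
    n <- length(age)
    if (n < 3L) {
        stop("need at least 3 observations in the stratum")
    }
    if (var(age) == 0) {
        stop("zero variance in age; slope is unidentifiable")
    }
    fit <- lm(y ~ age)
    sm <- summary(fit)
    slope <- unname(coef(fit)[2])
    se <- sm$coefficients[2, 2]
    tval <- slope / se
    p <- 2 * pt(-abs(tval), df = n - 2)
    ci <- slope + c(-1, 1) * qt(0.975, n - 2) * se
    .statRow(paste0("age_regression_", stratum), estimate = slope,
             statistic = tval, p = p, ciLow = ci[1], ciHigh = ci[2],
             r2 = sm$r.squared, n1 = n)
}

#' ADP condition response of a cohort
#'
#' Cohort means per aggregation class and condition, fold changes
#' (ADP mean over baseline mean) per class and for the WPA, and paired
#' contrasts on the per-donor WPA and CD62P MFI.  A class whose baseline
#' mean is zero gets an undefined (NA) fold change rather than infinity.
#'
#' @param summaries measurement-level data.frame with columns
#'   \code{donor_id}, \code{condition}, \code{m1..m4}, \code{wpa},
#'   \code{cd62p_mfi}.
#' @return list with \code{classMeans} (class x condition means),
#'   \code{foldChanges} (named vector m1..m4, wpa; NA where undefined),
#'   \code{wpaContrast} and \code{cd62pContrast} (paired t-tests on donor
#'   means).
#' @export
conditionResponse <- function(summaries) {
    need <- c("donor_id", "condition", "m1", "m2", "m3", "m4", "wpa")
    if (!all(need %in% names(summaries))) {
        stop("summaries must carry ", paste(need, collapse = ", "))
    }
    vars <- c("m1", "m2", "m3", "m4", "wpa")
    donorMeans <- aggregate(
        summaries[, c(vars, intersect("cd62p_mfi", names(summaries)))],
        by = list(donor_id = summaries$donor_id,
                  condition = summaries$condition), FUN = mean)
    base <- donorMeans[donorMeans$condition == "baseline", ]
    adp <- donorMeans[donorMeans$condition == "ADP", ]
    if (nrow(base) == 0L || nrow(adp) == 0L) {
        stop("paired baseline/ADP summaries are required")
    }
    common <- intersect(base$donor_id, adp$donor_id)
    base <- base[match(common, base$donor_id), ]
    adp <- adp[match(common, adp$donor_id), ]
    classMeans <- rbind(baseline = colMeans(base[, vars]),
                        ADP = colMeans(adp[, vars]))
    folds <- ifelse(classMeans["baseline", ] > 0,
                    classMeans["ADP", ] / classMeans["baseline", ],
                    NA_real_)
    paired <- function(a, b, label) {
        ## constant differences (e.g. zero-dispersion cohorts) have no
        ## paired-t sampling distribution; report the estimate alone
        if (length(a) < 3L || sd(b - a) == 0) {
            return(.statRow(label, estimate = mean(b - a),
                            statistic = NA_real_, p = NA_real_,
                            n1 = length(a)))
        }
        tt <- t.test(b, a, paired = TRUE)
        .statRow(label, estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic), p = tt$p.value,
                 ciLow = tt$conf.int[1], ciHigh = tt$conf.int[2],
                 n1 = length(a))
    }
    cd62p <- if ("cd62p_mfi" %in% names(base)) {
        paired(base$cd62p_mfi, adp$cd62p_mfi, "cd62p_adp_response")
    } else NULL
    list(classMeans = classMeans,
         foldChanges = folds,
         wpaContrast = paired(base$wpa, adp$wpa, "wpa_adp_response"),
         cd62pContrast = cd62p)
}

#' Standard cohort statistics table
#'
#' Runs the study's statistical layer on QC-passed measurement summaries
#' merged with donor covariates: sex contrast on baseline WPA, age
#' regressions of baseline WPA per stratum, and the ADP condition
#' response.  Returns one row per test.
#'
#' @param summaries measurement-level data.frame including \code{age} and
#'   \code{sex} columns.
#' @return data.frame of test results.
#' @export
cohortStatistics <- function(summaries) {
    donorBase <- aggregate(
        summaries[summaries$condition == "baseline",
                  c("wpa", "m1", "m2", "m3", "m4")],
        by = list(donor_id = summaries$donor_id[
                      summaries$condition == "baseline"]),
        FUN = mean)
    cov <- unique(summaries[, c("donor_id", "age", "sex")])
    donorBase <- merge(donorBase, cov, by = "donor_id")
    rows <- list()
    if (all(c("M", "F") %in% donorBase$sex) &&
        min(table(donorBase$sex)) >= 3) {
        sexRow <- contrastGroups(donorBase$wpa[donorBase$sex == "M"],
                                 donorBase$wpa[donorBase$sex == "F"])
        sexRow$test <- paste0("sex_contrast_wpa_", sexRow$test)
        rows <- c(rows, list(sexRow))
    }
    for (st in c("all", "male", "female")) {
        r <- try(ageRegression(donorBase$age, donorBase$wpa,
                               donorBase$sex, st), silent = TRUE)
        if (!inherits(r, "try-error")) {
            r$test <- paste0("wpa_", r$test)
            rows <- c(rows, list(r))
        }
    }
    if (all(c("baseline", "ADP") %in% summaries$condition)) {
        cr <- conditionResponse(summaries)
        rows <- c(rows, list(cr$wpaContrast),
                  if (!is.null(cr$cd62pContrast)) list(cr$cd62pContrast))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
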