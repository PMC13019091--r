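test_that("replicate concordance keeps the 70%/130% bounds inclusive", {
    s <- qcSummaries(list(c(2.0, 4.0),    # 66.7% of mean -> excluded
                          c(3.0, 3.0),    # both at 100% -> kept
                          c(2.1, 3.9)))   # exactly 70% -> kept (inclusive)
    r <- replicateConcordanceFilter(s, qcConfig())
    expect_equal(unique(r$excluded$donor_id), "D001")
    expect_setequal(r$retained, c("D002", "D003"))

    ## missing replicate: flagged incomplete, not band-excluded
    s2 <- s[-1, ]
    r2 <- replicateConcordanceFilter(s2, qcConfig())
    expect_equal(r2$incomplete, "D001")
    expect_false("D001" %in% r2$retained)

    expect_error(qcConfig(bandLower = 1.2), "bandLower")
})

test_that("ROUT flags the planted point and respects the FDR budget", {
    ## frozen hand computation: residuals from the median 2.05 are
    ## (-0.05, 0.05, -0.15, 0, 7.95); the 68.27th percentile of their
    ## absolute values (type-7) is 0.1231, so RSDR = 0.1231 * 5/4 =
    ## 0.1538; |7.95|/RSDR = 51.7 with df = 4 is overwhelmingly
    ## significant at alpha_1 = Q; the next residual 0.15 gives t = 0.97,
    ## p = 0.385 > alpha_2 = 0.008, so testing stops.
    v <- c(2.0, 2.1, 1.9, 2.05, 10.0)
    expect_equal(routOutliers(v, Q = 0.01),
                 c(FALSE, FALSE, FALSE, FALSE, TRUE))
    ## RSDR = (0.05 + 0.7308 * 0.10) * 5/4 = 0.15385
    rsdr <- unname(quantile(abs(v - median(v)), 0.6827, type = 7)) * 5 / 4
    expect_equal(rsdr, 0.15385, tolerance = 1e-5)

    expect_equal(routOutliers(rep(5, 5), Q = 0.01), rep(FALSE, 5))
    expect_equal(routOutliers(v, Q = 0), rep(FALSE, 5))
    expect_warning(fl <- routOutliers(c(1, 2), Q = 0.01), "fewer than")
    expect_equal(fl, c(FALSE, FALSE))

    ## monotonicity: larger Q never flags fewer points
    set.seed(31)
    for (i in 1:20) {
        x <- c(rnorm(8), rnorm(2, 6))
        f1 <- routOutliers(x, Q = 0.01)
        f2 <- routOutliers(x, Q = 0.05)
        expect_true(all(f2[f1]))
    }
})

test_that("full QC removes planted dates, keeps clean cohorts, idempotent", {
    ## clean tight cohort over 10 acquisition dates: nothing excluded
    set.seed(9)
    dates <- rep(format(as.Date("2023-01-09") + 7 * (0:9)), each = 4)
    clean <- qcSummaries(lapply(1:40, function(i) 2.5 + rnorm(2, 0, 0.05)),
                         dates = dates)
    q <- applyQC(clean, qcConfig())
    expect_equal(length(q$report@retainedDonors), 40L)
    expect_equal(length(q$report@stage2FlaggedDates), 0L)

    ## one date shifted by +10 SD: its donors go at stage 2
    shifted <- clean
    hit <- shifted$acquisition_date == max(dates)
    shifted$wpa[hit] <- shifted$wpa[hit] + 10 * sd(clean$wpa)
    q2 <- applyQC(shifted, qcConfig())
    expect_equal(q2$report@stage2FlaggedDates, max(dates))
    expect_equal(sort(unique(shifted$donor_id[hit])),
                 sort(q2$report@stage2Excluded))
    expect_equal(length(q2$report@retainedDonors), 36L)

    ## idempotence: re-running on the filtered output excludes nothing
    q3 <- applyQC(q2$summaries, qcConfig())
    expect_equal(sort(q3$report@retainedDonors),
                 sort(q2$report@retainedDonors))
    expect_equal(nrow(q3$report@stage1Excluded), 0L)

    ## donor mode excludes the same donors here
    q4 <- applyQC(shifted, qcConfig(stage2Mode = "donor"))
    expect_setequal(q4$report@stage2Excluded, q2$report@stage2Excluded)
})

test_that("widening the concordance band never excludes more donors", {
    set.seed(10)
    pairs <- lapply(1:30, function(i) {
        w <- 2.5 * exp(rnorm(1, 0, 0.3))
        c(w, w * exp(rnorm(1, 0, 0.25)))
    })
    s <- qcSummaries(pairs)
    n1 <- length(replicateConcordanceFilter(
        s, qcConfig(bandLower = 0.85, bandUpper = 1.15))$retained)
    n2 <- length(replicateConcordanceFilter(
        s, qcConfig(bandLower = 0.70, bandUpper = 1.30))$retained)
    n3 <- length(replicateConcordanceFilter(
        s, qcConfig(bandLower = 0.50, bandUpper = 1.50))$retained)
    expect_lte(n1, n2)
    expect_lte(n2, n3)
})
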