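test_that("WPA reproduces the baseline worked example and endpoints", {
    ## (8400, 200, 10, 0): (8830/8610 - 1) * 100
    expect_equal(computeWPA(ClassCounts(8400, 200, 10, 0)),
                 (8830 / 8610 - 1) * 100)
    expect_equal(round(computeWPA(ClassCounts(8400, 200, 10, 0)), 2), 2.56)
    for (N in c(1, 17, 5000)) {
        expect_identical(computeWPA(c(N, 0, 0, 0)), 0)
    }
    for (M in c(1, 3, 999)) {
        expect_identical(computeWPA(c(0, 0, 0, M)), 300)
    }
    expect_equal(computeWPA(c(0, 50, 0, 0)), 100)
})

test_that("WPA rejects empty or malformed counts", {
    expect_error(computeWPA(c(0, 0, 0, 0)), "undefined")
    expect_error(computeWPA(c(-1, 2, 0, 0)), "non-negative")
    expect_error(ClassCounts(-1, 0, 0, 0))
})

test_that("WPA is bounded, scale-invariant and exactly monotone in swaps", {
    set.seed(42)
    for (i in 1:200) {
        m <- rpois(4, c(800, 40, 5, 2))
        if (sum(m) == 0) m[1] <- 1
        w <- computeWPA(m)
        expect_gte(w, 0)
        expect_lte(w, 300)
        expect_equal(computeWPA(m * sample(2:9, 1)), w)
        if (m[1] > 0) {
            ## one singlet -> doublet raises WPA by exactly 100/N
            expect_equal(computeWPA(m + c(-1, 1, 0, 0)) - w, 100 / sum(m))
        }
    }
})

test_that("summarizeMeasurement tallies labels and averages MFIs", {
    ev <- data.frame(donor_id = "D001", condition = "baseline",
                     replicate = 1L, acquisition_date = "2023-01-09",
                     class = c(1L, 1L, 2L),
                     cd42b_mfi = c(100, 200, 300),
                     cd62p_mfi = c(5, 10, 15))
    s <- summarizeMeasurement(ev)
    expect_equal(unlist(s[, c("m1", "m2", "m3", "m4")], use.names = FALSE),
                 c(2, 1, 0, 0))
    expect_equal(s$wpa, (4 / 3 - 1) * 100)
    expect_equal(s$cd42b_mfi, 200)
    ## permutation invariance
    s2 <- summarizeMeasurement(ev[c(3, 1, 2), ])
    expect_equal(s2$wpa, s$wpa)
    expect_equal(s2[, -1], s[, -1])
    ## all singlets and degenerate inputs
    ev$class <- 1L
    expect_equal(summarizeMeasurement(ev)$wpa, 0)
    expect_error(summarizeMeasurement(ev[0, ]), "zero gated")
    ev$class <- c(1L, NA, 2L)
    expect_error(summarizeMeasurement(ev), "class label")
})
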