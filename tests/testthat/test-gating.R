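test_that("focus score behaves like a gradient sharpness measure", {
    expect_equal(focusScore(matrix(7, 20, 20)), 0)
    set.seed(6)
    sharp <- renderEvent(2, noiselessParams())
    set.seed(6)
    blurred <- renderEvent(2, noiselessParams(), outOfFocus = TRUE)
    expect_gt(focusScore(sharp), focusScore(blurred))
    ## invariance under positive intensity rescaling
    m <- channel(sharp, "brightfield")
    expect_equal(focusScore(m * 37.5), focusScore(m))
    expect_error(focusScore(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("gating partitions the stream and excludes ~99% of whole blood", {
    cfg <- cohortConfig(nDonors = 1, seed = 14)
    stream <- simulateWholeBlood(cfg, nEvents = 50000)
    g <- gateEvents(stream, gatingConfig())
    r <- g$report
    expect_equal(r@nOutsideCd42bGate + r@nOutOfFocus +
                 r@nCoincidenceExcluded + r@nRetained, r@nInput)
    expect_equal(r@nInput, nrow(stream))
    ## ~99% of whole-blood objects fall outside the CD42b gate
    frac <- r@nOutsideCd42bGate / r@nInput
    expect_gt(frac, 0.985)
    expect_lt(frac, 0.995)
    ## retained events keep their stream order
    expect_true(!is.unsorted(match(g$events$event_id,
                                   stream$event_id)))
})

test_that("gating is idempotent at resolved thresholds and monotone", {
    cfg <- cohortConfig(nDonors = 1, seed = 15)
    set.seed(15)
    m <- simulateMeasurement(condition = "baseline", config = cfg)
    g1 <- gateEvents(m$events, gatingConfig())
    resolved <- resolvedGatingConfig(g1$report)
    g2 <- gateEvents(g1$events, resolved)
    expect_equal(g2$report@nRetained, g1$report@nRetained)
    expect_equal(g2$report@fractionExcluded, 0)

    ## raising the CD42b threshold never increases retention
    thr <- g1$report@resolvedCd42bThreshold
    kept <- vapply(c(1, 2, 5, 20), function(f) {
        gateEvents(m$events, gatingConfig(cd42bThreshold = thr * f,
                                          focusThreshold = 1e-9)
                   )$report@nRetained
    }, integer(1))
    expect_true(all(diff(kept) <= 0))
})

test_that("gating handles clean, empty and undersized streams", {
    ## only in-focus platelets above threshold: everything retained
    ev <- data.frame(event_id = 1:100,
                     cd42b_mfi = rlnorm(100, log(200), 0.3),
                     focus = rnorm(100, 0.5, 0.02),
                     contains_erythrocyte = FALSE)
    g <- gateEvents(ev, gatingConfig(cd42bThreshold = 10,
                                     focusThreshold = 0.2))
    expect_equal(g$report@nRetained, 100L)
    expect_equal(g$report@fractionExcluded, 0)

    g0 <- gateEvents(ev[0, ], gatingConfig())
    expect_equal(nrow(g0$events), 0L)
    expect_equal(g0$report@nInput, 0L)

    expect_error(gateEvents(ev[1:10, ], gatingConfig()), "at least 50")
    expect_error(gatingConfig(cd42bThreshold = -2), "positive")
})
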