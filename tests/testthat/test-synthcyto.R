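test_that("rendered events record their geometry and stay reproducible", {
    p0 <- noiselessParams()
    set.seed(1)
    img <- renderEvent(1, p0)
    a <- annotation(img)
    expect_equal(a$nPlatelets, 1L)
    expect_equal(nrow(a$centers), 1L)
    ## one connected bright region: positive over the whole footprint
    m <- channel(img, "cd42b")
    expect_gt(m[round(a$centers[1, 2]), round(a$centers[1, 1])], 0)
    expect_true(all(m >= 0))

    set.seed(2)
    img2 <- renderEvent(2, p0)
    expect_equal(oracleClassify(img2), 2L)
    ## every annotated centre sits on positive cd42b signal
    m2 <- channel(img2, "cd42b")
    for (i in 1:2) {
        expect_gt(m2[round(annotation(img2)$centers[i, 2]),
                     round(annotation(img2)$centers[i, 1])], 0)
    }

    ## seeded determinism at default noise
    set.seed(33)
    imgA <- renderEvent(4, renderParams())
    set.seed(33)
    imgB <- renderEvent(4, renderParams())
    expect_identical(imgA@channels, imgB@channels)

    expect_error(renderEvent(0), "nPlatelets")
    expect_error(renderParams(imageSize = 4), "at least 8")
    expect_error(renderParams(plateletDiameter = c(-1, 2)), "positive")
})

test_that("background events match their kind", {
    p0 <- noiselessParams()
    cfg <- cohortConfig()
    set.seed(3)
    rbc <- renderBackgroundEvent("erythrocyte", p0)
    ## CD42b MFI far below the platelet signal range
    expect_lt(mean(channel(rbc, "cd42b")), 5)
    expect_true(annotation(rbc)$containsErythrocyte)

    set.seed(4)
    co <- renderBackgroundEvent("coincidence", p0)
    expect_true(annotation(co)$containsErythrocyte)
    expect_gte(annotation(co)$nPlatelets, 1L)

    set.seed(5)
    d1 <- renderBackgroundEvent("debris")
    set.seed(5)
    d2 <- renderBackgroundEvent("debris")
    expect_identical(d1@channels, d2@channels)

    expect_error(renderBackgroundEvent("virus"))
})

test_that("zero-dispersion measurements hit the configured counts exactly", {
    cfg <- cohortConfig(nDonors = 1, dispersion = 0,
                        baselineMeans = c(8400, 200, 10, 0),
                        coincidenceFraction = 0,
                        eventsPerMeasurement = 8610L)
    m <- simulateMeasurement(condition = "baseline", config = cfg,
                             perEvent = FALSE)
    expect_equal(unname(classCounts(m$truth$counts)),
                 c(8400L, 200L, 10L, 0L))

    ## ADP multipliers (2.5, 7, 5): doublets 500, triplets 70, multiplets
    ## stay 0, singlets depleted by 2*300 + 3*60 = 780
    ma <- simulateMeasurement(condition = "ADP", config = cfg,
                              perEvent = FALSE)
    expect_equal(unname(classCounts(ma$truth$counts)),
                 c(8400L - 780L, 500L, 70L, 0L))

    expect_error(cohortConfig(eventsPerMeasurement = 0),
                 "eventsPerMeasurement")
    ## depletion exceeding singlets is a parameterization error
    bad <- cohortConfig(baselineMeans = c(100, 200, 10, 1))
    expect_error(
        simulateMeasurement(condition = "ADP", config = bad,
                            perEvent = FALSE),
        "depletion")
})

test_that("per-event labels aggregate exactly to the measurement counts", {
    cfg <- cohortConfig(nDonors = 1, eventsPerMeasurement = 2000L,
                        seed = 8)
    set.seed(8)
    m <- simulateMeasurement(condition = "baseline", config = cfg)
    tab <- tabulate(m$events$gt_class[m$events$kind == "platelet"], 4L)
    expect_equal(tab, unname(classCounts(m$truth$counts)))
    ## event ids unique within the measurement
    expect_false(anyDuplicated(m$events$event_id) > 0)
})

test_that("cohorts are deterministic with the configured demographics", {
    cfg <- cohortConfig(nDonors = 96, sexFractionMale = 61 / 96,
                        eventsPerMeasurement = 500L, seed = 21)
    sc <- simulateCohort(cfg)
    expect_equal(sum(donors(sc)$sex == "M"), 61)
    expect_equal(sum(donors(sc)$sex == "F"), 35)
    expect_equal(nrow(measurements(sc)), 96 * 4)
    ## batches of up to 12 donors share an acquisition date
    expect_equal(length(unique(donors(sc)$acquisition_date)), 8)

    sc2 <- simulateCohort(cfg)
    expect_identical(measurements(sc), measurements(sc2))
    expect_identical(donors(sc), donors(sc2))

    ## zero dispersion, no planted slopes: all donors share the true WPA
    flat <- simulateCohort(cohortConfig(nDonors = 6, dispersion = 0,
                                        eventsPerMeasurement = 1000L))
    expect_equal(length(unique(donors(flat)$true_wpa_baseline)), 1L)

    expect_error(cohortConfig(nDonors = 0), "nDonors")
})

test_that("expected WPA rises strictly with the ADP doublet multiplier", {
    wpaFor <- function(d2) {
        cfg <- cohortConfig(adpMultipliers = c(d2, 7, 5))
        mu <- plateletIFC:::conditionClassMeans(cfg, "ADP")
        (sum(mu * 1:4) / sum(mu) - 1) * 100
    }
    vals <- vapply(seq(1, 3, by = 0.25), wpaFor, 0)
    expect_true(all(diff(vals) > 0))
})

test_that("planted age decline in platelet totals is recovered", {
    sc <- simulateCohort(cohortConfig(nDonors = 60, ageTotalSlope = -0.008,
                                      eventsPerMeasurement = 4000L,
                                      seed = 29),
                         conditions = "baseline")
    m <- measurements(sc)
    dm <- aggregate(cbind(N, age) ~ donor_id, data = m, FUN = mean)
    r <- ageRegression(dm$age, dm$N)
    expect_lt(r$estimate, 0)
    expect_lt(r$p, 0.01)
})

test_that("baseline-only cohorts reproduce the full run's measurements", {
    cfg <- cohortConfig(nDonors = 4, eventsPerMeasurement = 400L,
                        seed = 13)
    full <- measurements(simulateCohort(cfg))
    base <- measurements(simulateCohort(cfg, conditions = "baseline"))
    fullBase <- full[full$condition == "baseline", ]
    rownames(fullBase) <- NULL
    expect_identical(fullBase, base)
})
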