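## independent Mann-Whitney oracle: full enumeration of group assignments
enumMannWhitneyP <- function(x, y) {
    nx <- length(x)
    pooled <- c(x, y)
    n <- length(pooled)
    uStat <- function(ix) {
        r <- rank(pooled)
        sum(r[ix]) - nx * (nx + 1) / 2
    }
    uObs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
    combos <- combn(n, nx)
    us <- apply(combos, 2, function(ix) {
        sum(rank(pooled)[ix]) - nx * (nx + 1) / 2
    })
    mu <- length(x) * length(y) / 2
    mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}

test_that("Mann-Whitney matches exact enumeration on small samples", {
    r <- contrastGroups(c(1, 2, 3), c(4, 5, 6), mode = "mannwhitney")
    expect_equal(unname(r$statistic), 0)
    expect_equal(r$p, 0.1)   # 2/20 rank assignments as extreme
    expect_equal(r$p, enumMannWhitneyP(c(1, 2, 3), c(4, 5, 6)))

    set.seed(17)
    for (i in 1:10) {
        x <- round(rnorm(4), 3)
        y <- round(rnorm(5, 0.5), 3)
        r <- contrastGroups(x, y, mode = "mannwhitney")
        expect_equal(r$p, enumMannWhitneyP(x, y), tolerance = 1e-10)
    }
})

test_that("degenerate contrasts behave as expected", {
    x <- c(1, 2, 3, 4)
    r <- contrastGroups(x, x, mode = "mannwhitney")
    expect_equal(r$estimate, 0)
    expect_equal(r$p, 1)

    ## Welch on equal means, unequal variances
    a <- c(-1, 0, 1)
    b <- c(-10, 0, 10)
    rw <- contrastGroups(a, b, mode = "welch")
    expect_equal(unname(rw$statistic), 0)
    expect_equal(rw$p, 1)

    expect_error(contrastGroups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("auto mode picks Welch for normal and MW for skewed data", {
    set.seed(18)
    xn <- rnorm(30)
    yn <- rnorm(30, 0.2)
    expect_equal(contrastGroups(xn, yn)$test, "welch_t")
    xs <- rlnorm(30, 0, 1.5)
    ys <- rlnorm(30, 0.2, 1.5)
    expect_equal(contrastGroups(xs, ys)$test, "mann_whitney")
})

test_that("age regression matches the closed-form normal equations", {
    age <- c(21, 35, 44, 52, 60, 27, 39)
    y <- 2 * age + 1
    r <- ageRegression(age, y)
    expect_equal(r$estimate, 2, tolerance = 1e-12)
    expect_equal(r$r2, 1, tolerance = 1e-12)
    expect_lt(r$p, 1e-10)

    set.seed(19)
    y2 <- 0.3 * age + rnorm(7, 0, 2)
    r2 <- ageRegression(age, y2)
    ## independent closed form
    bx <- cov(age, y2) / var(age)
    expect_equal(r2$estimate, bx, tolerance = 1e-10)
    expect_equal(r2$r2, cor(age, y2)^2, tolerance = 1e-10)
    n <- length(age)
    se <- sqrt((sum((y2 - mean(y2) - bx * (age - mean(age)))^2) /
                (n - 2)) / sum((age - mean(age))^2))
    expect_equal(r2$p, 2 * pt(-abs(bx / se), n - 2), tolerance = 1e-10)

    expect_error(ageRegression(rep(40, 5), rnorm(5)), "zero variance")
    expect_error(ageRegression(age, y, stratum = "male"), "sex")
})

test_that("condition response recovers the configured fold changes", {
    cfg <- cohortConfig(nDonors = 4, dispersion = 0,
                        baselineMeans = c(8400, 200, 10, 0),
                        adpMultipliers = c(2.5, 7, 5),
                        eventsPerMeasurement = 10000L, seed = 20)
    m <- measurements(simulateCohort(cfg))
    m$wpa <- m$true_wpa
    cr <- conditionResponse(m)
    expect_equal(unname(cr$foldChanges["m2"]), 2.5)
    expect_equal(unname(cr$foldChanges["m3"]), 7)
    ## multiplet baseline mean 0: undefined, not infinite
    expect_true(is.na(cr$foldChanges["m4"]))
    ## WPA fold close to the closed-form ratio
    expect_equal(unname(cr$foldChanges["wpa"]),
                 mean(m$true_wpa[m$condition == "ADP"]) /
                 mean(m$true_wpa[m$condition == "baseline"]))

    ## no stimulation effect: all folds 1
    flat <- cohortConfig(nDonors = 4, dispersion = 0,
                         adpMultipliers = c(1, 1, 1), seed = 20)
    mf <- measurements(simulateCohort(flat))
    mf$wpa <- mf$true_wpa
    crf <- conditionResponse(mf)
    expect_true(all(abs(crf$foldChanges[c("m1", "m2", "m3", "wpa")] - 1)
                    < 1e-12))
})

test_that("planted male-only age slope is recovered in the right stratum", {
    maleSlopes <- numeric(20)
    femaleSlopes <- numeric(20)
    for (s in 1:20) {
        sc <- simulateCohort(cohortConfig(nDonors = 80,
                                          sexFractionMale = 49 / 80,
                                          maleAgeSlope = 0.04,
                                          seed = 2000 + s))
        m <- measurements(sc)
        base <- m[m$condition == "baseline", ]
        dm <- aggregate(cbind(m3, age) ~ donor_id + sex, data = base,
                        FUN = mean)
        maleSlopes[s] <- ageRegression(dm$age, dm$m3, dm$sex,
                                       "male")$estimate
        femaleSlopes[s] <- ageRegression(dm$age, dm$m3, dm$sex,
                                         "female")$estimate
    }
    expect_gte(sum(maleSlopes > 0), 17)
    ## female stratum carries no effect: mean slope near zero
    expect_lt(abs(mean(femaleSlopes)), 0.25 * mean(maleSlopes))
})
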