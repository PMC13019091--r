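## Synthetic cohort simulation.  Counts follow a Dirichlet-multinomial:
## each donor perturbs the condition-specific class probabilities through a
## single Dirichlet draw (dispersion phi); at phi = 0 the generator is fully
## deterministic and counts equal the largest-remainder rounding of the
## configured means.

## Expected per-measurement class means for one donor and condition.
## ADP multiplies the doublet/triplet/multiplet means and depletes singlets
## by the platelets consumed: 2*dm2 + 3*dm3 + 4*dm4.
conditionClassMeans <- function(config, condition, age = 39, sex = "M") {
    mu <- config@baselineMeans
    if (condition == "ADP") {
        mu234 <- mu[2:4] * config@adpMultipliers
        depletion <- sum((2:4) * (mu234 - mu[2:4]))
        if (depletion > mu[1]) {
            stop("ADP singlet depletion (", round(depletion, 1),
                 ") exceeds the available singlet mean (", mu[1],
                 "); lower the ADP multipliers or raise the singlet mean")
        }
        mu <- c(mu[1] - depletion, mu234)
    }
    if (sex == "M" && config@maleAgeSlope != 0) {
        mu[2:4] <- mu[2:4] * pmax(0, 1 + config@maleAgeSlope * (age - 39))
    }
    if (config@ageTotalSlope != 0) {
        mu <- mu * max(0, 1 + config@ageTotalSlope * (age - 39))
    }
    mu
}

## A donor state with neutral defaults; simulateCohort fills the random
## effects.
.defaultDonor <- function(id = "D001", age = 39, sex = "M",
                          date = "2023-01-09") {
    list(id = id, age = age, sex = sex, date = date,
         classRatio = rep(1, 4), mfiEffect = 0)
}

.complexScale <- function(config) {
    config@eventsPerMeasurement * (1 - config@coincidenceFraction) /
        sum(config@baselineMeans)
}

## Per-event rows for one measurement.  `counts` are platelet-complex
## counts m1..m4; coincidence and background events are appended and the
## stream order randomised.
.eventRows <- function(counts, nCoincidence, nBackground, donor,
                       condition, replicate, config) {
    kClass <- rep.int(1:4, counts)
    nPlatelets <- ifelse(kClass == 4L,
                         sample(4:6, length(kClass), replace = TRUE),
                         kClass)
    nPlate <- length(kClass)
    kind <- c(rep("platelet", nPlate),
              rep("coincidence", nCoincidence),
              rep("erythrocyte", nBackground))
    n <- length(kind)
    gtClass <- c(kClass, rep(NA_integer_, nCoincidence + nBackground))
    gtN <- c(nPlatelets, rep(1L, nCoincidence),
             rep(0L, nBackground))
    isPlateletLike <- kind != "erythrocyte"
    cd42b <- numeric(n)
    cd62p <- numeric(n)
    nPl <- sum(isPlateletLike)
    if (nPl > 0) {
        k <- gtN[isPlateletLike]
        cd42b[isPlateletLike] <- k * exp(config@cd42bMeanlog +
            donor$mfiEffect + rnorm(nPl, 0, config@cd42bSdlog))
        shift <- if (condition == "ADP") config@adpCd62pShift else 0
        masking <- if (condition == "baseline" && config@cd62pMasking > 0) {
            pmax(0, 1 - config@cd62pMasking * (k - 1))
        } else 1
        cd62p[isPlateletLike] <- masking * k * exp(config@cd62pMeanlog +
            shift + donor$mfiEffect + rnorm(nPl, 0, config@cd62pSdlog))
    }
    if (nBackground > 0) {
        cd42b[!isPlateletLike] <- exp(config@rbcCd42bMeanlog +
            rnorm(nBackground, 0, config@rbcCd42bSdlog))
        cd62p[!isPlateletLike] <- exp(rnorm(nBackground, -1, 0.4))
    }
    outFocus <- runif(n) < config@outOfFocusFraction
    focus <- ifelse(outFocus,
                    pmax(0.01, rnorm(n, 0.12, 0.03)),
                    pmax(0.05, rnorm(n, 0.5, 0.06)))
    ord <- sample.int(n)
    data.frame(donor_id = donor$id, age = donor$age, sex = donor$sex,
               condition = condition, replicate = replicate,
               acquisition_date = donor$date,
               event_id = seq_len(n),
               cd42b_mfi = cd42b[ord], cd62p_mfi = cd62p[ord],
               focus = focus[ord], gt_class = gtClass[ord],
               gt_n_platelets = gtN[ord],
               contains_erythrocyte = kind[ord] %in%
                   c("coincidence", "erythrocyte"),
               kind = kind[ord],
               stringsAsFactors = FALSE)
}

#' Simulate one measurement of one donor
#'
#' Draws per-measurement class counts around the donor's condition-specific
#' class probabilities (Dirichlet-multinomial; deterministic
#' largest-remainder counts at zero dispersion), then builds the per-event
#' stream: platelet complexes, platelet-erythrocyte coincidence images and,
#' optionally, the CD42b-negative whole-blood background interleaved so the
#' configured platelet fraction holds.
#'
#' @param donor list with \code{id}, \code{age}, \code{sex}, \code{date},
#'   and optionally \code{classRatio} (donor Dirichlet perturbation) and
#'   \code{mfiEffect}; missing fields take neutral defaults.
#' @param condition \code{"baseline"} or \code{"ADP"}.
#' @param config a \linkS4class{CohortConfig}.
#' @param replicate technical replicate index.
#' @param perEvent build the per-event table (otherwise counts only).
#' @param includeBackground interleave CD42b-negative background events.
#' @return list with \code{events} (data.frame or NULL), \code{truth}
#'   (list: \code{counts} as \linkS4class{ClassCounts}, \code{wpa}).
#' @examples
#' cfg <- cohortConfig(nDonors = 1, dispersion = 0,
#'                     baselineMeans = c(8400, 200, 10, 0),
#'                     coincidenceFraction = 0, eventsPerMeasurement = 8610L)
#' m <- simulateMeasurement(condition = "baseline", config = cfg,
#'                          perEvent = FALSE)
#' classCounts(m$truth$counts)
#' @export
simulateMeasurement <- function(donor = .defaultDonor(),
                                condition = c("baseline", "ADP"),
                                config = cohortConfig(), replicate = 1L,
                                perEvent = TRUE,
                                includeBackground = FALSE) {
    condition <- match.arg(condition)
    validObject(config)
    donor <- modifyList(.defaultDonor(), donor)
    mu <- conditionClassMeans(config, condition, donor$age, donor$sex)
    mu <- mu * .complexScale(config)
    nComplex <- max(1L, as.integer(round(sum(mu))))
    if (config@dispersion == 0) {
        counts <- apportionCounts(mu, nComplex)
    } else {
        p <- mu * donor$classRatio
        counts <- as.integer(rmultinom(1, nComplex, p / sum(p)))
    }
    cc <- ClassCounts(counts[1], counts[2], counts[3], counts[4])
    truth <- list(counts = cc, wpa = computeWPA(cc))
    ev <- NULL
    if (perEvent) {
        fCoin <- config@coincidenceFraction
        nCoin <- as.integer(round(nComplex * fCoin / (1 - fCoin)))
        nBg <- 0L
        if (includeBackground) {
            f <- config@wholeBloodPlateletFraction
            nBg <- as.integer(round((nComplex + nCoin) * (1 - f) / f))
        }
        ev <- .eventRows(counts, nCoin, nBg, donor, condition,
                         replicate, config)
    }
    list(events = ev, truth = truth)
}

#' Simulate a whole-blood event stream
#'
#' Builds an ungated stream of about \code{nEvents} objects in which only
#' the configured whole-blood platelet fraction are platelet events; the
#' remainder are CD42b-negative erythrocytes.  Used to exercise the
#' acquisition-side gate.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param nEvents approximate total number of objects in the stream.
#' @param seed seed for the stream (defaults to the config master seed).
#' @return per-event data.frame.
#' @export
simulateWholeBlood <- function(config = cohortConfig(), nEvents = 100000L,
                               seed = config@seed) {
    validObject(config)
    f <- config@wholeBloodPlateletFraction
    nRecorded <- max(1L, as.integer(round(nEvents * f)))
    nComplex <- max(1L, as.integer(round(nRecorded *
        (1 - config@coincidenceFraction))))
    cfg <- config
    cfg@eventsPerMeasurement <- as.integer(ceiling(
        nComplex / (1 - config@coincidenceFraction)))
    withSeed(seed, {
        simulateMeasurement(condition = "baseline", config = cfg,
                            perEvent = TRUE,
                            includeBackground = TRUE)$events
    })
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Each donor is measured in technical duplicate at baseline and after ADP
#' stimulation.  Donors are assigned to acquisition dates in batches, sexes
#' deterministically by the configured fraction, and ages uniformly over
#' the configured range.  The master seed fully determines the output;
#' per-measurement sub-streams are derived by fixed counter offsets so
#' results do not depend on iteration order.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param level \code{"measurement"} (counts and measurement MFIs only) or
#'   \code{"event"} (adds the per-event table).
#' @param includeBackground interleave whole-blood background events into
#'   the per-event table.
#' @param conditions which conditions to measure; sub-stream seeds are
#'   tied to the condition, so the baseline measurements of a
#'   baseline-only run equal those of a full run.
#' @return a \linkS4class{SyntheticCohort}.
#' @examples
#' sc <- simulateCohort(cohortConfig(nDonors = 6, seed = 7))
#' head(measurements(sc))
#' @export
simulateCohort <- function(config = cohortConfig(),
                           level = c("measurement", "event"),
                           includeBackground = FALSE,
                           conditions = c("baseline", "ADP")) {
    level <- match.arg(level)
    conditions <- match.arg(conditions, several.ok = TRUE)
    validObject(config)
    nd <- config@nDonors
    nMale <- as.integer(round(nd * config@sexFractionMale))
    withSeed(substreamSeed(config@seed, 0L), {
        sex <- rep(c("M", "F"), c(nMale, nd - nMale))
        age <- sample(seq(config@ageRange[1], config@ageRange[2]), nd,
                      replace = TRUE)
        ## shuffle sex-age pairing, keep counts deterministic
        age <- age[sample.int(nd)]
        batch <- (seq_len(nd) - 1L) %/% config@batchSize
        date <- format(as.Date("2023-01-09") + 7 * batch)
        phi <- config@dispersion
        pBase <- config@baselineMeans / sum(config@baselineMeans)
        ratio <- matrix(1, nd, 4)
        if (phi > 0) {
            g <- matrix(rgamma(nd * 4, shape = rep(pBase / phi,
                                                   each = nd)), nd, 4)
            w <- g / rowSums(g)
            ratio <- sweep(w, 2, pBase, "/")
        }
        mfiEffect <- rnorm(nd, 0, config@donorMfiSd)
    })
    ids <- sprintf("D%03d", seq_len(nd))
    donorsDf <- data.frame(donor_id = ids, age = age, sex = sex,
                           acquisition_date = date,
                           stringsAsFactors = FALSE)
    ## closed-form per-donor true WPA from the donor's expected counts
    trueWpa <- function(i, cond) {
        mu <- conditionClassMeans(config, cond, age[i], sex[i]) * ratio[i, ]
        (sum(mu * 1:4) / sum(mu) - 1) * 100
    }
    donorsDf$true_wpa_baseline <- vapply(seq_len(nd), trueWpa, 0,
                                         cond = "baseline")
    donorsDf$true_wpa_adp <- vapply(seq_len(nd), trueWpa, 0, cond = "ADP")

    conds <- c("baseline", "ADP")
    condIdx <- match(conditions, conds)
    nm <- nd * 2L * length(conditions)
    rows <- vector("list", nm)
    evList <- if (level == "event") vector("list", nm) else NULL
    k <- 0L
    for (i in seq_len(nd)) {
        donor <- list(id = ids[i], age = age[i], sex = sex[i],
                      date = date[i], classRatio = ratio[i, ],
                      mfiEffect = mfiEffect[i])
        for (ci in condIdx) {
            for (rep_ in 1:2) {
                k <- k + 1L
                sm <- withSeed(substreamSeed(config@seed, i, ci, rep_), {
                    simulateMeasurement(donor, conds[ci], config, rep_,
                                        perEvent = (level == "event"),
                                        includeBackground =
                                            includeBackground)
                })
                cc <- classCounts(sm$truth$counts)
                if (level == "event") {
                    evList[[k]] <- sm$events
                    pl <- sm$events$kind == "platelet"
                    mfi42 <- mean(sm$events$cd42b_mfi[pl])
                    mfi62 <- mean(sm$events$cd62p_mfi[pl])
                } else {
                    ## measurement-level MFI summary drawn directly
                    mfi <- withSeed(substreamSeed(config@seed, i, ci,
                                                  rep_, 99L), {
                        se <- config@cd42bSdlog / sqrt(sum(cc))
                        c(exp(config@cd42bMeanlog + mfiEffect[i] +
                              config@cd42bSdlog^2 / 2 + rnorm(1, 0, se)),
                          exp(config@cd62pMeanlog + mfiEffect[i] +
                              (if (conds[ci] == "ADP")
                                   config@adpCd62pShift else 0) +
                              config@cd62pSdlog^2 / 2 +
                              rnorm(1, 0, 3 * se)))
                    })
                    mfi42 <- mfi[1]
                    mfi62 <- mfi[2]
                }
                rows[[k]] <- data.frame(
                    donor_id = ids[i], age = age[i], sex = sex[i],
                    condition = conds[ci], replicate = rep_,
                    acquisition_date = date[i],
                    m1 = cc[1], m2 = cc[2], m3 = cc[3], m4 = cc[4],
                    N = sum(cc), true_wpa = sm$truth$wpa,
                    cd42b_mfi = mfi42, cd62p_mfi = mfi62,
                    stringsAsFactors = FALSE)
            }
        }
    }
    meas <- do.call(rbind, rows)
    rownames(meas) <- NULL
    ev <- if (level == "event") {
        out <- do.call(rbind, evList)
        rownames(out) <- NULL
        out
    } else NULL
    new("SyntheticCohort", donors = donorsDf, measurements = meas,
        events = ev, config = config)
}
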