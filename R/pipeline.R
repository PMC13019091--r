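## End-to-end orchestration: simulate -> gate -> train -> classify ->
## score -> QC -> statistics, with every stage's output written before
## the next begins and a manifest recording seed, config hash and file
## checksums.

.logLevels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

.plog <- function(config, level, ...) {
    if (.logLevels[[level]] >= .logLevels[[config@logLevel]]) {
        message(sprintf("[%s] %s %s", level,
                        format(Sys.time(), "%H:%M:%S"),
                        paste0(...)))
    }
}

## Render the images for one measurement's retained events, in stream
## order.  Platelet-complex and coincidence events are rendered from
## their ground-truth geometry; anything else as an erythrocyte.
.renderRetained <- function(events, render) {
    lapply(seq_len(nrow(events)), function(i) {
        k <- events$gt_n_platelets[i]
        if (events$kind[i] == "platelet" && k >= 1L) {
            renderEvent(k, render, channels = "cd42b")
        } else if (events$kind[i] == "coincidence") {
            renderBackgroundEvent("coincidence", render,
                                  channels = "cd42b")
        } else {
            renderBackgroundEvent("erythrocyte", render,
                                  channels = "cd42b")
        }
    })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, gate, train, classify, score, QC and statistics in
#' order.  Each stage writes its output to \code{outDir} before the next
#' stage starts; a failure therefore leaves all prior outputs intact.  A
#' manifest records the seed, a hash of the configuration and the MD5
#' checksum of every written file, so two runs with the same configuration
#' and seed produce identical manifests.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param model optional pre-trained \linkS4class{ClassifierModel}; when
#'   supplied the training stage is skipped.
#' @param conditions conditions to simulate and analyse.
#' @return list with \code{cohort}, \code{gatingReport}, \code{model},
#'   \code{summaries}, \code{qc}, \code{stats}, \code{manifest} and
#'   \code{outDir}.
#' @export
runPipeline <- function(config, model = NULL,
                        conditions = c("baseline", "ADP")) {
    validObject(config)
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    outFile <- function(name) file.path(config@outDir, name)
    written <- character()
    seed <- config@cohort@seed
    stage <- function(name, expr) {
        .plog(config, "info", "stage ", name, " ...")
        t0 <- Sys.time()
        res <- tryCatch(expr, error = function(e) {
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE)
        })
        .plog(config, "info", "stage ", name, " done in ",
              sprintf("%.1fs", as.numeric(Sys.time() - t0, units = "secs")))
        res
    }

    cohort <- stage("simulate", {
        sc <- simulateCohort(config@cohort, level = "event",
                             conditions = conditions)
        writeEventTable(events(sc), outFile("events.csv"))
        utils::write.csv(measurements(sc), outFile("ground_truth.csv"),
                         row.names = FALSE)
        written <<- c(written, "events.csv", "ground_truth.csv")
        sc
    })

    gated <- stage("gate", {
        gcfg <- config@gating
        ## "auto" thresholds are placed on a whole-blood calibration
        ## stream (as gates are set on the instrument), then applied to
        ## the recorded cohort events as fixed numeric cut-offs
        if (identical(gcfg@cd42bThreshold, "auto") ||
            identical(gcfg@focusThreshold, "auto")) {
            calib <- simulateWholeBlood(config@cohort, nEvents = 50000L,
                                        seed = substreamSeed(seed, 6001L))
            rcal <- gateEvents(calib, config@gating)$report
            gcfg <- resolvedGatingConfig(rcal, gcfg@coincidenceExclusion)
        }
        g <- gateEvents(events(cohort), gcfg)
        writeReport(g$report, outFile("gating_report.json"))
        written <<- c(written, "gating_report.json")
        g
    })

    model <- stage("train", {
        if (is.null(model)) {
            ts <- withSeed(substreamSeed(seed, 7001L), {
                renderTrainingSet(config@nTrainingImages, config@render)
            })
            cfg <- config@classifier
            cfg@seed <- substreamSeed(seed, 7002L)
            model <- trainClassifier(ts$images, ts$labels, cfg)
        }
        saveRDS(model, outFile("classifier_model.rds"))
        written <<- c(written, "classifier_model.rds")
        model
    })

    summaries <- stage("classify+score", {
        ev <- gated$events
        key <- interaction(ev$donor_id, ev$condition, ev$replicate,
                           drop = TRUE)
        parts <- split(seq_len(nrow(ev)), key)
        rows <- vector("list", length(parts))
        classified <- vector("list", length(parts))
        for (pi in seq_along(parts)) {
            ix <- parts[[pi]]
            sub <- ev[ix, , drop = FALSE]
            imgs <- withSeed(substreamSeed(seed, 8000L + pi), {
                .renderRetained(sub, config@render)
            })
            pred <- classifyEvents(model, imgs)
            sub$class <- pred$class
            sub[, c("p1", "p2", "p3", "p4")] <-
                pred[, c("p1", "p2", "p3", "p4")]
            classified[[pi]] <- sub
            rows[[pi]] <- summarizeMeasurement(sub)
        }
        cl <- do.call(rbind, classified)
        rownames(cl) <- NULL
        writeEventTable(cl, outFile("events_classified.csv"))
        sm <- do.call(rbind, rows)
        rownames(sm) <- NULL
        utils::write.csv(sm, outFile("measurement_summaries.csv"),
                         row.names = FALSE)
        written <<- c(written, "events_classified.csv",
                      "measurement_summaries.csv")
        sm
    })

    qc <- stage("qc", {
        q <- applyQC(summaries, config@qc)
        writeReport(q$report, outFile("qc_report.json"))
        utils::write.csv(q$annotated, outFile("summaries_qc.csv"),
                         row.names = FALSE)
        written <<- c(written, "qc_report.json", "summaries_qc.csv")
        q
    })

    stats <- stage("stats", {
        cov <- donors(cohort)[, c("donor_id", "age", "sex")]
        merged <- merge(qc$summaries, cov, by = "donor_id")
        st <- cohortStatistics(merged)
        utils::write.csv(st, outFile("stats.csv"), row.names = FALSE)
        written <<- c(written, "stats.csv")
        st
    })

    manifest <- stage("manifest", {
        cfgPath <- outFile("run_config.yaml")
        writeRunConfig(config, cfgPath)
        written <<- c(written, "run_config.yaml")
        sums <- tools::md5sum(file.path(config@outDir, written))
        names(sums) <- written
        ## the hash ignores the output location so identical analyses in
        ## different directories yield identical manifests
        hashCfg <- config
        hashCfg@outDir <- ""
        hashPath <- tempfile(fileext = ".yaml")
        writeRunConfig(hashCfg, hashPath)
        cfgHash <- unname(tools::md5sum(hashPath))
        unlink(hashPath)
        man <- list(seed = seed, configHash = cfgHash,
                    files = as.list(sums))
        jsonlite::write_json(man, outFile("manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        man
    })

    list(cohort = cohort, gatingReport = gated$report, model = model,
         summaries = summaries, qc = qc, stats = stats,
         manifest = manifest, outDir = config@outDir)
}
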