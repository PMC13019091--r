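## Plain-format I/O: RFC 4180 CSV for event tables, JSON for reports and
## manifests, YAML or JSON for configuration, multi-page 16-bit TIFF (or
## per-channel PNG) for event images.

.requiredEventCols <- c("donor_id", "age", "sex", "condition", "replicate",
                        "acquisition_date", "event_id", "cd42b_mfi",
                        "cd62p_mfi", "focus")

#' Write an event table to CSV
#'
#' @param events per-event data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEventTable <- function(events, path) {
    utils::write.csv(events, path, row.names = FALSE)
    invisible(path)
}

#' Read an event table from CSV
#'
#' Validates the schema: all required columns must be present (extra
#' columns are preserved); rows with unparseable numeric fields, an
#' invalid sex or condition code, or an unparseable ISO date are dropped
#' with a warning naming their line numbers.
#'
#' @param path CSV file with a header row.
#' @return typed data.frame of events.
#' @export
readEventTable <- function(path) {
    ev <- utils::read.csv(path, stringsAsFactors = FALSE)
    missingCols <- setdiff(.requiredEventCols, names(ev))
    if (length(missingCols)) {
        stop("event table lacks required column(s): ",
             paste(missingCols, collapse = ", "))
    }
    if (nrow(ev) == 0L) {
        return(ev)
    }
    bad <- rep(FALSE, nrow(ev))
    for (col in c("age", "replicate", "event_id", "cd42b_mfi",
                  "cd62p_mfi", "focus")) {
        v <- suppressWarnings(as.numeric(ev[[col]]))
        bad <- bad | !is.finite(v)
        ev[[col]] <- v
    }
    bad <- bad | !ev$sex %in% c("M", "F")
    bad <- bad | !ev$condition %in% c("baseline", "ADP")
    dateOk <- !is.na(suppressWarnings(
        as.Date(as.character(ev$acquisition_date), format = "%Y-%m-%d")))
    bad <- bad | !dateOk
    if (any(bad)) {
        ## +1 for the header line
        warning("dropping ", sum(bad), " malformed row(s) at line(s): ",
                paste(which(bad) + 1L, collapse = ", "))
        ev <- ev[!bad, , drop = FALSE]
        rownames(ev) <- NULL
    }
    ev
}

#' Write an event image
#'
#' Multi-page 16-bit TIFF (one page per channel, in channel order) or one
#' PNG per channel (suffixed with the channel name).  Intensities are
#' stored relative to \code{maxIntensity}.
#'
#' @param image an \linkS4class{EventImage}.
#' @param path output path (\code{.tif}/\code{.tiff} or \code{.png}).
#' @param maxIntensity full-scale intensity for quantisation.
#' @return the path(s) written, invisibly.
#' @export
writeEventImage <- function(image, path, maxIntensity = 4096) {
    stopifnot(is(image, "EventImage"))
    norm <- lapply(image@channels, function(m) {
        pmin(pmax(m / maxIntensity, 0), 1)
    })
    if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
        tiff::writeTIFF(norm, path, bits.per.sample = 16L)
        invisible(path)
    } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
        paths <- character(length(norm))
        for (i in seq_along(norm)) {
            p <- sub("\\.png$", sprintf("_%s.png", names(norm)[i]), path,
                     ignore.case = TRUE)
            png::writePNG(norm[[i]], p)
            paths[i] <- p
        }
        invisible(paths)
    } else {
        stop("unsupported image format: ", path)
    }
}

#' Read an event image written by \code{writeEventImage}
#'
#' @param path TIFF path.
#' @param channels channel names for the pages.
#' @param pixelSize micrometres per pixel to record.
#' @param maxIntensity full-scale intensity used at write time.
#' @return an \linkS4class{EventImage} (unannotated).
#' @export
readEventImage <- function(path, channels = c("brightfield", "cd42b",
                                              "cd62p"),
                           pixelSize = 0.33, maxIntensity = 4096) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != length(channels)) {
        stop("expected ", length(channels), " pages, found ",
             length(pages))
    }
    chan <- lapply(pages, function(m) m * maxIntensity)
    names(chan) <- channels
    new("EventImage", channels = chan, pixelSize = pixelSize,
        annotation = list())
}

## RunConfig <-> plain nested list (for YAML/JSON round-trips)
.configToList <- function(config) {
    slotList <- function(obj) {
        out <- lapply(slotNames(obj), function(s) slot(obj, s))
        names(out) <- slotNames(obj)
        out
    }
    list(cohort = slotList(config@cohort),
         gating = slotList(config@gating),
         classifier = slotList(config@classifier),
         qc = slotList(config@qc),
         render = slotList(config@render),
         nTrainingImages = config@nTrainingImages,
         outDir = config@outDir,
         logLevel = config@logLevel)
}

.listToConfig <- function(x) {
    build <- function(cls, fields) {
        fields <- lapply(fields, function(v) {
            if (is.list(v)) unlist(v) else v
        })
        proto <- getSlots(cls)
        for (nm in names(fields)) {
            if (proto[[nm]] == "integer") {
                fields[[nm]] <- as.integer(fields[[nm]])
            }
        }
        do.call(new, c(list(cls), fields))
    }
    new("RunConfig",
        cohort = build("CohortConfig", x$cohort),
        gating = build("GatingConfig", x$gating),
        classifier = build("ClassifierConfig", x$classifier),
        qc = build("QCConfig", x$qc),
        render = build("RenderParams", x$render),
        nTrainingImages = as.integer(x$nTrainingImages),
        outDir = x$outDir, logLevel = x$logLevel)
}

#' Write a pipeline configuration to YAML or JSON
#'
#' @param config a \linkS4class{RunConfig}.
#' @param path output path ending in \code{.yaml}/\code{.yml} or
#'   \code{.json}.
#' @return the path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
    x <- .configToList(config)
    if (grepl("\\.ya?ml$", path)) {
        yaml::write_yaml(x, path, precision = 15L)
    } else if (grepl("\\.json$", path)) {
        jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    } else {
        stop("unsupported config format: ", path)
    }
    invisible(path)
}

#' Read a pipeline configuration written by \code{writeRunConfig}
#'
#' @param path YAML or JSON config path.
#' @return a \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
    x <- if (grepl("\\.ya?ml$", path)) {
        yaml::read_yaml(path)
    } else if (grepl("\\.json$", path)) {
        jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
        stop("unsupported config format: ", path)
    }
    cfg <- .listToConfig(x)
    validObject(cfg)
    cfg
}

## Reports as JSON
.reportToList <- function(report) {
    out <- lapply(slotNames(report), function(s) slot(report, s))
    names(out) <- slotNames(report)
    out
}

#' Serialize a gating or QC report to JSON
#'
#' @param report a \linkS4class{GatingReport} or \linkS4class{QCReport}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path) {
    jsonlite::write_json(.reportToList(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE)
    invisible(path)
}
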