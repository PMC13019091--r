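## Shared fixtures.  The reference classifier is trained once per test run
## (lazily) on 2000 default-noise synthetic images and reused by the
## classifier and acceptance tests.

noiselessParams <- function() {
    renderParams(shotNoise = FALSE, readNoiseSd = 0)
}

.fixtureEnv <- new.env(parent = emptyenv())

referenceModel <- function() {
    if (is.null(.fixtureEnv$model)) {
        set.seed(11)
        ts <- renderTrainingSet(2000, renderParams())
        .fixtureEnv$model <- trainClassifier(
            ts$images, ts$labels, classifierConfig(epochs = 12, seed = 99))
    }
    .fixtureEnv$model
}

## Measurement-level summaries with exact replicate pairs, for QC tests.
qcSummaries <- function(wpaPairs, dates = NULL) {
    n <- length(wpaPairs)
    if (is.null(dates)) dates <- rep("2023-01-09", n)
    do.call(rbind, lapply(seq_len(n), function(i) {
        data.frame(donor_id = sprintf("D%03d", i), condition = "baseline",
                   replicate = 1:2, acquisition_date = dates[i],
                   wpa = wpaPairs[[i]], stringsAsFactors = FALSE)
    }))
}
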