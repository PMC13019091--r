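test_that("oracle classification is exact on annotations and images", {
    p0 <- noiselessParams()
    set.seed(7)
    expect_equal(oracleClassify(renderEvent(2, p0)), 2L)
    ## open-ended fourth class
    set.seed(7)
    expect_equal(oracleClassify(renderEvent(6, p0)), 4L)
    ## image mode (annotation stripped): peak counting on the noiseless
    ## CD42b channel recovers the class
    set.seed(70)
    hits <- 0L
    for (n in 1:4) for (r in 1:10) {
        img <- renderEvent(n, p0)
        img@annotation <- list()
        hits <- hits + (oracleClassify(img) == n)
    }
    expect_gte(hits, 38L)
    ## a noisy unannotated image is refused
    set.seed(7)
    noisy <- renderEvent(3, renderParams())
    noisy@annotation <- list()
    expect_error(oracleClassify(noisy), "noiseless")
})

test_that("training is seeded, validated, and refuses missing classes", {
    set.seed(55)
    ts <- renderTrainingSet(160, renderParams())
    cfgA <- classifierConfig(epochs = 2, seed = 5)
    m1 <- trainClassifier(ts$images, ts$labels, cfgA)
    m2 <- trainClassifier(ts$images, ts$labels, cfgA)
    expect_identical(m1@metrics$heldOutAccuracy,
                     m2@metrics$heldOutAccuracy)
    expect_identical(m1@params, m2@params)

    keep <- ts$labels != 4L
    expect_error(
        trainClassifier(ts$images[keep], ts$labels[keep], cfgA),
        "class\\(es\\): 4")
})

test_that("the trained classifier agrees with the oracle at >=95%", {
    model <- referenceModel()
    expect_gte(model@metrics$heldOutAccuracy, 0.95)
    ## zero-noise held-out set, oracle as ground truth
    set.seed(123)
    tst <- renderTrainingSet(400, noiselessParams())
    pred <- classifyEvents(model, tst$images)
    orc <- vapply(tst$images, oracleClassify, integer(1))
    expect_gte(mean(pred$class == orc), 0.95)
    ## probability vectors are proper distributions
    expect_true(all(abs(rowSums(as.matrix(pred[, 2:5])) - 1) < 1e-6))
    ## permutation invariance
    perm <- sample(length(tst$images))
    pred2 <- classifyEvents(model, tst$images[perm])
    expect_equal(pred2$class, pred$class[perm])
    ## class-count conservation into the downstream tally
    expect_equal(sum(tabulate(pred$class, 4L)), length(tst$images))
})

test_that("classification rejects mismatched input and passes empties", {
    model <- referenceModel()
    expect_equal(nrow(classifyEvents(model, list())), 0L)
    expect_error(classifyEvents(model, list(matrix(0, 12, 12))),
                 "expects 48x48")
})
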