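## Event classification: a two-stage conv/pool network over the CD42b
## channel, plus a deterministic geometric oracle used for testing.

.asCd42bMatrix <- function(image) {
    if (is(image, "EventImage")) channel(image, "cd42b") else image
}

## Per-image normalisation: scale to unit maximum so classification is
## invariant to overall staining intensity.
.normalizeImage <- function(m) {
    mx <- max(m)
    if (mx > 0) m / mx else m
}

.imagesToCube <- function(images, inputSize) {
    n <- length(images)
    X <- array(0, c(inputSize, inputSize, n))
    for (i in seq_len(n)) {
        m <- .asCd42bMatrix(images[[i]])
        if (!all(dim(m) == inputSize)) {
            stop("image ", i, " is ", nrow(m), "x", ncol(m),
                 " but the model expects ", inputSize, "x", inputSize)
        }
        X[, , i] <- .normalizeImage(m)
    }
    X
}

#' Deterministic oracle classification of a synthetic event
#'
#' Returns the ground-truth aggregation class min(nPlatelets, 4) from the
#' annotation when present.  For unannotated noiseless renderings it counts
#' platelet centres by peak detection on the CD42b channel: greedy
#' non-maximum suppression of local intensity maxima with a minimum
#' physical separation just below the smallest platelet diameter.  Noisy
#' images without an annotation are refused.
#'
#' @param image an \linkS4class{EventImage} or CD42b intensity matrix.
#' @param minSeparation minimum centre separation in micrometres.
#' @param relThreshold peaks below this fraction of the image maximum are
#'   ignored.
#' @return integer class in 1..4.
#' @export
oracleClassify <- function(image, minSeparation = 1.15,
                           relThreshold = 0.15) {
    px <- 0.33
    if (is(image, "EventImage")) {
        a <- annotation(image)
        if (length(a) > 0L && !is.null(a$nPlatelets) && a$nPlatelets > 0L) {
            return(min(a$nPlatelets, 4L))
        }
        px <- pixelSize(image)
    }
    m <- .asCd42bMatrix(image)
    mx <- max(m)
    if (mx <= 0) {
        stop("cannot oracle-classify an empty image")
    }
    ## a noiseless blurred rendering is strictly positive everywhere;
    ## shot/read noise (with non-negativity clipping) leaves many exact
    ## zeros in the background
    if (mean(m == 0) > 0.05) {
        stop("oracle classification of an unannotated image requires a ",
             "noiseless rendering")
    }
    minSep2 <- (minSeparation / px)^2
    nr <- nrow(m)
    ord <- order(m, decreasing = TRUE)
    ord <- ord[m[ord] >= relThreshold * mx]
    peaks <- matrix(0, 0, 2)
    for (ix in ord) {
        i <- ((ix - 1L) %% nr) + 1L
        j <- ((ix - 1L) %/% nr) + 1L
        nb <- m[max(1, i - 1):min(nr, i + 1),
                max(1, j - 1):min(ncol(m), j + 1)]
        if (m[i, j] < max(nb)) next
        if (nrow(peaks) == 0L ||
            all((peaks[, 1] - i)^2 + (peaks[, 2] - j)^2 >= minSep2)) {
            peaks <- rbind(peaks, c(i, j))
        }
    }
    n <- nrow(peaks)
    if (n < 1L) {
        stop("no platelet found in image")
    }
    min(n, 4L)
}

.initParams <- function(config) {
    k <- config@kernelSize
    C1 <- config@convFilters[1]
    C2 <- config@convFilters[2]
    o1 <- config@inputSize - k + 1L
    q1 <- o1 %/% 2L
    o2 <- q1 - k + 1L
    q2 <- o2 %/% 2L
    flat <- C2 * q2 * q2
    he <- function(nr, nc, fanIn) {
        matrix(rnorm(nr * nc, 0, sqrt(2 / fanIn)), nr, nc)
    }
    list(W1 = he(C1, k * k, k * k), b1 = rep(0, C1),
         W2 = he(C2, k * k * C1, k * k * C1), b2 = rep(0, C2),
         W3 = he(config@fcWidth, flat, flat), b3 = rep(0, config@fcWidth),
         W4 = he(4L, config@fcWidth, config@fcWidth), b4 = rep(0, 4L))
}

#' Train the event classifier
#'
#' Trains the two-conv-stage network on labelled event images with Adam on
#' cross-entropy.  A stratified fraction is held out and the agreement on
#' it reported; batches are resampled to uniform class frequency when
#' class balancing is on (raw acquisitions are ~97 percent singlets, which
#' would otherwise collapse training to the majority class).  Training is
#' deterministic given the config seed.
#'
#' @param images list of \linkS4class{EventImage} (CD42b channel used) or
#'   intensity matrices.
#' @param labels integer classes 1-4; every class must be represented.
#' @param config a \linkS4class{ClassifierConfig}.
#' @return a \linkS4class{ClassifierModel}.
#' @export
trainClassifier <- function(images, labels, config = classifierConfig()) {
    validObject(config)
    labels <- as.integer(labels)
    if (length(images) != length(labels)) {
        stop("images and labels differ in length")
    }
    present <- sort(unique(labels))
    missing <- setdiff(1:4, present)
    if (length(missing)) {
        stop("training data lacks class(es): ",
             paste(missing, collapse = ", "))
    }
    X <- .imagesToCube(images, config@inputSize)
    withSeed(config@seed, {
        ## stratified held-out split
        valIdx <- unlist(lapply(1:4, function(k) {
            ix <- which(labels == k)
            sample(ix, max(1L, floor(config@validationFraction *
                                     length(ix))))
        }))
        trainIdx <- setdiff(seq_along(labels), valIdx)
        yTr <- labels[trainIdx]
        nTrain <- length(trainIdx)
        stepsPerEpoch <- ceiling(nTrain / config@batchSize)
        steps <- config@epochs * stepsPerEpoch
        classPos <- lapply(1:4, function(k) which(yTr == k))
        batches <- matrix(0L, steps, config@batchSize)
        if (config@balanceClasses) {
            for (s in seq_len(steps)) {
                cls <- sample(1:4, config@batchSize, replace = TRUE)
                batches[s, ] <- vapply(cls, function(k) {
                    classPos[[k]][sample.int(length(classPos[[k]]), 1L)]
                }, integer(1))
            }
        } else {
            for (e in seq_len(config@epochs)) {
                ord <- rep(sample.int(nTrain),
                           length.out = stepsPerEpoch * config@batchSize)
                batches[(e - 1L) * stepsPerEpoch +
                        seq_len(stepsPerEpoch), ] <-
                    matrix(ord, stepsPerEpoch, config@batchSize,
                           byrow = TRUE)
            }
        }
        params0 <- .initParams(config)
        fit <- .cnnTrain(params0, X[, , trainIdx, drop = FALSE], yTr - 1L,
                         batches - 1L, config@learningRate)
        model <- new("ClassifierModel", params = fit$params,
                     config = config,
                     metrics = list(lossCurve = as.numeric(fit$loss),
                                    nTrain = nTrain,
                                    nValidation = length(valIdx)))
        pv <- .cnnPredict(fit$params, X[, , valIdx, drop = FALSE])
        predVal <- apply(pv, 1, which.max)
        model@metrics$heldOutAccuracy <- mean(predVal == labels[valIdx])
        model
    })
}

#' Classify event images
#'
#' Applies a trained \linkS4class{ClassifierModel}; the predicted class is
#' the argmax of the 4-way probability vector, ties broken toward the
#' smaller class index.  Images are processed in chunks to bound memory.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param images list of \linkS4class{EventImage} or intensity matrices.
#' @param chunkSize images per prediction chunk.
#' @return data.frame with columns \code{class} and \code{p1..p4}.
#' @export
classifyEvents <- function(model, images, chunkSize = 2000L) {
    stopifnot(is(model, "ClassifierModel"))
    n <- length(images)
    if (n == 0L) {
        return(data.frame(class = integer(0), p1 = numeric(0),
                          p2 = numeric(0), p3 = numeric(0),
                          p4 = numeric(0)))
    }
    sz <- model@config@inputSize
    out <- vector("list", ceiling(n / chunkSize))
    for (ci in seq_along(out)) {
        ix <- ((ci - 1L) * chunkSize + 1L):min(ci * chunkSize, n)
        X <- .imagesToCube(images[ix], sz)
        probs <- .cnnPredict(model@params, X)
        cls <- apply(probs, 1, which.max)
        out[[ci]] <- data.frame(class = as.integer(cls),
                                p1 = probs[, 1], p2 = probs[, 2],
                                p3 = probs[, 3], p4 = probs[, 4])
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
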