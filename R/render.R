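## Synthetic event rendering: platelet complexes, erythrocytes, debris.
## Forward model: flat disks (annulus for erythrocytes) -> isotropic
## Gaussian blur -> Poisson shot noise -> additive Gaussian read noise.

.gridCache <- new.env(parent = emptyenv())
.pixelGrid <- function(n) {
    key <- as.character(n)
    if (is.null(.gridCache[[key]])) {
        idx <- seq_len(n)
        .gridCache[[key]] <- list(X = matrix(idx, n, n, byrow = TRUE),
                                  Y = matrix(idx, n, n))
    }
    .gridCache[[key]]
}

## profile = "flat": uniform disk; "dome": projected cell body, brightest
## at the centre and positive over the whole footprint.
.rasterDisks <- function(n, centers, radii, amplitudes,
                         profile = c("flat", "dome")) {
    profile <- match.arg(profile)
    g <- .pixelGrid(n)
    img <- matrix(0, n, n)
    for (i in seq_along(radii)) {
        q2 <- ((g$X - centers[i, 1])^2 + (g$Y - centers[i, 2])^2) /
            radii[i]^2
        mask <- q2 <= 1
        if (profile == "flat") {
            img[mask] <- img[mask] + amplitudes[i]
        } else {
            img[mask] <- img[mask] + amplitudes[i] *
                (0.15 + 0.85 * sqrt(1 - q2[mask]))
        }
    }
    img
}

## Tangent-disk geometry for an aggregate of n platelets: each new disk is
## attached tangent to a uniformly chosen existing member with fractional
## jitter on the centre distance, then the constellation is recentred.
.plateletGeometry <- function(nPlatelets, params) {
    sz <- params@imageSize
    rpx <- runif(nPlatelets, params@plateletDiameter[1],
                 params@plateletDiameter[2]) / 2 / params@pixelSize
    centers <- matrix(0, nPlatelets, 2)
    centers[1, ] <- (sz + 1) / 2 + runif(2, -1, 1)
    if (nPlatelets > 1L) {
        for (i in 2:nPlatelets) {
            for (try in 1:25) {
                j <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
                theta <- runif(1, 0, 2 * pi)
                d <- (rpx[i] + rpx[j]) *
                    (1 + params@centerJitter * runif(1, -1, 1))
                cand <- centers[j, ] + d * c(cos(theta), sin(theta))
                margin <- rpx[i] + 2
                inFrame <- all(cand > margin) && all(cand < sz - margin)
                ## avoid landing on non-parent members: projections of a
                ## planar aggregate must keep every platelet resolvable
                others <- setdiff(seq_len(i - 1L), j)
                clear <- length(others) == 0L ||
                    all(sqrt((centers[others, 1] - cand[1])^2 +
                             (centers[others, 2] - cand[2])^2) >=
                        0.95 * (rpx[others] + rpx[i]))
                if (inFrame && clear) break
            }
            centers[i, ] <- cand
        }
    }
    ## recentre so large aggregates stay in frame
    shift <- (sz + 1) / 2 - colMeans(centers)
    centers <- sweep(centers, 2, shift, "+")
    list(centers = centers, radii = rpx)
}

.applyNoise <- function(img, params, blurSigma) {
    img <- gaussianBlur(img, blurSigma)
    if (params@shotNoise) {
        img <- matrix(rpois(length(img), pmax(img, 0)),
                      nrow(img), ncol(img))
    }
    if (params@readNoiseSd > 0) {
        img <- img + rnorm(length(img), 0, params@readNoiseSd)
    }
    pmax(img, 0)
}

.rbcGeometry <- function(params, offset = c(0, 0)) {
    sz <- params@imageSize
    rOut <- params@rbcDiameter / 2 / params@pixelSize
    center <- (sz + 1) / 2 + offset + runif(2, -1, 1)
    list(center = center, rOut = rOut, rIn = 0.55 * rOut)
}

.composeEvent <- function(plateletGeom, rbcGeom, params, outOfFocus,
                          channels) {
    sz <- params@imageSize
    sigma <- params@blurSigma *
        if (outOfFocus) params@outOfFocusFactor else 1
    nP <- if (is.null(plateletGeom)) 0L else nrow(plateletGeom$centers)
    chan <- list()
    cellMask <- matrix(0, sz, sz)
    if (nP > 0L) {
        cellMask <- cellMask + .rasterDisks(sz, plateletGeom$centers,
                                            plateletGeom$radii,
                                            rep(1, nP))
    }
    if (!is.null(rbcGeom)) {
        ## biconcave cell approximated as a dimmed-centre annulus
        ring <- .rasterDisks(sz, rbind(rbcGeom$center), rbcGeom$rOut, 1) -
            0.6 * .rasterDisks(sz, rbind(rbcGeom$center), rbcGeom$rIn, 1)
        cellMask <- cellMask + ring
    }
    if ("cd42b" %in% channels) {
        img <- matrix(0, sz, sz)
        if (nP > 0L) {
            amps <- plateletGeom$amplitudes
            img <- .rasterDisks(sz, plateletGeom$centers,
                                plateletGeom$radii, amps, "dome")
        }
        if (!is.null(rbcGeom)) {
            ## erythrocyte autofluorescence, far below the platelet gate
            img <- img + 0.5 * .rasterDisks(sz, rbind(rbcGeom$center),
                                            rbcGeom$rOut, 1)
        }
        chan$cd42b <- .applyNoise(img, params, sigma)
    }
    if ("cd62p" %in% channels) {
        img <- matrix(0, sz, sz)
        if (nP > 0L) {
            img <- .rasterDisks(sz, plateletGeom$centers,
                                plateletGeom$radii,
                                rep(params@cd62pAmplitude, nP) *
                                    runif(nP, 0.6, 1.4), "dome")
        }
        chan$cd62p <- .applyNoise(img, params, sigma)
    }
    if ("brightfield" %in% channels) {
        img <- params@brightfieldLevel *
            (1 - params@brightfieldAbsorption * pmin(cellMask, 1))
        chan$brightfield <- .applyNoise(img, params, sigma)
    }
    chan[intersect(channels, names(chan))]
}

#' Render a synthetic platelet-complex event image
#'
#' Draws \code{nPlatelets} disks with diameters sampled from the configured
#' range, attached mutually tangent with centre jitter, and renders the
#' brightfield, CD42b and CD62P channels through the noise model in
#' \code{params}.  The returned annotation records the true platelet count
#' and centres.
#'
#' @param nPlatelets number of platelets in the complex (>= 1).
#' @param params a \linkS4class{RenderParams} object.
#' @param outOfFocus render with the out-of-focus blur width.
#' @param channels which channels to render.
#' @return an \linkS4class{EventImage}.
#' @examples
#' set.seed(1)
#' img <- renderEvent(2, renderParams(shotNoise = FALSE, readNoiseSd = 0))
#' annotation(img)$nPlatelets
#' @export
renderEvent <- function(nPlatelets, params = renderParams(),
                        outOfFocus = FALSE,
                        channels = c("brightfield", "cd42b", "cd62p")) {
    if (!is.numeric(nPlatelets) || length(nPlatelets) != 1L ||
        nPlatelets < 1) {
        stop("nPlatelets must be a single integer >= 1")
    }
    validObject(params)
    geom <- .plateletGeometry(as.integer(nPlatelets), params)
    geom$amplitudes <- params@cd42bAmplitude *
        exp(rnorm(nPlatelets, 0, 0.15))
    chan <- .composeEvent(geom, NULL, params, outOfFocus, channels)
    new("EventImage", channels = chan, pixelSize = params@pixelSize,
        annotation = list(nPlatelets = as.integer(nPlatelets),
                          centers = geom$centers,
                          containsErythrocyte = FALSE))
}

#' Render a synthetic background event
#'
#' Background objects are what conditional gating removes: CD42b-negative
#' erythrocytes, platelet-erythrocyte coincidence images, and debris.
#'
#' @param kind one of \code{"erythrocyte"}, \code{"coincidence"},
#'   \code{"debris"}.
#' @param params a \linkS4class{RenderParams} object.
#' @param outOfFocus render with the out-of-focus blur width.
#' @param channels which channels to render.
#' @return an \linkS4class{EventImage}; coincidence events are flagged
#'   \code{containsErythrocyte} and carry at least one platelet centre.
#' @export
renderBackgroundEvent <- function(kind = c("erythrocyte", "coincidence",
                                           "debris"),
                                  params = renderParams(),
                                  outOfFocus = FALSE,
                                  channels = c("brightfield", "cd42b",
                                               "cd62p")) {
    kind <- match.arg(kind)
    validObject(params)
    sz <- params@imageSize
    if (kind == "erythrocyte") {
        rbc <- .rbcGeometry(params)
        chan <- .composeEvent(NULL, rbc, params, outOfFocus, channels)
        ann <- list(nPlatelets = 0L, centers = NULL,
                    containsErythrocyte = TRUE)
    } else if (kind == "coincidence") {
        nP <- sample(1:2, 1L, prob = c(0.8, 0.2))
        geom <- .plateletGeometry(nP, params)
        geom$amplitudes <- params@cd42bAmplitude * exp(rnorm(nP, 0, 0.15))
        ## shift platelet aside, erythrocyte on the other side
        shift <- sz / 5
        geom$centers <- sweep(geom$centers, 2, c(-shift, 0), "+")
        rbc <- .rbcGeometry(params, offset = c(shift, 0))
        chan <- .composeEvent(geom, rbc, params, outOfFocus, channels)
        ann <- list(nPlatelets = nP, centers = geom$centers,
                    containsErythrocyte = TRUE)
    } else {
        ## debris: a few faint sub-micron specks, visible in brightfield
        nSpeck <- sample(2:4, 1L)
        centers <- matrix((sz + 1) / 2 + runif(2 * nSpeck, -sz / 6, sz / 6),
                          nSpeck, 2)
        geom <- list(centers = centers,
                     radii = runif(nSpeck, 0.5, 1.5),
                     amplitudes = rep(2, nSpeck))
        chan <- .composeEvent(geom, NULL, params, outOfFocus, channels)
        ann <- list(nPlatelets = 0L, centers = NULL,
                    containsErythrocyte = FALSE)
    }
    new("EventImage", channels = chan, pixelSize = params@pixelSize,
        annotation = ann)
}

#' Render a balanced labelled training set
#'
#' Generates synthetic platelet-complex images with equal numbers per
#' aggregation class.  Multiplet (class 4) images contain 4-6 platelets,
#' mirroring the open-ended fourth class.
#'
#' @param n total number of images (rounded up to a multiple of 4).
#' @param params a \linkS4class{RenderParams} object.
#' @param channels channels to render; the classifier uses CD42b only.
#' @return list with \code{images} (list of \linkS4class{EventImage}) and
#'   \code{labels} (integer classes 1-4).
#' @export
renderTrainingSet <- function(n, params = renderParams(),
                              channels = "cd42b") {
    perClass <- ceiling(n / 4)
    labels <- rep(1:4, each = perClass)
    images <- vector("list", length(labels))
    for (i in seq_along(labels)) {
        np <- if (labels[i] == 4L) sample(4:6, 1L) else labels[i]
        images[[i]] <- renderEvent(np, params, channels = channels)
    }
    list(images = images, labels = labels)
}
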