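## Internal numerical helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores \code{.Random.seed} so that seeded simulation helpers
#' do not disturb the caller's random number stream.
#'
#' @param seed integer seed, or \code{NULL} to leave the stream untouched.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
    if (is.null(seed)) {
        return(expr)
    }
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    }, add = TRUE)
    set.seed(as.integer(seed))
    expr
}

## Deterministic substream seeds from a master seed.  A fixed polynomial hash
## keeps substreams independent of iteration order and below 2^31.
substreamSeed <- function(master, ...) {
    idx <- c(...)
    h <- as.double(master) %% 2147483629
    for (k in idx) {
        h <- (h * 69069 + as.double(k) + 1) %% 2147483629
    }
    as.integer(h)
}

## Largest-remainder apportionment: integer counts summing to `total`
## proportional to non-negative weights `w`.
apportionCounts <- function(w, total) {
    stopifnot(all(w >= 0), total >= 0)
    if (sum(w) == 0) {
        return(c(total, rep(0L, length(w) - 1L)))
    }
    exact <- w / sum(w) * total
    lo <- floor(exact)
    rem <- as.integer(total - sum(lo))
    if (rem > 0) {
        add <- order(exact - lo, decreasing = TRUE)[seq_len(rem)]
        lo[add] <- lo[add] + 1
    }
    as.integer(lo)
}

## Otsu's minimum-within-class-variance threshold on a numeric vector.
## Exhaustive search over histogram bin edges; returns the threshold value.
otsuThreshold <- function(x, nbins = 512L) {
    x <- x[is.finite(x)]
    if (length(x) < 2L || diff(range(x)) == 0) {
        stop("cannot place a bimodal threshold on degenerate data")
    }
    br <- seq(min(x), max(x), length.out = nbins + 1L)
    h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE),
                             nbins))
    mids <- (br[-1L] + br[-length(br)]) / 2
    w <- cumsum(h)
    m <- cumsum(h * mids)
    wTot <- w[nbins]
    mTot <- m[nbins]
    ## between-class variance for every cut point
    w1 <- w[-nbins]
    w2 <- wTot - w1
    valid <- w1 > 0 & w2 > 0
    mu1 <- m[-nbins] / w1
    mu2 <- (mTot - m[-nbins]) / w2
    sigmaB <- ifelse(valid, w1 * w2 * (mu1 - mu2)^2, -Inf)
    br[which.max(sigmaB) + 1L]
}

## Banded separable Gaussian blur operator for an n x n image (memoised).
.blurCache <- new.env(parent = emptyenv())
blurMatrix <- function(n, sigma) {
    key <- sprintf("%d_%.6f", n, sigma)
    if (!is.null(.blurCache[[key]])) {
        return(.blurCache[[key]])
    }
    idx <- seq_len(n)
    d <- outer(idx, idx, "-")
    B <- exp(-d^2 / (2 * sigma^2))
    B <- B / rowSums(B)
    .blurCache[[key]] <- B
    B
}

gaussianBlur <- function(img, sigma) {
    if (sigma <= 0) {
        return(img)
    }
    B <- blurMatrix(nrow(img), sigma)
    B %*% img %*% t(B)
}

## Distribution-free confidence interval for the median by the
## order-statistic (binomial) method.
medianCI <- function(x, conf = 0.95) {
    x <- sort(x[is.finite(x)])
    n <- length(x)
    if (n < 3L) {
        return(c(NA_real_, NA_real_))
    }
    alpha <- 1 - conf
    k <- qbinom(alpha / 2, n, 0.5)
    ## widen until coverage reached
    while (k > 0 && (pbinom(n - k, n, 0.5) - pbinom(k - 1, n, 0.5)) < conf) {
        k <- k - 1
    }
    if (k < 1) {
        return(c(x[1], x[n]))
    }
    c(x[k], x[n - k + 1])
}
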