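#' @include AllClasses.R assoc.R
NULL

## vectorized per-marker IVW meta across datasets
.metaRows <- function(betaMat, seMat) {
    w <- 1 / seMat^2
    w[is.na(betaMat)] <- NA
    sw <- rowSums(w, na.rm = TRUE)
    b <- rowSums(w * betaMat, na.rm = TRUE) / sw
    z <- b * sqrt(sw)
    p <- 2 * stats::pnorm(-abs(z))
    p[sw == 0] <- NA
    p
}

#' Empirical genome-wide threshold by paired min-p permutation
#'
#' Estimates the family-wise significance threshold for the local-ancestry x
#' BMI interaction scan. In each iteration, the (case status, PC1) pairs are
#' jointly permuted against all other columns within each dataset -- the
#' pairing preserves the correlation between global ancestry and case status
#' while breaking marker-outcome association; local ancestry, BMI, age and
#' the remaining PCs stay fixed to individuals. The full interaction scan is
#' rerun per dataset, per-marker estimates are combined by inverse-variance
#' fixed-effects meta-analysis, and the smallest interaction p-value over
#' testable markers is stored. The threshold is the \code{alpha} empirical
#' quantile (linear interpolation, type 7) of the stored minima. Iterations
#' in which no marker is testable are redrawn and counted.
#'
#' @param datasets list of datasets; each a list with elements \code{la}
#'   (a \linkS4class{LocalAncestryResult} or markers x individuals call
#'   matrix; marker rows aligned across datasets), \code{bmi}, \code{age},
#'   \code{pcs} (individuals x k, PC1 in column 1; may be NULL), and
#'   \code{outcome} (0/1).
#' @param config a \linkS4class{PermutationConfig}.
#' @return List: \code{threshold}, \code{minp} (the per-iteration minima),
#'   \code{alpha}, \code{nPerm}, \code{seed}, \code{redrawn} (count of
#'   redrawn iterations).
#' @export
minpPermutationThreshold <- function(datasets, config = PermutationConfig()) {
    stopifnot(length(datasets) >= 1L)
    validObject(config)
    ds <- lapply(datasets, function(d) {
        laM <- .laMatrix(d$la)
        n <- length(d$outcome)
        stopifnot(ncol(laM) == n, length(d$bmi) == n, length(d$age) == n)
        list(laT = t(laM), bmi = d$bmi, age = d$age,
             pcs = d$pcs, outcome = d$outcome, n = n)
    })
    M <- ncol(ds[[1L]]$laT)
    for (d in ds) stopifnot(ncol(d$laT) == M)
    set.seed(config@seed)
    minp <- numeric(config@nPerm)
    redrawn <- 0L
    it <- 1L
    while (it <= config@nPerm) {
        betaMat <- seMat <- matrix(NA_real_, M, length(ds))
        for (j in seq_along(ds)) {
            d <- ds[[j]]
            perm <- sample.int(d$n)
            yP <- d$outcome[perm]
            pcsP <- d$pcs
            if (!is.null(pcsP)) pcsP[, 1L] <- d$pcs[perm, 1L]
            covar <- cbind(age = d$age, pcsP)
            res <- .interactionScanCore(d$laT, d$bmi, covar, yP)
            betaMat[, j] <- res$beta
            seMat[, j] <- res$se
        }
        p <- .metaRows(betaMat, seMat)
        if (all(is.na(p))) {
            redrawn <- redrawn + 1L
            next
        }
        minp[it] <- min(p, na.rm = TRUE)
        it <- it + 1L
    }
    list(threshold = unname(stats::quantile(minp, config@alpha, type = 7)),
         minp = minp, alpha = config@alpha, nPerm = config@nPerm,
         seed = config@seed, redrawn = redrawn)
}

#' Effective number of independent tests (simpleM)
#'
#' Eigen-decomposes the marker-marker Pearson correlation matrix (markers
#' mean-imputed; constant markers dropped and counted) and returns the
#' smallest number of top eigenvalues whose sum reaches
#' \code{varExplained} of the trace.
#'
#' @param genotypes markers x individuals matrix (NA = missing).
#' @param varExplained fraction of variance to capture (default 0.995).
#' @return List: \code{meff}, \code{nMarkersUsed}, \code{nConstantDropped},
#'   \code{eigenvalues}.
#' @export
simpleM <- function(genotypes, varExplained = 0.995) {
    f <- rowMeans(genotypes, na.rm = TRUE)
    g <- genotypes
    if (anyNA(g)) {
        idx <- which(is.na(g), arr.ind = TRUE)
        g[idx] <- f[idx[, 1L]]
    }
    v <- apply(g, 1L, stats::var)
    keep <- v > 0
    g <- g[keep, , drop = FALSE]
    if (nrow(g) < 2L) stop("need >= 2 variable markers")
    C <- stats::cor(t(g))
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    meff <- which(cumsum(ev) >= varExplained * sum(ev))[1L]
    list(meff = as.integer(meff), nMarkersUsed = nrow(g),
         nConstantDropped = sum(!keep), eigenvalues = ev)
}

#' Bonferroni threshold from effective test counts
#'
#' Divides \code{alpha} by the most conservative (largest) effective number
#' of tests across datasets.
#'
#' @param alpha family-wise level (default 0.05).
#' @param meff one effective-test count per dataset.
#' @return The significance threshold alpha / max(meff).
#' @examples
#' bonferroniThreshold(0.05, c(7215, 6885))  # 6.9e-6
#' @export
bonferroniThreshold <- function(alpha = 0.05, meff) {
    stopifnot(all(meff >= 1))
    alpha / max(meff)
}
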