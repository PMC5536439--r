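#' @include AllClasses.R
NULL

#' Genotype call rate
#'
#' Fraction of non-missing genotypes per sample or per marker.
#'
#' @param genotypes markers x individuals matrix (NA = missing).
#' @param margin \code{"sample"} (columns) or \code{"marker"} (rows).
#' @return Numeric vector of call rates in [0, 1].
#' @export
callRate <- function(genotypes, margin = c("sample", "marker")) {
    margin <- match.arg(margin)
    if (length(genotypes) == 0L) stop("empty genotype matrix")
    ok <- !is.na(genotypes)
    if (margin == "sample") colMeans(ok) else rowMeans(ok)
}

#' Minor allele frequency
#'
#' MAF per marker: \code{min(f, 1 - f)} with f the mean genotype over
#' non-missing entries divided by 2. All-missing markers return NA.
#'
#' @param genotypes markers x individuals matrix, or a single genotype vector.
#' @return MAF in [0, 0.5] per marker (NA where no data).
#' @export
minorAlleleFreq <- function(genotypes) {
    if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1L)
    f <- rowMeans(genotypes, na.rm = TRUE) / 2
    f[!rowSums(!is.na(genotypes))] <- NA_real_
    pmin(f, 1 - f)
}

#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against the proportions p^2, 2pq, q^2 expected from the observed
#' allele frequency; no continuity correction. Monomorphic markers return
#' p = 1 by convention (no test possible).
#'
#' @param nRR,nRA,nAA counts of reference-homozygote, heterozygote and
#'   alternate-homozygote genotypes (vectorized).
#' @return Two-sided upper-tail p-value(s) in [0, 1].
#' @examples
#' hweTest(25, 50, 25)   # exact HWE proportions -> p = 1
#' hweTest(60, 20, 20)   # chi-square ~ 27.44 -> p ~ 1.6e-7
#' @export
hweTest <- function(nRR, nRA, nAA) {
    n <- nRR + nRA + nAA
    if (any(n <= 0)) stop("total genotype count must be positive")
    p <- (2 * nRR + nRA) / (2 * n)
    q <- 1 - p
    eRR <- n * p^2; eRA <- n * 2 * p * q; eAA <- n * q^2
    stat <- ifelse(p == 0 | q == 0, 0,
                   (nRR - eRR)^2 / eRR + (nRA - eRA)^2 / eRA +
                   (nAA - eAA)^2 / eAA)
    stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

.hwePerMarker <- function(genotypes) {
    nRR <- rowSums(genotypes == 0L, na.rm = TRUE)
    nRA <- rowSums(genotypes == 1L, na.rm = TRUE)
    nAA <- rowSums(genotypes == 2L, na.rm = TRUE)
    tot <- nRR + nRA + nAA
    p <- rep(1, nrow(genotypes))
    p[tot > 0] <- hweTest(nRR[tot > 0], nRA[tot > 0], nAA[tot > 0])
    p
}

#' Run cohort quality control
#'
#' Applies the array-QC filter cascade in fixed order: per-sample call rate,
#' then per-marker call rate, then minor allele frequency, then Hardy-Weinberg
#' equilibrium (computed in controls only by default). All comparisons are
#' strict (entities exactly at a threshold are retained); markers with no data
#' are removed with reason \code{"no data"}. A marker failing several filters
#' is attributed to the first applicable one.
#'
#' @param cohort an \linkS4class{AdmixCohort}.
#' @param thresholds a \linkS4class{QcThresholds}.
#' @return List with the filtered \code{cohort} and a \code{report}
#'   data.frame (one row per filter step: entities tested, removed, retained).
#' @export
runQc <- function(cohort, thresholds = QcThresholds()) {
    stopifnot(is(cohort, "AdmixCohort"), is(thresholds, "QcThresholds"))
    validObject(thresholds)
    g <- genotypes(cohort)
    steps <- list()

    cr <- callRate(g, "sample")
    keepInd <- cr >= thresholds@minSampleCallRate
    steps$sample_call_rate <- c(tested = ncol(g), removed = sum(!keepInd))
    if (!any(keepInd)) stop("QC removed all individuals (sample call rate)")
    cohort <- cohort[, keepInd]
    g <- genotypes(cohort)

    crM <- callRate(g, "marker")
    noData <- crM == 0
    keepM <- crM >= thresholds@minSnpCallRate & !noData
    steps$marker_no_data <- c(tested = nrow(g), removed = sum(noData))
    steps$marker_call_rate <- c(tested = sum(!noData),
                                removed = sum(!keepM & !noData))
    cohort <- cohort[keepM, ]
    g <- genotypes(cohort)

    maf <- minorAlleleFreq(g)
    keepMaf <- !is.na(maf) & maf >= thresholds@minMaf
    steps$maf <- c(tested = nrow(g), removed = sum(!keepMaf))
    cohort <- cohort[keepMaf, ]
    g <- genotypes(cohort)

    hweG <- if (thresholds@hweInControlsOnly)
        g[, SummarizedExperiment::colData(cohort)$case == 0, drop = FALSE]
    else g
    if (ncol(hweG) == 0L) {
        keepHwe <- rep(TRUE, nrow(g))
    } else {
        pHwe <- .hwePerMarker(hweG)
        keepHwe <- pHwe >= thresholds@hwePMin
    }
    steps$hwe <- c(tested = nrow(g), removed = sum(!keepHwe))
    cohort <- cohort[keepHwe, ]

    if (nrow(cohort) == 0L) stop("QC removed all markers")
    report <- data.frame(step = names(steps),
                         tested = vapply(steps, `[`, numeric(1), "tested"),
                         removed = vapply(steps, `[`, numeric(1), "removed"),
                         row.names = NULL, stringsAsFactors = FALSE)
    report$retained <- report$tested - report$removed
    list(cohort = cohort, report = report)
}
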