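#' @include AllClasses.R
NULL

#' Select ancestry-informative markers
#'
#' Retains markers whose absolute ancestral allele-frequency difference
#' (delta = |freq_afr - freq_eur|) strictly exceeds \code{deltaMin}.
#'
#' @param panel an \linkS4class{AncestralPanel}.
#' @param deltaMin minimum delta, exclusive (default 0.2).
#' @return An \linkS4class{AncestralPanel} subset (possibly empty, with a
#'   warning).
#' @export
selectAims <- function(panel, deltaMin = 0.2) {
    stopifnot(is(panel, "AncestralPanel"))
    keep <- abs(panel$freq_afr - panel$freq_eur) > deltaMin
    if (!any(keep))
        warning("no markers exceed delta ", deltaMin, "; returning empty panel")
    panel[keep, ]
}

#' Greedy windowed LD pruning
#'
#' Slides a window of \code{window} markers (in position order) by
#' \code{step}; within each window, for any retained pair with squared
#' Pearson genotype correlation above \code{r2Max}, the later-position marker
#' is removed. Constant markers have undefined correlation, treated as 0.
#'
#' @param genotypes markers x individuals matrix (rows in position order).
#' @param r2Max maximum allowed r-squared (default 0.1).
#' @param window window size in markers (default 50).
#' @param step window slide in markers (default 5).
#' @return Logical vector: TRUE for retained markers.
#' @export
ldPrune <- function(genotypes, r2Max = 0.1, window = 50L, step = 5L) {
    M <- nrow(genotypes)
    stopifnot(M >= 2L, window >= 2L, step >= 1L)
    keep <- rep(TRUE, M)
    starts <- unique(c(seq(1L, max(1L, M - window + 1L), by = step)))
    for (s in starts) {
        idx <- s:min(s + window - 1L, M)
        idx <- idx[keep[idx]]
        if (length(idx) < 2L) next
        x <- t(genotypes[idx, , drop = FALSE])
        r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
        r[!is.finite(r)] <- 0
        r2 <- r^2
        for (a in seq_len(length(idx) - 1L)) {
            if (!keep[idx[a]]) next
            hits <- which(r2[a, ] > r2Max)
            hits <- hits[hits > a & keep[idx[hits]]]
            if (length(hits)) keep[idx[hits]] <- FALSE
        }
    }
    names(keep) <- rownames(genotypes)
    keep
}

## frequency flooring guards against zero-likelihood lock-in
.FREQ_FLOOR <- 1e-4

## genotype-emission table for one marker: rows = state k 0/1/2,
## columns = genotype 0/1/2; P(g | k) under per-haplotype allele draws
.emissionTable <- function(pA, pE) {
    rbind(c((1 - pA)^2, 2 * pA * (1 - pA), pA^2),
          c((1 - pA) * (1 - pE), pE * (1 - pA) + pA * (1 - pE), pA * pE),
          c((1 - pE)^2, 2 * pE * (1 - pE), pE^2))
}

## diploid transition matrix for one inter-marker interval; s = switch prob
.diploidTransition <- function(s, lam) {
    pAE <- s * lam                 # AFR hap -> EUR
    pEE <- (1 - s) + s * lam       # EUR hap stays EUR
    rbind(c((1 - pAE)^2, 2 * pAE * (1 - pAE), pAE^2),
          c((1 - pEE) * (1 - pAE), pEE * (1 - pAE) + pAE * (1 - pEE), pEE * pAE),
          c((1 - pEE)^2, 2 * pEE * (1 - pEE), pEE^2))
}

#' Infer diploid local ancestry by hidden Markov model
#'
#' The hidden state at each marker is the European-copy count k in {0, 1, 2}.
#' The two haplotypes follow independent re-draw-from-stationary Markov
#' chains (the tract kernel of \code{\link{simulateHaplotypeTracts}}), so the
#' diploid chain starts at Binomial(2, lambda) and the per-interval transition
#' is the two-haplotype composition of the haplotype kernel. Emissions are
#' binomial mixtures of the ancestral allele frequencies (floored to
#' [1e-4, 1 - 1e-4] against panel-estimate error); missing genotypes emit
#' likelihood 1 in every state. Posterior state probabilities come from the
#' scaled forward-backward recursion per chromosome, and calls are the
#' per-marker posterior mode (an additive 0/1/2 dosage for downstream models).
#'
#' @param x an \linkS4class{AdmixCohort} or a markers x individuals genotype
#'   matrix.
#' @param panel the matching \linkS4class{AncestralPanel}; taken from
#'   \code{x} when it is a cohort.
#' @param config an \linkS4class{AdmixtureConfig} (lambda, generations,
#'   recombination rate).
#' @return A \linkS4class{LocalAncestryResult}.
#' @export
inferLocalAncestry <- function(x, panel = NULL, config = AdmixtureConfig()) {
    if (is(x, "AdmixCohort")) {
        g <- genotypes(x)
        if (is.null(panel)) panel <- panelData(x)
    } else g <- x
    stopifnot(is(panel, "AncestralPanel"), nrow(g) == nrow(panel))
    validObject(config)
    lam <- config@lambdaEur
    n <- ncol(g); M <- nrow(g)
    pA <- pmin(pmax(panel$freq_afr, .FREQ_FLOOR), 1 - .FREQ_FLOOR)
    pE <- pmin(pmax(panel$freq_eur, .FREQ_FLOOR), 1 - .FREQ_FLOOR)
    pi0 <- stats::dbinom(0:2, 2L, lam)
    post <- array(NA_real_, c(M, n, 3L))

    for (ch in unique(panel$chrom)) {
        idx <- which(panel$chrom == ch)
        Mc <- length(idx)
        psw <- 1 - exp(-config@generations * config@recombRate *
                       diff(panel$pos[idx]))
        trans <- lapply(psw, .diploidTransition, lam = lam)
        ## per-marker n x 3 emission likelihoods
        emit <- vector("list", Mc)
        for (j in seq_len(Mc)) {
            tab <- .emissionTable(pA[idx[j]], pE[idx[j]])
            e <- matrix(1, n, 3L)
            gv <- g[idx[j], ]
            obs <- !is.na(gv)
            if (any(obs)) e[obs, ] <- t(tab[, gv[obs] + 1L, drop = FALSE])
            emit[[j]] <- e
        }
        alpha <- vector("list", Mc)
        a <- sweep(emit[[1L]], 2L, pi0, `*`)
        a <- a / rowSums(a)
        alpha[[1L]] <- a
        for (j in seq_len(Mc - 1L)) {
            a <- (a %*% trans[[j]]) * emit[[j + 1L]]
            a <- a / rowSums(a)
            alpha[[j + 1L]] <- a
        }
        b <- matrix(1, n, 3L)
        post[idx[Mc], , ] <- alpha[[Mc]]
        for (j in rev(seq_len(Mc - 1L))) {
            b <- (b * emit[[j + 1L]]) %*% t(trans[[j]])
            b <- b / rowSums(b)
            p <- alpha[[j]] * b
            post[idx[j], , ] <- p / rowSums(p)
        }
    }

    calls <- apply(post, c(1L, 2L), which.max) - 1L
    mk <- list(panel$marker_id, colnames(g))
    dimnames(calls) <- mk
    mkmat <- function(k) {
        m <- post[, , k, drop = FALSE]; dim(m) <- c(M, n); dimnames(m) <- mk; m
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls, p0 = mkmat(1L), p1 = mkmat(2L),
                      p2 = mkmat(3L)),
        rowData = as(panel, "DFrame"))
    new("LocalAncestryResult", se)
}

#' Genotype principal components
#'
#' PCA for population-structure adjustment: markers are mean-imputed, centered
#' by twice the allele frequency and scaled by sqrt(2 f (1 - f)); scores are
#' the left singular vectors scaled by the singular values. Constant markers
#' are dropped. Sign is fixed deterministically: the largest-magnitude marker
#' loading of each component is made positive.
#'
#' @param genotypes markers x individuals matrix (NA = missing).
#' @param k number of components (default 10; reduced with a warning when
#'   fewer than k + 1 individuals are available).
#' @return Individuals x k score matrix.
#' @export
computePCs <- function(genotypes, k = 10L) {
    n <- ncol(genotypes)
    if (n - 1L < k) {
        k <- max(1L, n - 1L)
        warning("fewer individuals than requested components; returning ", k)
    }
    f <- rowMeans(genotypes, na.rm = TRUE) / 2
    keep <- !is.na(f) & f > 0 & f < 1
    g <- genotypes[keep, , drop = FALSE]
    f <- f[keep]
    g[is.na(g)] <- (2 * f)[which(is.na(g), arr.ind = TRUE)[, 1L]]
    X <- t((g - 2 * f) / sqrt(2 * f * (1 - f)))   # individuals x markers
    M <- ncol(X)
    if (M <= n) {
        ev <- eigen(crossprod(X), symmetric = TRUE)
        V <- ev$vectors[, seq_len(k), drop = FALSE]
        scores <- X %*% V
    } else {
        ev <- eigen(tcrossprod(X), symmetric = TRUE)
        d <- sqrt(pmax(ev$values[seq_len(k)], 0))
        U <- ev$vectors[, seq_len(k), drop = FALSE]
        scores <- sweep(U, 2L, d, `*`)
        V <- crossprod(X, U)
        V <- sweep(V, 2L, pmax(d^2, .Machine$double.eps), `/`) *
             rep(d, each = M)
    }
    for (j in seq_len(k)) {
        v <- V[, j]
        if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
    }
    dimnames(scores) <- list(colnames(genotypes), paste0("PC", seq_len(k)))
    scores
}
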