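# Shared fixtures and independent oracles. All randomness is seeded.

# a small AIM panel on two chromosomes
toyPanel <- function(nMarkers = 40L, nChrom = 2L, seed = 42L, minDelta = 0.2,
                     spacing = 1.5e5) {
    simulatePanel(nMarkers = nMarkers, nChrom = nChrom,
                  spacingMeanBp = spacing, minDelta = minDelta, seed = seed)
}

# hand-built panel with explicit positions/frequencies
handPanel <- function(pos, freqAfr, freqEur, chrom = "1") {
    n <- length(pos)
    AncestralPanel(marker_id = paste0("hm", seq_len(n)), chrom = chrom,
                   pos = pos, ref = "A", alt = "G",
                   freq_afr = freqAfr, freq_eur = freqEur)
}

# exhaustive-path posterior oracle for the diploid ancestry HMM.
# Derived independently of the package internals: the two haplotypes are
# explicit, each following the re-draw kernel over {AFR, EUR}; all
# (2^M)^2 ordered haplotype label paths are enumerated and the diploid
# posterior is the marginal of the European copy count.
bruteForcePosterior <- function(genotype, pos, freqAfr, freqEur, lam, G, r) {
    M <- length(genotype)
    fa <- pmin(pmax(freqAfr, 1e-4), 1 - 1e-4)
    fe <- pmin(pmax(freqEur, 1e-4), 1 - 1e-4)
    s <- 1 - exp(-G * r * diff(pos))
    hapPaths <- as.matrix(expand.grid(rep(list(0:1), M)))  # 0=AFR, 1=EUR
    hapPrior <- apply(hapPaths, 1L, function(h) {
        p <- if (h[1] == 1) lam else 1 - lam
        for (j in seq_len(M - 1L)) {
            stay <- (1 - s[j]) + s[j] * (if (h[j + 1] == 1) lam else 1 - lam)
            move <- s[j] * (if (h[j + 1] == 1) lam else 1 - lam)
            p <- p * (if (h[j + 1] == h[j]) stay else move)
        }
        p
    })
    post <- matrix(0, M, 3L)
    norm <- 0
    for (i in seq_len(nrow(hapPaths))) for (j in seq_len(nrow(hapPaths))) {
        h1 <- hapPaths[i, ]; h2 <- hapPaths[j, ]
        lik <- 1
        for (m in seq_len(M)) {
            if (is.na(genotype[m])) next
            p1 <- if (h1[m] == 1) fe[m] else fa[m]
            p2 <- if (h2[m] == 1) fe[m] else fa[m]
            g <- genotype[m]
            lik <- lik * switch(g + 1L,
                (1 - p1) * (1 - p2),
                p1 * (1 - p2) + p2 * (1 - p1),
                p1 * p2)
        }
        w <- hapPrior[i] * hapPrior[j] * lik
        norm <- norm + w
        k <- h1 + h2
        for (m in seq_len(M)) post[m, k[m] + 1L] <- post[m, k[m] + 1L] + w
    }
    post / norm
}

# independent genotype matrix with no LD: per-marker binomial draws
independentGenotypes <- function(M, n, freq = NULL, seed = 1L) {
    set.seed(seed)
    if (is.null(freq)) freq <- stats::runif(M, 0.1, 0.9)
    g <- matrix(stats::rbinom(M * n, 2L, rep(freq, n)), M, n)
    rownames(g) <- paste0("g", seq_len(M))
    g
}
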