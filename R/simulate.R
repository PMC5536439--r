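#' @include AllClasses.R
NULL

## lower-truncated normal via inverse-CDF; exact, vectorized
.rtruncnorm <- function(n, mean, sd, lower) {
    plo <- stats::pnorm(lower, mean, sd)
    stats::qnorm(stats::runif(n, plo, 1), mean, sd)
}

#' Simulate an ancestral allele-frequency panel
#'
#' Draws a synthetic marker panel for two ancestral populations: marker
#' positions per chromosome with exponentially distributed spacing, and
#' independent uniform alternate-allele frequencies in each population,
#' optionally rejected until the absolute frequency difference (delta) exceeds
#' \code{minDelta} so the panel emulates an AIM set.
#'
#' @param nMarkers total number of markers.
#' @param nChrom number of chromosomes (markers split evenly).
#' @param spacingMeanBp mean inter-marker spacing in bp. The default 1.5e5
#'   matches the density of a 20,000-marker genome-wide AIM panel on the
#'   human autosomes; at G = 7 and r = 1e-8 it gives an expected
#'   per-interval ancestry-switch probability of about 0.01.
#' @param minDelta minimum |freq_afr - freq_eur|; 0 disables the constraint.
#' @param freqRange range for the uniform frequency draws (keeps markers
#'   polymorphic in both populations).
#' @param seed integer seed.
#' @return An \linkS4class{AncestralPanel}.
#' @export
simulatePanel <- function(nMarkers = 500L, nChrom = 10L, spacingMeanBp = 1.5e5,
                          minDelta = 0, freqRange = c(0.05, 0.95), seed = 1L) {
    stopifnot(nMarkers >= 1L, nChrom >= 1L, minDelta < diff(freqRange))
    set.seed(as.integer(seed))
    chrom <- as.character(rep_len(seq_len(nChrom), nMarkers))
    chrom <- chrom[order(as.integer(chrom))]
    pos <- integer(nMarkers)
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        gaps <- pmax(1, round(stats::rexp(length(idx), 1 / spacingMeanBp)))
        pos[idx] <- cumsum(gaps)
    }
    fa <- stats::runif(nMarkers, freqRange[1], freqRange[2])
    fe <- stats::runif(nMarkers, freqRange[1], freqRange[2])
    if (minDelta > 0) {
        repeat {
            bad <- which(abs(fa - fe) <= minDelta)
            if (!length(bad)) break
            fa[bad] <- stats::runif(length(bad), freqRange[1], freqRange[2])
            fe[bad] <- stats::runif(length(bad), freqRange[1], freqRange[2])
        }
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nMarkers, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    AncestralPanel(marker_id = sprintf("m%05d", seq_len(nMarkers)),
                   chrom = chrom, pos = pos, ref = ref, alt = alt,
                   freq_afr = fa, freq_eur = fe)
}

#' Simulate haplotype ancestry tracts
#'
#' Each haplotype follows a Markov chain along each chromosome under the
#' re-draw-from-stationary tract kernel: the first marker of a chromosome is
#' European with probability lambda; between adjacent markers separated by
#' d bp the ancestry is re-drawn from the stationary distribution
#' \{EUR: lambda, AFR: 1 - lambda\} with probability
#' \eqn{1 - \exp(-G r d)}, and kept otherwise. Chromosomes are independent.
#' This is the exponential tract-length model implied by G generations of
#' admixture at recombination rate r.
#'
#' When \code{config@lambdaSd > 0}, each individual (consecutive haplotype
#' pair) receives its own admixture proportion drawn from the Beta
#' distribution with mean \code{lambdaEur} and that SD, emulating the
#' between-individual ancestry spread of real admixed cohorts; both chains of
#' an individual use its proportion, and the marker-wise expected European
#' fraction remains \code{lambdaEur}.
#'
#' @param panel an \linkS4class{AncestralPanel}.
#' @param config an \linkS4class{AdmixtureConfig}.
#' @param nHaplotypes number of haplotypes to draw.
#' @param seed optional seed; default \code{config@seed}.
#' @return Integer matrix (markers x haplotypes), 1 = European, 0 = African.
#' @export
simulateHaplotypeTracts <- function(panel, config, nHaplotypes,
                                    seed = config@seed) {
    stopifnot(is(panel, "AncestralPanel"), is(config, "AdmixtureConfig"),
              nrow(panel) >= 1L, nHaplotypes >= 1L)
    validObject(panel); validObject(config)
    if (!is.null(seed)) set.seed(as.integer(seed))
    lam <- config@lambdaEur
    M <- nrow(panel); H <- as.integer(nHaplotypes)
    if (config@lambdaSd > 0) {
        v <- config@lambdaSd^2
        ab <- lam * (1 - lam) / v - 1
        lamInd <- stats::rbeta(ceiling(H / 2), lam * ab, (1 - lam) * ab)
        lamH <- rep(lamInd, each = 2L)[seq_len(H)]
    } else lamH <- rep(lam, H)
    out <- matrix(0L, M, H,
                  dimnames = list(panel$marker_id, NULL))
    for (ch in unique(panel$chrom)) {
        idx <- which(panel$chrom == ch)
        pos <- panel$pos[idx]
        psw <- 1 - exp(-config@generations * config@recombRate * diff(pos))
        state <- as.integer(stats::runif(H) < lamH)
        out[idx[1L], ] <- state
        for (j in seq_along(psw)) {
            sw <- stats::runif(H) < psw[j]
            if (any(sw))
                state[sw] <- as.integer(stats::runif(sum(sw)) < lamH[sw])
            out[idx[j + 1L], ] <- state
        }
    }
    out
}

#' Simulate genotypes given haplotype ancestry tracts
#'
#' On a European-labelled haplotype the alternate allele is drawn with
#' probability \code{freq_eur}, on an African-labelled haplotype with
#' probability \code{freq_afr}; the genotype is the sum of the two allele
#' draws and the true local ancestry the sum of the two haplotype labels.
#' Consecutive haplotype pairs (columns 1-2, 3-4, ...) form individuals.
#'
#' @param tracts markers x haplotypes 0/1 matrix from
#'   \code{\link{simulateHaplotypeTracts}}; an even number of columns.
#' @param panel the \linkS4class{AncestralPanel} the tracts were drawn on.
#' @param missingRate fraction of genotype entries set missing at random
#'   (default 0; exercises QC).
#' @param seed optional seed.
#' @return List with integer matrices \code{genotypes} (NA = missing) and
#'   \code{trueLocalAncestry}, both markers x individuals.
#' @export
simulateGenotypes <- function(tracts, panel, missingRate = 0, seed = NULL) {
    stopifnot(is(panel, "AncestralPanel"), nrow(tracts) == nrow(panel),
              ncol(tracts) %% 2L == 0L,
              missingRate >= 0, missingRate < 1)
    if (!is.null(seed)) set.seed(as.integer(seed))
    M <- nrow(tracts); H <- ncol(tracts); n <- H %/% 2L
    pAlt <- ifelse(tracts == 1L, panel$freq_eur, panel$freq_afr)
    alleles <- matrix(as.integer(stats::runif(M * H) < pAlt), M, H)
    odd <- seq(1L, H, by = 2L); even <- odd + 1L
    geno <- alleles[, odd, drop = FALSE] + alleles[, even, drop = FALSE]
    la <- tracts[, odd, drop = FALSE] + tracts[, even, drop = FALSE]
    if (missingRate > 0) {
        drop <- stats::runif(M * n) < missingRate
        geno[drop] <- NA_integer_
    }
    rownames(geno) <- rownames(la) <- panel$marker_id
    list(genotypes = geno, trueLocalAncestry = la)
}

#' Simulate case-control outcomes under a local-ancestry x BMI model
#'
#' Draws Bernoulli outcomes with
#' \eqn{logit P(case) = \beta_0 + \beta_{la} a + \beta_{bmi} BMI +
#' \beta_{int} a (BMI - 25) + \beta_{age} age}, where \eqn{a} is the true
#' European-copy count at the causal marker (0 when no causal marker is set).
#' BMI is centered at 25 kg/m2 inside the product term only, anchoring the
#' main ancestry effect at the normal-weight boundary.
#'
#' @param causalLa integer vector of true European copies at the causal
#'   marker, one per individual (use 0 for a null model).
#' @param bmi,age covariate vectors (kg/m2, years).
#' @param pcfg a \linkS4class{PhenotypeConfig} providing the coefficients.
#' @param seed optional seed; default \code{pcfg@seed}.
#' @return Integer 0/1 outcome vector.
#' @export
simulatePhenotype <- function(causalLa, bmi, age, pcfg, seed = pcfg@seed) {
    stopifnot(is(pcfg, "PhenotypeConfig"),
              length(bmi) == length(age),
              length(causalLa) %in% c(1L, length(bmi)))
    validObject(pcfg)
    if (!is.null(seed)) set.seed(as.integer(seed))
    eta <- pcfg@beta0 + pcfg@betaLa * causalLa + pcfg@betaBmi * bmi +
        pcfg@betaInt * causalLa * (bmi - 25) + pcfg@betaAge * age
    stats::rbinom(length(bmi), 1L, stats::plogis(eta))
}

#' Simulate a complete admixed case-control cohort
#'
#' Composes tract, genotype, covariate and phenotype simulation into an
#' \linkS4class{AdmixCohort} with known truth. Covariates are independent
#' truncated normals (BMI >= 15 kg/m2, age >= 18 years) with the moments in
#' \code{pcfg}. Tract and genotype draws are seeded by \code{config@seed},
#' covariate and outcome draws by \code{pcfg@seed}, so the same configuration
#' reproduces the cohort bit-exactly. When \code{dir} is given the cohort is
#' also written to disk (VCF, covariate TSV, truth TSV) via
#' \code{\link{writeCohort}}.
#'
#' @param panel an \linkS4class{AncestralPanel}.
#' @param config an \linkS4class{AdmixtureConfig}.
#' @param pcfg a \linkS4class{PhenotypeConfig}; \code{pcfg@causalMarker} must
#'   be \code{""} or a panel marker id.
#' @param missingRate fraction of genotypes set missing at random (default 0).
#' @param dir optional output directory.
#' @return An \linkS4class{AdmixCohort} with assay \code{trueLocalAncestry}.
#' @examples
#' panel <- simulatePanel(nMarkers = 50, nChrom = 2, seed = 7)
#' cohort <- simulateCohort(panel, AdmixtureConfig(seed = 7),
#'                          PhenotypeConfig(nIndividuals = 100, seed = 7))
#' cohort
#' @export
simulateCohort <- function(panel, config = AdmixtureConfig(),
                           pcfg = PhenotypeConfig(), missingRate = 0,
                           dir = NULL) {
    stopifnot(is(panel, "AncestralPanel"))
    if (nzchar(pcfg@causalMarker) &&
        !pcfg@causalMarker %in% panel$marker_id)
        stop("causal marker '", pcfg@causalMarker, "' not in panel")
    n <- pcfg@nIndividuals
    tracts <- simulateHaplotypeTracts(panel, config, 2L * n)
    gm <- simulateGenotypes(tracts, panel, missingRate = missingRate,
                            seed = NULL)
    set.seed(pcfg@seed)
    bmi <- .rtruncnorm(n, pcfg@bmiMean, pcfg@bmiSd, 15)
    age <- .rtruncnorm(n, pcfg@ageMean, pcfg@ageSd, 18)
    causalLa <- if (nzchar(pcfg@causalMarker))
        gm$trueLocalAncestry[pcfg@causalMarker, ] else rep(0L, n)
    y <- simulatePhenotype(causalLa, bmi, age, pcfg, seed = NULL)
    ids <- sprintf("ind%05d", seq_len(n))
    colnames(gm$genotypes) <- colnames(gm$trueLocalAncestry) <- ids
    cov <- data.frame(individual_id = ids, case = y, age = age, bmi = bmi,
                      stringsAsFactors = FALSE)
    cohort <- AdmixCohort(gm$genotypes, panel, cov,
                          trueLocalAncestry = gm$trueLocalAncestry)
    if (!is.null(dir)) writeCohort(cohort, dir)
    cohort
}
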