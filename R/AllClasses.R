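#' @import methods
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## AncestralPanel
## ---------------------------------------------------------------------------

#' Ancestral allele-frequency panel
#'
#' Per-marker positions and alternate-allele frequencies in the two ancestral
#' populations (African and European). The panel is the basis for cohort
#' simulation, ancestry-informative-marker (AIM) selection, and the emission
#' model of the local-ancestry HMM.
#'
#' Required columns: \code{marker_id}, \code{chrom}, \code{pos} (1-based bp),
#' \code{ref}, \code{alt}, \code{freq_afr}, \code{freq_eur}. Positions must be
#' strictly increasing within each chromosome and marker ids unique;
#' frequencies live in [0, 1].
#'
#' @aliases AncestralPanel-class
#' @exportClass AncestralPanel
setClass("AncestralPanel", contains = "DFrame")

.validAncestralPanel <- function(object) {
    msg <- NULL
    req <- c("marker_id", "chrom", "pos", "ref", "alt", "freq_afr", "freq_eur")
    miss <- setdiff(req, colnames(object))
    if (length(miss))
        return(paste("missing panel column(s):", paste(miss, collapse = ", ")))
    if (anyDuplicated(object$marker_id))
        msg <- c(msg, "marker_id values must be unique")
    fa <- object$freq_afr; fe <- object$freq_eur
    if (any(fa < 0 | fa > 1 | fe < 0 | fe > 1, na.rm = TRUE) ||
        anyNA(fa) || anyNA(fe))
        msg <- c(msg, "panel frequencies must be in [0, 1] and non-missing")
    pos <- object$pos
    if (anyNA(pos) || any(pos < 1) || any(pos != round(pos)))
        msg <- c(msg, "positions must be positive integers")
    for (ch in unique(object$chrom)) {
        p <- pos[object$chrom == ch]
        if (any(diff(p) <= 0)) {
            msg <- c(msg, sprintf(
                "positions must be strictly increasing within chromosome %s", ch))
            break
        }
    }
    if (is.null(msg)) TRUE else msg
}

setValidity("AncestralPanel", .validAncestralPanel)

#' Construct an AncestralPanel
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param chrom chromosome label per marker.
#' @param pos 1-based base-pair position, strictly increasing within chromosome.
#' @param ref,alt allele strings.
#' @param freq_afr,freq_eur alternate-allele frequency in the African and
#'   European ancestral panels, in [0, 1].
#' @return An \linkS4class{AncestralPanel}.
#' @examples
#' AncestralPanel(marker_id = c("m1", "m2"), chrom = "1", pos = c(100L, 200L),
#'                ref = "A", alt = "G", freq_afr = c(0.9, 0.1),
#'                freq_eur = c(0.1, 0.8))
#' @export
AncestralPanel <- function(marker_id, chrom, pos, ref, alt, freq_afr, freq_eur) {
    df <- S4Vectors::DataFrame(
        marker_id = as.character(marker_id),
        chrom     = as.character(chrom),
        pos       = as.integer(pos),
        ref       = as.character(ref),
        alt       = as.character(alt),
        freq_afr  = as.numeric(freq_afr),
        freq_eur  = as.numeric(freq_eur))
    rownames(df) <- df$marker_id
    new("AncestralPanel", df)
}

## ---------------------------------------------------------------------------
## Configuration classes
## ---------------------------------------------------------------------------

#' Admixture model configuration
#'
#' Parameters of the two-way admixture tract model shared by the simulator and
#' the local-ancestry HMM: the expected European ancestry proportion, the
#' number of generations since admixture, and the per-bp per-generation
#' recombination rate.
#'
#' @slot lambdaEur expected European ancestry proportion (default 0.2).
#' @slot lambdaSd between-individual SD of the admixture proportion
#'   (default 0.1, matching the ancestry spread seen in African American
#'   cohorts); 0 gives every individual the same proportion. Individual
#'   proportions are drawn from the Beta distribution with this mean and SD.
#' @slot generations generations since admixture (default 7).
#' @slot recombRate recombination rate per bp per generation (default 1e-8).
#' @slot seed integer seed for any randomness drawn under this configuration.
#' @aliases AdmixtureConfig-class
#' @exportClass AdmixtureConfig
setClass("AdmixtureConfig",
    representation(lambdaEur = "numeric", lambdaSd = "numeric",
                   generations = "integer",
                   recombRate = "numeric", seed = "integer"),
    prototype(lambdaEur = 0.2, lambdaSd = 0.1, generations = 7L,
              recombRate = 1e-8, seed = 1L))

setValidity("AdmixtureConfig", function(object) {
    msg <- NULL
    lam <- object@lambdaEur
    if (lam <= 0 || lam >= 1)
        msg <- c(msg, "lambdaEur must be in (0, 1)")
    else if (object@lambdaSd < 0 ||
             object@lambdaSd^2 >= lam * (1 - lam))
        msg <- c(msg, "lambdaSd^2 must be in [0, lambdaEur * (1 - lambdaEur))")
    if (object@generations < 1L)
        msg <- c(msg, "generations must be >= 1")
    if (object@recombRate <= 0)
        msg <- c(msg, "recombRate must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' @param lambdaEur,lambdaSd,generations,recombRate,seed see slots.
#' @return An \linkS4class{AdmixtureConfig}.
#' @rdname AdmixtureConfig-class
#' @export
AdmixtureConfig <- function(lambdaEur = 0.2, lambdaSd = 0.1, generations = 7L,
                            recombRate = 1e-8, seed = 1L) {
    new("AdmixtureConfig", lambdaEur = lambdaEur, lambdaSd = lambdaSd,
        generations = as.integer(generations), recombRate = recombRate,
        seed = as.integer(seed))
}

#' Phenotype-generation configuration
#'
#' Parameters of the generative logistic outcome model used by the simulator:
#' \deqn{logit P(case) = \beta_0 + \beta_{la} a + \beta_{bmi} BMI +
#'       \beta_{int} a (BMI - 25) + \beta_{age} age}
#' where \eqn{a} is the true number of European-ancestry copies at the causal
#' marker and BMI is centered at 25 kg/m2 inside the product term only.
#'
#' Default covariate moments mirror an obesity-enriched adult case-control
#' population (BMI mean 32.5, SD 8.7 kg/m2; age mean 41, SD 13 years), with
#' BMI truncated at 15 kg/m2 and age at 18 years.
#'
#' @slot beta0 intercept, log-odds.
#' @slot betaLa per-European-copy log-OR at the causal marker.
#' @slot betaBmi per-kg/m2 log-OR.
#' @slot betaInt log-OR of the local-ancestry-by-BMI product term.
#' @slot betaAge per-year log-OR.
#' @slot causalMarker marker_id of the causal locus ("" for none).
#' @slot bmiMean,bmiSd BMI moments, kg/m2.
#' @slot ageMean,ageSd age moments, years.
#' @slot nIndividuals cohort size.
#' @slot seed integer seed.
#' @aliases PhenotypeConfig-class
#' @exportClass PhenotypeConfig
setClass("PhenotypeConfig",
    representation(beta0 = "numeric", betaLa = "numeric", betaBmi = "numeric",
                   betaInt = "numeric", betaAge = "numeric",
                   causalMarker = "character",
                   bmiMean = "numeric", bmiSd = "numeric",
                   ageMean = "numeric", ageSd = "numeric",
                   nIndividuals = "integer", seed = "integer"),
    prototype(beta0 = -0.25, betaLa = log(0.74), betaBmi = 0.02,
              betaInt = log(0.95), betaAge = 0, causalMarker = "",
              bmiMean = 32.5, bmiSd = 8.7, ageMean = 41, ageSd = 13,
              nIndividuals = 1000L, seed = 1L))

setValidity("PhenotypeConfig", function(object) {
    msg <- NULL
    if (object@bmiSd <= 0) msg <- c(msg, "bmiSd must be > 0")
    if (object@ageSd <= 0) msg <- c(msg, "ageSd must be > 0")
    if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
    if (length(object@causalMarker) != 1L)
        msg <- c(msg, "causalMarker must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' @param beta0,betaLa,betaBmi,betaInt,betaAge,causalMarker see slots.
#' @param bmiMean,bmiSd,ageMean,ageSd,nIndividuals,seed see slots.
#' @return A \linkS4class{PhenotypeConfig}.
#' @rdname PhenotypeConfig-class
#' @export
PhenotypeConfig <- function(beta0 = -0.25, betaLa = log(0.74), betaBmi = 0.02,
                            betaInt = log(0.95), betaAge = 0,
                            causalMarker = "", bmiMean = 32.5, bmiSd = 8.7,
                            ageMean = 41, ageSd = 13, nIndividuals = 1000L,
                            seed = 1L) {
    new("PhenotypeConfig", beta0 = beta0, betaLa = betaLa, betaBmi = betaBmi,
        betaInt = betaInt, betaAge = betaAge,
        causalMarker = as.character(causalMarker),
        bmiMean = bmiMean, bmiSd = bmiSd, ageMean = ageMean, ageSd = ageSd,
        nIndividuals = as.integer(nIndividuals), seed = as.integer(seed))
}

#' Quality-control thresholds
#'
#' Array-style QC cutoffs. All comparisons are strict: entities strictly below
#' a call-rate or MAF cutoff, or with an HWE p-value strictly below the floor,
#' are removed; boundary values are retained.
#'
#' @slot minSampleCallRate minimum per-sample call rate (default 0.95).
#' @slot minSnpCallRate minimum per-marker call rate (default 0.95).
#' @slot minMaf minimum minor allele frequency (default 0.01).
#' @slot hwePMin Hardy-Weinberg p-value floor (default 1e-6).
#' @slot hweInControlsOnly compute HWE in controls only (default TRUE).
#' @aliases QcThresholds-class
#' @exportClass QcThresholds
setClass("QcThresholds",
    representation(minSampleCallRate = "numeric", minSnpCallRate = "numeric",
                   minMaf = "numeric", hwePMin = "numeric",
                   hweInControlsOnly = "logical"),
    prototype(minSampleCallRate = 0.95, minSnpCallRate = 0.95, minMaf = 0.01,
              hwePMin = 1e-6, hweInControlsOnly = TRUE))

setValidity("QcThresholds", function(object) {
    msg <- NULL
    for (s in c("minSampleCallRate", "minSnpCallRate", "minMaf")) {
        v <- slot(object, s)
        if (v <= 0 || v > 1) msg <- c(msg, sprintf("%s must be in (0, 1]", s))
    }
    if (object@hwePMin <= 0 || object@hwePMin >= 1)
        msg <- c(msg, "hwePMin must be in (0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' @param minSampleCallRate,minSnpCallRate,minMaf,hwePMin,hweInControlsOnly see slots.
#' @return A \linkS4class{QcThresholds}.
#' @rdname QcThresholds-class
#' @export
QcThresholds <- function(minSampleCallRate = 0.95, minSnpCallRate = 0.95,
                         minMaf = 0.01, hwePMin = 1e-6,
                         hweInControlsOnly = TRUE) {
    new("QcThresholds", minSampleCallRate = minSampleCallRate,
        minSnpCallRate = minSnpCallRate, minMaf = minMaf, hwePMin = hwePMin,
        hweInControlsOnly = hweInControlsOnly)
}

#' Min-p permutation configuration
#'
#' @slot nPerm number of permutation iterations (default 1000; increase to
#'   10000 for production thresholds).
#' @slot alpha tail level of the min-p distribution (default 0.05).
#' @slot suggestiveAlpha p-value level flagged for follow-up (default 5e-4).
#' @slot seed integer seed.
#' @aliases PermutationConfig-class
#' @exportClass PermutationConfig
setClass("PermutationConfig",
    representation(nPerm = "integer", alpha = "numeric",
                   suggestiveAlpha = "numeric", seed = "integer"),
    prototype(nPerm = 1000L, alpha = 0.05, suggestiveAlpha = 5e-4, seed = 1L))

setValidity("PermutationConfig", function(object) {
    msg <- NULL
    if (object@nPerm < 100L)
        msg <- c(msg, "nPerm must be >= 100 for any threshold estimate")
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must be in (0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' @param nPerm,alpha,suggestiveAlpha,seed see slots.
#' @return A \linkS4class{PermutationConfig}.
#' @rdname PermutationConfig-class
#' @export
PermutationConfig <- function(nPerm = 1000L, alpha = 0.05,
                              suggestiveAlpha = 5e-4, seed = 1L) {
    new("PermutationConfig", nPerm = as.integer(nPerm), alpha = alpha,
        suggestiveAlpha = suggestiveAlpha, seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## AdmixCohort
## ---------------------------------------------------------------------------

#' Admixed case-control cohort
#'
#' A \linkS4class{SummarizedExperiment} with markers as rows and individuals
#' as columns. Assay \code{"genotypes"} holds 0/1/2 alternate-allele copies
#' (NA = missing); simulated cohorts additionally carry assay
#' \code{"trueLocalAncestry"} with the true number of European-ancestry copies.
#' \code{rowData} holds the ancestral panel columns; \code{colData} holds
#' \code{case} (0/1), \code{age} (years) and \code{bmi} (kg/m2).
#'
#' @aliases AdmixCohort-class
#' @exportClass AdmixCohort
setClass("AdmixCohort", contains = "SummarizedExperiment")

setValidity("AdmixCohort", function(object) {
    msg <- NULL
    if (!"genotypes" %in% SummarizedExperiment::assayNames(object))
        return("assay 'genotypes' is required")
    g <- SummarizedExperiment::assay(object, "genotypes")
    if (!all(g %in% c(0, 1, 2) | is.na(g)))
        msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
    if ("trueLocalAncestry" %in% SummarizedExperiment::assayNames(object)) {
        a <- SummarizedExperiment::assay(object, "trueLocalAncestry")
        if (anyNA(a) || !all(a %in% c(0, 1, 2)))
            msg <- c(msg, "trueLocalAncestry must be 0, 1 or 2")
    }
    cd <- SummarizedExperiment::colData(object)
    miss <- setdiff(c("case", "age", "bmi"), colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("missing colData column(s):",
                            paste(miss, collapse = ", ")))
    else if (!all(cd$case %in% c(0, 1)))
        msg <- c(msg, "case must be 0/1")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "individual ids (colnames) must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct an AdmixCohort
#'
#' @param genotypes markers-by-individuals matrix of 0/1/2 alt-allele copies
#'   (NA = missing); rownames are marker ids, colnames individual ids.
#' @param panel an \linkS4class{AncestralPanel} whose markers match the
#'   genotype rows.
#' @param covariates data.frame with columns \code{individual_id}, \code{case},
#'   \code{age}, \code{bmi} (one row per genotype column).
#' @param trueLocalAncestry optional matched matrix of true European-copy
#'   counts (simulation truth).
#' @return An \linkS4class{AdmixCohort}.
#' @export
AdmixCohort <- function(genotypes, panel, covariates, trueLocalAncestry = NULL) {
    stopifnot(is(panel, "AncestralPanel"),
              nrow(genotypes) == nrow(panel))
    if (is.null(rownames(genotypes)))
        rownames(genotypes) <- panel$marker_id
    stopifnot(identical(rownames(genotypes), panel$marker_id))
    ord <- match(colnames(genotypes), covariates$individual_id)
    if (anyNA(ord))
        stop("covariates missing for individual(s): ",
             paste(utils::head(colnames(genotypes)[is.na(ord)]), collapse = ", "))
    covariates <- covariates[ord, , drop = FALSE]
    cd <- S4Vectors::DataFrame(covariates[setdiff(colnames(covariates),
                                                  "individual_id")],
                               row.names = covariates$individual_id)
    assays <- list(genotypes = genotypes)
    if (!is.null(trueLocalAncestry)) {
        dimnames(trueLocalAncestry) <- dimnames(genotypes)
        assays$trueLocalAncestry <- trueLocalAncestry
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, rowData = as(panel, "DFrame"), colData = cd)
    new("AdmixCohort", se)
}

## ---------------------------------------------------------------------------
## LocalAncestryResult
## ---------------------------------------------------------------------------

#' Inferred local ancestry
#'
#' A \linkS4class{SummarizedExperiment} (markers x individuals) with assay
#' \code{"calls"} holding posterior-mode European-copy counts (0/1/2) and
#' assays \code{"p0"}, \code{"p1"}, \code{"p2"} holding the per-state
#' posterior probabilities from the forward-backward pass.
#'
#' @aliases LocalAncestryResult-class
#' @exportClass LocalAncestryResult
setClass("LocalAncestryResult", contains = "SummarizedExperiment")

setValidity("LocalAncestryResult", function(object) {
    an <- SummarizedExperiment::assayNames(object)
    miss <- setdiff(c("calls", "p0", "p1", "p2"), an)
    if (length(miss))
        return(paste("missing assay(s):", paste(miss, collapse = ", ")))
    cl <- SummarizedExperiment::assay(object, "calls")
    if (!all(cl %in% c(0, 1, 2)))
        return("calls must be 0, 1 or 2")
    tot <- SummarizedExperiment::assay(object, "p0") +
           SummarizedExperiment::assay(object, "p1") +
           SummarizedExperiment::assay(object, "p2")
    if (max(abs(tot - 1)) > 1e-6)
        return("posterior probabilities must sum to 1 at every marker")
    TRUE
})
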