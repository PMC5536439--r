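#' @include AllClasses.R
NULL

#' Accessors for cohort and ancestry objects
#'
#' \code{genotypes} returns the markers-by-individuals 0/1/2 genotype matrix;
#' \code{trueLocalAncestry} the simulation-truth European-copy matrix (or NULL);
#' \code{covariates} the per-individual phenotype/covariate table;
#' \code{panelData} the per-marker ancestral-panel table;
#' \code{ancestryCalls} the inferred 0/1/2 European-copy calls;
#' \code{ancestryPosteriors} the three posterior-probability matrices.
#'
#' @param x an \linkS4class{AdmixCohort} or \linkS4class{LocalAncestryResult}.
#' @return See description; matrices are markers x individuals.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setMethod("genotypes", "AdmixCohort", function(x)
    SummarizedExperiment::assay(x, "genotypes"))

#' @rdname accessors
#' @export
setGeneric("trueLocalAncestry", function(x) standardGeneric("trueLocalAncestry"))

#' @rdname accessors
#' @export
setMethod("trueLocalAncestry", "AdmixCohort", function(x) {
    if ("trueLocalAncestry" %in% SummarizedExperiment::assayNames(x))
        SummarizedExperiment::assay(x, "trueLocalAncestry")
    else NULL
})

#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname accessors
#' @export
setMethod("covariates", "AdmixCohort", function(x) {
    cd <- SummarizedExperiment::colData(x)
    out <- data.frame(individual_id = rownames(cd),
                      as.data.frame(cd), row.names = NULL,
                      stringsAsFactors = FALSE)
    out
})

#' @rdname accessors
#' @export
setGeneric("panelData", function(x) standardGeneric("panelData"))

#' @rdname accessors
#' @export
setMethod("panelData", "AdmixCohort", function(x) {
    df <- SummarizedExperiment::rowData(x)
    new("AncestralPanel", as(df, "DFrame"))
})

#' @rdname accessors
#' @export
setMethod("panelData", "LocalAncestryResult", function(x) {
    df <- SummarizedExperiment::rowData(x)
    new("AncestralPanel", as(df, "DFrame"))
})

#' @rdname accessors
#' @export
setGeneric("ancestryCalls", function(x) standardGeneric("ancestryCalls"))

#' @rdname accessors
#' @export
setMethod("ancestryCalls", "LocalAncestryResult", function(x)
    SummarizedExperiment::assay(x, "calls"))

#' @rdname accessors
#' @export
setGeneric("ancestryPosteriors", function(x) standardGeneric("ancestryPosteriors"))

#' @rdname accessors
#' @export
setMethod("ancestryPosteriors", "LocalAncestryResult", function(x)
    list(p0 = SummarizedExperiment::assay(x, "p0"),
         p1 = SummarizedExperiment::assay(x, "p1"),
         p2 = SummarizedExperiment::assay(x, "p2")))

#' Global ancestry proportions
#'
#' Per-individual European ancestry proportion
#' \eqn{\theta_i = \sum_m c_{im} / (2M)} from 0/1/2 European-copy calls.
#' The divisor 2M puts \eqn{\theta} on the proportion scale in [0, 1].
#'
#' @param x a \linkS4class{LocalAncestryResult} or a 0/1/2 call matrix
#'   (markers x individuals).
#' @return Named numeric vector of per-individual ancestry proportions.
#' @examples
#' calls <- matrix(c(2, 1, 0, 1), nrow = 4)  # one individual, four markers
#' globalAncestry(calls)  # 4/8 = 0.5
#' @export
setGeneric("globalAncestry", function(x) standardGeneric("globalAncestry"))

#' @rdname globalAncestry
#' @export
setMethod("globalAncestry", "LocalAncestryResult", function(x)
    globalAncestry(SummarizedExperiment::assay(x, "calls")))

#' @rdname globalAncestry
#' @export
setMethod("globalAncestry", "matrix", function(x) {
    if (nrow(x) == 0L) stop("global ancestry undefined with zero markers")
    colSums(x) / (2 * nrow(x))
})

setMethod("show", "AdmixCohort", function(object) {
    cat(sprintf("AdmixCohort: %d markers x %d individuals\n",
                nrow(object), ncol(object)))
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("  cases: %d / controls: %d\n",
                sum(cd$case == 1), sum(cd$case == 0)))
    g <- SummarizedExperiment::assay(object, "genotypes")
    cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(g))))
    cat(sprintf("  truth available: %s\n",
                "trueLocalAncestry" %in% SummarizedExperiment::assayNames(object)))
    invisible(NULL)
})

setMethod("show", "LocalAncestryResult", function(object) {
    cat(sprintf("LocalAncestryResult: %d markers x %d individuals\n",
                nrow(object), ncol(object)))
    th <- globalAncestry(object)
    cat(sprintf("  mean global European ancestry: %.3f\n", mean(th)))
    invisible(NULL)
})

setMethod("show", "AdmixtureConfig", function(object) {
    cat(sprintf(paste0("AdmixtureConfig: lambdaEur=%.3g (SD %.3g), ",
                       "generations=%d, recombRate=%.3g, seed=%d\n"),
                object@lambdaEur, object@lambdaSd, object@generations,
                object@recombRate, object@seed))
    invisible(NULL)
})

setMethod("show", "PhenotypeConfig", function(object) {
    cat(sprintf("PhenotypeConfig: n=%d, causal marker '%s', seed=%d\n",
                object@nIndividuals, object@causalMarker, object@seed))
    cat(sprintf("  beta0=%.3g betaLa=%.3g betaBmi=%.3g betaInt=%.3g betaAge=%.3g\n",
                object@beta0, object@betaLa, object@betaBmi, object@betaInt,
                object@betaAge))
    cat(sprintf("  BMI ~ N(%.1f, %.1f) >= 15; age ~ N(%.1f, %.1f) >= 18\n",
                object@bmiMean, object@bmiSd, object@ageMean, object@ageSd))
    invisible(NULL)
})
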