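#' @include AllClasses.R
NULL

.writeTsv <- function(d, path) {
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
}

.readTsv <- function(path, required = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    miss <- setdiff(required, colnames(d))
    if (length(miss))
        stop("file ", path, " is missing required column(s): ",
             paste(miss, collapse = ", "))
    d
}

#' Read and write ancestral panels
#'
#' Panel TSVs have columns marker_id, chrom, pos, ref, alt, freq_afr,
#' freq_eur.
#'
#' @param path file path.
#' @return \code{readPanel}: an \linkS4class{AncestralPanel}.
#' @export
readPanel <- function(path) {
    d <- .readTsv(path, c("marker_id", "chrom", "pos", "ref", "alt",
                          "freq_afr", "freq_eur"))
    AncestralPanel(d$marker_id, d$chrom, d$pos, d$ref, d$alt,
                   d$freq_afr, d$freq_eur)
}

#' @param panel an \linkS4class{AncestralPanel}.
#' @rdname readPanel
#' @export
writePanel <- function(panel, path) {
    .writeTsv(as.data.frame(panel), path)
    invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Requires columns individual_id, case, age, bmi; duplicate ids are
#' rejected.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readCovariates <- function(path) {
    d <- .readTsv(path, c("individual_id", "case", "age", "bmi"))
    if (anyDuplicated(d$individual_id))
        stop("duplicate individual_id values in ", path)
    if (!all(d$case %in% c(0, 1)))
        stop("case must be 0/1 in ", path)
    d
}

#' Read a diploid genotype VCF
#'
#' Parses a VCF 4.2 with GT fields into a markers x individuals matrix of
#' alternate-allele copy counts. Unphased and phased separators are treated
#' identically; \code{./.} becomes NA. Multi-allelic records and non-diploid
#' genotypes are rejected with record context.
#'
#' @param path VCF path (plain or gzipped).
#' @return List: \code{genotypes} integer matrix, \code{variants} data.frame
#'   (chrom, pos, marker_id, ref, alt).
#' @export
readGenotypeVcf <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT, fixed = TRUE)
    if (any(multi))
        stop("multi-allelic record(s) not supported, e.g. ",
             fix$CHROM[multi][1L], ":", fix$POS[multi][1L])
    gt <- vcfR::extract.gt(v, element = "GT")
    u <- unique(as.vector(gt))
    u <- u[!is.na(u)]
    alleles <- strsplit(u, "[/|]")
    bad <- lengths(alleles) != 2L |
        !vapply(alleles, function(a) all(a %in% c("0", "1", ".")),
                logical(1))
    if (any(bad))
        stop("malformed or non-diploid GT value(s): ",
             paste(u[bad], collapse = ", "))
    map <- vapply(alleles, function(a) {
        if (any(a == ".")) NA_integer_ else sum(a == "1")
    }, integer(1))
    names(map) <- u
    geno <- matrix(map[as.vector(gt)], nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
    list(genotypes = geno,
         variants = data.frame(chrom = fix$CHROM,
                               pos = as.integer(fix$POS),
                               marker_id = fix$ID, ref = fix$REF,
                               alt = fix$ALT, stringsAsFactors = FALSE))
}

#' Write genotypes as VCF 4.2
#'
#' Emits diploid unphased GT records (\code{0/0}, \code{0/1}, \code{1/1},
#' \code{./.}) for a markers x individuals 0/1/2 matrix.
#'
#' @param genotypes markers x individuals matrix (NA = missing).
#' @param panel matching \linkS4class{AncestralPanel} (chrom/pos/ref/alt).
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeGenotypeVcf <- function(genotypes, panel, path) {
    stopifnot(nrow(genotypes) == nrow(panel))
    gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix(gtmap[as.character(genotypes)], nrow(genotypes),
                 ncol(genotypes))
    gt[is.na(gt)] <- "./."
    header <- c("##fileformat=VCFv4.2",
                "##source=admixscan",
                paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                       "Description=\"Genotype\">"),
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", colnames(genotypes)),
                      collapse = "\t"))
    body <- paste(panel$chrom, panel$pos, panel$marker_id, panel$ref,
                  panel$alt, ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Write a cohort to disk
#'
#' Writes \code{genotypes.vcf}, \code{covariates.tsv}, \code{panel.tsv} and,
#' when simulation truth is present, \code{truth.tsv} (long format:
#' individual_id, marker_id, true_la) into \code{dir}.
#'
#' @param cohort an \linkS4class{AdmixCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    panel <- panelData(cohort)
    writeGenotypeVcf(genotypes(cohort), panel,
                     file.path(dir, "genotypes.vcf"))
    .writeTsv(covariates(cohort), file.path(dir, "covariates.tsv"))
    writePanel(panel, file.path(dir, "panel.tsv"))
    la <- trueLocalAncestry(cohort)
    if (!is.null(la)) {
        long <- data.frame(
            individual_id = rep(colnames(la), each = nrow(la)),
            marker_id = rep(rownames(la), times = ncol(la)),
            true_la = as.vector(la), stringsAsFactors = FALSE)
        .writeTsv(long, file.path(dir, "truth.tsv"))
    }
    invisible(dir)
}

#' Read a cohort from disk
#'
#' Inverse of \code{\link{writeCohort}}: joins the VCF, covariate TSV and
#' panel TSV (and truth TSV when present) back into an
#' \linkS4class{AdmixCohort}. Covariate rows are aligned to VCF sample
#' columns by individual_id; unmatched ids are dropped with a message.
#'
#' @param dir directory written by \code{\link{writeCohort}}.
#' @return An \linkS4class{AdmixCohort}.
#' @export
readCohort <- function(dir) {
    vcf <- readGenotypeVcf(file.path(dir, "genotypes.vcf"))
    panel <- readPanel(file.path(dir, "panel.tsv"))
    stopifnot(identical(vcf$variants$marker_id, panel$marker_id))
    cov <- readCovariates(file.path(dir, "covariates.tsv"))
    ids <- colnames(vcf$genotypes)
    unmatched <- setdiff(ids, cov$individual_id)
    if (length(unmatched)) {
        message("dropping ", length(unmatched),
                " individual(s) without covariates")
        ids <- setdiff(ids, unmatched)
    }
    geno <- vcf$genotypes[, ids, drop = FALSE]
    cov <- cov[match(ids, cov$individual_id), , drop = FALSE]
    truthPath <- file.path(dir, "truth.tsv")
    la <- NULL
    if (file.exists(truthPath)) {
        tl <- .readTsv(truthPath, c("individual_id", "marker_id", "true_la"))
        la <- matrix(NA_integer_, nrow(geno), length(ids),
                     dimnames = list(rownames(geno), ids))
        la[cbind(match(tl$marker_id, rownames(la)),
                 match(tl$individual_id, ids))] <- tl$true_la
    }
    AdmixCohort(geno, panel, cov, trueLocalAncestry = la)
}

#' Write and read inferred local ancestry
#'
#' Long-format TSV with columns individual_id, marker_id, call, p0, p1, p2.
#'
#' @param lar a \linkS4class{LocalAncestryResult}.
#' @param path file path.
#' @return \code{writeLocalAncestry}: the path; \code{readLocalAncestry}:
#'   a list of matrices \code{calls}, \code{p0}, \code{p1}, \code{p2}.
#' @export
writeLocalAncestry <- function(lar, path) {
    calls <- ancestryCalls(lar)
    po <- ancestryPosteriors(lar)
    long <- data.frame(
        individual_id = rep(colnames(calls), each = nrow(calls)),
        marker_id = rep(rownames(calls), times = ncol(calls)),
        call = as.vector(calls),
        p0 = as.vector(po$p0), p1 = as.vector(po$p1), p2 = as.vector(po$p2),
        stringsAsFactors = FALSE)
    .writeTsv(long, path)
    invisible(path)
}

#' @rdname writeLocalAncestry
#' @export
readLocalAncestry <- function(path) {
    d <- .readTsv(path, c("individual_id", "marker_id", "call",
                          "p0", "p1", "p2"))
    ids <- unique(d$individual_id)
    mk <- unique(d$marker_id)
    shape <- function(v) {
        m <- matrix(NA_real_, length(mk), length(ids),
                    dimnames = list(mk, ids))
        m[cbind(match(d$marker_id, mk), match(d$individual_id, ids))] <- v
        m
    }
    list(calls = shape(d$call), p0 = shape(d$p0), p1 = shape(d$p1),
         p2 = shape(d$p2))
}
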