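#' @include AllClasses.R io.R
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.PIPELINE_KEYS <- c("out_dir", "panel", "admixture", "datasets", "qc",
                    "ancestry", "permutation")

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full admixture-mapping workflow
#'
#' Executes the stages simulate -> qc -> ancestry (AIM selection, LD pruning,
#' HMM local ancestry, global ancestry, PCs) -> interaction scan per dataset
#' -> fixed-effects meta-analysis -> min-p permutation threshold, writing all
#' artifacts under \code{out_dir}. The configuration (YAML path or list)
#' fully determines every output: all randomness flows from the seeds it
#' names, and the resolved configuration plus its MD5 hash are persisted
#' alongside the results.
#'
#' Configuration keys (unknown keys are rejected): \code{out_dir};
#' \code{panel} (n_markers, n_chrom, min_delta, spacing_mean_bp, seed);
#' \code{admixture} (lambda_eur, generations, recomb_rate, seed);
#' \code{datasets} -- a list, each with name, n_individuals, seed and
#' optional outcome-model fields (beta0, beta_la, beta_bmi, beta_int,
#' beta_age, causal_marker, bmi_mean, bmi_sd, age_mean, age_sd,
#' missing_rate); \code{qc} (min_sample_call_rate, min_snp_call_rate,
#' min_maf, hwe_p_min); \code{ancestry} (delta_min, r2_max, k_pcs);
#' \code{permutation} (n_perm, alpha, seed; omit to skip the stage).
#'
#' @param config YAML file path or equivalent named list.
#' @param outDir optional override of \code{out_dir}.
#' @return Invisibly, a list with the per-dataset scan tables, the meta
#'   table, the permutation threshold (or NULL) and the output directory.
#' @export
runPipeline <- function(config, outDir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    unknown <- setdiff(names(config), .PIPELINE_KEYS)
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    outDir <- outDir %||% config$out_dir %||% stop("out_dir is required")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfgPath <- file.path(outDir, "config.yaml")
    yaml::write_yaml(config, cfgPath)
    cfgHash <- unname(tools::md5sum(cfgPath))
    logPath <- file.path(outDir, "pipeline.log")
    logMsg <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                                "\n", sep = "", file = logPath, append = TRUE)
    cat("", file = logPath)
    logMsg("config hash ", cfgHash)

    pc <- config$panel %||% list()
    panel <- .stage("panel", simulatePanel(
        nMarkers = pc$n_markers %||% 300L, nChrom = pc$n_chrom %||% 10L,
        spacingMeanBp = pc$spacing_mean_bp %||% 1e6,
        minDelta = pc$min_delta %||% 0, seed = pc$seed %||% 1L))
    writePanel(panel, file.path(outDir, "panel.tsv"))
    logMsg("panel: ", nrow(panel), " markers, seed ", pc$seed %||% 1L)

    ac <- config$admixture %||% list()
    admixCfg <- AdmixtureConfig(
        lambdaEur = ac$lambda_eur %||% 0.2,
        generations = ac$generations %||% 7L,
        recombRate = ac$recomb_rate %||% 1e-8, seed = ac$seed %||% 1L)

    qcc <- config$qc %||% list()
    thr <- QcThresholds(
        minSampleCallRate = qcc$min_sample_call_rate %||% 0.95,
        minSnpCallRate = qcc$min_snp_call_rate %||% 0.95,
        minMaf = qcc$min_maf %||% 0.01, hwePMin = qcc$hwe_p_min %||% 1e-6)

    anc <- config$ancestry %||% list()
    deltaMin <- anc$delta_min %||% 0.2
    r2Max <- anc$r2_max %||% 0.1
    kPcs <- anc$k_pcs %||% 10L

    dsCfgs <- config$datasets %||% stop("datasets are required")
    cohorts <- list()
    for (i in seq_along(dsCfgs)) {
        d <- dsCfgs[[i]]
        nm <- d$name %||% paste0("dataset", i)
        pcfg <- PhenotypeConfig(
            beta0 = d$beta0 %||% -0.25, betaLa = d$beta_la %||% log(0.74),
            betaBmi = d$beta_bmi %||% 0.02,
            betaInt = d$beta_int %||% log(0.95),
            betaAge = d$beta_age %||% 0,
            causalMarker = d$causal_marker %||% "",
            bmiMean = d$bmi_mean %||% 32.5, bmiSd = d$bmi_sd %||% 8.7,
            ageMean = d$age_mean %||% 41, ageSd = d$age_sd %||% 13,
            nIndividuals = d$n_individuals %||% 500L,
            seed = d$seed %||% i)
        aCfg <- admixCfg
        aCfg@seed <- as.integer((ac$seed %||% 1L) + i)
        dsDir <- file.path(outDir, nm)
        cohorts[[nm]] <- .stage(paste0("simulate:", nm), simulateCohort(
            panel, aCfg, pcfg, missingRate = d$missing_rate %||% 0,
            dir = dsDir))
        logMsg("simulated ", nm, ": n=", pcfg@nIndividuals,
               " seeds=(", aCfg@seed, ",", pcfg@seed, ")")
    }

    qcd <- lapply(names(cohorts), function(nm) {
        res <- .stage(paste0("qc:", nm), runQc(cohorts[[nm]], thr))
        .writeTsv(res$report, file.path(outDir, nm, "qc_report.tsv"))
        logMsg("qc ", nm, ": ", nrow(res$cohort), " markers, ",
               ncol(res$cohort), " individuals retained")
        res$cohort
    })
    names(qcd) <- names(cohorts)

    ## common post-QC marker set, AIM-filtered on the panel
    aims <- selectAims(panel, deltaMin)
    common <- Reduce(intersect, lapply(qcd, rownames))
    common <- intersect(common, aims$marker_id)
    if (!length(common)) stop("no common AIMs survive QC")
    qcd <- lapply(qcd, function(co) co[common, ])
    keep <- .stage("ld_prune",
                   ldPrune(genotypes(qcd[[1L]]), r2Max = r2Max))
    qcd <- lapply(qcd, function(co) co[keep, ])
    logMsg("ancestry marker set: ", sum(keep), " AIMs after pruning")

    datasets <- list(); scans <- list()
    for (nm in names(qcd)) {
        co <- qcd[[nm]]
        lar <- .stage(paste0("ancestry:", nm),
                      inferLocalAncestry(co, config = admixCfg))
        writeLocalAncestry(lar, file.path(outDir, nm, "local_ancestry.tsv"))
        theta <- globalAncestry(lar)
        .writeTsv(data.frame(individual_id = names(theta), theta = theta),
                  file.path(outDir, nm, "global_ancestry.tsv"))
        pcs <- .stage(paste0("pca:", nm), computePCs(genotypes(co), kPcs))
        .writeTsv(data.frame(individual_id = rownames(pcs), pcs),
                  file.path(outDir, nm, "pcs.tsv"))
        cd <- covariates(co)
        scan <- .stage(paste0("scan:", nm), interactionScan(
            lar, cd$bmi, cd$age, pcs, cd$case))
        .writeTsv(scan, file.path(outDir, nm, "interaction_scan.tsv"))
        scans[[nm]] <- scan
        datasets[[nm]] <- list(la = lar, bmi = cd$bmi, age = cd$age,
                               pcs = pcs, outcome = cd$case)
        logMsg("scan ", nm, ": ", sum(scan$converged), "/", nrow(scan),
               " markers testable")
    }

    meta <- .stage("meta", metaScan(scans))
    .writeTsv(meta, file.path(outDir, "meta_scan.tsv"))

    threshold <- NULL
    if (!is.null(config$permutation)) {
        pp <- config$permutation
        permCfg <- PermutationConfig(nPerm = pp$n_perm %||% 1000L,
                                     alpha = pp$alpha %||% 0.05,
                                     seed = pp$seed %||% 1L)
        threshold <- .stage("permute",
                            minpPermutationThreshold(datasets, permCfg))
        jsonlite::write_json(
            list(threshold = threshold$threshold, alpha = threshold$alpha,
                 n_perm = threshold$nPerm, seed = threshold$seed,
                 config_hash = cfgHash, minp = threshold$minp),
            file.path(outDir, "threshold.json"), auto_unbox = TRUE,
            digits = NA)
        logMsg("permutation threshold: ", signif(threshold$threshold, 3))
    }
    logMsg("done")
    invisible(list(scans = scans, meta = meta, threshold = threshold,
                   outDir = outDir))
}
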