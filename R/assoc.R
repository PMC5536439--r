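#' @include AllClasses.R
NULL

.Z95 <- 1.959964
.SEPARATION_BOUND <- 15

#' Fit a logistic regression by IRLS
#'
#' Thin wrapper around \code{stats::glm.fit} (iteratively reweighted least
#' squares) adding the bookkeeping the scan functions need: Wald statistics
#' from the inverse observed information, aliased-column reporting under rank
#' deficiency, and a separation guard that flags fits with any
#' |coefficient| > 15 on the logit scale as non-converged.
#'
#' @param x design matrix (including the intercept column).
#' @param y 0/1 outcome; both classes must be present.
#' @param tol IRLS convergence tolerance (default 1e-8).
#' @param maxIter maximum IRLS iterations (default 50).
#' @return List: \code{coefficients} data.frame (term, beta, se, z, p),
#'   \code{converged}, \code{aliased} (dropped column names), \code{logLik},
#'   \code{n}, \code{rank}.
#' @export
fitLogistic <- function(x, y, tol = 1e-8, maxIter = 50L) {
    if (length(unique(y)) < 2L)
        stop("outcome must contain both classes")
    if (is.null(colnames(x)))
        colnames(x) <- paste0("x", seq_len(ncol(x)))
    fit <- suppressWarnings(stats::glm.fit(
        x, y, family = stats::binomial(),
        control = stats::glm.control(epsilon = tol, maxit = maxIter)))
    beta <- fit$coefficients
    aliased <- names(beta)[is.na(beta)]
    r <- fit$rank
    Rm <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
    Rm[lower.tri(Rm)] <- 0
    cov <- chol2inv(Rm)
    se <- rep(NA_real_, length(beta))
    se[fit$qr$pivot[seq_len(r)]] <- sqrt(diag(cov))
    z <- beta / se
    p <- 2 * stats::pnorm(-abs(z))
    converged <- isTRUE(fit$converged) &&
        all(abs(beta[!is.na(beta)]) <= .SEPARATION_BOUND)
    list(coefficients = data.frame(term = names(beta), beta = beta, se = se,
                                   z = z, p = p, row.names = NULL,
                                   stringsAsFactors = FALSE),
         converged = converged, aliased = aliased,
         logLik = -fit$deviance / 2, n = length(y), rank = r)
}

## one tidy result row for a named term of a fitLogistic() result
.termRow <- function(fit, term, marker = NA_character_,
                     stratum = NA_character_) {
    co <- fit$coefficients
    i <- match(term, co$term)
    beta <- co$beta[i]; se <- co$se[i]
    ok <- fit$converged && !is.na(beta) && !is.na(se)
    reason <- if (!fit$converged) "nonconverged"
              else if (term %in% fit$aliased || is.na(beta)) "aliased"
              else ""
    if (!ok) beta <- se <- NA_real_
    data.frame(marker_id = marker, term = term, stratum = stratum,
               beta = beta, se = se, z = beta / se,
               p = 2 * stats::pnorm(-abs(beta / se)),
               or = exp(beta), ci_low = exp(beta - .Z95 * se),
               ci_high = exp(beta + .Z95 * se),
               n = fit$n, converged = fit$converged, reason = reason,
               row.names = NULL, stringsAsFactors = FALSE)
}

.untestableRow <- function(marker, term, stratum = NA_character_, n = NA_real_,
                           reason = "untestable") {
    data.frame(marker_id = marker, term = term, stratum = stratum,
               beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
               or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n = n,
               converged = FALSE, reason = reason, row.names = NULL,
               stringsAsFactors = FALSE)
}

.laMatrix <- function(la) {
    if (is(la, "LocalAncestryResult")) ancestryCalls(la) else la
}

#' BMI categories
#'
#' Left-closed categorization: 3-level 0 = [0, 25), 1 = [25, 30),
#' 2 = [30, Inf); 4-level splits the top category at 35 kg/m2.
#'
#' @param bmi numeric vector, kg/m2.
#' @param nLevels 3 (default) or 4.
#' @return Integer category codes starting at 0.
#' @export
bmiCategory <- function(bmi, nLevels = 3L) {
    br <- if (nLevels == 3L) c(-Inf, 25, 30, Inf)
          else if (nLevels == 4L) c(-Inf, 25, 30, 35, Inf)
          else stop("nLevels must be 3 or 4")
    as.integer(cut(bmi, breaks = br, right = FALSE)) - 1L
}

## core interaction scan: one glm per marker, columns 2/4 of a preallocated
## design updated in place (hot loop of the permutation threshold)
.interactionScanCore <- function(laT, bmi, covar, y) {
    n <- length(y); M <- ncol(laT)
    X <- cbind(`(Intercept)` = rep(1, n), la = 0, bmi = bmi, laxbmi = 0, covar)
    beta <- se <- rep(NA_real_, M)
    ok <- logical(M)
    for (m in seq_len(M)) {
        lav <- laT[, m]
        if (stats::var(lav) == 0) next
        X[, 2L] <- lav
        X[, 4L] <- lav * bmi
        fit <- suppressWarnings(stats::glm.fit(
            X, y, family = stats::binomial(),
            control = stats::glm.control(epsilon = 1e-8, maxit = 50L)))
        b <- fit$coefficients
        if (is.na(b[4L]) || !fit$converged ||
            any(abs(b[!is.na(b)]) > .SEPARATION_BOUND)) next
        r <- fit$rank
        Rm <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
        Rm[lower.tri(Rm)] <- 0
        v <- rep(NA_real_, length(b))
        v[fit$qr$pivot[seq_len(r)]] <- diag(chol2inv(Rm))
        beta[m] <- b[4L]; se[m] <- sqrt(v[4L]); ok[m] <- TRUE
    }
    list(beta = beta, se = se, ok = ok)
}

#' Genome-wide local-ancestry x BMI interaction scan
#'
#' Per marker, fits \code{logit(Y) ~ LA + BMI + LA x BMI + age + PCs} and
#' reports the Wald test of the product term. Markers with zero
#' local-ancestry variance are flagged untestable; non-converged or separated
#' fits carry a reason code and an NA p-value (both are excluded from min-p
#' permutation minima).
#'
#' @param la a \linkS4class{LocalAncestryResult} or markers x individuals
#'   0/1/2 matrix of European-copy calls.
#' @param bmi,age per-individual covariates.
#' @param pcs individuals x k principal-component score matrix (may be NULL).
#' @param outcome 0/1 case status.
#' @return data.frame, one row per marker, with beta/se/z/p/or/ci/n/reason.
#' @export
interactionScan <- function(la, bmi, age, pcs, outcome) {
    laM <- .laMatrix(la)
    n <- length(outcome)
    stopifnot(ncol(laM) == n, length(bmi) == n, length(age) == n,
              is.null(pcs) || nrow(pcs) == n)
    covar <- cbind(age = age, pcs)
    res <- .interactionScanCore(t(laM), bmi, covar, outcome)
    out <- data.frame(marker_id = rownames(laM), term = "laxbmi",
                      stratum = NA_character_,
                      beta = res$beta, se = res$se,
                      z = res$beta / res$se,
                      p = 2 * stats::pnorm(-abs(res$beta / res$se)),
                      or = exp(res$beta),
                      ci_low = exp(res$beta - .Z95 * res$se),
                      ci_high = exp(res$beta + .Z95 * res$se),
                      n = n, converged = res$ok,
                      reason = ifelse(res$ok, "", "untestable"),
                      row.names = NULL, stringsAsFactors = FALSE)
    out
}

#' BMI-stratified local-ancestry scan
#'
#' Within each 3-level BMI category, fits \code{logit(Y) ~ LA + age + PCs}
#' per marker and reports the local-ancestry main effect. A stratum without
#' both outcome classes or with fewer than \code{minCases} cases yields
#' missing results with a reason code.
#'
#' @inheritParams interactionScan
#' @param minCases minimum cases per stratum (default 10).
#' @return data.frame with one row per marker per stratum (strata labelled
#'   \code{"<25"}, \code{"25-30"}, \code{">30"}).
#' @export
stratifiedScan <- function(la, outcome, age, pcs, bmi, minCases = 10L) {
    laM <- .laMatrix(la)
    n <- length(outcome)
    cat3 <- bmiCategory(bmi, 3L)
    labs <- c("<25", "25-30", ">30")
    out <- vector("list", 3L)
    for (s in 0:2) {
        sel <- cat3 == s
        lab <- labs[s + 1L]
        ys <- outcome[sel]
        if (sum(ys == 1) < minCases || sum(ys == 0) < 1L ||
            length(unique(ys)) < 2L) {
            out[[s + 1L]] <- do.call(rbind, lapply(
                rownames(laM), .untestableRow, term = "la", stratum = lab,
                n = sum(sel), reason = "stratum too small"))
            next
        }
        covar <- cbind(age = age[sel], pcs[sel, , drop = FALSE])
        rows <- vector("list", nrow(laM))
        for (m in seq_len(nrow(laM))) {
            lav <- laM[m, sel]
            if (stats::var(lav) == 0) {
                rows[[m]] <- .untestableRow(rownames(laM)[m], "la", lab,
                                            n = sum(sel))
                next
            }
            X <- cbind(`(Intercept)` = 1, la = lav, covar)
            fit <- fitLogistic(X, ys)
            rows[[m]] <- .termRow(fit, "la", rownames(laM)[m], lab)
        }
        out[[s + 1L]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
}

#' Race/group x BMI-category interaction by likelihood ratio test
#'
#' Fits a reduced model \code{logit(Y) ~ BMI categories + group + age} and a
#' full model adding the three group x category product terms (4-level BMI
#' categorization, lowest as reference), and compares them by a 3-df LRT.
#' Stratum-specific group odds ratios are read from full-model linear
#' combinations with delta-method standard errors. Empty group x category
#' cells drop the aliased term and reduce the df with a warning.
#'
#' @param outcome 0/1 outcome.
#' @param group binary group indicator (0/1).
#' @param bmi continuous BMI, categorized internally at 25/30/35 kg/m2.
#' @param age adjustment covariate.
#' @return List: \code{statistic}, \code{df}, \code{p}, and \code{strata}
#'   data.frame of per-category group log-ORs/ORs.
#' @export
categoricalInteractionLrt <- function(outcome, group, bmi, age) {
    stopifnot(all(group %in% 0:1))
    cat4 <- factor(bmiCategory(bmi, 4L), levels = 0:3)
    dat <- data.frame(y = outcome, g = group, cat = cat4, age = age)
    red <- stats::glm(y ~ cat + g + age, binomial(), dat)
    full <- stats::glm(y ~ cat + g + cat:g + age, binomial(), dat)
    cf <- stats::coef(full)
    intTerms <- grep("^cat[123]:g$", names(cf), value = TRUE)
    aliased <- intTerms[is.na(cf[intTerms])]
    df <- length(intTerms) - length(aliased)
    if (length(aliased))
        warning("empty cell(s); dropped ", paste(aliased, collapse = ", "),
                "; df reduced to ", df)
    stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(red))))
    V <- stats::vcov(full)
    labs <- c("<25", "25-30", "30-35", ">35")
    rows <- lapply(0:3, function(s) {
        term <- if (s == 0) NULL else sprintf("cat%d:g", s)
        if (!is.null(term) && (is.na(cf[term]) || !term %in% rownames(V)))
            return(data.frame(stratum = labs[s + 1L], beta = NA_real_,
                              se = NA_real_, or = NA_real_,
                              stringsAsFactors = FALSE))
        b <- cf["g"] + if (is.null(term)) 0 else cf[term]
        v <- V["g", "g"] + if (is.null(term)) 0 else
            V[term, term] + 2 * V["g", term]
        data.frame(stratum = labs[s + 1L], beta = unname(b),
                   se = sqrt(unname(v)), or = exp(unname(b)),
                   stringsAsFactors = FALSE)
    })
    list(statistic = stat, df = df,
         p = stats::pchisq(stat, df, lower.tail = FALSE),
         strata = do.call(rbind, rows))
}

#' SNP x BMI interaction tests in four parameterizations
#'
#' For a single SNP dosage, fits the interaction with BMI encoded as
#' (1) continuous kg/m2, (2) 3-level category trend 0/1/2, (3) per-SD
#' standardized (pooled within-dataset mean/SD), and (4) the SNP main effect
#' within BMI strata. SNPs at or below the MAF floor are skipped with a
#' reason.
#'
#' @param snp 0/1/2 dosage vector.
#' @param bmi,age,pcs,outcome as in \code{\link{interactionScan}}.
#' @param marker marker id used in the output rows.
#' @param mafMin minimum (exclusive) minor allele frequency, default 0.05.
#' @param minCases minimum cases per stratum for the stratified fits.
#' @return data.frame of result rows (terms \code{snpxbmi},
#'   \code{snpxbmicat}, \code{snpxbmisd}, and stratified \code{snp}).
#' @export
snpInteractionTests <- function(snp, bmi, age, pcs, outcome,
                                marker = "snp", mafMin = 0.05,
                                minCases = 10L) {
    maf <- minorAlleleFreq(snp)
    if (is.na(maf) || maf <= mafMin)
        return(.untestableRow(marker, "snpxbmi", reason = "maf below floor"))
    covar <- cbind(age = age, pcs)
    fitInt <- function(mod, term) {
        X <- cbind(`(Intercept)` = 1, snp = snp, mod = mod, int = snp * mod,
                   covar)
        colnames(X)[3:4] <- c("modifier", term)
        fit <- fitLogistic(X, outcome)
        .termRow(fit, term, marker)
    }
    rows <- list(
        fitInt(bmi, "snpxbmi"),
        fitInt(as.numeric(bmiCategory(bmi, 3L)), "snpxbmicat"),
        fitInt((bmi - mean(bmi)) / stats::sd(bmi), "snpxbmisd"))
    cat3 <- bmiCategory(bmi, 3L)
    labs <- c("<25", "25-30", ">30")
    for (s in 0:2) {
        sel <- cat3 == s
        ys <- outcome[sel]
        if (sum(ys == 1) < minCases || length(unique(ys)) < 2L ||
            stats::var(snp[sel]) == 0) {
            rows <- c(rows, list(.untestableRow(marker, "snp", labs[s + 1L],
                                                n = sum(sel),
                                                reason = "stratum too small")))
            next
        }
        X <- cbind(`(Intercept)` = 1, snp = snp[sel],
                   covar[sel, , drop = FALSE])
        rows <- c(rows, list(.termRow(fitLogistic(X, ys), "snp", marker,
                                      labs[s + 1L])))
    }
    do.call(rbind, rows)
}

#' Conditional association adjusting for local ancestry
#'
#' Refits a SNP (or local-ancestry) association with the local-ancestry
#' dosage at a named conditioning marker added as a covariate, and reports
#' the SNP term. A constant conditioning vector is aliased against the
#' intercept and leaves the estimate unchanged; a SNP collinear with the
#' conditioning dosage is flagged aliased.
#'
#' @param snp 0/1/2 dosage vector.
#' @param outcome,age,pcs as in \code{\link{interactionScan}}.
#' @param conditionLa local-ancestry dosage at the conditioning marker.
#' @param bmi optional BMI vector; with \code{stratum} one of \code{"<25"},
#'   \code{"25-30"}, \code{">30"} the fit is restricted to that category.
#' @param marker marker id for the output row.
#' @param stratum optional BMI stratum label.
#' @return One result row (data.frame).
#' @export
conditionalScan <- function(snp, outcome, age, pcs, conditionLa, bmi = NULL,
                            stratum = NULL, marker = "snp") {
    if (is.null(conditionLa)) stop("conditioning local-ancestry dosage missing")
    n <- length(outcome)
    stopifnot(length(conditionLa) == n, length(snp) == n)
    sel <- rep(TRUE, n)
    if (!is.null(stratum)) {
        if (is.null(bmi)) stop("stratified conditioning requires bmi")
        labs <- c("<25", "25-30", ">30")
        sel <- bmiCategory(bmi, 3L) == (match(stratum, labs) - 1L)
    }
    X <- cbind(`(Intercept)` = 1, snp = snp[sel], age = age[sel],
               pcs[sel, , drop = FALSE], cond_la = conditionLa[sel])
    fit <- fitLogistic(X, outcome[sel])
    strat <- if (is.null(stratum)) NA_character_ else stratum
    # a conditioning dosage aliased against the SNP (or other covariates)
    # means the SNP term cannot be adjusted; flag rather than report the
    # unadjusted estimate -- unless the dosage is constant, which is
    # absorbed by the intercept and changes nothing
    if ("cond_la" %in% fit$aliased && stats::var(conditionLa[sel]) > 0)
        return(.untestableRow(marker, "snp", strat, n = sum(sel),
                              reason = "aliased"))
    .termRow(fit, "snp", marker, strat)
}
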