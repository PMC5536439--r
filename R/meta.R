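#' @include AllClasses.R
NULL

#' Recover a log-OR and SE from a printed OR and 95\% CI
#'
#' Inverts the reporting convention OR (95\% CI): beta = ln(OR),
#' se = (ln(hi) - ln(lo)) / (2 * 1.959964). The CI is assumed symmetric on
#' the log scale, as produced by Wald intervals.
#'
#' @param or odds ratio(s).
#' @param ciLow,ciHigh 95\% confidence limits.
#' @return data.frame with columns \code{beta} and \code{se}.
#' @examples
#' seFromOrCi(0.54, 0.38, 0.77)  # beta ~ -0.616, se ~ 0.180
#' @export
seFromOrCi <- function(or, ciLow, ciHigh) {
    if (any(or <= 0 | ciLow <= 0 | ciHigh <= 0))
        stop("odds ratios and confidence limits must be positive")
    if (any(ciLow > or | or > ciHigh))
        stop("confidence interval must bracket the odds ratio")
    data.frame(beta = log(or), se = (log(ciHigh) - log(ciLow)) / (2 * .Z95))
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Combines study-level log-ORs with weights 1/se^2:
#' beta = sum(w b) / sum(w), se = sqrt(1 / sum(w)), two-sided normal p.
#' With k >= 2 studies, Cochran's Q, its chi-square(k - 1) p-value, and
#' I^2 = max(0, (Q - (k - 1)) / Q) * 100 quantify heterogeneity; the
#' direction string holds one sign character per study in input order.
#'
#' @param beta study log-ORs.
#' @param se study standard errors (all > 0).
#' @param labels optional study labels.
#' @return One-row data.frame: beta, se, z, p, or, ci_low, ci_high, k, Q,
#'   het_p, i2, direction.
#' @examples
#' ivwMeta(c(log(1.49), log(1.55)), c(0.11, 0.22))  # meta OR 1.50
#' @export
ivwMeta <- function(beta, se, labels = NULL) {
    k <- length(beta)
    if (k < 1L) stop("at least one study estimate is required")
    stopifnot(length(se) == k)
    if (any(!is.finite(beta) | !is.finite(se) | se <= 0))
        stop("all study estimates need finite beta and se > 0")
    w <- 1 / se^2
    b <- sum(w * beta) / sum(w)
    s <- sqrt(1 / sum(w))
    z <- b / s
    if (k >= 2L) {
        Q <- sum(w * (beta - b)^2)
        hetP <- stats::pchisq(Q, df = k - 1L, lower.tail = FALSE)
        i2 <- max(0, (Q - (k - 1L)) / Q) * 100
        if (Q == 0) i2 <- 0
    } else {
        Q <- hetP <- i2 <- NA_real_
    }
    data.frame(beta = b, se = s, z = z, p = 2 * stats::pnorm(-abs(z)),
               or = exp(b), ci_low = exp(b - .Z95 * s),
               ci_high = exp(b + .Z95 * s), k = k, Q = Q, het_p = hetP,
               i2 = i2,
               direction = paste(ifelse(beta >= 0, "+", "-"), collapse = ""),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Cochran heterogeneity statistics
#'
#' Q = sum w_i (beta_i - beta_meta)^2 against chi-square(k - 1), and
#' I^2 floored at zero. Undefined (all NA) for a single study.
#'
#' @inheritParams ivwMeta
#' @return List with \code{Q}, \code{het_p}, \code{i2}.
#' @export
heterogeneity <- function(beta, se) {
    m <- ivwMeta(beta, se)
    list(Q = m$Q, het_p = m$het_p, i2 = m$i2)
}

#' Meta-analyze per-marker scan results across studies
#'
#' Joins per-study scan tables (as returned by \code{\link{interactionScan}}
#' and friends) on (marker_id, term, stratum) and combines testable rows by
#' \code{\link{ivwMeta}}. Markers missing or untestable in any study are
#' reported with the available subset (k reflects the studies used).
#'
#' @param ... two or more scan result data.frames, or a single list of them.
#' @param minStudies minimum studies with a testable estimate (default 1).
#' @return data.frame keyed by (marker_id, term, stratum) with meta columns.
#' @export
metaScan <- function(..., minStudies = 1L) {
    tabs <- list(...)
    if (length(tabs) == 1L && is.list(tabs[[1]]) &&
        !is.data.frame(tabs[[1]])) tabs <- tabs[[1]]
    stopifnot(length(tabs) >= 1L)
    key <- function(d) paste(d$marker_id, d$term,
                             ifelse(is.na(d$stratum), "", d$stratum))
    keys <- unique(unlist(lapply(tabs, key)))
    rows <- lapply(keys, function(kk) {
        est <- do.call(rbind, lapply(tabs, function(d) {
            d <- d[key(d) == kk & !is.na(d$beta) & !is.na(d$se), ,
                   drop = FALSE]
            d[, c("marker_id", "term", "stratum", "beta", "se")]
        }))
        proto <- do.call(rbind, lapply(tabs, function(d)
            d[key(d) == kk, c("marker_id", "term", "stratum")]))[1L, ]
        if (is.null(est) || nrow(est) < minStudies)
            return(cbind(proto, ivwMetaNA()))
        cbind(proto, ivwMeta(est$beta, est$se))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

ivwMetaNA <- function() {
    data.frame(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
               or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, k = 0L,
               Q = NA_real_, het_p = NA_real_, i2 = NA_real_,
               direction = "", stringsAsFactors = FALSE)
}
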