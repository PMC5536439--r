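test_that("logistic fit matches the closed-form 2x2 oracle", {
    # cases: 30 exposed / 10 unexposed; controls: 20 exposed / 40 unexposed
    y <- rep(c(1L, 1L, 0L, 0L), c(30, 10, 20, 40))
    x <- rep(c(1, 0, 1, 0), c(30, 10, 20, 40))
    fit <- fitLogistic(cbind(`(Intercept)` = 1, exposure = x), y)
    co <- fit$coefficients
    betaHat <- co$beta[co$term == "exposure"]
    seHat <- co$se[co$term == "exposure"]
    expect_lt(abs(betaHat - log(6)), 1e-6)
    expect_lt(abs(seHat - sqrt(1 / 30 + 1 / 10 + 1 / 20 + 1 / 40)), 1e-6)
    expect_true(fit$converged)
    # Wald p identity
    expect_equal(co$p, 2 * pnorm(-abs(co$beta / co$se)), tolerance = 1e-12)
})

test_that("logistic fit flags separation, aliasing and one-class outcomes", {
    # perfect separation
    x <- c(rep(0, 20), rep(1, 20))
    y <- as.integer(x == 1)
    fit <- fitLogistic(cbind(1, x), y)
    expect_false(fit$converged)
    # duplicated column is aliased and recorded
    set.seed(44)
    z <- rnorm(100); yy <- rbinom(100, 1, plogis(z))
    fit2 <- fitLogistic(cbind(`(Intercept)` = 1, a = z, b = z), yy)
    expect_identical(fit2$aliased, "b")
    expect_false(is.na(fit2$coefficients$beta[2]))
    # one-class outcome
    expect_error(fitLogistic(cbind(1, z), rep(0L, 100)), "both classes")
})

test_that("affine BMI re-encoding rescales the interaction by the Jacobian", {
    set.seed(46)
    n <- 600
    la <- rbinom(n, 2, 0.3); bmi <- rnorm(n, 31, 7); age <- rnorm(n, 41, 10)
    y <- rbinom(n, 1, plogis(-0.3 + 0.02 * bmi - 0.06 * la * (bmi - 25)))
    fit1 <- fitLogistic(cbind(1, la, bmi, int = la * bmi, age), y)
    bmi2 <- 3 * bmi - 5
    fit2 <- fitLogistic(cbind(1, la, bmi2, int = la * bmi2, age), y)
    b1 <- fit1$coefficients$beta[fit1$coefficients$term == "int"]
    b2 <- fit2$coefficients$beta[fit2$coefficients$term == "int"]
    expect_lt(abs(b2 - b1 / 3), 1e-8)
})

test_that("interaction scan flags untestable markers and finds a planted one", {
    panel <- toyPanel(nMarkers = 30, seed = 47)
    pcfg <- PhenotypeConfig(nIndividuals = 2500, causalMarker = "m00015",
                            betaInt = log(0.7), betaLa = 0, seed = 48)
    co <- simulateCohort(panel, AdmixtureConfig(seed = 47), pcfg)
    cd <- covariates(co)
    la <- trueLocalAncestry(co)
    la[4, ] <- 1L                       # constant-LA marker
    pcs <- computePCs(genotypes(co), 10)
    scan <- interactionScan(la, cd$bmi, cd$age, pcs, cd$case)
    expect_identical(scan$reason[4], "untestable")
    expect_true(is.na(scan$p[4]))
    expect_lt(scan$p[15], 1e-4)
    expect_lt(abs(scan$beta[15] - log(0.7)), 3 * scan$se[15])
    expect_equal(scan$or, exp(scan$beta))
})

test_that("stratified scan recovers a stratum-specific planted effect", {
    set.seed(50)
    n <- 6000
    la <- matrix(rbinom(n, 2, 0.3), 1, n,
                 dimnames = list("mk1", paste0("i", seq_len(n))))
    bmi <- runif(n, 18, 42)
    age <- rnorm(n, 41, 10)
    obese <- bmi >= 30
    y <- rbinom(n, 1, plogis(-0.2 + log(0.5) * la[1, ] * obese))
    res <- stratifiedScan(la, y, age, NULL, bmi)
    expect_identical(res$stratum, c("<25", "25-30", ">30"))
    bObese <- res$beta[res$stratum == ">30"]
    expect_lt(abs(bObese - log(0.5)), 3 * res$se[res$stratum == ">30"])
    for (s in c("<25", "25-30"))
        expect_lt(abs(res$beta[res$stratum == s]), 0.15)
})

test_that("stratified scan reports small strata as missing with a reason", {
    set.seed(51)
    n <- 300
    la <- matrix(rbinom(n, 2, 0.3), 1, n,
                 dimnames = list("mk1", paste0("i", seq_len(n))))
    bmi <- c(runif(12, 18, 24), runif(n - 12, 26, 42))
    y <- c(rep(0L, 12), rbinom(n - 12, 1, 0.4))   # no cases below BMI 25
    res <- stratifiedScan(la, y, rnorm(n, 40, 8), NULL, bmi)
    expect_identical(res$reason[res$stratum == "<25"], "stratum too small")
    expect_true(is.na(res$beta[res$stratum == "<25"]))
    expect_false(any(is.na(res$beta[res$stratum != "<25"])))
})

test_that("categorical interaction LRT is calibrated and nested", {
    # null: no group x category interaction
    set.seed(52)
    pvals <- replicate(120, {
        n <- 400
        g <- rbinom(n, 1, 0.5)
        bmi <- runif(n, 18, 45)
        age <- rnorm(n, 40, 10)
        y <- rbinom(n, 1, plogis(-0.5 + 0.4 * g + 0.02 * bmi))
        categoricalInteractionLrt(y, g, bmi, age)$p
    })
    expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
    # the statistic is non-negative by nesting (checked across the nulls)
    set.seed(53)
    n <- 500
    g <- rbinom(n, 1, 0.5); bmi <- runif(n, 18, 45)
    y <- rbinom(n, 1, 0.4)
    expect_gte(categoricalInteractionLrt(y, g, bmi, rnorm(n, 40, 8))$statistic,
               0)
})

test_that("categorical interaction LRT detects a category-increasing effect", {
    set.seed(54)
    hits <- replicate(30, {
        n <- 5000
        g <- rbinom(n, 1, 0.5)
        bmi <- runif(n, 18, 45)
        cat4 <- bmiCategory(bmi, 4)
        age <- rnorm(n, 40, 10)
        y <- rbinom(n, 1, plogis(-0.6 + 0.25 * g * cat4 + 0.05 * cat4))
        fit <- categoricalInteractionLrt(y, g, bmi, age)
        fit$p < 0.05
    })
    expect_gte(mean(hits), 0.8)
    # stratum-specific group ORs increase across categories
    set.seed(55)
    n <- 20000
    g <- rbinom(n, 1, 0.5); bmi <- runif(n, 18, 45)
    cat4 <- bmiCategory(bmi, 4)
    y <- rbinom(n, 1, plogis(-0.6 + 0.3 * g * cat4))
    fit <- categoricalInteractionLrt(y, g, bmi, rnorm(n, 40, 8))
    expect_true(all(diff(fit$strata$beta) > 0))
})

test_that("BMI categorization uses left-closed boundaries", {
    expect_identical(bmiCategory(c(24.9, 25, 29.9, 30, 35, 40), 3),
                     c(0L, 1L, 1L, 2L, 2L, 2L))
    expect_identical(bmiCategory(c(25, 30, 34.9, 35), 4),
                     c(1L, 2L, 2L, 3L))
})

test_that("SNP interaction parameterizations are consistent", {
    set.seed(56)
    n <- 2500
    snp <- rbinom(n, 2, 0.4)
    bmi <- runif(n, 18, 45)
    age <- rnorm(n, 40, 10)
    y <- rbinom(n, 1, plogis(-0.5 + 0.05 * snp * (bmi - 25)))
    res <- snpInteractionTests(snp, bmi, age, NULL, y, marker = "rsX")
    cont <- res[res$term == "snpxbmi", ]
    psd <- res[res$term == "snpxbmisd", ]
    trend <- res[res$term == "snpxbmicat", ]
    # per-SD beta is the continuous beta scaled by SD(BMI), exactly
    expect_lt(abs(psd$beta - cont$beta * sd(bmi)), 1e-8)
    expect_identical(sign(trend$beta), sign(cont$beta))
    # stratified rows present for all three categories
    expect_setequal(res$stratum[res$term == "snp"], c("<25", "25-30", ">30"))
})

test_that("low-MAF SNPs are skipped with a reason", {
    snp <- rep(c(0L, 1L), c(96, 4))       # MAF 2%
    res <- snpInteractionTests(snp, runif(100, 18, 45), rnorm(100, 40, 8),
                               NULL, rbinom(100, 1, 0.5))
    expect_identical(res$reason, "maf below floor")
    expect_true(is.na(res$beta))
})

test_that("conditioning on a constant leaves the estimate unchanged", {
    set.seed(57)
    n <- 800
    snp <- rbinom(n, 2, 0.35); age <- rnorm(n, 40, 10)
    y <- rbinom(n, 1, plogis(-0.3 + 0.3 * snp))
    base <- fitLogistic(cbind(`(Intercept)` = 1, snp = snp, age = age), y)
    cond <- conditionalScan(snp, y, age, NULL, conditionLa = rep(1, n))
    b0 <- base$coefficients$beta[base$coefficients$term == "snp"]
    expect_lt(abs(cond$beta - b0), 1e-8)
    # SNP collinear with the conditioning dosage is aliased
    col <- conditionalScan(snp, y, age, NULL, conditionLa = snp)
    expect_true(col$reason %in% c("aliased", "nonconverged"))
    expect_error(conditionalScan(snp, y, age, NULL, conditionLa = NULL),
                 "missing")
})

test_that("conditioning attenuates confounding by local ancestry", {
    # LA is causal; the SNP is only associated through its ancestry
    # informativeness, so adjusting for LA pulls the SNP effect toward zero
    set.seed(58)
    n <- 4000
    la <- rbinom(n, 2, 0.25)
    pSnp <- c(0.9, 0.5, 0.1)[la + 1L]     # high-delta marker tags ancestry
    snp <- rbinom(n, 2, pSnp)
    age <- rnorm(n, 40, 10)
    y <- rbinom(n, 1, plogis(-0.4 - 0.6 * la))
    un <- conditionalScan(snp, y, age, NULL, conditionLa = rep(0, n))
    ad <- conditionalScan(snp, y, age, NULL, conditionLa = la)
    expect_gt(abs(un$beta), 0.15)
    expect_lt(abs(ad$beta), abs(un$beta))
})
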