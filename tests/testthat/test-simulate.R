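test_that("tract kernel: adjacent markers at negligible distance share labels", {
    # d -> 0 limit: switch probability 1 - exp(-G r d) vanishes
    panel <- handPanel(pos = c(1000L, 1001L), freqAfr = c(0.8, 0.8),
                       freqEur = c(0.2, 0.2))
    tr <- simulateHaplotypeTracts(panel, AdmixtureConfig(seed = 1), 10000L)
    expect_identical(tr[1L, ], tr[2L, ])
})

test_that("tract kernel matches its closed-form switch probability", {
    # d = 1e6, G = 7, r = 1e-8: re-draw prob 1 - exp(-0.07) = 0.06761
    # a label change needs a re-draw AND a different stationary draw:
    # P(change) = s * 2 lam (1 - lam) under lambdaSd = 0
    panel <- handPanel(pos = c(1L, 1000001L), freqAfr = c(0.8, 0.8),
                       freqEur = c(0.2, 0.2))
    cfg <- AdmixtureConfig(lambdaSd = 0, seed = 11)
    H <- 50000L
    tr <- simulateHaplotypeTracts(panel, cfg, H)
    s <- 1 - exp(-7 * 1e-8 * 1e6)
    expect_equal(s, 0.0676, tolerance = 1e-3)
    pChange <- s * 2 * 0.2 * 0.8
    obs <- mean(tr[1L, ] != tr[2L, ])
    expect_lt(abs(obs - pChange), 3 * sqrt(pChange * (1 - pChange) / H))
})

test_that("marker-wise European fraction matches lambda", {
    cfg0 <- AdmixtureConfig(lambdaSd = 0, seed = 21)
    panel <- toyPanel(nMarkers = 10, seed = 21)
    tr <- simulateHaplotypeTracts(panel, cfg0, 10000L)
    # binomial sampling error band from the stationary draw
    expect_true(all(abs(rowMeans(tr) - 0.2) <= 0.012))
    # with between-individual ancestry variance the expectation is unchanged
    cfg1 <- AdmixtureConfig(lambdaSd = 0.1, seed = 22)
    tr1 <- simulateHaplotypeTracts(panel, cfg1, 10000L)
    expect_true(all(abs(rowMeans(tr1) - 0.2) <= 4 * sqrt(0.2 * 0.8 / 10000)))
})

test_that("observed ancestry segment lengths match the kernel's closed form", {
    # re-draw events occur at rate G per Morgan, but only a fraction
    # 2 lam (1-lam) change the label, so same-label segments average
    # 1 / (2 G lam (1-lam)) Morgans
    lam <- 0.2; G <- 7; r <- 1e-8
    panel <- simulatePanel(nMarkers = 4000, nChrom = 1, spacingMeanBp = 2e5,
                           seed = 31)
    cfg <- AdmixtureConfig(lambdaEur = lam, lambdaSd = 0, generations = G,
                           recombRate = r, seed = 31)
    H <- 400L
    tr <- simulateHaplotypeTracts(panel, cfg, H)
    nChanges <- sum(tr[-1L, ] != tr[-nrow(tr), ])
    lengthMorgans <- (max(panel$pos) - min(panel$pos)) * r
    meanSegment <- lengthMorgans * H / nChanges
    expected <- 1 / (2 * G * lam * (1 - lam))
    expect_lt(abs(meanSegment - expected) / expected, 0.10)
})

test_that("genotypes follow ancestry-conditional allele frequencies", {
    # fixed difference: genotype equals the European copy count
    panel <- handPanel(pos = c(1e5, 2e5, 3e5), freqAfr = c(0, 0.5, 0.73),
                       freqEur = c(1, 0.5, 0.17))
    cfg <- AdmixtureConfig(seed = 5)
    tr <- simulateHaplotypeTracts(panel, cfg, 8000L)
    gm <- simulateGenotypes(tr, panel, seed = 6)
    expect_identical(gm$genotypes[1L, ], gm$trueLocalAncestry[1L, ])
    # ancestry-uninformative marker: mean genotype 1 regardless of ancestry
    expect_lt(abs(mean(gm$genotypes[2L, ]) - 1), 4 * sqrt(0.5 / 4000))
    # mixture mean: lam fE + (1-lam) fA = 0.2*0.17 + 0.8*0.73 = 0.618
    expect_lt(abs(mean(gm$genotypes[3L, ]) / 2 - 0.618),
              4 * sqrt(0.618 * 0.382 / (2 * 4000)) + 0.01)
})

test_that("phenotype model reduces to coin flips and saturates correctly", {
    n <- 4000L
    bmi <- rep(30, n); age <- rep(40, n)
    null <- PhenotypeConfig(beta0 = 0, betaLa = 0, betaBmi = 0, betaInt = 0,
                            betaAge = 0, nIndividuals = n, seed = 3)
    y <- simulatePhenotype(rep(1L, n), bmi, age, null)
    expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / n))
    allCtl <- PhenotypeConfig(beta0 = -30, betaLa = 0, betaBmi = 0,
                              betaInt = 0, betaAge = 0, nIndividuals = n,
                              seed = 3)
    expect_identical(sum(simulatePhenotype(rep(2L, n), bmi, age, allCtl)), 0L)
})

test_that("cohort simulation is seed-deterministic and seed-sensitive", {
    panel <- toyPanel(seed = 7)
    cfg <- AdmixtureConfig(seed = 7)
    pcfg <- PhenotypeConfig(nIndividuals = 80, causalMarker = "m00010",
                            seed = 8)
    c1 <- simulateCohort(panel, cfg, pcfg)
    c2 <- simulateCohort(panel, cfg, pcfg)
    expect_identical(genotypes(c1), genotypes(c2))
    expect_identical(covariates(c1), covariates(c2))
    c3 <- simulateCohort(panel, AdmixtureConfig(seed = 9), pcfg)
    expect_false(identical(genotypes(c1), genotypes(c3)))
    # same marginal allele frequencies under a different seed
    expect_lt(abs(mean(genotypes(c1)) - mean(genotypes(c3))), 0.05)
})

test_that("covariates respect truncation bounds and moments", {
    panel <- toyPanel(seed = 7)
    pcfg <- PhenotypeConfig(nIndividuals = 2000, seed = 12)
    co <- simulateCohort(panel, AdmixtureConfig(seed = 12), pcfg)
    cd <- covariates(co)
    expect_true(all(cd$bmi >= 15))
    expect_true(all(cd$age >= 18))
    # lower truncation shifts the mean up by sd * phi(a) / (1 - Phi(a))
    truncMean <- function(m, s, lo) {
        a <- (lo - m) / s
        m + s * dnorm(a) / (1 - pnorm(a))
    }
    expect_lt(abs(mean(cd$bmi) - truncMean(32.5, 8.7, 15)),
              4 * 8.7 / sqrt(2000))
    expect_lt(abs(mean(cd$age) - truncMean(41, 13, 18)),
              4 * 13 / sqrt(2000))
})

test_that("simulation rejects invalid inputs", {
    expect_error(AncestralPanel("m1", "1", 0L, "A", "G", 0.5, 0.5),
                 "positive integers")
    expect_error(AncestralPanel(c("m1", "m2"), "1", c(10L, 10L), "A", "G",
                                c(0.5, 0.5), c(0.5, 0.5)),
                 "strictly increasing")
    expect_error(AncestralPanel("m1", "1", 10L, "A", "G", 1.2, 0.5), "0, 1")
    expect_error(AdmixtureConfig(lambdaEur = 0), "lambdaEur")
    expect_error(simulateCohort(toyPanel(seed = 1), AdmixtureConfig(),
                                PhenotypeConfig(causalMarker = "nope",
                                                nIndividuals = 10)),
                 "not in panel")
})
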