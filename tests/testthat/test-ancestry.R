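test_that("AIM selection uses a strict delta threshold", {
    panel <- handPanel(pos = c(1e5, 2e5, 3e5, 4e5),
                       freqAfr = c(0.5, 0.73, 0.5, 0.9),
                       freqEur = c(0.5, 0.17, 0.3, 0.2))
    aims <- selectAims(panel, 0.2)
    # delta 0, 0.56, exactly 0.2, 0.7 -> keep markers 2 and 4 only
    expect_identical(aims$marker_id, c("hm2", "hm4"))
    expect_warning(selectAims(panel, 0.9), "no markers")
})

test_that("LD pruning removes duplicates and keeps independent markers", {
    g <- independentGenotypes(10, 200, seed = 2)
    g[2, ] <- g[1, ]               # duplicated column pair
    keep <- ldPrune(g, r2Max = 0.1, window = 10, step = 5)
    expect_true(keep[1]); expect_false(keep[2])

    # three mutually identical markers -> exactly one survivor
    g2 <- independentGenotypes(6, 200, seed = 3)
    g2[3, ] <- g2[5, ] <- g2[1, ]
    keep2 <- ldPrune(g2, r2Max = 0.1, window = 6, step = 3)
    expect_identical(sum(keep2[c(1, 3, 5)]), 1L)
    expect_true(keep2[1])          # earlier-position marker wins

    # independent markers: >= 95% retained beyond chance removals
    g3 <- independentGenotypes(200, 500, seed = 4)
    expect_gte(mean(ldPrune(g3)), 0.95)

    # constant marker: correlation undefined, treated as zero, retained
    g4 <- independentGenotypes(5, 100, seed = 5)
    g4[2, ] <- 1L
    expect_true(all(ldPrune(g4, window = 5, step = 2)[2]))
})

test_that("fixed-difference marker yields a certain ancestry call", {
    panel <- handPanel(pos = 1e5, freqAfr = 0, freqEur = 1)
    g <- matrix(2L, 1, 1, dimnames = list(panel$marker_id, "i1"))
    lar <- inferLocalAncestry(g, panel, AdmixtureConfig(seed = 1))
    expect_identical(unname(ancestryCalls(lar)[1, 1]), 2L)
    expect_gt(ancestryPosteriors(lar)$p2[1, 1], 0.999)
})

test_that("forward-backward equals the exhaustive-path oracle", {
    lam <- 0.2; G <- 7; r <- 1e-8
    pos <- c(1e5, 1.4e6, 2.1e6)
    fa <- c(0.9, 0.15, 0.8); fe <- c(0.2, 0.85, 0.1)
    panel <- handPanel(pos = pos, freqAfr = fa, freqEur = fe)
    cfg <- AdmixtureConfig(lambdaEur = lam, generations = G, recombRate = r)
    for (geno in list(c(0L, 1L, 2L), c(2L, 2L, 0L), c(1L, NA, 1L))) {
        g <- matrix(geno, 3, 1, dimnames = list(panel$marker_id, "i1"))
        lar <- inferLocalAncestry(g, panel, cfg)
        po <- ancestryPosteriors(lar)
        got <- cbind(po$p0[, 1], po$p1[, 1], po$p2[, 1])
        want <- bruteForcePosterior(geno, pos, fa, fe, lam, G, r)
        expect_lt(max(abs(got - want)), 1e-10)
    }
    # 4-marker instance
    pos4 <- c(1e5, 9e5, 1.6e6, 3.0e6)
    fa4 <- c(0.85, 0.2, 0.7, 0.95); fe4 <- c(0.1, 0.9, 0.05, 0.3)
    panel4 <- handPanel(pos = pos4, freqAfr = fa4, freqEur = fe4)
    geno4 <- c(1L, 2L, 0L, 1L)
    g4 <- matrix(geno4, 4, 1, dimnames = list(panel4$marker_id, "i1"))
    po4 <- ancestryPosteriors(inferLocalAncestry(g4, panel4, cfg))
    got4 <- cbind(po4$p0[, 1], po4$p1[, 1], po4$p2[, 1])
    expect_lt(max(abs(got4 - bruteForcePosterior(geno4, pos4, fa4, fe4,
                                                 lam, G, r))), 1e-10)
})

test_that("posteriors are proper distributions and match calls", {
    panel <- toyPanel(nMarkers = 50, seed = 25)
    cfg <- AdmixtureConfig(seed = 25)
    co <- simulateCohort(panel, cfg, PhenotypeConfig(nIndividuals = 60,
                                                     seed = 26),
                         missingRate = 0.05)
    lar <- inferLocalAncestry(co, config = cfg)
    po <- ancestryPosteriors(lar)
    tot <- po$p0 + po$p1 + po$p2
    expect_lt(max(abs(tot - 1)), 1e-8)
    # calls are the posterior mode
    mode <- (po$p1 > po$p0 & po$p1 >= po$p2) + 2L * (po$p2 > po$p0 &
                                                     po$p2 > po$p1)
    expect_true(mean(mode == ancestryCalls(lar)) > 0.999)
})

test_that("decoding accuracy increases with delta", {
    accs <- vapply(c(0.3, 0.6, 0.9), function(delta) {
        fa <- rep(0.5 + delta / 2, 80)
        fe <- rep(0.5 - delta / 2, 80)
        set.seed(27)
        pos <- cumsum(pmax(1, round(rexp(80, 1 / 1.5e5))))
        panel <- handPanel(pos = pos, freqAfr = fa, freqEur = fe)
        cfg <- AdmixtureConfig(seed = 27)
        co <- simulateCohort(panel, cfg,
                             PhenotypeConfig(nIndividuals = 150, seed = 28))
        lar <- inferLocalAncestry(co, config = cfg)
        mean(ancestryCalls(lar) == trueLocalAncestry(co))
    }, numeric(1))
    expect_true(all(diff(accs) >= 0))
    expect_gt(accs[3], 0.98)
})

test_that("global ancestry is the call mean over 2M", {
    calls <- matrix(c(2L, 1L, 0L, 1L), 4, 1)
    expect_equal(unname(globalAncestry(calls)), 0.5)
    expect_equal(unname(globalAncestry(matrix(2L, 5, 2))), c(1, 1))
    expect_equal(unname(globalAncestry(matrix(0L, 5, 2))), c(0, 0))
    expect_error(globalAncestry(matrix(integer(0), 0, 3)), "zero markers")
})

test_that("mean global ancestry tracks lambda", {
    panel <- toyPanel(nMarkers = 150, nChrom = 5, seed = 29)
    cfg <- AdmixtureConfig(seed = 29)
    co <- simulateCohort(panel, cfg, PhenotypeConfig(nIndividuals = 300,
                                                     seed = 30))
    thetaTrue <- globalAncestry(trueLocalAncestry(co))
    seMean <- sd(thetaTrue) / sqrt(length(thetaTrue))
    expect_lt(abs(mean(thetaTrue) - 0.2), 4 * seMean)
    # inferred theta tracks the truth closely
    lar <- inferLocalAncestry(co, config = cfg)
    expect_gt(cor(globalAncestry(lar), thetaTrue), 0.97)
})

test_that("principal components are orthogonal and separate populations", {
    # two-population toy: 20 EUR-like vs 20 AFR-like at 50 high-delta markers
    set.seed(33)
    fa <- runif(50, 0.75, 0.95); fe <- runif(50, 0.05, 0.25)
    gE <- matrix(rbinom(50 * 20, 2, rep(fe, 20)), 50, 20)
    gA <- matrix(rbinom(50 * 20, 2, rep(fa, 20)), 50, 20)
    g <- cbind(gE, gA)
    rownames(g) <- paste0("t", 1:50)
    colnames(g) <- paste0("i", 1:40)
    pcs <- computePCs(g, 5)
    expect_lt(max(abs(crossprod(pcs)[upper.tri(diag(5))])), 1e-8)
    expect_true(max(pcs[1:20, 1]) < min(pcs[21:40, 1]) ||
                min(pcs[1:20, 1]) > max(pcs[21:40, 1]))
    # deterministic sign: recomputation is identical, not sign-flipped
    expect_identical(pcs, computePCs(g, 5))
    expect_warning(computePCs(g[, 1:4], 10), "fewer individuals")
})
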