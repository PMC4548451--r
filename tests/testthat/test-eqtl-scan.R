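test_that("interval collapsing merges recombination-free runs", {
    cfg <- smallConfig(seed = 61, nLines = 20L, nMarkers = 30L,
                       recombRate = 0.5)
    hap <- simulatePopulation(cfg)
    col <- collapseIntervals(hap, 0)
    # truth from the simulator: one interval per effective breakpoint + 1
    expected <- sum(lengths(hap@breakpoints)) + nrow(cfg@chromosomes)
    expect_equal(nrow(lociTable(col)), expected)
    # merged matrices still diploid
    sums <- apply(dosageArray(col), c(1, 2), sum)
    expect_true(all(abs(sums - 2) < 1e-9))
    # identical adjacent loci merge to one with the same matrix
    d <- dosageArray(hap)[, 1:2, , drop = FALSE]
    d[, 2, ] <- d[, 1, ]
    tiny <- new("HaplotypeDosage", lines = lineIds(hap),
                loci = data.frame(chrom = "1", pos = c(100, 200)),
                founders = founderNames(hap), dosages = d,
                breakpoints = list())
    col2 <- collapseIntervals(tiny, 0)
    expect_equal(nrow(lociTable(col2)), 1)
    expect_equal(col2@dosages[, 1, ], d[, 1, ])
    expect_equal(lociTable(col2)$pos, 150)
    # with all-distinct loci and tolerance 0 the map is unchanged
    hapBlur <- simulatePopulation(smallConfig(seed = 61, nLines = 20L,
                                              nMarkers = 30L,
                                              recombRate = 0.5,
                                              dosageBlur = 0.05))
    colB <- collapseIntervals(hapBlur, 0)
    expect_equal(nrow(lociTable(colB)), nrow(lociTable(hapBlur)))
    expect_error(collapseIntervals(hap, -1), "tolerance")
})

test_that("single-locus fits recover exact and degenerate structure", {
    cfg <- smallConfig(seed = 62)
    hap <- simulatePopulation(cfg)
    D <- dosageArray(hap)[, 5, ]
    # constant trait: zero effects, zero R2
    f0 <- fitQtl(rep(3, 40), D)
    expect_equal(unname(f0@r2), 0)
    expect_true(all(abs(f0@effects[!is.na(f0@effects)]) < 1e-8))
    # exact linear function of dosages: R2 = 1, RSS ~ 0
    beta <- c(0, 1, -1, 2, 0.5, -0.5, 1.5, -2)
    y <- as.numeric(D %*% beta)
    f1 <- fitQtl(y, D)
    expect_equal(f1@r2, 1, tolerance = 1e-10)
    expect_lt(f1@rss, 1e-16 * sum(y^2) + 1e-12)
    # random case matches the normal-equations oracle to 1e-10
    set.seed(1)
    y2 <- rnorm(40)
    f2 <- fitQtl(y2, D)
    X <- cbind(1, D[, -1])
    betaHat <- solve(crossprod(X), crossprod(X, y2))
    rssHat <- sum((y2 - X %*% betaHat)^2)
    expect_equal(f2@rss, rssHat, tolerance = 1e-10)
    expect_equal(unname(f2@effects), as.numeric(betaHat[-1]),
                 tolerance = 1e-8)
    # a founder absent from the locus is dropped and flagged
    D2 <- D; D2[, "CAST/EiJ"] <- 0
    f3 <- fitQtl(rnorm(40), D2)
    expect_true("CAST/EiJ" %in% f3@aliased)
    expect_error(fitQtl(rnorm(5), D[1:5, ]), "10")
})

test_that("LOD scans equal the per-locus OLS likelihood-ratio oracle", {
    cfg <- smallConfig(seed = 63)
    hap <- simulatePopulation(cfg)
    e <- simulateLineExpression(hap, cfg)
    y <- e[, "mir-planted-1"]
    lod <- lodScan(y, hap)
    expect_true(all(lod >= 0))
    expect_equal(lod, lodOracle(y, hap), tolerance = 1e-8)
    # with covariates too
    covs <- dosageArray(hap)[, 30, -1]
    expect_equal(lodScan(y, hap, covs), lodOracle(y, hap, covs),
                 tolerance = 1e-8)
    # zero-variance locus (all lines one founder) scores exactly 0
    d <- dosageArray(hap)
    d[, 3, ] <- 0; d[, 3, 1] <- 2
    hap2 <- new("HaplotypeDosage", lines = lineIds(hap),
                loci = lociTable(hap), founders = founderNames(hap),
                dosages = d, breakpoints = list())
    expect_equal(lodScan(y, hap2)[3], 0)
    # constant trait: flat zero curve
    expect_true(all(lodScan(rep(1, 40), hap) == 0))
})

test_that("permutation thresholds use the add-one plug-in rule", {
    cfg <- smallConfig(seed = 64)
    hap <- simulatePopulation(cfg)
    e <- simulateLineExpression(hap, cfg)
    pt <- permuteThresholds(e[, "mir-planted-1"], hap, nPerm = 250,
                            seed = 7)
    # a planted h2 = 0.6 peak dwarfs every null maximum
    expect_true(all(pt@nullMax < pt@observedMax))
    expect_equal(pt@adjP, 1 / 251)
    expect_gte(pt@thresholds[["0.05"]], pt@thresholds[["0.1"]])
    # observed below (or tied with) every null maximum: adjusted p = 1
    ptFlat <- permuteThresholds(rep(2, 40), hap, nPerm = 20, seed = 7)
    expect_equal(ptFlat@adjP, 1)
    # joint line relabelling leaves the observed scan invariant and the
    # adjusted p equal up to permutation-sampling noise
    perm <- sample(40)
    hapP <- new("HaplotypeDosage", lines = lineIds(hap)[perm],
                loci = lociTable(hap), founders = founderNames(hap),
                dosages = dosageArray(hap)[perm, , ],
                breakpoints = hap@breakpoints)
    yP <- e[perm, "mir-planted-1"]
    expect_equal(lodScan(yP, hapP), lodScan(e[, "mir-planted-1"], hap),
                 tolerance = 1e-10)
    ptP <- permuteThresholds(yP, hapP, nPerm = 250, seed = 7)
    expect_lt(abs(ptP@adjP - pt@adjP), 0.05)
})

test_that("support intervals follow the LOD-drop rule", {
    loci <- data.frame(chrom = "1", pos = c(10, 20, 30, 40, 50) * 1e5)
    si <- lodSupportInterval(c(0, 2, 6, 2, 0), loci, drop = 1.5)
    expect_equal(si$start, 20e5)     # qualifying set {pos3} plus flanks
    expect_equal(si$end, 40e5)
    expect_true(si$start <= loci$pos[attr(si, "peakIndex")] &&
                loci$pos[attr(si, "peakIndex")] <= si$end)
    # infinite drop: the whole chromosome
    siInf <- lodSupportInterval(c(0, 2, 6, 2, 0), loci, drop = Inf)
    expect_equal(c(siInf$start, siInf$end), c(10e5, 50e5))
    # monotone non-shrinking in drop
    widths <- vapply(c(0.5, 1.5, 3, 5), function(dr) {
        s <- lodSupportInterval(c(0, 1, 3, 6, 5.2, 2, 0.5, 0),
                                data.frame(chrom = "1",
                                           pos = (1:8) * 1e6), dr)
        s$end - s$start
    }, 0)
    expect_true(all(diff(widths) >= 0))
    # flat curve: whole chromosome with a warning
    expect_warning(siF <- lodSupportInterval(rep(1, 5), loci), "flat")
    expect_equal(c(siF$start, siF$end), c(10e5, 50e5))
    # peak ties resolve leftmost
    siT <- lodSupportInterval(c(0, 6, 6, 0, 0), loci, drop = 1.5)
    expect_equal(attr(siT, "peakIndex"), 2L)
})

test_that("eQTL are classified local within 10 Mb and distal beyond", {
    expect_equal(classifyEqtl("12", 109161374, "12", 109.90e6), "local")
    expect_equal(classifyEqtl("1", 5e6, "1", 5e6), "local")
    expect_equal(classifyEqtl("1", 5e6, "2", 5e6), "distal")
    expect_equal(classifyEqtl("1", 5e6, "1", 15e6 + 1), "distal")
    expect_equal(classifyEqtl("1", 5e6, "1", 15e6), "local")  # boundary
    expect_error(classifyEqtl(NA, 1, "1", 1), "chromosome")
})

test_that("conditional scans absorb the conditioned locus", {
    cfg <- smallConfig(seed = 66)
    hap <- simulatePopulation(cfg)
    e <- simulateLineExpression(hap, cfg)
    y <- e[, "mir-planted-1"]
    # empty condition set: identical to the plain scan
    expect_equal(conditionalScan(y, hap, NULL), lodScan(y, hap))
    # conditioning on the scanned locus zeroes it by aliasing
    cs <- conditionalScan(y, hap, 10)
    expect_equal(cs[10], 0)
    # single planted eQTL, conditioned out: nothing clears the threshold
    hits <- vapply(1:10, function(s) {
        cfgS <- smallConfig(seed = 200 + s, nLines = 60L)
        hapS <- simulatePopulation(cfgS)
        yS <- simulateLineExpression(hapS, cfgS)[, "mir-planted-1"]
        ptS <- permuteThresholds(yS, hapS, nPerm = 100, seed = s,
                                 covariates = dosageArray(hapS)[, 10, -1])
        ptS@observedMax >= ptS@thresholds[["0.05"]]
    }, TRUE)
    expect_lte(sum(hits), 1)
    # two unlinked planted eQTL: the second survives conditioning on the
    # first
    cfg2 <- smallConfig(seed = 67, nLines = 80L)
    cfg2@plantedEqtl <- list(
        list(mirna = "m", locus = 10L,
             effects = c(0, 0, 0, -2, 0, -2, 0, 0), h2 = 0.4),
        list(mirna = "m", locus = 40L,
             effects = c(0, 2, 0, 0, 2, 0, 0, 0), h2 = 0.4))
    hap2 <- simulatePopulation(cfg2)
    y2 <- simulateLineExpression(hap2, cfg2)[, "m"]
    cs2 <- conditionalScan(y2, hap2, 10)
    loci2 <- lociTable(hap2)
    onChr2 <- loci2$chrom == "2"
    expect_gt(max(cs2[onChr2]), 3)
})

test_that("full scans assemble peak, interval, fit and classification", {
    cfg <- smallConfig(seed = 68, nLines = 60L)
    hap <- simulatePopulation(cfg)
    e <- simulateLineExpression(hap, cfg)
    truePos <- lociTable(hap)$pos[10]
    sr <- scanMirna(e[, "mir-planted-1"], hap, "mir-planted-1",
                    genePos = list(chrom = "1", pos = truePos),
                    nPerm = 100, seed = 5)
    expect_s4_class(sr, "ScanResult")
    expect_lt(sr@adjP, 0.05)
    expect_equal(sr@classification, "local")
    si <- supportInterval(sr)
    expect_true(si$chrom == "1" && si$start <= truePos &&
                truePos <= si$end)
    # NOD and PWK carry the planted low allele at the peak
    eff <- sr@fit@effects
    expect_lt(eff[["NOD/ShiLtJ"]], -1)
    expect_lt(eff[["PWK/PhJ"]], -1)
    tab <- eqtlTable(list(sr))
    expect_equal(tab$p_threshold, 0.05)
    expect_equal(tab$chrom, "1")
    expect_true(tab$h2 > 0.3 && tab$h2 < 0.9)
})
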