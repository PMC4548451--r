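test_that("anova screen handles degenerate and separated miRNAs", {
    sm <- matrix(5, nrow = 8, ncol = 3,
                 dimnames = list(.CCF, c("mir-a", "mir-b", "mir-c")))
    sm[, "mir-b"] <- c(1, 1, 1, 1, 9, 9, 9, 9)   # perfect separation
    panel <- designedPanel(sm, noise = 0)
    expect_warning(anovaDE(panel), "constant")
    tab <- suppressWarnings(anovaDE(panel))
    expect_equal(tab$p[tab$mirna == "mir-a"], 1)   # constant -> p = 1
    expect_equal(tab$p[tab$mirna == "mir-b"], 0)   # separated -> p = 0
    expect_true(all(tab$q >= tab$p - 1e-12))
    expect_true(all(tab$MSB >= 0 & tab$MSW >= 0))
})

test_that("BH adjustment matches the step-up oracle", {
    cfg <- simConfig(seed = 21, panelSpec = list(
        nMirnas = 60L, icc = 0.3, fracNull = 0.5, meanRange = c(4, 12)))
    tab <- anovaDE(simulateFounderPanel(cfg))
    expect_equal(tab$q, bhOracle(tab$p), tolerance = 1e-12)
})

test_that("heritability formulas match hand-computed values", {
    h <- heritability(10, 2, 4)
    expect_equal(h$r1, 0.5)
    expect_equal(h$g2, 1 / 3, tolerance = 1e-12)
    expect_equal(heritability(5, 5, 4)$r1, 0)      # MSB = MSW
    expect_equal(heritability(5, 5, 4)$g2, 0)
    expect_equal(heritability(3, 0, 4)$r1, 1)      # no within variance
    expect_equal(heritability(3, 0, 4)$g2, 1)
    expect_error(heritability(0, 0, 4), "degenerate")
    expect_error(heritability(-1, 2, 4), ">= 0")
    # g2 <= r1 whenever MSB >= MSW
    msb <- c(2, 5, 9); msw <- c(1, 2, 3)
    h2 <- heritability(msb, msw, 4)
    expect_true(all(h2$g2 <= h2$r1 + 1e-12))
})

test_that("r1 equals a method-of-moments variance-components oracle", {
    set.seed(31)
    strain <- factor(rep(letters[1:8], each = 4))
    y <- rnorm(32) + rep(rnorm(8, 0, 2), each = 4)
    panel <- FounderPanel(matrix(y, nrow = 1,
                                 dimnames = list("m", NULL)), strain)
    tab <- anovaDE(panel)
    # oracle: one-way ANOVA mean squares from aov(), then sigma ratios
    ms <- summary(stats::aov(y ~ strain))[[1]]$`Mean Sq`
    sb <- (ms[1] - ms[2]) / 4
    expect_equal(heritability(tab$MSB, tab$MSW, 4)$r1,
                 sb / (sb + ms[2]), tolerance = 1e-10)
    expect_equal(tab$MSB, ms[1], tolerance = 1e-10)
    expect_equal(tab$MSW, ms[2], tolerance = 1e-10)
})

test_that("expression filters enforce the percentile and fold rules", {
    # 120 miRNAs: 28 constant (not DE), 38 designed to pass both filters,
    # 30 DE failing the fold rule, 24 DE failing the percentile rule.
    nm <- c(sprintf("null%02d", 1:28), sprintf("pass%02d", 1:38),
            sprintf("foldfail%02d", 1:30), sprintf("pctfail%02d", 1:24))
    sm <- matrix(0, nrow = 8, ncol = 120, dimnames = list(.CCF, nm))
    sm[, 1:28] <- rep(5 + (1:28) * 0.01, each = 8)
    for (k in 1:38) {                      # high in one strain, fold 1
        sm[, 28 + k] <- 11
        sm[(k %% 8) + 1, 28 + k] <- 12
    }
    for (k in 1:30) {                      # fold 0.3 < log2(1.5)
        sm[, 66 + k] <- 8
        sm[(k %% 8) + 1, 66 + k] <- 8.3
    }
    for (k in 1:24) {                      # fold ok but low everywhere
        sm[, 96 + k] <- 1
        sm[(k %% 8) + 1, 96 + k] <- 2.5
    }
    panel <- designedPanel(sm, noise = 0)
    tab <- suppressWarnings(anovaDE(panel))
    expect_equal(sum(tab$differential), 92)
    scr <- filterExpressed(tab, panel)
    expect_equal(sum(scr$selected), 38)
    expect_true(all(grepl("^pass", scr$mirna[scr$selected])))
    expect_false(any(scr$selected[grepl("foldfail", scr$mirna)]))
    expect_false(any(scr$selected[grepl("pctfail", scr$mirna)]))
    # selected implies all three flags
    expect_true(all((!scr$selected) |
        (scr$differential & scr$highExpression & scr$foldRange)))
    # idempotent and order-independent
    perm <- sample(nrow(tab))
    scr2 <- filterExpressed(tab[perm, ], panel)
    expect_equal(scr2$selected[order(scr2$mirna)],
                 scr$selected[order(scr$mirna)])
})

test_that("reference selection picks the non-DE miRNA nearest the mean", {
    # selected miRNAs average 7.3; candidates at 7.1, 6.0, 9.0
    nm <- c(sprintf("sel%02d", 1:10), "cand71", "cand60", "cand90")
    sm <- matrix(0, nrow = 8, ncol = 13, dimnames = list(.CCF, nm))
    for (k in 1:10) { sm[, k] <- 7.3; sm[(k %% 8) + 1, k] <- 7.3 + 1 }
    sm[, 1:10] <- sm[, 1:10] - 0.1          # strain means average 7.3
    sm[, "cand71"] <- 7.1
    sm[, "cand60"] <- 6.0
    sm[, "cand90"] <- 9.0
    panel <- designedPanel(sm, noise = 0)
    tab <- suppressWarnings(anovaDE(panel))
    scr <- filterExpressed(tab, panel, percentile = 0.5, fold = 1.2)
    grand <- mean(colMeans(sm[, scr$selected[match(nm, scr$mirna)]]))
    ref <- selectReference(scr, panel)
    expect_equal(as.character(ref), "cand71")
    expect_lt(abs(attr(ref, "grandMean") - grand), 1e-6)
    # tie in distance: lexicographically smallest id
    sm2 <- sm
    gm <- attr(ref, "grandMean")
    sm2[, "cand60"] <- gm - 0.2
    sm2[, "cand71"] <- gm + 0.2
    sm2[, "cand90"] <- 9.0
    panel2 <- designedPanel(sm2, noise = 0)
    tab2 <- suppressWarnings(anovaDE(panel2))
    scr2 <- filterExpressed(tab2, panel2, percentile = 0.5, fold = 1.2)
    expect_equal(as.character(selectReference(scr2, panel2)), "cand60")
})

test_that("delta-Ct normalisation is the stated arithmetic", {
    ct <- matrix(c(25, 20, 30,
                   24, 21, 28), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("mirA", "ref", "mirB")))
    d <- deltaCt(ct, "ref")
    expect_equal(d["s1", "mirA"], -5)
    expect_equal(unname(d[, "ref"]), c(0, 0))      # identity
    # sample missing the reference is dropped with a warning
    ct2 <- ct; ct2["s2", "ref"] <- NA
    expect_warning(d2 <- deltaCt(ct2, "ref"), "dropping")
    expect_equal(rownames(d2), "s1")
    # two references differ by a per-sample shift: correlations over
    # samples of the shifted tables agree
    set.seed(41)
    ct3 <- matrix(rnorm(60, 25), nrow = 6,
                  dimnames = list(paste0("s", 1:6),
                                  c(paste0("m", 1:8), "r1", "r2")))
    dA <- deltaCt(ct3, "r1"); dB <- deltaCt(ct3, "r2")
    shift <- ct3[, "r2"] - ct3[, "r1"]
    expect_equal(dA[, "m1"], dB[, "m1"] - shift)
})

test_that("strain clustering groups replicates of the same strain", {
    cfg <- simConfig(seed = 51, panelSpec = list(
        nMirnas = 80L, icc = 0.95, fracNull = 0, meanRange = c(4, 12)))
    panel <- simulateFounderPanel(cfg)
    hc <- clusterStrains(panel)
    grp <- stats::cutree(hc, k = 8)
    strain <- as.character(strainLabels(panel))
    pure <- vapply(unique(strain), function(s)
        length(unique(grp[strain == s])) == 1L, TRUE)
    expect_gte(sum(pure), 7)
    # identical samples merge first at distance 0
    X <- matrix(rnorm(40), nrow = 10,
                dimnames = list(paste0("m", 1:10), paste0("x", 1:4)))
    X[, 2] <- X[, 1]
    pan2 <- FounderPanel(X, factor(c("a", "a", "b", "b")))
    hc2 <- clusterStrains(pan2)
    expect_equal(min(hc2$height), 0, tolerance = 1e-12)
    expect_setequal(abs(hc2$merge[1, ]), c(1, 2))
    # anti-correlated pair sits at the maximal distance 2
    Y <- cbind(a1 = 1:10 + 0, a2 = -(1:10) + 0)
    rownames(Y) <- paste0("m", 1:10)
    Y <- Y + matrix(rnorm(20, 0, 1e-6), 10)
    pan3 <- FounderPanel(Y, factor(c("a", "a")))
    expect_equal(max(stats::cophenetic(clusterStrains(pan3))), 2,
                 tolerance = 1e-3)
    # constant sample vector is an error naming the sample
    Z <- matrix(rnorm(20), 10); Z[, 2] <- 3
    colnames(Z) <- c("ok", "flat"); rownames(Z) <- paste0("m", 1:10)
    expect_error(clusterStrains(FounderPanel(Z, factor(c("a", "a")))),
                 "flat")
})
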