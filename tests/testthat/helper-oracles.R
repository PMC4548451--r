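# Independent oracles and fixture builders shared across test files.

# Small, fast default configuration for module tests.
smallConfig <- function(seed = 1L, nLines = 40L, nMarkers = 25L,
                        recombRate = 1,
                        plantedEqtl = list(list(
                            mirna = "mir-planted-1", locus = 10L,
                            effects = c(0, 0, 0, -2, 0, -2, 0, 0),
                            h2 = 0.6)), ...) {
    simConfig(nLines = nLines, seed = seed, recombRate = recombRate,
              chromosomes = data.frame(
                  name = c("1", "2"), length_bp = c(1e8, 8e7),
                  n_markers = c(nMarkers, nMarkers),
                  stringsAsFactors = FALSE),
              plantedEqtl = plantedEqtl,
              nMrna = 500L, nMirnasMeasured = 5L, ...)
}

# Brute-force per-locus OLS likelihood-ratio LOD via lm(); the oracle the
# fast QR engine must match.
lodOracle <- function(y, hap, covariates = NULL) {
    d <- dosageArray(hap)
    n <- length(y)
    X0 <- if (is.null(covariates)) matrix(1, n, 1) else
        cbind(1, covariates)
    rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
    vapply(seq_len(nrow(lociTable(hap))), function(l) {
        X1 <- cbind(X0, d[, l, -1])
        fit <- stats::lm.fit(X1, y)
        rss1 <- sum(fit$residuals^2)
        max((n / 2) * log10(rss0 / rss1), 0)
    }, 0)
}

# Benjamini-Hochberg step-up, written out from the definition.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    out <- numeric(m)
    out[o] <- pmin(q, 1)
    out
}

# Per-SNP predicate scan for strain-distribution-pattern filtering.
sdpOracle <- function(snps, grouping) {
    keep <- logical(nrow(snps))
    for (i in seq_len(nrow(snps))) {
        ga <- unlist(snps[i, grouping$groupA])
        gb <- unlist(snps[i, grouping$groupB])
        ok <- all(c(ga, gb) %in% c("ref", "alt")) &&
            length(unique(ga)) == 1L && length(unique(gb)) == 1L &&
            ga[1] != gb[1]
        keep[i] <- ok
    }
    snps[keep, , drop = FALSE]
}

# Nested-loop SNP-to-gene assignment.
annotateOracle <- function(snps, genes, flank = 5000) {
    rows <- list()
    for (i in seq_len(nrow(snps))) {
        hit <- FALSE
        for (j in seq_len(nrow(genes))) {
            if (snps$chrom[i] == genes$chrom[j] &&
                snps$pos[i] >= genes$start[j] - flank &&
                snps$pos[i] <= genes$end[j] + flank) {
                rows[[length(rows) + 1L]] <- data.frame(
                    chrom = snps$chrom[i], pos = snps$pos[i],
                    gene = genes$gene[j], stringsAsFactors = FALSE)
                hit <- TRUE
            }
        }
        if (!hit)
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = snps$chrom[i], pos = snps$pos[i],
                gene = "intergenic", stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

# Exhaustive hypergeometric upper tail by enumerating draw compositions.
overlapOracle <- function(nA, nB, k, U) {
    tot <- choose(U, nB)
    sum(vapply(k:min(nA, nB), function(i)
        choose(nA, i) * choose(U - nA, nB - i), 0)) / tot
}

.CCF <- c("A/J", "C57BL/6J", "129S1/SvImJ", "NOD/ShiLtJ",
          "NZO/H1LtJ", "PWK/PhJ", "CAST/EiJ", "WSB/EiJ")

# SNP table for a candidate interval: exactly nMatch SNPs carry the
# NOD/PWK-vs-rest pattern; decoys carry near-miss patterns (het in group,
# non-concordant groups, low-confidence calls).
snpFixture <- function(nMatch = 938L, nDecoy = 1200L, seed = 11L,
                       chrom = "12", lo = 108668025, hi = 110004769) {
    set.seed(seed)
    n <- nMatch + nDecoy
    pos <- sort(sample(seq(lo, hi), n))
    g <- matrix("ref", nrow = n, ncol = 8, dimnames = list(NULL, .CCF))
    grpA <- c("NOD/ShiLtJ", "PWK/PhJ")
    g[seq_len(nMatch), grpA] <- "alt"
    for (i in (nMatch + 1L):n) {
        kind <- sample(4L, 1L)
        if (kind == 1L) {                       # het inside group A
            g[i, grpA] <- c("alt", "het")
        } else if (kind == 2L) {                # group B not concordant
            g[i, grpA] <- "alt"
            g[i, "WSB/EiJ"] <- "alt"
        } else if (kind == 3L) {                # low-confidence call
            g[i, grpA] <- "alt"
            g[i, "A/J"] <- "low_confidence"
        } else {                                # no split at all
            g[i, ] <- "ref"
        }
    }
    perm <- sample.int(n)
    cbind(data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE),
          as.data.frame(g, stringsAsFactors = FALSE))[perm, ]
}

# Founder panel with designed strain means and near-zero noise, for
# deterministic screen/filter behaviour.
designedPanel <- function(strainMeans, nRep = 4L, noise = 0.005,
                          seed = 3L) {
    set.seed(seed)
    founders <- rownames(strainMeans)
    strain <- factor(rep(founders, each = nRep), levels = founders)
    expr <- t(strainMeans[as.integer(strain), , drop = FALSE])
    expr <- expr + matrix(stats::rnorm(length(expr), 0, noise),
                          nrow = nrow(expr))
    colnames(expr) <- sprintf("%s_r%d", gsub("/", ".", strain),
                              rep(seq_len(nRep), times = length(founders)))
    FounderPanel(expr, strain)
}
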