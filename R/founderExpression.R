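#' Per-miRNA one-way ANOVA across founder strains
#'
#' Fits the fixed-effects one-way ANOVA of log2 expression on strain for
#' every miRNA in the panel and adjusts p-values across miRNAs by
#' Benjamini-Hochberg. A miRNA that is constant across all samples has no
#' defined F ratio; its p-value is set to 1 by convention, with a warning.
#' The replicate count `n` reported per miRNA is the harmonic mean of
#' per-strain replicate counts, the standard choice for intraclass
#' correlation under mild imbalance (e.g. after outlier-array removal).
#'
#' @param panel a [FounderPanel-class].
#' @param qThreshold BH q-value cut-off for the `differential` flag
#'   (default 0.05).
#' @return data.frame, one row per miRNA: `mirna`, `MSB`, `MSW`, `n`, `F`,
#'   `p`, `q`, `differential`.
#' @examples
#' cfg <- simConfig(seed = 5)
#' tab <- anovaDE(simulateFounderPanel(cfg))
#' head(tab)
#' @export
anovaDE <- function(panel, qThreshold = 0.05) {
    stopifnot(is(panel, "FounderPanel"))
    expr <- exprValues(panel)
    strain <- droplevels(factor(strainLabels(panel)))
    if (nlevels(strain) < 2L)
        stop("need >= 2 strains for the ANOVA screen")
    ns <- as.numeric(table(strain))
    N <- ncol(expr)
    S <- nlevels(strain)
    grp <- as.integer(strain)
    # strain means per miRNA via rowsum on the transposed matrix
    sums <- rowsum(t(expr), grp)                    # S x miRNA
    means <- sums / ns
    grand <- colMeans(t(expr))
    ssb <- colSums(ns * (t(t(means) - grand))^2)
    sst <- colSums((t(expr) - rep(grand, each = N))^2)
    ssw <- pmax(sst - ssb, 0)
    msb <- ssb / (S - 1)
    msw <- ssw / (N - S)
    Fstat <- msb / msw
    p <- stats::pf(Fstat, S - 1, N - S, lower.tail = FALSE)
    degenerate <- ssb < 1e-12 & ssw < 1e-12
    if (any(degenerate)) {
        warning(sum(degenerate), " constant miRNA(s); p set to 1")
        p[degenerate] <- 1
        Fstat[degenerate] <- NA_real_
    }
    sep <- msw < 1e-12 & msb > 1e-12   # perfect separation
    p[sep] <- 0
    q <- stats::p.adjust(p, method = "BH")
    nH <- S / sum(1 / ns)
    data.frame(mirna = rownames(expr), MSB = msb, MSW = msw, n = nH,
               F = Fstat, p = p, q = q, differential = q < qThreshold,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Broad-sense heritability from ANOVA mean squares
#'
#' The interclass correlation and the coefficient of genetic determination:
#' \deqn{r_1 = (MSB - MSW) / (MSB + (n - 1) MSW)}
#' \deqn{g^2 = (MSB - MSW) / (MSB + (2n - 1) MSW)}
#' where MSB and MSW are the between- and within-strain mean squares of a
#' one-way ANOVA over inbred strains and n is the number of mice per strain.
#' g2 corrects for the doubling of additive genetic variance under
#' inbreeding, so g2 <= r1 whenever MSB >= MSW.
#'
#' @param MSB between-strain mean square(s), >= 0 (vectorised).
#' @param MSW within-strain mean square(s), >= 0.
#' @param n mice per strain (harmonic mean if unbalanced), >= 1.
#' @return data.frame with columns `r1` and `g2`.
#' @examples
#' heritability(10, 2, 4)   # r1 = 0.5, g2 = 1/3
#' @export
heritability <- function(MSB, MSW, n) {
    if (any(MSB < 0) || any(MSW < 0) || any(n < 1))
        stop("MSB, MSW must be >= 0 and n >= 1")
    k <- max(length(MSB), length(MSW), length(n))
    MSB <- rep_len(MSB, k); MSW <- rep_len(MSW, k); n <- rep_len(n, k)
    if (any(MSB == 0 & MSW == 0))
        stop("degenerate input: MSB and MSW both zero")
    data.frame(r1 = (MSB - MSW) / (MSB + (n - 1) * MSW),
               g2 = (MSB - MSW) / (MSB + (2 * n - 1) * MSW))
}

#' Expression and fold-range filters on the DE screen
#'
#' Flags each screened miRNA as highly expressed (its strain mean reaches
#' the 80th percentile of all miRNA strain means within at least one
#' strain), as sufficiently variable (highest minus lowest strain mean at
#' least log2(fold) on the log2 scale, i.e. a `fold`-times range on the raw
#' scale), and as selected when it is differential and passes both filters.
#'
#' @param screen output of [anovaDE()].
#' @param panel the [FounderPanel-class] the screen was computed on.
#' @param percentile expression percentile applied within each strain
#'   (default 0.80).
#' @param fold minimum max/min strain-mean ratio (default 1.5).
#' @return data.frame with flags `differential`, `highExpression`,
#'   `foldRange`, `selected`; the strain-mean matrix is attached as
#'   attribute `"strainMeans"` (strains x miRNAs).
#' @export
filterExpressed <- function(screen, panel, percentile = 0.80, fold = 1.5) {
    stopifnot(is(panel, "FounderPanel"))
    expr <- exprValues(panel)
    if (ncol(expr) == 0L || nrow(expr) == 0L) stop("empty panel")
    if (!all(screen$mirna %in% rownames(expr)))
        stop("panel does not cover all screened miRNAs")
    expr <- expr[screen$mirna, , drop = FALSE]
    strain <- droplevels(factor(strainLabels(panel)))
    sm <- rowsum(t(expr), as.integer(strain)) /
        as.numeric(table(strain))                 # strains x miRNAs
    rownames(sm) <- levels(strain)
    thr <- apply(sm, 1L, stats::quantile, probs = percentile)
    high <- colSums(sm >= thr) > 0L
    frange <- apply(sm, 2L, max) - apply(sm, 2L, min)
    foldOk <- frange >= log2(fold) - 1e-12
    out <- data.frame(mirna = screen$mirna,
                      differential = screen$differential,
                      highExpression = unname(high),
                      foldRange = unname(foldOk),
                      selected = screen$differential & high & foldOk,
                      stringsAsFactors = FALSE)
    attr(out, "strainMeans") <- sm
    out
}

#' Choose a reference miRNA for qPCR normalisation
#'
#' Among miRNAs not differentially expressed by strain, returns the one
#' whose overall mean expression is closest to the grand mean of the
#' selected (differential + highly expressed + variable) miRNAs, so that
#' the reference sits in the abundance range of the miRNAs it normalises.
#' Ties go to the lexicographically smallest identifier.
#'
#' @param screen output of [filterExpressed()] (needs `differential` and
#'   `selected` flags).
#' @param panel the [FounderPanel-class].
#' @return single miRNA id, with attributes `"mean"` (its overall mean) and
#'   `"grandMean"` (grand mean of the selected miRNAs).
#' @export
selectReference <- function(screen, panel) {
    stopifnot(is(panel, "FounderPanel"))
    expr <- exprValues(panel)[screen$mirna, , drop = FALSE]
    means <- rowMeans(expr)
    if (!any(screen$selected))
        stop("no miRNA passed selection; grand mean undefined")
    if (all(screen$differential))
        stop("all miRNAs are differentially expressed; ",
             "choose a reference manually")
    grand <- mean(means[screen$selected])
    cand <- screen$mirna[!screen$differential]
    d <- abs(means[cand] - grand)
    best <- cand[d == min(d)]
    ref <- sort(best)[1L]
    structure(ref, mean = unname(means[ref]), grandMean = grand)
}

#' Normalise qPCR Ct values to a reference miRNA
#'
#' Computes `-(Ct_miRNA - Ct_reference)` per sample, the -dCt scale on
#' which abundance increases with the value. Samples missing the reference
#' Ct are dropped with a warning.
#'
#' @param rawCt numeric matrix, samples (lines) x miRNAs, of raw Ct values.
#' @param reference reference miRNA id; must be a column of `rawCt`.
#' @return matrix of -dCt values (same shape, possibly fewer rows); the
#'   reference column is identically zero.
#' @export
deltaCt <- function(rawCt, reference) {
    if (!reference %in% colnames(rawCt))
        stop("reference miRNA ", reference, " not in the Ct table")
    refCt <- rawCt[, reference]
    bad <- is.na(refCt)
    if (any(bad)) {
        warning("dropping ", sum(bad), " sample(s) missing the reference Ct")
        rawCt <- rawCt[!bad, , drop = FALSE]
        refCt <- refCt[!bad]
    }
    -(rawCt - refCt)
}

#' Hierarchically cluster founder samples on miRNA expression
#'
#' Average-linkage clustering on correlation distance (1 - Pearson r)
#' between samples over the chosen miRNAs; used to check that samples group
#' by strain in a way consistent with strain phylogeny.
#'
#' @param panel a [FounderPanel-class].
#' @param mirnas miRNA ids to cluster on (default: all).
#' @return an [stats::hclust] object; leaf order in `$order`, labels are
#'   sample names.
#' @export
clusterStrains <- function(panel, mirnas = NULL) {
    stopifnot(is(panel, "FounderPanel"))
    expr <- exprValues(panel)
    if (!is.null(mirnas)) expr <- expr[mirnas, , drop = FALSE]
    if (ncol(expr) < 2L) stop("need >= 2 samples to cluster")
    sds <- apply(expr, 2L, stats::sd)
    if (any(sds == 0))
        stop("constant expression vector for sample(s): ",
             paste(colnames(expr)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(expr))
    stats::hclust(d, method = "average")
}
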