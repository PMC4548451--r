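#' Simulate a recombinant-inbred haplotype dosage matrix
#'
#' Draws each line's two haploid strands per chromosome by a Markov walk
#' along the marker index: a uniform starting founder, a Poisson number of
#' crossovers with breakpoints uniform on inter-marker gaps, and a uniform
#' new founder after each crossover. Dosages are the per-founder strand
#' counts (0/1/2); with `dosageBlur > 0` they are blurred by a Dirichlet
#' draw centred on the hard calls (mimicking probabilistic haplotype
#' reconstruction) while still summing to 2.
#'
#' @param cfg a [SimConfig-class].
#' @return a [HaplotypeDosage-class]; its `breakpoints` metadata lists, per
#'   chromosome, the gap indices at which any line's dosage actually changes
#'   (the population's effective recombination breakpoints).
#' @examples
#' hap <- simulatePopulation(simConfig(nLines = 20, seed = 3))
#' dim(dosageArray(hap))
#' @export
simulatePopulation <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    if (any(cfg@chromosomes$n_markers < 1L))
        stop("invalid config: every chromosome needs markers")
    set.seed(.childSeed(cfg@seed, "population"))
    nL <- cfg@nLines
    lines <- sprintf("line%03d", seq_len(nL))
    lociList <- list()
    dosList <- list()
    bkList <- list()
    for (ci in seq_len(nrow(cfg@chromosomes))) {
        chr <- cfg@chromosomes$name[ci]
        nm <- cfg@chromosomes$n_markers[ci]
        len <- cfg@chromosomes$length_bp[ci]
        pos <- floor(len * seq_len(nm) / nm)
        lociList[[ci]] <- data.frame(chrom = chr, pos = pos,
                                     stringsAsFactors = FALSE)
        dos <- array(0, dim = c(nL, nm, 8L))
        bset <- integer()
        for (l in seq_len(nL)) {
            fvecs <- matrix(0L, nrow = 2L, ncol = nm)
            for (strand in 1:2) {
                f <- sample.int(8L, 1L)
                fv <- rep(f, nm)
                if (nm > 1L && cfg@recombRate > 0) {
                    k <- stats::rpois(1L, cfg@recombRate)
                    if (k > 0L) {
                        gaps <- sort(unique(sample.int(nm - 1L, size = k,
                                                       replace = TRUE)))
                        for (g in gaps) {
                            nf <- sample.int(8L, 1L)
                            if (nf != fv[g + 1L]) {
                                fv[(g + 1L):nm] <- nf
                                bset <- c(bset, g)
                            }
                        }
                    }
                }
                fvecs[strand, ] <- fv
            }
            for (strand in 1:2)
                dos[cbind(l, seq_len(nm), fvecs[strand, ])] <-
                    dos[cbind(l, seq_len(nm), fvecs[strand, ])] + 1
        }
        if (cfg@dosageBlur > 0) {
            kappa <- 1 / cfg@dosageBlur
            for (l in seq_len(nL)) for (m in seq_len(nm)) {
                alpha <- (dos[l, m, ] + 0.01) * kappa
                g <- stats::rgamma(8L, shape = alpha)
                dos[l, m, ] <- 2 * g / sum(g)
            }
        }
        dosList[[ci]] <- dos
        bkList[[chr]] <- sort(unique(bset))
    }
    loci <- do.call(rbind, lociList)
    rownames(loci) <- NULL
    dosages <- array(0, dim = c(nL, nrow(loci), 8L),
                     dimnames = list(lines, NULL, cfg@founders))
    off <- 0L
    for (ci in seq_along(dosList)) {
        nm <- dim(dosList[[ci]])[2L]
        dosages[, off + seq_len(nm), ] <- dosList[[ci]]
        off <- off + nm
    }
    new("HaplotypeDosage", lines = lines, loci = loci,
        founders = cfg@founders, dosages = dosages, breakpoints = bkList)
}

#' Simulate per-line miRNA expression with planted eQTL
#'
#' For each planted eQTL the trait is `intercept + dosage %*% effects +`
#' Gaussian noise, with the noise variance chosen so the locus explains the
#' configured h2 fraction of trait variance (h2 = 0 gives pure noise). The
#' remaining measured miRNAs are pure noise. Values are on the -dCt scale
#' (higher = more abundant).
#'
#' @param hap a [HaplotypeDosage-class] from [simulatePopulation()].
#' @param cfg the same [SimConfig-class].
#' @return numeric matrix, lines x miRNAs, -dCt scale.
#' @export
simulateLineExpression <- function(hap, cfg) {
    stopifnot(is(hap, "HaplotypeDosage"), is(cfg, "SimConfig"))
    nLoci <- nrow(lociTable(hap))
    for (pe in cfg@plantedEqtl) {
        if (pe$locus < 1L || pe$locus > nLoci)
            stop("planted locus ", pe$locus, " not in the dosage matrix")
        if (is.null(pe$h2) || pe$h2 < 0 || pe$h2 >= 1)
            stop("invalid config: planted h2 must lie in [0, 1)")
    }
    set.seed(.childSeed(cfg@seed, "expression"))
    n <- length(lineIds(hap))
    planted <- vapply(cfg@plantedEqtl, `[[`, "", "mirna")
    nNull <- max(0L, cfg@nMirnasMeasured - length(unique(planted)))
    ids <- c(unique(planted), sprintf("mir-null-%02d", seq_len(nNull)))
    expr <- matrix(0, nrow = n, ncol = length(ids),
                   dimnames = list(lineIds(hap), ids))
    baseline <- -5
    genetic <- matrix(0, nrow = n, ncol = length(ids),
                      dimnames = list(NULL, ids))
    h2max <- stats::setNames(numeric(length(ids)), ids)
    for (pe in cfg@plantedEqtl) {
        g <- dosageArray(hap)[, pe$locus, ] %*% pe$effects
        genetic[, pe$mirna] <- genetic[, pe$mirna] + as.numeric(g)
        h2max[pe$mirna] <- max(h2max[pe$mirna], pe$h2)
    }
    for (j in seq_along(ids)) {
        g <- genetic[, j]
        h2 <- h2max[ids[j]]
        vg <- stats::var(g)
        if (h2 > 0 && vg > 0) {
            sd <- sqrt(vg * (1 - h2) / h2)
            expr[, j] <- baseline + g + stats::rnorm(n, 0, sd)
        } else {
            expr[, j] <- baseline + stats::rnorm(n, 0, cfg@noiseSd)
        }
    }
    expr
}

#' Simulate a founder strain replicate panel
#'
#' Per-miRNA strain effects are drawn so that the one-way ANOVA intraclass
#' correlation matches the configured ICC (`panelSpec$icc`); a configured
#' fraction of miRNAs (`panelSpec$fracNull`) has no strain effect at all.
#' Replicates are i.i.d. Gaussian within strain, total unit variance, on a
#' log2 array scale with baseline means uniform over `panelSpec$meanRange`.
#'
#' @param cfg a [SimConfig-class]; `nReplicates` must be >= 2.
#' @return a [FounderPanel-class]. `rowData` carries the true ICC per miRNA.
#' @export
simulateFounderPanel <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    if (cfg@nReplicates < 2L)
        stop("invalid config: nReplicates must be >= 2")
    set.seed(.childSeed(cfg@seed, "panel"))
    ps <- cfg@panelSpec
    nMir <- ps$nMirnas
    icc <- rep_len(ps$icc, nMir)
    nNull <- round(ps$fracNull * nMir)
    if (nNull > 0L) icc[seq_len(nNull)] <- 0
    ids <- sprintf("mir-sim-%03d", seq_len(nMir))
    strains <- factor(rep(cfg@founders, each = cfg@nReplicates),
                      levels = cfg@founders)
    nS <- length(strains)
    mu <- stats::runif(nMir, ps$meanRange[1L], ps$meanRange[2L])
    expr <- matrix(0, nrow = nMir, ncol = nS,
                   dimnames = list(ids, sprintf("%s_r%d",
                       gsub("/", ".", as.character(strains)),
                       rep(seq_len(cfg@nReplicates), times = 8L))))
    for (j in seq_len(nMir)) {
        a <- stats::rnorm(8L, 0, sqrt(icc[j]))
        e <- stats::rnorm(nS, 0, sqrt(1 - icc[j]))
        expr[j, ] <- mu[j] + a[as.integer(strains)] + e
    }
    FounderPanel(expr, strains, rowData = S4Vectors::DataFrame(
        trueICC = icc, row.names = ids))
}

#' Construct a FounderPanel
#'
#' @param expr numeric matrix, miRNAs x samples, log2 scale.
#' @param strain per-sample strain labels (coerced to factor).
#' @param rowData optional per-miRNA annotation.
#' @return a [FounderPanel-class].
#' @export
FounderPanel <- function(expr, strain, rowData = NULL) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = expr),
        colData = S4Vectors::DataFrame(strain = factor(strain)))
    if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
    new("FounderPanel", se)
}

#' Simulate granulocyte phenotypes and a phenotype-correlated mRNA layer
#'
#' Eosinophil and neutrophil counts are drawn log-normal per
#' `phenotypeSpec` and rounded to whole cells. A configured fraction of
#' mRNAs (`qttSpec$fraction` per phenotype, half positive / half negative
#' sign) has log-scale Pearson correlation of magnitude `qttSpec$r` with
#' `log(count + 1)`; the rest are independent noise.
#'
#' @param cfg a [SimConfig-class].
#' @param lines line identifiers (defaults to `line001..`).
#' @return list with `phenotypes` (data.frame `line`, `eosinophils`,
#'   `neutrophils`), `mrna` (lines x genes matrix, log2-like scale), and
#'   `truth` (per phenotype, the planted gene ids by sign).
#' @export
simulatePhenotypesAndMrna <- function(cfg,
                                      lines = sprintf("line%03d",
                                                      seq_len(cfg@nLines))) {
    stopifnot(is(cfg, "SimConfig"))
    if (abs(cfg@qttSpec$r) >= 1)
        stop("invalid config: correlation magnitude must be < 1")
    set.seed(.childSeed(cfg@seed, "phenotypes"))
    n <- length(lines)
    ph <- lapply(cfg@phenotypeSpec, function(p)
        round(stats::rlnorm(n, meanlog = p[["meanlog"]],
                            sdlog = p[["sdlog"]])))
    pheno <- data.frame(line = lines, ph, stringsAsFactors = FALSE,
                        check.names = FALSE)
    genes <- sprintf("gene%05d", seq_len(cfg@nMrna))
    mrna <- matrix(stats::rnorm(n * cfg@nMrna, mean = 8),
                   nrow = n, dimnames = list(lines, genes))
    r <- cfg@qttSpec$r
    kPer <- round(cfg@qttSpec$fraction * cfg@nMrna)
    truth <- list()
    used <- 0L
    for (pn in names(cfg@phenotypeSpec)) {
        z <- as.numeric(scale(log(pheno[[pn]] + 1)))
        idx <- used + seq_len(min(kPer, cfg@nMrna - used))
        used <- used + length(idx)
        sgn <- rep(c(1, -1), length.out = length(idx))
        for (k in seq_along(idx)) {
            j <- idx[k]
            mrna[, j] <- 8 + sgn[k] * r * z +
                sqrt(1 - r^2) * stats::rnorm(n)
        }
        truth[[pn]] <- list(positive = genes[idx[sgn > 0]],
                            negative = genes[idx[sgn < 0]])
    }
    list(phenotypes = pheno, mrna = mrna, truth = truth)
}

#' Simulate a TargetScan-style target-prediction table
#'
#' Background site counts per miRNA-gene pair are Poisson with mean
#' `targetSpec$sitesPerGeneMean`; the planted hub miRNA's mean is multiplied
#' by `targetSpec$enrichment` on the genes in `enrichedGenes` (typically the
#' phenotype-correlated set). Each site gets a type drawn from
#' `siteTypeFreq`, a uniform UTR position, and independent conservation
#' flags for rat/human/chicken with probability `consProb` each.
#'
#' @param cfg a [SimConfig-class].
#' @param enrichedGenes gene ids on which the hub miRNA is enriched (NULL
#'   for none).
#' @return data.frame with columns `mirna`, `gene`, `site_type`,
#'   `utr_position`, `conserved_species` (comma list, possibly empty).
#' @export
simulateTargetTable <- function(cfg, enrichedGenes = NULL) {
    stopifnot(is(cfg, "SimConfig"))
    ts <- cfg@targetSpec
    if (ts$enrichment < 1)
        stop("invalid config: enrichment factor must be >= 1")
    set.seed(.childSeed(cfg@seed, "targets"))
    genes <- sprintf("gene%05d", seq_len(cfg@nMrna))
    mirnas <- sprintf("mir-t%02d", seq_len(ts$nMirnas))
    if (!ts$hubMirna %in% mirnas)
        mirnas[1L] <- ts$hubMirna
    lam <- matrix(ts$sitesPerGeneMean, nrow = cfg@nMrna,
                  ncol = ts$nMirnas, dimnames = list(genes, mirnas))
    if (!is.null(enrichedGenes))
        lam[genes %in% enrichedGenes, ts$hubMirna] <-
            ts$sitesPerGeneMean * ts$enrichment
    counts <- stats::rpois(length(lam), as.numeric(lam))
    gi <- rep(rep(genes, times = ts$nMirnas), counts)
    mi <- rep(rep(mirnas, each = cfg@nMrna), counts)
    nSites <- length(gi)
    types <- sample(names(ts$siteTypeFreq), nSites, replace = TRUE,
                    prob = ts$siteTypeFreq)
    posn <- sample.int(ts$utrLength, nSites, replace = TRUE)
    cons <- vapply(seq_len(nSites), function(i) {
        sp <- c("rat", "human", "chicken")[
            stats::runif(3L) < ts$consProb]
        paste(sp, collapse = ",")
    }, "")
    data.frame(mirna = mi, gene = gi, site_type = types,
               utr_position = posn, conserved_species = cons,
               stringsAsFactors = FALSE)
}
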