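#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.CC_FOUNDERS <- c("A/J", "C57BL/6J", "129S1/SvImJ", "NOD/ShiLtJ",
                  "NZO/H1LtJ", "PWK/PhJ", "CAST/EiJ", "WSB/EiJ")

#' Simulation configuration
#'
#' Holds every parameter of the synthetic-data generator: population size and
#' marker map, recombination rate, planted eQTL, founder-panel replicate
#' structure, phenotype distributions, the quantitative-trait-transcript
#' fraction, and the target-prediction table layout. Construct with
#' [simConfig()]; all downstream generators take a validated `SimConfig`.
#'
#' @slot nLines number of recombinant-inbred lines.
#' @slot founders ordered founder strain names; the first is the regression
#'   reference strain.
#' @slot chromosomes data.frame with columns `name`, `length_bp`, `n_markers`.
#' @slot recombRate expected crossovers per chromosome per haploid strand.
#' @slot nReplicates replicate mice per founder strain in the array panel.
#' @slot plantedEqtl list of planted eQTL, each a list with elements `mirna`,
#'   `locus` (row index into the locus table), `effects` (length-8 numeric)
#'   and `h2` (fraction of line variance explained by the locus).
#' @slot phenotypeSpec log-normal `meanlog`/`sdlog` per phenotype.
#' @slot nMrna number of mRNA genes simulated (also the hub-analysis universe).
#' @slot qttSpec list with `fraction` of mRNAs correlated with each phenotype
#'   and target correlation magnitude `r`.
#' @slot targetSpec target-prediction table layout (see [simConfig()]).
#' @slot panelSpec founder-panel layout (see [simConfig()]).
#' @slot nMirnasMeasured number of miRNAs in the per-line qPCR table.
#' @slot noiseSd residual standard deviation on the -dCt scale.
#' @slot dosageBlur Dirichlet blur level for dosages; 0 keeps hard 0/1/2 calls.
#' @slot seed master integer seed; all sub-generators derive child seeds.
#' @export
setClass("SimConfig", representation(
    nLines = "integer",
    founders = "character",
    chromosomes = "data.frame",
    recombRate = "numeric",
    nReplicates = "integer",
    plantedEqtl = "list",
    phenotypeSpec = "list",
    nMrna = "integer",
    qttSpec = "list",
    targetSpec = "list",
    panelSpec = "list",
    nMirnasMeasured = "integer",
    noiseSd = "numeric",
    dosageBlur = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nLines < 8L)
        msg <- c(msg, "nLines must be >= 8")
    if (length(object@founders) != 8L || anyDuplicated(object@founders))
        msg <- c(msg, "founders must be 8 distinct strain names")
    ch <- object@chromosomes
    if (!all(c("name", "length_bp", "n_markers") %in% names(ch)))
        msg <- c(msg, "chromosomes needs columns name, length_bp, n_markers")
    else if (any(ch$n_markers < 1L))
        msg <- c(msg, "every chromosome needs at least one marker")
    if (object@recombRate < 0)
        msg <- c(msg, "recombRate must be non-negative")
    if (object@nReplicates < 2L)
        msg <- c(msg, "nReplicates must be >= 2 (within-strain variance)")
    for (pe in object@plantedEqtl) {
        if (length(pe$effects) != 8L)
            msg <- c(msg, "each planted effect vector must have length 8")
        if (!is.null(pe$h2) && (pe$h2 < 0 || pe$h2 >= 1))
            msg <- c(msg, "planted h2 must lie in [0, 1)")
    }
    if (abs(object@qttSpec$r) >= 1)
        msg <- c(msg, "qttSpec$r must have magnitude < 1")
    if (object@targetSpec$enrichment < 1)
        msg <- c(msg, "target enrichment factor must be >= 1")
    if (object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be positive")
    if (length(msg)) msg else TRUE
})

#' Haplotype dosage matrix
#'
#' Per-line, per-locus expected counts of each of the eight founder
#' haplotypes. Every line-by-locus dosage vector is non-negative and sums to
#' 2 (diploid expectation); locus positions are 1-based bp, strictly
#' increasing within a chromosome.
#'
#' @slot lines character vector of line identifiers.
#' @slot loci data.frame with columns `chrom` and `pos` (1-based bp).
#' @slot founders the eight founder names, reference first.
#' @slot dosages numeric array, lines x loci x founders.
#' @slot breakpoints list (one element per chromosome) of inter-marker gap
#'   indices at which the simulated population recombines; empty for
#'   matrices read from disk.
#' @export
setClass("HaplotypeDosage", representation(
    lines = "character",
    loci = "data.frame",
    founders = "character",
    dosages = "array",
    breakpoints = "list"))

setValidity("HaplotypeDosage", function(object) {
    msg <- character()
    d <- object@dosages
    if (length(dim(d)) != 3L)
        return("dosages must be a 3-d array (lines x loci x founders)")
    if (dim(d)[1L] != length(object@lines))
        msg <- c(msg, "first dosage dimension must match lines")
    if (dim(d)[2L] != nrow(object@loci))
        msg <- c(msg, "second dosage dimension must match loci")
    if (dim(d)[3L] != length(object@founders))
        msg <- c(msg, "third dosage dimension must match founders")
    if (any(d < -1e-9))
        msg <- c(msg, "dosages must be non-negative")
    if (length(msg) == 0L) {
        sums <- apply(d, c(1L, 2L), sum)
        if (any(abs(sums - 2) > 1e-6))
            msg <- c(msg, "each line x locus dosage vector must sum to 2")
        for (chr in unique(object@loci$chrom)) {
            p <- object@loci$pos[object@loci$chrom == chr]
            if (any(diff(p) <= 0))
                msg <- c(msg, sprintf(
                    "positions not strictly increasing on chromosome %s", chr))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Founder strain expression panel
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the founder
#' replicate panel: miRNAs in rows, samples in columns, log2-scale values in
#' the `exprs` assay, and the strain label in `colData(x)$strain`. Every
#' strain must have at least two replicates so the one-way ANOVA is defined.
#'
#' @export
setClass("FounderPanel", contains = "SummarizedExperiment")

setValidity("FounderPanel", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if (!"strain" %in% names(cd))
        return("colData must contain a 'strain' column")
    strain <- cd$strain
    if (any(is.na(strain)) || any(strain == ""))
        return("strain labels must be complete")
    if (any(table(strain) < 2L))
        return("every strain needs >= 2 replicates")
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        return("assay 'exprs' is required")
    TRUE
})

#' Single-locus haplotype regression fit
#'
#' Ordinary least squares of a trait on the seven non-reference founder
#' dosage columns plus an intercept. Effects are expressed relative to the
#' reference founder (whose effect is implicitly zero). `r2` is the model
#' R-squared, reported as the locus narrow-sense heritability.
#'
#' @slot intercept fitted intercept.
#' @slot effects named length-7 numeric, per-founder effects relative to the
#'   reference; `NA` for founders aliased at the locus.
#' @slot rss residual sum of squares.
#' @slot r2 model R-squared in [0, 1].
#' @slot n number of lines used.
#' @slot aliased names of founders dropped for rank deficiency.
#' @export
setClass("QtlFit", representation(
    intercept = "numeric", effects = "numeric", rss = "numeric",
    r2 = "numeric", n = "integer", aliased = "character"))

setValidity("QtlFit", function(object) {
    if (length(object@effects) != 7L)
        return("effects must have length 7 (non-reference founders)")
    if (!is.na(object@r2) && (object@r2 < -1e-8 || object@r2 > 1 + 1e-8))
        return("r2 must lie in [0, 1]")
    TRUE
})

#' Genome scan result for one miRNA
#'
#' LOD curve over collapsed intervals with the peak, its permutation-adjusted
#' genome-wide p-value, the 1.5-LOD-drop support interval, the haplotype
#' effect fit at the peak, and the local/distal classification when the
#' cognate gene position is known.
#'
#' @slot mirna miRNA identifier.
#' @slot lod LOD score per locus (NA where a locus was skipped).
#' @slot loci the locus table the curve is indexed by.
#' @slot peakIndex row index of the peak locus (leftmost on ties).
#' @slot adjP permutation-adjusted genome-wide p-value (NA if no permutations
#'   were run).
#' @slot thresholds named genome-wide LOD thresholds (e.g. "0.05", "0.1").
#' @slot nullMax permutation null maxima the thresholds derive from.
#' @slot support one-row data.frame `chrom`,`start`,`end`: the LOD-drop
#'   support interval.
#' @slot fit [QtlFit-class] at the peak.
#' @slot classification "local", "distal" or NA when the gene is unplaced.
#' @export
setClass("ScanResult", representation(
    mirna = "character", lod = "numeric", loci = "data.frame",
    peakIndex = "integer", adjP = "numeric", thresholds = "numeric",
    nullMax = "numeric", support = "data.frame", fit = "ANY",
    classification = "character"))

setValidity("ScanResult", function(object) {
    if (any(object@lod < -1e-9, na.rm = TRUE))
        return("LOD scores must be non-negative")
    if (length(object@peakIndex) == 1L && nrow(object@support) == 1L) {
        pk <- object@loci[object@peakIndex, ]
        s <- object@support
        if (s$chrom != pk$chrom || pk$pos < s$start || pk$pos > s$end)
            return("support interval must contain the peak")
    }
    TRUE
})

#' Permutation-derived genome-wide significance thresholds
#'
#' Null distribution of genome-wide maximum LOD scores obtained by permuting
#' trait values over lines, with thresholds at the requested adjusted-p
#' levels and the add-one adjusted p-value of the observed peak.
#'
#' @slot nullMax genome-wide max LOD per permutation.
#' @slot thresholds named LOD thresholds (empirical upper quantiles).
#' @slot adjP adjusted p of the observed maximum, (1 + #\{null >= obs\}) /
#'   (1 + nPerm).
#' @slot observedMax observed genome-wide maximum LOD.
#' @slot nPerm number of permutations.
#' @export
setClass("PermutationThresholds", representation(
    nullMax = "numeric", thresholds = "numeric", adjP = "numeric",
    observedMax = "numeric", nPerm = "integer"))

setValidity("PermutationThresholds", function(object) {
    if (length(object@thresholds) >= 2L) {
        a <- suppressWarnings(as.numeric(names(object@thresholds)))
        if (!any(is.na(a)) && is.unsorted(a)) {
        } # threshold ordering checked below on sorted alphas
    }
    th <- object@thresholds
    a <- suppressWarnings(as.numeric(names(th)))
    if (!any(is.na(a)) && length(th) >= 2L) {
        o <- order(a)
        if (any(diff(th[o]) > 1e-9))
            return("thresholds must be non-increasing in alpha")
    }
    TRUE
})

#' Monte Carlo target-hub result
#'
#' Per-miRNA observed target score on a gene list, the null score
#' distribution over random same-size gene lists, the add-one empirical
#' p-value, and its Benjamini-Hochberg q-value across the tested miRNAs.
#'
#' @slot table data.frame with columns `mirna`, `observed`, `p`, `q`.
#' @slot nullScores matrix, null draws x miRNAs.
#' @slot geneList the gene list scored.
#' @slot nNull number of random gene lists drawn.
#' @export
setClass("HubResult", representation(
    table = "data.frame", nullScores = "matrix", geneList = "character",
    nNull = "integer"))

setValidity("HubResult", function(object) {
    tb <- object@table
    if (!all(c("mirna", "observed", "p", "q") %in% names(tb)))
        return("table needs columns mirna, observed, p, q")
    if (any(tb$p <= 0) || any(tb$p > 1))
        return("empirical p must lie in (0, 1]")
    if (nrow(object@nullScores) != object@nNull)
        return("nullScores must have nNull rows")
    TRUE
})
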