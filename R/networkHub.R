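#' Identify quantitative trait transcripts / miRNAs
#'
#' Pearson-correlates every feature (gene or miRNA) with a log-transformed
#' phenotype (`log(count + 1)`, admitting zero counts), computes the
#' textbook t-distributed p-value, and adjusts across features by
#' Benjamini-Hochberg. Features significant at the FDR cut-off form the
#' quantitative-trait set, split by correlation sign. Zero-variance
#' features are excluded with a warning.
#'
#' @param expr numeric matrix, lines x features.
#' @param pheno data.frame with a `line` column and phenotype count
#'   columns; rows are matched to `rownames(expr)` by line id.
#' @param phenotype name of the phenotype column.
#' @param fdr BH q cut-off (default 0.1).
#' @param logTransform log-transform the counts (default TRUE).
#' @return data.frame `feature`, `r`, `p`, `q`, `sign`, `significant`.
#' @export
quantitativeTraits <- function(expr, pheno, phenotype, fdr = 0.1,
                               logTransform = TRUE) {
    if (!phenotype %in% names(pheno))
        stop("phenotype column ", phenotype, " not found")
    idx <- match(rownames(expr), pheno$line)
    if (any(is.na(idx)))
        stop("expression lines missing from the phenotype table")
    x <- pheno[[phenotype]][idx]
    if (logTransform) x <- log(x + 1)
    n <- length(x)
    if (n < 3L) stop("need >= 3 paired observations")
    sds <- apply(expr, 2L, stats::sd)
    if (any(sds == 0)) {
        warning("excluding ", sum(sds == 0), " zero-variance feature(s)")
        expr <- expr[, sds > 0, drop = FALSE]
    }
    r <- as.numeric(stats::cor(expr, x))
    df <- n - 2L
    tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[abs(r) >= 1 - 1e-15] <- 0
    q <- stats::p.adjust(p, method = "BH")
    data.frame(feature = colnames(expr), r = r, p = p, q = q,
               sign = sign(r), significant = q < fdr,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Pair opposite-sign quantitative trait transcripts and miRNAs
#'
#' For one phenotype, pairs the positively correlated genes with the
#' negatively correlated miRNAs and vice-versa — the sign structure
#' expected if the miRNAs repress the transcripts.
#'
#' @param qttGenes [quantitativeTraits()] table for mRNAs.
#' @param qttMirnas [quantitativeTraits()] table for miRNAs.
#' @return list of two pairings, `posGenes_negMirnas` and
#'   `negGenes_posMirnas`, each with `genes`, `mirnas` and an `empty` flag.
#' @export
pairOpposite <- function(qttGenes, qttMirnas) {
    pick <- function(tab, s)
        tab$feature[tab$significant & tab$sign == s]
    mk <- function(g, m) list(genes = g, mirnas = m,
                              empty = length(g) == 0L || length(m) == 0L)
    list(posGenes_negMirnas = mk(pick(qttGenes, 1), pick(qttMirnas, -1)),
         negGenes_posMirnas = mk(pick(qttGenes, -1), pick(qttMirnas, 1)))
}

# Per-(miRNA, gene) target scores: conservation-eligible sites weighted by
# seed-match class, with a multiplier for sites clustered within `window`
# nt of another eligible site of the same miRNA in the same UTR.
.perGeneScores <- function(targets, conservation = 1L,
                           weights = c("8mer" = 3, "7mer-m8" = 2,
                                       "7mer-A1" = 1),
                           window = 35, multiplier = 1.5) {
    unknown <- setdiff(unique(targets$site_type), names(weights))
    if (length(unknown))
        stop("unknown site type(s): ", paste(unknown, collapse = ", "))
    nCons <- ifelse(targets$conserved_species == "", 0L,
                    lengths(strsplit(targets$conserved_species, ",",
                                     fixed = TRUE)))
    el <- targets[nCons >= conservation, , drop = FALSE]
    if (nrow(el) == 0L)
        return(data.frame(mirna = character(), gene = character(),
                          score = numeric(), stringsAsFactors = FALSE))
    key <- paste(el$mirna, el$gene, sep = "\r")
    w <- unname(weights[el$site_type])
    mult <- rep(1, nrow(el))
    o <- order(key, el$utr_position)
    ko <- key[o]; po <- el$utr_position[o]
    same <- ko == c("", ko[-length(ko)])
    nearPrev <- same & c(FALSE, diff(po) <= window)[seq_along(po)]
    # a site is clustered if within `window` of its previous OR next
    # eligible site in the same miRNA/gene
    nearNext <- c(nearPrev[-1L], FALSE)
    clustered <- nearPrev | nearNext
    mult[o] <- ifelse(clustered, multiplier, 1)
    sc <- rowsum(w * mult, key)
    parts <- strsplit(rownames(sc), "\r", fixed = TRUE)
    data.frame(mirna = vapply(parts, `[[`, "", 1L),
               gene = vapply(parts, `[[`, "", 2L),
               score = as.numeric(sc), stringsAsFactors = FALSE)
}

#' Target score of one miRNA on a gene list
#'
#' Sums, over the listed genes, weighted counts of the miRNA's
#' conservation-eligible target sites: a site counts only if conserved in
#' at least `conservation` of rat, human and chicken; seed-match weights
#' default to 8mer = 3, 7mer-m8 = 2, 7mer-A1 = 1; a site within `window`
#' nt of another eligible site of the same miRNA in the same UTR is
#' multiplied by `multiplier`.
#'
#' @param mirna miRNA id.
#' @param genes gene list to score.
#' @param targets target-prediction table (see [simulateTargetTable()] for
#'   the columns).
#' @param conservation minimum number of other species (default 1).
#' @param weights named site-type weights.
#' @param window clustering window in nt (default 35).
#' @param multiplier clustering multiplier (default 1.5).
#' @return numeric score (0 when the miRNA has no eligible sites).
#' @examples
#' tt <- data.frame(mirna = "m1", gene = "g1", site_type = "8mer",
#'                  utr_position = 100, conserved_species = "rat")
#' targetScore("m1", "g1", tt)   # 3
#' @export
targetScore <- function(mirna, genes, targets, conservation = 1L,
                        weights = c("8mer" = 3, "7mer-m8" = 2,
                                    "7mer-A1" = 1),
                        window = 35, multiplier = 1.5) {
    sub <- targets[targets$mirna == mirna & targets$gene %in% genes, ,
                   drop = FALSE]
    unknown <- setdiff(unique(targets$site_type), names(weights))
    if (length(unknown))
        stop("unknown site type(s): ", paste(unknown, collapse = ", "))
    if (nrow(sub) == 0L) return(0)
    pg <- .perGeneScores(sub, conservation, weights, window, multiplier)
    sum(pg$score)
}

#' Monte Carlo target-hub enrichment (miRhub-style)
#'
#' Scores every miRNA on the observed gene list, then on `nNull` random
#' gene lists of the same size drawn uniformly without replacement from the
#' universe, and reports the add-one empirical p-value
#' `(1 + #[null >= observed]) / (1 + nNull)` with BH adjustment across the
#' tested miRNAs. miRNAs whose q-value falls below 0.05 are candidate
#' regulatory hubs.
#'
#' @param geneList observed gene list (must be a subset of `universe`).
#' @param targets target-prediction table.
#' @param universe the expressed-gene universe the null lists are drawn
#'   from; must be strictly larger than the gene list.
#' @param mirnas miRNAs to test (default: all in `targets`).
#' @param nNull number of random lists (default 1000).
#' @param seed optional seed for the null draws.
#' @param conservation,weights,window,multiplier passed to the scorer.
#' @return a [HubResult-class].
#' @export
mirhub <- function(geneList, targets, universe,
                   mirnas = sort(unique(targets$mirna)), nNull = 1000L,
                   seed = NULL, conservation = 1L,
                   weights = c("8mer" = 3, "7mer-m8" = 2, "7mer-A1" = 1),
                   window = 35, multiplier = 1.5) {
    if (!all(geneList %in% universe))
        stop("gene list must be a subset of the universe")
    if (length(geneList) >= length(universe))
        stop("universe must be larger than the gene list")
    if (!is.null(seed)) set.seed(seed)
    pg <- .perGeneScores(targets, conservation, weights, window,
                         multiplier)
    pg <- pg[pg$mirna %in% mirnas, , drop = FALSE]
    # dense gene x miRNA score matrix over the universe
    S <- matrix(0, nrow = length(universe), ncol = length(mirnas),
                dimnames = list(universe, mirnas))
    keep <- pg$gene %in% universe
    S[cbind(match(pg$gene[keep], universe),
            match(pg$mirna[keep], mirnas))] <- pg$score[keep]
    observed <- colSums(S[match(geneList, universe), , drop = FALSE])
    k <- length(geneList)
    nullScores <- matrix(0, nrow = nNull, ncol = length(mirnas),
                         dimnames = list(NULL, mirnas))
    for (b in seq_len(nNull)) {
        idx <- sample.int(length(universe), k)
        nullScores[b, ] <- colSums(S[idx, , drop = FALSE])
    }
    exceed <- colSums(nullScores >= rep(observed, each = nNull))
    p <- (1 + exceed) / (1 + nNull)
    p[observed == 0] <- 1
    q <- stats::p.adjust(p, method = "BH")
    tb <- data.frame(mirna = mirnas, observed = unname(observed),
                     p = unname(p), q = unname(q),
                     stringsAsFactors = FALSE)
    new("HubResult", table = tb, nullScores = nullScores,
        geneList = geneList, nNull = as.integer(nNull))
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of observing at least the actual overlap when
#' drawing `|B|` genes from a universe of `universeSize` in which `|A|`
#' genes are marked.
#'
#' @param setA,setB character gene sets.
#' @param universeSize size of the common universe (must be at least
#'   `|A union B|`).
#' @return list: `p`, `overlap` (the shared members), `k` (overlap size).
#' @examples
#' overlapTest(letters[1:5], letters[1:5], 10)$p   # 1/252
#' @export
overlapTest <- function(setA, setB, universeSize) {
    setA <- unique(setA); setB <- unique(setB)
    if (universeSize < length(union(setA, setB)))
        stop("universe smaller than the union of the sets")
    k <- length(intersect(setA, setB))
    p <- stats::phyper(k - 1, length(setA),
                       universeSize - length(setA), length(setB),
                       lower.tail = FALSE)
    list(p = p, overlap = intersect(setA, setB), k = k)
}
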