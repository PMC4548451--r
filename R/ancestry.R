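#' Group founder alleles by the largest effect gap
#'
#' Sorts the eight founder allele effects (reference founder at 0) and
#' splits them into a low and a high group at the largest gap between
#' adjacent ordered effects. With two equally large gaps the split is made
#' at the first (lowest-value) one. Invariant to permuting the input order
#' and to adding a constant to all effects.
#'
#' @param effects named numeric of length 8, one allele effect per founder.
#' @return list with `groupA` (low side), `groupB` (high side) and `gap`
#'   (the effect difference at the split).
#' @examples
#' eff <- c(A = 0.1, B = 0.2, C = 0.9, D = 1.0, E = 1.1, F = 1.2,
#'          G = 1.3, H = 1.4)
#' groupAlleles(eff)$groupA   # A, B
#' @export
groupAlleles <- function(effects) {
    if (length(effects) != 8L || any(!is.finite(effects)))
        stop("need 8 finite founder effects")
    if (is.null(names(effects)))
        names(effects) <- paste0("F", seq_along(effects))
    o <- order(effects, names(effects))
    srt <- effects[o]
    gaps <- diff(srt)
    if (max(gaps) < 1e-12)
        stop("all allele effects equal; no meaningful split")
    cut <- which.max(gaps)          # first largest gap
    list(groupA = names(srt)[seq_len(cut)],
         groupB = names(srt)[(cut + 1L):8L],
         gap = unname(gaps[cut]))
}

#' Filter SNPs matching a strain distribution pattern
#'
#' Keeps SNPs at which all group-A founders carry one allele, all group-B
#' founders carry the other, and no founder in either group is heterozygous
#' or a low-confidence/missing call. Genotype calls are `"ref"`, `"alt"`,
#' `"het"`, `"low_confidence"`.
#'
#' @param snps data.frame with columns `chrom`, `pos` and one genotype
#'   column per founder.
#' @param grouping output of [groupAlleles()] (or any list with `groupA`,
#'   `groupB` founder name sets).
#' @return the matching subset of `snps` (possibly zero rows).
#' @export
filterSdp <- function(snps, grouping) {
    if (nrow(snps) == 0L) return(snps)
    a <- grouping$groupA
    b <- grouping$groupB
    if (!all(c(a, b) %in% names(snps)))
        stop("grouping names missing from the SNP table columns")
    ga <- as.matrix(snps[, a, drop = FALSE])
    gb <- as.matrix(snps[, b, drop = FALSE])
    clean <- function(m) rowSums(m != "ref" & m != "alt") == 0L
    sameA <- clean(ga) &
        (rowSums(ga == "ref") == 0L | rowSums(ga == "alt") == 0L)
    sameB <- clean(gb) &
        (rowSums(gb == "ref") == 0L | rowSums(gb == "alt") == 0L)
    opposite <- ga[, 1L] != gb[, 1L]
    snps[sameA & sameB & opposite, , drop = FALSE]
}

#' Annotate SNPs with nearby genes
#'
#' Assigns each SNP to every gene whose interval, extended by `flank` bp on
#' both sides, contains it (closed 1-based coordinates, via
#' GenomicRanges overlap); SNPs hitting no gene are labelled intergenic.
#'
#' @param snps data.frame with `chrom`, `pos`.
#' @param genes data.frame with `gene`, `chrom`, `start`, `end`.
#' @param flank bp added on each side of a gene (default 5000).
#' @return data.frame `chrom`, `pos`, `gene` with one row per SNP-gene
#'   assignment; unassigned SNPs appear once with gene `"intergenic"`.
#' @export
annotateSnps <- function(snps, genes, flank = 5000) {
    if (flank < 0) stop("flank must be >= 0")
    if (nrow(snps) == 0L)
        return(data.frame(chrom = character(), pos = numeric(),
                          gene = character(), stringsAsFactors = FALSE))
    snpGr <- GenomicRanges::GRanges(snps$chrom,
        IRanges::IRanges(snps$pos, snps$pos))
    geneGr <- GenomicRanges::GRanges(genes$chrom,
        IRanges::IRanges(pmax(genes$start - flank, 1),
                         genes$end + flank))
    hits <- GenomicRanges::findOverlaps(snpGr, geneGr)
    out <- data.frame(
        chrom = snps$chrom[S4Vectors::queryHits(hits)],
        pos = snps$pos[S4Vectors::queryHits(hits)],
        gene = genes$gene[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE)
    orphan <- setdiff(seq_len(nrow(snps)),
                      unique(S4Vectors::queryHits(hits)))
    if (length(orphan))
        out <- rbind(out, data.frame(chrom = snps$chrom[orphan],
                                     pos = snps$pos[orphan],
                                     gene = "intergenic",
                                     stringsAsFactors = FALSE))
    out[order(match(paste(out$chrom, out$pos),
                    paste(snps$chrom, snps$pos))), , drop = FALSE]
}

#' Tukey HSD comparison of founder allele groups at a locus
#'
#' Assigns each line to its most probable founder at the locus (argmax
#' dosage, requiring a dosage of at least `minDosage`), fits the one-way
#' ANOVA of expression on assigned founder, and runs Tukey's honestly
#' significant difference test over all founder pairs. Founders with fewer
#' than two assigned lines are excluded and flagged.
#'
#' @param y expression vector over lines.
#' @param dosages n x 8 dosage matrix at the locus (founder columns named).
#' @param founder founder of interest; its pairwise comparisons are
#'   returned in `$focal`.
#' @param minDosage minimum max-dosage for a confident assignment
#'   (default 1.0).
#' @return list: `tukey` (full TukeyHSD table), `focal` (rows involving the
#'   founder of interest), `assigned` (per-line founder, NA when
#'   unassignable), `excluded` (founders with < 2 assigned lines).
#' @export
alleleGroupTest <- function(y, dosages, founder, minDosage = 1.0) {
    founders <- colnames(dosages)
    if (is.null(founders)) stop("dosage columns must be named by founder")
    if (!founder %in% founders)
        stop("unknown founder of interest: ", founder)
    mx <- apply(dosages, 1L, max)
    amx <- founders[apply(dosages, 1L, which.max)]
    amx[mx < minDosage] <- NA_character_
    tab <- table(amx)
    keep <- names(tab)[tab >= 2L]
    excluded <- setdiff(names(tab), keep)
    use <- !is.na(amx) & amx %in% keep
    if (length(keep) < 2L)
        stop("fewer than two founders with >= 2 assigned lines")
    f <- factor(amx[use], levels = keep)
    fit <- stats::aov(y[use] ~ f)
    tk <- stats::TukeyHSD(fit)$f
    pairs <- rownames(tk)
    halves <- strsplit(pairs, "-", fixed = TRUE)
    # founder names may themselves contain "-"; match by membership instead
    focal <- vapply(pairs, function(p) {
        others <- setdiff(keep, founder)
        grepl(founder, p, fixed = TRUE) &&
            any(vapply(others, grepl, TRUE, x = p, fixed = TRUE))
    }, TRUE)
    list(tukey = tk, focal = tk[focal, , drop = FALSE],
         assigned = amx, excluded = excluded)
}

#' Neighbor-joining founder phylogeny with bootstrap support
#'
#' Builds a neighbor-joining tree from pairwise Hamming distances over
#' shared called genotypes (het and low-confidence calls treated as
#' missing), then bootstraps by resampling SNP columns with replacement and
#' counting how often each internal bipartition of the original tree is
#' recovered.
#'
#' @param snps SNP table as in [filterSdp()] (genotype columns per strain).
#' @param strains strain columns to use (default: all non-coordinate
#'   columns).
#' @param nBootstrap bootstrap replicates (default 100).
#' @param seed optional seed for the resampling.
#' @return an [ape::phylo] tree; `$node.label` holds bootstrap counts (out
#'   of `nBootstrap`) for each internal node.
#' @export
buildTree <- function(snps, strains = setdiff(names(snps),
                                              c("chrom", "pos")),
                      nBootstrap = 100L, seed = NULL) {
    if (length(strains) < 3L) stop("need >= 3 strains")
    if (nrow(snps) < 1L) stop("need >= 1 SNP")
    if (!is.null(seed)) set.seed(seed)
    G <- t(as.matrix(snps[, strains, drop = FALSE]))  # strains x SNPs
    G[!(G %in% c("ref", "alt"))] <- NA
    G <- matrix(G, nrow = length(strains),
                dimnames = list(strains, NULL))
    allMissing <- rowSums(!is.na(G)) == 0L
    if (any(allMissing))
        stop("strain(s) with no called genotypes: ",
             paste(strains[allMissing], collapse = ", "))
    hamming <- function(M) {
        k <- nrow(M)
        D <- matrix(0, k, k, dimnames = list(rownames(M), rownames(M)))
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
            shared <- !is.na(M[i, ]) & !is.na(M[j, ])
            D[i, j] <- D[j, i] <-
                if (any(shared)) mean(M[i, shared] != M[j, shared]) else 0
        }
        stats::as.dist(D)
    }
    tree <- ape::nj(hamming(G))
    boots <- lapply(seq_len(nBootstrap), function(b) {
        idx <- sample.int(ncol(G), replace = TRUE)
        ape::nj(hamming(G[, idx, drop = FALSE]))
    })
    support <- ape::prop.clades(tree, boots, rooted = FALSE)
    support[is.na(support)] <- 0L
    tree$node.label <- support
    tree
}
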