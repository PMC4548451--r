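#' Collapse loci between recombinations
#'
#' Merges runs of consecutive loci (within a chromosome) whose dosage
#' matrices differ by at most `tolerance` in maximum absolute entry across
#' all lines. The merged dosage is the element-wise mean (so rows still sum
#' to 2) and the merged position is the midpoint of the first and last
#' merged positions. At tolerance 0 on hard dosages this reduces the map to
#' one interval per population recombination block.
#'
#' @param hap a [HaplotypeDosage-class] with sorted loci.
#' @param tolerance maximum absolute per-entry dosage difference between
#'   consecutive loci that still counts as "no recombination" (default 0).
#' @return a collapsed [HaplotypeDosage-class].
#' @export
collapseIntervals <- function(hap, tolerance = 0) {
    stopifnot(is(hap, "HaplotypeDosage"))
    if (tolerance < 0) stop("tolerance must be >= 0")
    d <- dosageArray(hap)
    loci <- lociTable(hap)
    L <- nrow(loci)
    grp <- integer(L)
    g <- 1L
    grp[1L] <- g
    for (l in seq_len(L - 1L)) {
        newChrom <- loci$chrom[l + 1L] != loci$chrom[l]
        if (newChrom ||
            max(abs(d[, l + 1L, ] - d[, l, ])) > tolerance + 1e-12)
            g <- g + 1L
        grp[l + 1L] <- g
    }
    nG <- g
    newDos <- array(0, dim = c(dim(d)[1L], nG, dim(d)[3L]),
                    dimnames = list(lineIds(hap), NULL, founderNames(hap)))
    newLoci <- data.frame(chrom = character(nG), pos = numeric(nG),
                          stringsAsFactors = FALSE)
    for (gi in seq_len(nG)) {
        idx <- which(grp == gi)
        slab <- d[, idx, , drop = FALSE]
        newDos[, gi, ] <- apply(slab, c(1L, 3L), mean)
        newLoci$chrom[gi] <- loci$chrom[idx[1L]]
        newLoci$pos[gi] <- round((loci$pos[idx[1L]] +
                                  loci$pos[idx[length(idx)]]) / 2)
    }
    new("HaplotypeDosage", lines = lineIds(hap), loci = newLoci,
        founders = founderNames(hap), dosages = newDos,
        breakpoints = hap@breakpoints)
}

# Orthonormal column basis of X (rank columns only), via pivoted QR.
.projector <- function(X) {
    qrX <- qr(X)
    qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
}

# Residual sums of squares of every column of Y against the column space
# spanned by Q (orthonormal): RSS = |y|^2 - |Q'y|^2.
.rssQ <- function(Q, Y) {
    pmax(colSums(Y^2) - colSums(crossprod(Q, Y)^2), 0)
}

# Multi-trait LOD engine: Y is n x m (traits in columns), returns an
# L x m matrix of LOD scores. The per-locus design is intercept +
# covariates + the 7 non-reference founder dosage columns; the null design
# is intercept + covariates. Rank deficiency is absorbed by pivoted QR.
.lodMatrix <- function(Y, hap, covariates = NULL) {
    d <- dosageArray(hap)
    n <- nrow(Y)
    if (n != dim(d)[1L])
        stop("trait rows must align with dosage lines")
    L <- dim(d)[2L]
    X0 <- cbind(rep(1, n), covariates)
    Q0 <- .projector(X0)
    rss0 <- .rssQ(Q0, Y)
    tiny <- .Machine$double.eps * n
    lod <- matrix(NA_real_, nrow = L, ncol = ncol(Y))
    for (l in seq_len(L)) {
        X1 <- cbind(X0, d[, l, -1L, drop = TRUE])
        if (n < ncol(X1)) next  # skipped locus sentinel: NA
        Q1 <- .projector(X1)
        rss1 <- .rssQ(Q1, Y)
        lv <- (n / 2) * log10(pmax(rss0, tiny) / pmax(rss1, tiny))
        lv[rss0 <= tiny] <- 0
        lod[l, ] <- pmax(lv, 0)
    }
    lod
}

#' Genome-wide haplotype regression LOD scan
#'
#' At each locus, regresses the trait on an intercept, optional covariates,
#' and the seven non-reference founder dosage columns, and reports
#' \deqn{LOD = (n/2) \log_{10}(RSS_0 / RSS_1)} against the null model of
#' intercept + covariates only. A locus with zero dosage variance (aliased
#' with the null design) scores 0; a locus with more parameters than lines
#' is skipped with an `NA` sentinel.
#'
#' @param y numeric trait vector, aligned to the lines of `hap`.
#' @param hap a [HaplotypeDosage-class].
#' @param covariates optional numeric matrix of additional null-model
#'   regressors (e.g. dosages of a conditioning locus), n x k.
#' @return numeric LOD vector, one entry per locus.
#' @examples
#' cfg <- simConfig(nLines = 40, seed = 2,
#'                  chromosomes = data.frame(name = "1", length_bp = 1e8,
#'                                           n_markers = 30))
#' hap <- simulatePopulation(cfg)
#' lod <- lodScan(rnorm(40), hap)
#' @export
lodScan <- function(y, hap, covariates = NULL) {
    as.numeric(.lodMatrix(cbind(y), hap, covariates))
}

#' Fit the haplotype dosage regression at one locus
#'
#' Ordinary least squares of the trait on an intercept plus the dosages of
#' the seven non-reference founders; the reference founder's effect is
#' implicitly zero. Founders aliased at the locus (e.g. absent from the
#' population there) are dropped and flagged. The model R2 is reported as
#' the fraction of trait variance explained by the locus.
#'
#' @param y numeric trait vector.
#' @param dosages n x 8 dosage matrix at one locus, founder columns in the
#'   reference-first order (e.g. `dosageArray(hap)[, l, ]`).
#' @return a [QtlFit-class].
#' @export
fitQtl <- function(y, dosages) {
    n <- length(y)
    if (nrow(dosages) != n) stop("dosages must align with y")
    if (n < 10L) stop("need >= 10 informative samples")
    founders <- colnames(dosages)
    if (is.null(founders)) founders <- paste0("F", 1:8)
    X <- cbind(`(Intercept)` = 1, dosages[, -1L, drop = FALSE])
    qrX <- qr(X)
    beta <- qr.coef(qrX, y)
    fitted <- X[, !is.na(beta), drop = FALSE] %*% beta[!is.na(beta)]
    rss <- sum((y - fitted)^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss <= .Machine$double.eps * n) 0 else
        min(max(1 - rss / tss, 0), 1)
    eff <- beta[-1L]
    names(eff) <- founders[-1L]
    aliased <- names(eff)[is.na(eff)]
    if (tss <= .Machine$double.eps * n) eff[!is.na(eff)] <- 0
    new("QtlFit", intercept = unname(beta[1L]), effects = eff,
        rss = rss, r2 = r2, n = as.integer(n), aliased = aliased)
}

#' Permutation genome-wide significance thresholds
#'
#' Permutes the trait over lines `nPerm` times, rescans the genome, and
#' records each permutation's maximum LOD. Thresholds at adjusted level
#' alpha are the empirical (1 - alpha) quantiles of these null maxima; the
#' adjusted p-value of the observed peak is the add-one plug-in estimate
#' `(1 + #[null >= observed]) / (1 + nPerm)`, which never returns zero.
#'
#' @param y trait vector.
#' @param hap a [HaplotypeDosage-class].
#' @param nPerm number of permutations (default 250).
#' @param alpha adjusted-p levels for thresholds (default 0.05 and 0.10).
#' @param seed optional integer seed for the permutations.
#' @param covariates optional covariates, kept fixed under permutation of y.
#' @return a [PermutationThresholds-class].
#' @export
permuteThresholds <- function(y, hap, nPerm = 250L,
                              alpha = c(0.05, 0.10), seed = NULL,
                              covariates = NULL) {
    if (nPerm < 1L) stop("nPerm must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    n <- length(y)
    Y <- cbind(y, vapply(seq_len(nPerm),
                         function(i) y[sample.int(n)], numeric(n)))
    lod <- .lodMatrix(Y, hap, covariates)
    obs <- max(lod[, 1L], na.rm = TRUE)
    nullMax <- apply(lod[, -1L, drop = FALSE], 2L, max, na.rm = TRUE)
    thr <- stats::quantile(nullMax, probs = 1 - alpha, names = FALSE)
    names(thr) <- as.character(alpha)
    adjP <- (1 + sum(nullMax >= obs)) / (1 + nPerm)
    new("PermutationThresholds", nullMax = unname(nullMax),
        thresholds = thr, adjP = adjP, observedMax = obs,
        nPerm = as.integer(nPerm))
}

#' LOD-drop support interval
#'
#' Takes the smallest contiguous run of loci on the peak chromosome that
#' contains the peak and keeps LOD within `drop` units of it, then extends
#' by one flanking locus on each side when available. Ties at the peak go
#' to the leftmost locus (chromosome order, then bp). An all-equal curve
#' returns the whole chromosome with a warning.
#'
#' @param lod LOD vector over loci.
#' @param loci matching locus table (`chrom`, `pos`).
#' @param drop LOD units below the peak that still qualify (default 1.5).
#' @return one-row data.frame `chrom`, `start`, `end` (1-based, closed);
#'   attribute `"peakIndex"` carries the peak's row index in `loci`.
#' @export
lodSupportInterval <- function(lod, loci, drop = 1.5) {
    if (length(lod) != nrow(loci)) stop("lod and loci must align")
    if (all(is.na(lod))) stop("empty LOD curve")
    peak <- which(lod == max(lod, na.rm = TRUE))[1L]
    chr <- loci$chrom[peak]
    onChr <- which(loci$chrom == chr)
    lodC <- lod[onChr]
    pkC <- match(peak, onChr)
    if (diff(range(lodC, na.rm = TRUE)) < 1e-12) {
        warning("flat LOD curve; returning the whole chromosome")
        lo <- 1L; hi <- length(onChr)
    } else {
        ok <- !is.na(lodC) & lodC >= max(lodC, na.rm = TRUE) - drop
        lo <- pkC
        while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
        hi <- pkC
        while (hi < length(onChr) && ok[hi + 1L]) hi <- hi + 1L
        if (lo > 1L) lo <- lo - 1L                 # flank extension
        if (hi < length(onChr)) hi <- hi + 1L
    }
    out <- data.frame(chrom = chr, start = loci$pos[onChr[lo]],
                      end = loci$pos[onChr[hi]], stringsAsFactors = FALSE)
    attr(out, "peakIndex") <- peak
    out
}

#' Classify an eQTL as local or distal
#'
#' Local means the peak lies within `localMb` megabases of the cognate
#' gene on the same chromosome; anything farther, or on another
#' chromosome, is distal.
#'
#' @param peakChrom,peakPos peak chromosome and position (bp).
#' @param geneChrom,genePos cognate gene chromosome and position (bp).
#' @param localMb distance threshold in Mb (default 10).
#' @return `"local"` or `"distal"`.
#' @examples
#' classifyEqtl("12", 109161374, "12", 109.90e6)   # local
#' @export
classifyEqtl <- function(peakChrom, peakPos, geneChrom, genePos,
                         localMb = 10) {
    if (is.na(peakChrom) || is.na(geneChrom) ||
        !nzchar(peakChrom) || !nzchar(geneChrom))
        stop("unknown chromosome")
    if (peakChrom == geneChrom &&
        abs(peakPos - genePos) <= localMb * 1e6) "local" else "distal"
}

#' Conditional genome scan
#'
#' Rescans the genome with the seven non-reference dosage columns of a
#' conditioning locus added to the null model, so that signal explained by
#' that locus is absorbed. Conditioning on the scanned locus itself yields
#' LOD 0 there by construction (the added columns are aliased).
#'
#' @param y trait vector.
#' @param hap a [HaplotypeDosage-class].
#' @param conditionLocus row index of the conditioning locus in
#'   `lociTable(hap)`; NULL reduces to [lodScan()].
#' @return LOD vector.
#' @export
conditionalScan <- function(y, hap, conditionLocus = NULL) {
    covs <- NULL
    if (!is.null(conditionLocus)) {
        if (conditionLocus < 1L || conditionLocus > nrow(lociTable(hap)))
            stop("condition locus not in the dosage matrix")
        covs <- dosageArray(hap)[, conditionLocus, -1L, drop = TRUE]
    }
    lodScan(y, hap, covariates = covs)
}

#' Full scan for one miRNA
#'
#' Runs the genome scan, permutation thresholds, LOD-drop support interval,
#' peak-locus haplotype fit, and (when the cognate gene position is given)
#' the local/distal classification, returning a [ScanResult-class].
#'
#' @param y trait vector (e.g. -dCt values) aligned to `hap` lines.
#' @param hap a [HaplotypeDosage-class].
#' @param mirna miRNA identifier for the result.
#' @param genePos optional `list(chrom=, pos=)` of the cognate gene.
#' @param nPerm permutations (default 250; 0 skips the permutation step).
#' @param drop LOD-drop for the support interval (default 1.5).
#' @param alpha threshold levels (default 0.05, 0.10).
#' @param localMb local/distal threshold in Mb (default 10).
#' @param seed optional permutation seed.
#' @param covariates optional covariates for a conditional scan.
#' @return a [ScanResult-class].
#' @export
scanMirna <- function(y, hap, mirna = "miRNA", genePos = NULL,
                      nPerm = 250L, drop = 1.5, alpha = c(0.05, 0.10),
                      localMb = 10, seed = NULL, covariates = NULL) {
    lod <- lodScan(y, hap, covariates)
    loci <- lociTable(hap)
    support <- lodSupportInterval(lod, loci, drop)
    peak <- attr(support, "peakIndex")
    fit <- fitQtl(y, dosageArray(hap)[, peak, , drop = TRUE])
    if (nPerm > 0L) {
        pt <- permuteThresholds(y, hap, nPerm, alpha, seed, covariates)
        adjP <- pt@adjP; thr <- pt@thresholds; nullMax <- pt@nullMax
    } else {
        adjP <- NA_real_; thr <- numeric(); nullMax <- numeric()
    }
    cls <- NA_character_
    if (!is.null(genePos))
        cls <- classifyEqtl(loci$chrom[peak], loci$pos[peak],
                            genePos$chrom, genePos$pos, localMb)
    new("ScanResult", mirna = mirna, lod = lod, loci = loci,
        peakIndex = as.integer(peak), adjP = adjP, thresholds = thr,
        nullMax = nullMax, support = support, fit = fit,
        classification = cls)
}
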