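#' Read and write package tables as TSV
#'
#' Plain-text interchange for every input and output of the pipeline:
#' long-form haplotype dosage matrices (one row per line x locus with one
#' dosage column per founder), expression tables (lines x features with a
#' `line` id column), phenotype tables, TargetScan-style target tables,
#' founder SNP tables, and Table-style eQTL summaries (TSV and BED; the BED
#' export converts the 1-based closed intervals to 0-based half-open).
#'
#' @param hap a [HaplotypeDosage-class].
#' @param path file path.
#' @name tsv-io
NULL

#' @rdname tsv-io
#' @export
writeDosageTable <- function(hap, path) {
    d <- dosageArray(hap)
    loci <- lociTable(hap)
    nL <- length(lineIds(hap)); nLoc <- nrow(loci)
    long <- data.frame(
        line = rep(lineIds(hap), times = nLoc),
        chrom = rep(loci$chrom, each = nL),
        pos = rep(loci$pos, each = nL),
        stringsAsFactors = FALSE, check.names = FALSE)
    for (f in seq_along(founderNames(hap)))
        long[[founderNames(hap)[f]]] <- as.numeric(d[, , f])
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname tsv-io
#' @export
readDosageTable <- function(path) {
    long <- utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE)
    founders <- setdiff(names(long), c("line", "chrom", "pos"))
    lines <- unique(long$line)
    key <- paste(long$chrom, long$pos)
    lociKey <- unique(key)
    loci <- unique(long[, c("chrom", "pos")])
    rownames(loci) <- NULL
    loci$chrom <- as.character(loci$chrom)
    d <- array(0, dim = c(length(lines), nrow(loci), length(founders)),
               dimnames = list(lines, NULL, founders))
    li <- match(long$line, lines)
    ci <- match(key, lociKey)
    for (f in seq_along(founders))
        d[cbind(li, ci, f)] <- long[[founders[f]]]
    new("HaplotypeDosage", lines = lines, loci = loci,
        founders = founders, dosages = d, breakpoints = list())
}

#' @rdname tsv-io
#' @param mat numeric matrix, lines (rows) x features.
#' @export
writeExpressionTable <- function(mat, path) {
    df <- data.frame(line = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname tsv-io
#' @export
readExpressionTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, setdiff(names(df), "line"), drop = FALSE])
    rownames(m) <- df$line
    m
}

#' @rdname tsv-io
#' @param df a data.frame (phenotypes, target predictions, SNP table).
#' @export
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname tsv-io
#' @export
readTsv <- function(path) {
    utils::read.delim(path, check.names = FALSE,
                      stringsAsFactors = FALSE)
}

#' Summarise scan results in an eQTL table
#'
#' One row per scan: miRNA, the adjusted-p threshold class it meets (0.05,
#' 0.1, or NA), peak LOD, chromosome, peak position, and the support
#' interval bounds — the conventional eQTL summary layout.
#'
#' @param scans list of [ScanResult-class] objects.
#' @param alphaLevels threshold classes to report (default 0.05, 0.10).
#' @return data.frame with columns `mirna`, `p_threshold`, `LOD`, `chrom`,
#'   `peak_bp`, `start_bp`, `end_bp`, `classification`, `h2`.
#' @export
eqtlTable <- function(scans, alphaLevels = c(0.05, 0.10)) {
    rows <- lapply(scans, function(s) {
        pk <- s@loci[s@peakIndex, ]
        cls <- NA_real_
        if (!is.na(s@adjP))
            for (a in sort(alphaLevels)) if (s@adjP < a) { cls <- a; break }
        data.frame(mirna = s@mirna, p_threshold = cls,
                   LOD = max(s@lod, na.rm = TRUE), chrom = pk$chrom,
                   peak_bp = pk$pos, start_bp = s@support$start,
                   end_bp = s@support$end,
                   classification = s@classification[1L],
                   h2 = if (is(s@fit, "QtlFit")) s@fit@r2 else NA_real_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Write eQTL support intervals as BED
#'
#' Converts the 1-based closed support intervals to BED's 0-based
#' half-open convention (start - 1, end) with the miRNA id as the name
#' column and the peak LOD as the score.
#'
#' @param tab output of [eqtlTable()].
#' @param path output file.
#' @export
writeEqtlBed <- function(tab, path) {
    bed <- data.frame(chrom = tab$chrom, start = tab$start_bp - 1,
                      end = tab$end_bp, name = tab$mirna,
                      score = round(tab$LOD, 2))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Serialise results as JSON
#'
#' @param x a list, data.frame, or [eqtlTable()] output.
#' @param path output file.
#' @export
writeJsonSummary <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg a [SimConfig-class].
#' @param path file path.
#' @export
writeSimConfig <- function(cfg, path) {
    slots <- methods::slotNames("SimConfig")
    lst <- lapply(slots, function(s) {
        v <- methods::slot(cfg, s)
        if (is.data.frame(v)) as.list(v) else v
    })
    names(lst) <- slots
    yaml::write_yaml(lst, path)
    invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
    lst <- yaml::read_yaml(path)
    lst$chromosomes <- data.frame(lst$chromosomes,
                                  stringsAsFactors = FALSE)
    lst$chromosomes$name <- as.character(lst$chromosomes$name)
    do.call(simConfig, lst[setdiff(names(lst), character())])
}

#' Write a phylogeny with bootstrap support as Newick
#'
#' Support counts are written as internal node labels.
#'
#' @param tree an [ape::phylo] with `node.label` support values.
#' @param path output file.
#' @export
writeTreeNewick <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}
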