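#' Build a simulation configuration
#'
#' Constructs a validated [SimConfig-class]. The defaults emulate the design
#' of an eight-founder multiparental allergic-airway study: ~129 recombinant
#' lines genotyped on a collapsed interval map, four array replicates per
#' founder strain, a large-effect local eQTL whose locus explains 84% of line
#' variance (driven by a low *musculus*-derived allele shared by NOD/ShiLtJ
#' and PWK/PhJ), log-normal granulocyte counts, a 10,000-gene mRNA layer of
#' which a small fraction is phenotype-correlated, and a TargetScan-style
#' site table with one planted regulatory-hub miRNA.
#'
#' @param nLines number of lines (default 129).
#' @param founders eight strain names, reference strain first (default the
#'   CC founders with A/J as reference).
#' @param chromosomes data.frame `name`, `length_bp`, `n_markers`.
#' @param recombRate expected crossovers per chromosome per haploid strand
#'   (default 3, the mosaic density of a multi-generation funnel descendant).
#' @param nReplicates founder replicates (default 4).
#' @param plantedEqtl list of planted eQTL; each element needs `mirna`,
#'   `locus` (global row index of the locus table), `effects` (length 8,
#'   ordered as `founders`), `h2` in [0,1).
#' @param phenotypeSpec named list of `c(meanlog, sdlog)` per phenotype.
#' @param nMrna number of simulated mRNAs / hub universe size.
#' @param qttSpec list(`fraction`, `r`): fraction of mRNAs correlated with
#'   each phenotype and the target correlation magnitude.
#' @param targetSpec list(`nMirnas`, `sitesPerGeneMean`, `siteTypeFreq`,
#'   `consProb`, `hubMirna`, `enrichment`, `utrLength`).
#' @param panelSpec list(`nMirnas`, `icc`, `fracNull`, `meanRange`): panel
#'   size, intraclass correlation of strain-affected miRNAs, fraction with no
#'   strain effect, and the uniform range of baseline log2 means.
#' @param nMirnasMeasured number of miRNAs in the per-line qPCR table.
#' @param noiseSd residual SD on the -dCt scale (a knob, not a data claim).
#' @param dosageBlur Dirichlet blur (0 = hard 0/1/2 dosages).
#' @param seed master integer seed.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nLines = 50, seed = 7)
#' cfg
#' @export
simConfig <- function(nLines = 129L,
                      founders = .CC_FOUNDERS,
                      chromosomes = data.frame(
                          name = c("1", "2", "3"),
                          length_bp = c(150e6, 120e6, 100e6),
                          n_markers = c(120L, 100L, 80L),
                          stringsAsFactors = FALSE),
                      recombRate = 3,
                      nReplicates = 4L,
                      plantedEqtl = list(list(
                          mirna = "mir-planted-1", locus = 170L,
                          effects = c(0, 0, 0, -2, 0, -2, 0, 0),
                          h2 = 0.84)),
                      phenotypeSpec = list(
                          eosinophils = c(meanlog = log(6e4), sdlog = 1),
                          neutrophils = c(meanlog = log(1e4), sdlog = 1)),
                      nMrna = 10000L,
                      qttSpec = list(fraction = 0.0674, r = 0.6),
                      targetSpec = list(
                          nMirnas = 25L, sitesPerGeneMean = 0.3,
                          siteTypeFreq = c("8mer" = 0.2, "7mer-m8" = 0.4,
                                           "7mer-A1" = 0.4),
                          consProb = 0.5, hubMirna = "mir-t01",
                          enrichment = 5, utrLength = 2000L),
                      panelSpec = list(nMirnas = 120L, icc = 0.8,
                                       fracNull = 0.3,
                                       meanRange = c(4, 12)),
                      nMirnasMeasured = 40L,
                      noiseSd = 1,
                      dosageBlur = 0,
                      seed = 1L) {
    # normalise list-valued fields (e.g. after a YAML round trip)
    plantedEqtl <- lapply(plantedEqtl, function(pe) {
        pe$effects <- as.numeric(unlist(pe$effects))
        pe$locus <- as.integer(pe$locus)
        pe
    })
    phenotypeSpec <- lapply(phenotypeSpec, function(p) {
        v <- unlist(p)
        if (is.null(names(v)) && length(v) == 2L)
            names(v) <- c("meanlog", "sdlog")
        v
    })
    targetSpec$siteTypeFreq <- unlist(targetSpec$siteTypeFreq)
    panelSpec$meanRange <- as.numeric(unlist(panelSpec$meanRange))
    new("SimConfig",
        nLines = as.integer(nLines), founders = founders,
        chromosomes = chromosomes, recombRate = recombRate,
        nReplicates = as.integer(nReplicates), plantedEqtl = plantedEqtl,
        phenotypeSpec = phenotypeSpec, nMrna = as.integer(nMrna),
        qttSpec = qttSpec, targetSpec = targetSpec, panelSpec = panelSpec,
        nMirnasMeasured = as.integer(nMirnasMeasured), noiseSd = noiseSd,
        dosageBlur = dosageBlur, seed = as.integer(seed))
}

# Deterministic child seed per generator stage, so that each simulate*()
# call is reproducible on its own and independent of call order.
.childSeed <- function(seed, tag) {
    s <- sum(utf8ToInt(tag)) * 7919
    as.integer((as.numeric(seed) * 48271 + s) %% 2147483647)
}
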