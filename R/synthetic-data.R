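REGULATOR_PRODUCTS <- c(
  "Transcriptional regulator, TetR family",
  "Transcriptional regulator, AcrR family",
  "Transcriptional regulator, IclR family",
  "Transcriptional regulator, WhiB family",
  "Regulatory protein",
  "Two-component system response regulator",
  "RNA polymerase sigma factor",
  "Regulator of polyketide synthase expression")

OTHER_PRODUCTS <- c(
  "ABC transporter, ATP-binding protein",
  "O-antigen export system, permease protein",
  "Arsenical resistance protein ACR3",
  "Thioredoxin reductase",
  "NADH:flavin oxidoreductase/NADH oxidase",
  "Peptidase S1 and S6, chymotrypsin/Hap",
  "Polyketide synthase module",
  "Hypothetical protein",
  "Membrane transport protein",
  "Glycosyl transferase, group 1")

#' Generate a synthetic single-contig bacterial annotation
#'
#' Genes are tiled head-to-tail along one contig with fixed intergenic
#' spacing, ordinals 1..n, random strands, and CDS lengths drawn around
#' \code{meanCdsLen} (multiples of 3). A \code{regulatorFraction} of
#' products is drawn from a regulator-keyword phrase list, the rest from a
#' non-regulator list. Fully deterministic for a fixed seed.
#'
#' @param nGenes number of genes (>= 1).
#' @param meanCdsLen mean CDS length in bases (default 900).
#' @param intergenicLen spacing between consecutive CDS (default 150).
#' @param regulatorFraction fraction of genes given a regulator-style
#'   product annotation (default 0.08).
#' @param seed integer seed.
#' @param seqid contig name.
#' @return Gene models \code{GRanges} (see \code{\link{geneModels}}).
#' @export
generateAnnotation <- function(nGenes, meanCdsLen = 900,
                               intergenicLen = 150,
                               regulatorFraction = 0.08, seed = 1,
                               seqid = "chr") {
  stopifnot(nGenes >= 1)
  withSeed(seed, {
    ## lengths around the mean, floor 300 bp, forced to full codons
    len <- pmax(300, round(rnorm(nGenes, meanCdsLen, meanCdsLen / 4)))
    len <- as.integer((len %/% 3) * 3)
    start <- cumsum(c(500L, len[-nGenes] + intergenicLen))
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    isReg <- runif(nGenes) < regulatorFraction
    product <- ifelse(
      isReg,
      sample(REGULATOR_PRODUCTS, nGenes, replace = TRUE),
      sample(OTHER_PRODUCTS, nGenes, replace = TRUE))
    suppressWarnings(geneModels(
      seqid = seqid, start = start, end = start + len - 1L,
      strand = strand, geneId = sprintf("orf%d", seq_len(nGenes)),
      product = product))
  })
}

#' Generate a paired wild-type/mutant methylome with planted loss
#'
#' Wild-type m4C sites are placed uniformly at random over each gene's CDS
#' and upstream promoter window, with per-gene Poisson counts at
#' \code{siteRate} sites per kb. Planted candidate genes instead receive a
#' deterministic CDS site count of \code{plantedSiteRate} per kb (at least
#' \code{minWtSites}) plus at least one promoter site, emulating the
#' denser methylation observed at methyltransferase target genes. The
#' mutant methylome is the wild type minus \emph{all} sites of the planted
#' candidates (CDS and promoter) minus an independent
#' \code{backgroundLossRate} fraction of the remaining sites.
#'
#' @param genes gene models from \code{\link{generateAnnotation}}.
#' @param siteRate background site density, sites per kb (default 8).
#' @param plantedCandidates gene ids to plant with complete m4C loss;
#'   must be a subset of the annotation.
#' @param backgroundLossRate fraction of non-planted sites lost in the
#'   mutant (default 0.3).
#' @param promoterLen promoter window length in bases (default 300).
#' @param plantedSiteRate site density of planted genes, sites per kb
#'   (default 13, matching the CDS m4C density observed at screened
#'   methyltransferase targets); applied as a deterministic count.
#' @param minWtSites minimum wild-type sites per planted gene (default 5).
#' @param seed integer seed.
#' @return List with \code{wt} and \code{mut} \code{\link{Methylome}}s and
#'   a \code{truth} list recording the planted set, per-gene wild-type
#'   counts and the full parameter echo.
#' @export
generateMethylomes <- function(genes, siteRate = 8,
                               plantedCandidates = character(),
                               backgroundLossRate = 0.3,
                               promoterLen = 300, plantedSiteRate = 13,
                               minWtSites = 5, seed = 1) {
  stopifnot(all(plantedCandidates %in% genes$gene_id),
            backgroundLossRate >= 0, backgroundLossRate <= 1)
  withSeed(seed, {
    planted <- genes$gene_id %in% plantedCandidates
    prom <- promoterRanges(genes, promoterLen)
    seqid <- as.character(GenomeInfoDb::seqnames(genes))

    placeGene <- function(i) {
      cdsSpan <- BiocGenerics::start(genes)[i]:BiocGenerics::end(genes)[i]
      promSpan <- if (BiocGenerics::width(prom)[i] > 0)
        BiocGenerics::start(prom)[i]:BiocGenerics::end(prom)[i]
      else integer()
      if (planted[i]) {
        ## deterministic elevated CDS density so a planted full loss always
        ## clears the abundance screen; at least one promoter site so the
        ## promoter loss of a planted gene is defined and complete
        nCds <- max(minWtSites,
                    ceiling(plantedSiteRate * length(cdsSpan) / 1000))
        nProm <- max(1L, rpois(1, siteRate * length(promSpan) / 1000))
      } else {
        nCds <- rpois(1, siteRate * length(cdsSpan) / 1000)
        nProm <- rpois(1, siteRate * length(promSpan) / 1000)
      }
      c(sort(sample(cdsSpan, min(nCds, length(cdsSpan)))),
        if (length(promSpan))
          sort(sample(promSpan, min(nProm, length(promSpan)))))
    }
    posList <- lapply(seq_along(genes), placeGene)
    ns <- lengths(posList)
    pos <- unlist(posList)
    geneOf <- rep(seq_along(genes), ns)
    strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    ## duplicate (pos, strand) pairs across overlapping windows collapse in
    ## the Methylome constructor; drop them here so truth counts match
    key <- paste(seqid[geneOf], pos, strand)
    keep <- !duplicated(key)
    pos <- pos[keep]; strand <- strand[keep]; geneOf <- geneOf[keep]

    wt <- Methylome("WT_synthetic",
                    seqid = seqid[geneOf], position = pos, strand = strand,
                    modType = rep("m4C", length(pos)),
                    score = round(runif(length(pos), 30, 200)),
                    coverage = rpois(length(pos), 80))

    ## mutant: drop all planted-gene sites, then background loss
    plantedRegions <- c(GenomicRanges::granges(genes[planted]),
                        GenomicRanges::granges(prom[planted]))
    inPlanted <- if (length(plantedRegions))
      IRanges::overlapsAny(calls(wt), plantedRegions, ignore.strand = TRUE)
    else rep(FALSE, length(wt))
    survives <- !inPlanted & runif(length(wt)) >= backgroundLossRate
    mutGr <- calls(wt)[survives]
    mut <- new("Methylome", sampleId = "mutant_synthetic", calls = mutGr)

    wtCounts <- tabulate(
      S4Vectors::subjectHits(GenomicRanges::findOverlaps(
        calls(wt), genes, ignore.strand = TRUE)),
      nbins = length(genes))
    truth <- list(
      planted_candidate_ids = as.character(plantedCandidates),
      wt_counts = setNames(as.integer(wtCounts), genes$gene_id),
      seed = seed,
      parameters = list(siteRate = siteRate,
                        plantedSiteRate = plantedSiteRate,
                        backgroundLossRate = backgroundLossRate,
                        promoterLen = promoterLen,
                        minWtSites = minWtSites))
    list(wt = wt, mut = mut, truth = truth)
  })
}

#' Generate a pathway-assignment table with planted dense regions
#'
#' Membership of the pathway category is drawn per gene: with probability
#' \code{inRegionRate} for genes whose ordinal falls in a planted span,
#' \code{backgroundRate} elsewhere.
#'
#' @param genes gene models.
#' @param regionSpans data.frame (or list) with \code{start_ordinal} /
#'   \code{end_ordinal} half-open ordinal spans; may be empty.
#' @param inRegionRate membership probability inside spans (default 0.3).
#' @param backgroundRate membership probability outside (default 0.02).
#' @param seed integer seed.
#' @return \code{data.frame} with \code{gene_id}, \code{in_category}.
#' @export
generatePathwayTable <- function(genes, regionSpans = NULL,
                                 inRegionRate = 0.3,
                                 backgroundRate = 0.02, seed = 1) {
  stopifnot(inRegionRate >= 0, inRegionRate <= 1,
            backgroundRate >= 0, backgroundRate <= 1)
  withSeed(seed, {
    inSpan <- rep(FALSE, length(genes))
    if (!is.null(regionSpans) && NROW(regionSpans))
      inSpan <- ordinalInRegions(genes$orf_ordinal,
                                 as.data.frame(regionSpans))
    p <- ifelse(inSpan, inRegionRate, backgroundRate)
    data.frame(gene_id = genes$gene_id,
               in_category = runif(length(genes)) < p)
  })
}

#' Generate time-course DE tables with planted consistent genes
#'
#' Planted up/down genes get \code{+/- lfcMagnitude} plus Gaussian noise at
#' every time point and an adjusted p-value of 0.001; all other genes get
#' pure noise and an adjusted p-value of 0.9.
#'
#' @param genes gene models.
#' @param timeLabels labels of the time points (default 48h/72h/120h, the
#'   log, late-log and stationary phases of a typical time course).
#' @param plantedUp,plantedDown gene ids planted as consistently up / down.
#' @param lfcMagnitude absolute planted log2 fold change (default 4).
#' @param noiseSd fold-change noise SD for planted genes (default 0.3).
#' @param nullSd fold-change SD for null genes (default 0.3).
#' @param seed integer seed.
#' @return List with \code{tables} (one DE table per time label, see
#'   \code{\link{readDeTable}}) and \code{truth} (planted id sets).
#' @export
generateDeTables <- function(genes, timeLabels = c("48h", "72h", "120h"),
                             plantedUp = character(),
                             plantedDown = character(),
                             lfcMagnitude = 4, noiseSd = 0.3,
                             nullSd = 0.3, seed = 1) {
  stopifnot(all(c(plantedUp, plantedDown) %in% genes$gene_id),
            !anyDuplicated(c(plantedUp, plantedDown)))
  withSeed(seed, {
    ids <- genes$gene_id
    base <- numeric(length(ids))
    base[ids %in% plantedUp] <- lfcMagnitude
    base[ids %in% plantedDown] <- -lfcMagnitude
    plantedMask <- base != 0
    tables <- lapply(timeLabels, function(lab) {
      noise <- rnorm(length(ids), 0, ifelse(plantedMask, noiseSd, nullSd))
      tab <- data.frame(gene_id = ids, log2fc = base + noise,
                        padj = ifelse(plantedMask, 0.001, 0.9))
      attr(tab, "time_label") <- lab
      tab
    })
    names(tables) <- timeLabels
    list(tables = tables,
         truth = list(planted_up_ids = as.character(plantedUp),
                      planted_down_ids = as.character(plantedDown),
                      seed = seed))
  })
}

#' Simulate a complete study and write every input file
#'
#' Convenience wrapper chaining the four generators with per-stage seeds
#' derived from one master seed (\code{seed + 1..4}), writing the
#' annotation GFF3, both methylome TSVs, the pathway table, one DE table
#' per time point and a JSON ground-truth manifest to \code{outDir}.
#'
#' @param outDir output directory (created if needed).
#' @param seed master integer seed.
#' @param nGenes genome size in genes (default 2000).
#' @param nPlanted number of regulator genes planted as full-loss
#'   candidates inside planted dense regions (default 2).
#' @param regionSpans planted dense-region ordinal spans; default two
#'   spans scaled to the genome.
#' @param ... further arguments passed to
#'   \code{\link{generateMethylomes}} (e.g. \code{backgroundLossRate}).
#' @return The truth manifest, invisibly; side effect: files in
#'   \code{outDir}.
#' @export
simulateStudy <- function(outDir, seed = 1, nGenes = 2000, nPlanted = 2,
                          regionSpans = NULL, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  genes <- generateAnnotation(nGenes, seed = seed + 1)
  if (is.null(regionSpans)) {
    ## spans aligned to the 100-ordinal bin grid, like real called regions
    q <- max(100L, (nGenes %/% 10) %/% 100L * 100L)
    regionSpans <- data.frame(
      start_ordinal = c(3 * q, 7 * q),
      end_ordinal = c(4 * q, 8 * q))
    if (8 * q > nGenes)
      stop("genome too small for the default planted spans; pass ",
           "regionSpans explicitly")
  }
  isReg <- identifyRegulators(genes)
  inSpan <- ordinalInRegions(genes$orf_ordinal, regionSpans)
  pool <- genes$gene_id[isReg & inSpan]
  if (length(pool) < nPlanted)
    stop("not enough regulator genes inside the planted spans to plant ",
         nPlanted, " candidate(s)")
  planted <- withSeed(seed + 1, sample(pool, nPlanted))

  meth <- generateMethylomes(genes, plantedCandidates = planted,
                             seed = seed + 2, ...)
  pathway <- generatePathwayTable(genes, regionSpans, seed = seed + 3)
  de <- generateDeTables(genes,
                         plantedUp = planted,
                         plantedDown = withSeed(
                           seed + 3,
                           sample(setdiff(genes$gene_id[!isReg], planted),
                                  3)),
                         seed = seed + 4)

  writeGeneAnnotationGff(genes, file.path(outDir, "annotation.gff3"))
  writeMethylomeTsv(meth$wt, file.path(outDir, "wt_methylome.tsv"))
  writeMethylomeTsv(meth$mut, file.path(outDir, "mut_methylome.tsv"))
  writePathwayTable(pathway, file.path(outDir, "pathway.tsv"))
  for (lab in names(de$tables))
    writeDeTable(de$tables[[lab]],
                 file.path(outDir, paste0("de_", lab, ".tsv")))

  truth <- list(
    seed = seed,
    n_genes = nGenes,
    planted_candidate_ids = meth$truth$planted_candidate_ids,
    planted_region_spans = regionSpans,
    planted_up_ids = de$truth$planted_up_ids,
    planted_down_ids = de$truth$planted_down_ids,
    parameters = meth$truth$parameters)
  jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
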