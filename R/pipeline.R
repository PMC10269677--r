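#' Pipeline configuration
#'
#' Builds a validated configuration for \code{\link{runPipeline}}. All
#' thresholds default to the screening strategy's values: 300 bp promoter
#' window, 100-ordinal density bins with a strict 10\% threshold, strict
#' 80\% site-loss and 1\% abundance-loss screening thresholds, |log2FC|
#' >= 1 and adjusted p <= 0.05 for differential expression. The full
#' configuration is echoed verbatim into the JSON report for provenance.
#'
#' @param wtMethylome,mutMethylome paths to the wild-type and mutant call
#'   sets (\code{.gff}/\code{.gff3} parsed as SMRT basemods GFF3, anything
#'   else as methylome TSV).
#' @param annotation path to the gene-annotation GFF3.
#' @param pathwayTable path to the pathway-assignment TSV, or \code{NULL}
#'   to skip the density stage.
#' @param deTables named character vector of DE-table paths (names =
#'   time labels), or \code{NULL} to skip the consistency stage.
#' @param outDir output directory for the report files.
#' @param modType,promoterLen,minScore methylome-diff settings.
#' @param binSize,densityThreshold density-region settings.
#' @param minSiteLoss,minAbundanceLoss,minWtSites,regulatorKeywords
#'   screening settings.
#' @param minAbsLog2fc,maxPadj DE significance settings.
#' @return A list of class \code{"methscreenConfig"}.
#' @export
pipelineConfig <- function(wtMethylome, mutMethylome, annotation,
                           pathwayTable = NULL, deTables = NULL,
                           outDir = ".", modType = "m4C",
                           promoterLen = 300, minScore = NULL,
                           binSize = 100, densityThreshold = 0.10,
                           minSiteLoss = 0.80, minAbundanceLoss = 0.01,
                           minWtSites = 1,
                           regulatorKeywords = REGULATOR_KEYWORDS,
                           minAbsLog2fc = 1.0, maxPadj = 0.05) {
  config <- list(
    wtMethylome = wtMethylome, mutMethylome = mutMethylome,
    annotation = annotation, pathwayTable = pathwayTable,
    deTables = deTables, outDir = outDir, modType = modType,
    promoterLen = promoterLen, minScore = minScore, binSize = binSize,
    densityThreshold = densityThreshold, minSiteLoss = minSiteLoss,
    minAbundanceLoss = minAbundanceLoss, minWtSites = minWtSites,
    regulatorKeywords = regulatorKeywords, minAbsLog2fc = minAbsLog2fc,
    maxPadj = maxPadj)
  stopifnot(promoterLen >= 0, binSize >= 1,
            densityThreshold >= 0, densityThreshold <= 1,
            minSiteLoss >= 0, minSiteLoss <= 1,
            minAbundanceLoss >= 0, minAbundanceLoss <= 1,
            minAbsLog2fc > 0, maxPadj > 0)
  for (p in c(wtMethylome, mutMethylome, annotation, pathwayTable,
              unname(deTables)))
    if (!file.exists(p))
      stop("configured input does not exist: ", p)
  class(config) <- "methscreenConfig"
  config
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{pipelineConfig}};
#' \code{deTables} is a mapping of time label to path. Unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file (e.g. from command-line
#'   flags); overrides win.
#' @return A validated configuration (see \code{\link{pipelineConfig}}).
#' @export
readPipelineConfig <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$deTables)) raw$deTables <- unlist(raw$deTables)
  do.call(pipelineConfig, raw)
}

readAnyMethylome <- function(path, modType) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE))
    readBasemodsGff(path, modFilter = modType)
  else readMethylomeTsv(path, modFilter = modType)
}

#' Run the full mining pipeline
#'
#' Stages: per-gene wild-type/mutant methylation diff; pathway-density
#' region calling (when a pathway table is configured); regulator
#' screening, region flagging and ranking; and the cross-timepoint DE
#' sign-consistency filter (when DE tables are configured). Writes
#' \code{candidates.tsv}, \code{candidates.json} (with the configuration
#' echo), \code{regions.bed} and \code{de_consistency.tsv} into the
#' configured output directory. Identical inputs and configuration yield
#' byte-identical outputs.
#'
#' @param config configuration from \code{\link{pipelineConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @return Invisible list with \code{deltas}, \code{totals},
#'   \code{regions}, \code{candidates} and (when configured)
#'   \code{consistency}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "methscreenConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  msg("stage diff: reading inputs")
  wt <- readAnyMethylome(config$wtMethylome, config$modType)
  mut <- readAnyMethylome(config$mutMethylome, config$modType)
  genes <- readGeneAnnotation(config$annotation)
  diffRes <- genomeWideDiff(wt, mut, genes,
                            promoterLen = config$promoterLen,
                            minScore = config$minScore,
                            modType = config$modType)

  regions <- callDenseRegions(
    data.frame(bin_index = integer(), start_ordinal = integer(),
               end_ordinal = integer(), n_genes = integer(),
               n_assigned = integer(), density = numeric()))
  if (!is.null(config$pathwayTable)) {
    msg("stage density: calling dense pathway regions")
    assignments <- readPathwayTable(config$pathwayTable)
    bins <- computeBinDensities(genes, assignments,
                                binSize = config$binSize)
    regions <- callDenseRegions(bins, threshold = config$densityThreshold)
    msg("stage density: ", nrow(regions), " region(s) above threshold")
  }

  msg("stage screen: thresholding regulator candidates")
  regulatorMap <- identifyRegulators(genes, config$regulatorKeywords)
  candidates <- screenByMethylation(
    diffRes$deltas, regulatorMap,
    minSiteLoss = config$minSiteLoss,
    minAbundanceLoss = config$minAbundanceLoss,
    minWtSites = config$minWtSites)
  candidates <- rankCandidates(flagInRegion(candidates, regions))
  msg("stage screen: ", nrow(candidates), " candidate(s), ",
      sum(candidates$in_dense_region), " in dense region(s)")

  configEcho <- unclass(config)
  configEcho$regulatorKeywords <- as.list(configEcho$regulatorKeywords)
  writeCandidateReport(candidates,
                       file.path(config$outDir, "candidates.tsv"),
                       file.path(config$outDir, "candidates.json"),
                       extra = list(
                         totals = as.list(diffRes$totals),
                         regions = regions,
                         config = configEcho))
  writeRegionsBed(regions, genes, file.path(config$outDir, "regions.bed"))

  consistency <- NULL
  if (!is.null(config$deTables)) {
    msg("stage de-filter: cross-timepoint consistency")
    labels <- names(config$deTables)
    if (is.null(labels)) labels <- paste0("t", seq_along(config$deTables))
    tables <- Map(readDeTable, config$deTables, labels)
    crossover <- crossoverGenes(tables,
                                minAbsLog2fc = config$minAbsLog2fc,
                                maxPadj = config$maxPadj)
    consistency <- filterConsistent(crossover, tables)
    msg("stage de-filter: ", length(crossover), " crossover gene(s), ",
        sum(consistency$direction != "inconsistent"), " sign-consistent")
    writeConsistencyTable(consistency,
                          file.path(config$outDir, "de_consistency.tsv"))
  }

  invisible(list(deltas = diffRes$deltas, totals = diffRes$totals,
                 regions = regions, candidates = candidates,
                 consistency = consistency))
}
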