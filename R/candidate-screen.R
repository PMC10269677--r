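## Default product keywords marking a gene as a presumed regulator.
REGULATOR_KEYWORDS <- c("regulator", "regulatory protein",
                        "transcription factor", "sigma factor")

#' Flag regulator-annotated genes by product keywords
#'
#' Case-insensitive substring match of any keyword against the free-text
#' product annotation. The default list covers the usual bacterial
#' regulator annotations (e.g. "Transcriptional regulator, TetR family");
#' it is configurable because regulator inventories differ between
#' annotation pipelines.
#'
#' @param genes gene models from \code{\link{geneModels}}.
#' @param keywords non-empty character vector of keywords.
#' @return Named logical vector (names = \code{gene_id}).
#' @export
identifyRegulators <- function(genes, keywords = REGULATOR_KEYWORDS) {
  stopifnot(length(keywords) >= 1)
  product <- tolower(genes$product)
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k)
    grepl(k, product, fixed = TRUE)), rep(FALSE, length(genes)))
  setNames(hit, genes$gene_id)
}

#' Screen per-gene methylation deltas for candidate regulators
#'
#' Keeps genes that (i) are regulator-annotated, (ii) lose strictly more
#' than \code{minSiteLoss} of their wild-type CDS m4C sites, (iii) lose at
#' least \code{minAbundanceLoss} of methylation abundance, where the
#' abundance-loss fraction is compared after rounding half-up to one
#' decimal on the percent scale (so a gene printing exactly "1.0\%" passes
#' the 1\% threshold), and (iv) have at least \code{minWtSites} wild-type
#' CDS sites.
#'
#' @param deltas \code{DataFrame} from \code{\link{genomeWideDiff}}.
#' @param regulatorMap named logical vector from
#'   \code{\link{identifyRegulators}}.
#' @param minSiteLoss site-loss fraction that must be strictly exceeded
#'   (default 0.80).
#' @param minAbundanceLoss abundance-loss fraction threshold (default
#'   0.01), applied as \code{>=} on the one-decimal-rounded percent.
#' @param minWtSites minimum wild-type CDS site count (default 1).
#' @return \code{DataFrame} of candidate records ordered by
#'   \code{orf_ordinal}: the delta columns plus \code{is_regulator};
#'   \code{in_dense_region} and \code{rank} are added later by
#'   \code{\link{flagInRegion}} and \code{\link{rankCandidates}}.
#' @export
screenByMethylation <- function(deltas, regulatorMap, minSiteLoss = 0.80,
                                minAbundanceLoss = 0.01, minWtSites = 1) {
  stopifnot(minSiteLoss >= 0, minSiteLoss <= 1,
            minAbundanceLoss >= 0, minAbundanceLoss <= 1)
  isReg <- unname(regulatorMap[deltas$gene_id])
  isReg[is.na(isReg)] <- FALSE
  abundancePct <- roundHalfUp(100 * deltas$abundance_loss_fraction, 1)
  keep <- isReg &
    deltas$cds_loss_fraction > minSiteLoss &
    abundancePct >= 100 * minAbundanceLoss &
    deltas$cds_sites_wt >= minWtSites
  out <- deltas[keep, , drop = FALSE]
  out$is_regulator <- rep(TRUE, nrow(out))
  out[order(out$orf_ordinal), , drop = FALSE]
}

#' Mark candidates lying inside dense pathway regions
#'
#' @param candidates \code{DataFrame} from
#'   \code{\link{screenByMethylation}}.
#' @param regions dense regions from \code{\link{callDenseRegions}}.
#' @return The candidates with a logical \code{in_dense_region} column.
#' @export
flagInRegion <- function(candidates, regions) {
  candidates$in_dense_region <-
    ordinalInRegions(candidates$orf_ordinal, regions)
  candidates
}

#' Rank screened candidates
#'
#' Candidates are ordered by: inside a dense pathway region first, then
#' higher promoter loss, then higher CDS site loss, then higher abundance
#' loss, then lower ORF ordinal. Ranks are 1-based positions in that
#' order; the ordering is a total order, so permuting the input never
#' changes the result.
#'
#' @param candidates \code{DataFrame} with \code{in_dense_region} set (see
#'   \code{\link{flagInRegion}}).
#' @return The candidates sorted with a \code{rank} column added.
#' @export
rankCandidates <- function(candidates) {
  if (is.null(candidates$in_dense_region))
    stop("candidates must be region-flagged before ranking ",
         "(run flagInRegion)")
  ord <- order(-as.integer(candidates$in_dense_region),
               -candidates$promoter_loss_fraction,
               -candidates$cds_loss_fraction,
               -candidates$abundance_loss_fraction,
               candidates$orf_ordinal)
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
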