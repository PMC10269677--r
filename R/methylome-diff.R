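## Strand-aware upstream promoter windows, clipped at contig position 1.
## For '+' genes: [start - promoterLen, start - 1]; for '-' genes:
## [end + 1, end + promoterLen]. Zero-width windows are allowed (promoterLen
## 0 or a '+' gene starting at position 1).
promoterRanges <- function(genes, promoterLen) {
  stopifnot(promoterLen >= 0)
  plus <- as.character(BiocGenerics::strand(genes)) == "+"
  s <- ifelse(plus,
              pmax(1L, BiocGenerics::start(genes) - as.integer(promoterLen)),
              BiocGenerics::end(genes) + 1L)
  e <- ifelse(plus,
              BiocGenerics::start(genes) - 1L,
              BiocGenerics::end(genes) + as.integer(promoterLen))
  e <- pmax(e, s - 1L)  # zero-width when the window vanishes
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                         IRanges::IRanges(start = s, end = e),
                         strand = BiocGenerics::strand(genes))
}

#' Assign methylation calls to the CDS and promoter of one gene
#'
#' A call belongs to the CDS when its genomic position lies inside the CDS
#' interval on either strand; it belongs to the promoter when it lies in
#' the upstream window of length \code{promoterLen} on the coding-strand
#' side (upstream of \code{start} for '+' genes, downstream of \code{end}
#' for '-' genes), again on either strand. Windows are clipped at contig
#' position 1.
#'
#' @param methylome a \code{\link{Methylome}}.
#' @param gene a single gene model (one-element \code{GRanges} from
#'   \code{\link{geneModels}}).
#' @param promoterLen upstream window length in bases (default 300).
#' @return List with character vectors \code{cds} and \code{promoter} of
#'   call keys (possibly empty).
#' @export
assignSitesToGene <- function(methylome, gene, promoterLen = 300) {
  stopifnot(is(methylome, "Methylome"), length(gene) == 1L)
  gr <- calls(methylome)
  keys <- methylomeKeys(methylome)
  cdsHits <- GenomicRanges::findOverlaps(gr, gene, ignore.strand = TRUE)
  promHits <- GenomicRanges::findOverlaps(
    gr, promoterRanges(gene, promoterLen), ignore.strand = TRUE)
  list(cds = keys[S4Vectors::queryHits(cdsHits)],
       promoter = keys[S4Vectors::queryHits(promHits)])
}

#' Genome-wide per-gene m4C loss between wild type and mutant
#'
#' For every gene, compares the wild-type and mutant call sets by exact key
#' \code{(seqid, position, strand, mod_type)}. A site is \emph{lost} when
#' its key is present in the wild type and absent from the mutant. Reported
#' per gene: lost/total CDS site counts, the CDS site-loss fraction
#' (defined as 0 when the wild type has no CDS site), the abundance-loss
#' fraction (lost CDS sites / CDS length in bases — the screening metric),
#' the coding-strand-relative positions of the lost CDS sites, and the
#' analogous promoter-window statistics.
#'
#' @param wt,mut wild-type and mutant \code{\link{Methylome}}s.
#' @param genes gene models from \code{\link{geneModels}}, sorted by
#'   ordinal.
#' @param promoterLen upstream promoter window length in bases.
#' @param minScore optional score floor applied to both samples before
#'   differencing; calls with unknown score are kept.
#' @param modType the modification type analysed (default \code{"m4C"});
#'   both methylomes are restricted to it first.
#' @return List with \code{deltas}, a \link[S4Vectors]{DataFrame} with one
#'   row per gene in input order (\code{cds_lost_positions} is an
#'   \code{IntegerList}), and \code{totals}, the named whole-methylome call
#'   counts \code{c(wt=, mut=)} after type/score filtering but before any
#'   gene assignment.
#' @export
genomeWideDiff <- function(wt, mut, genes, promoterLen = 300,
                           minScore = NULL, modType = "m4C") {
  stopifnot(is(wt, "Methylome"), is(mut, "Methylome"))
  wt <- filterCalls(wt, modTypes = modType, minScore = minScore)
  mut <- filterCalls(mut, modTypes = modType, minScore = minScore)
  totals <- c(wt = length(wt), mut = length(mut))

  contigs <- union(as.character(GenomeInfoDb::seqnames(calls(wt))),
                   as.character(GenomeInfoDb::seqnames(calls(mut))))
  off <- !(as.character(GenomeInfoDb::seqnames(genes)) %in% contigs)
  if (length(contigs) && any(off))
    warning(sum(off), " gene(s) on contig(s) absent from both methylomes; ",
            "their deltas are all zero")

  wtGr <- calls(wt)
  lost <- !(methylomeKeys(wt) %in% methylomeKeys(mut))
  n <- length(genes)
  lev <- seq_len(n)

  countRegion <- function(regions, relative = FALSE) {
    ## disjoint seqlevels already produce the explicit absent-contig
    ## warning above; silence the generic GenomicRanges one
    hits <- withCallingHandlers(
      GenomicRanges::findOverlaps(wtGr, regions, ignore.strand = TRUE),
      warning = function(w) {
        if (grepl("sequence levels in common", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    res <- list(wt = tabulate(s, nbins = n),
                lost = tabulate(s[lost[q]], nbins = n))
    if (relative) {
      ql <- q[lost[q]]; sl <- s[lost[q]]
      plus <- as.character(BiocGenerics::strand(genes))[sl] == "+"
      pos <- BiocGenerics::start(wtGr)[ql]
      rel <- ifelse(plus, pos - BiocGenerics::start(genes)[sl] + 1L,
                    BiocGenerics::end(genes)[sl] - pos + 1L)
      res$positions <- S4Vectors::endoapply(
        S4Vectors::splitAsList(as.integer(rel), factor(sl, levels = lev)),
        sort)
    }
    res
  }

  cds <- countRegion(genes, relative = TRUE)
  prom <- countRegion(promoterRanges(genes, promoterLen))
  frac <- function(lostN, wtN) ifelse(wtN > 0, lostN / wtN, 0)

  deltas <- S4Vectors::DataFrame(
    gene_id = genes$gene_id,
    orf_ordinal = genes$orf_ordinal,
    product = genes$product,
    mod_type = modType,
    cds_length = genes$cds_length,
    cds_sites_wt = cds$wt,
    cds_sites_lost = cds$lost,
    cds_loss_fraction = frac(cds$lost, cds$wt),
    cds_lost_positions = unname(cds$positions),
    abundance_loss_fraction = cds$lost / genes$cds_length,
    promoter_sites_wt = prom$wt,
    promoter_sites_lost = prom$lost,
    promoter_loss_fraction = frac(prom$lost, prom$wt))
  msg("diffed ", n, " gene(s): WT ", totals["wt"], " vs mutant ",
      totals["mut"], " ", modType, " call(s)")
  list(deltas = deltas, totals = totals)
}

#' Per-gene m4C loss statistics for a single gene
#'
#' Convenience wrapper around \code{\link{genomeWideDiff}} for one gene.
#'
#' @inheritParams genomeWideDiff
#' @param gene a one-element gene-model \code{GRanges}.
#' @return One-row \code{DataFrame} of loss statistics (see
#'   \code{\link{genomeWideDiff}}).
#' @export
diffGeneMethylation <- function(wt, mut, gene, promoterLen = 300,
                                minScore = NULL, modType = "m4C") {
  stopifnot(length(gene) == 1L)
  suppressMessages(
    genomeWideDiff(wt, mut, gene, promoterLen = promoterLen,
                   minScore = minScore, modType = modType)$deltas)
}

#' Format a loss fraction as a printed percentage
#'
#' Percentages are rounded half-up on the percent scale: site-loss columns
#' print with 0 decimals (6/7 -> "86\%"), abundance columns with 1 decimal.
#'
#' @param fraction numeric in [0, 1] (vectorised).
#' @param decimals 0 or 1 decimal places.
#' @return Character vector like \code{"86\%"}.
#' @examples
#' formatLossPercent(6 / 7)        # "86%"
#' formatLossPercent(9 / 621, 1)   # "1.4%"
#' @export
formatLossPercent <- function(fraction, decimals = 0) {
  stopifnot(decimals %in% c(0, 1))
  if (any(is.na(fraction)) || any(fraction < 0 | fraction > 1))
    stop("fraction must lie in [0, 1]")
  sprintf(paste0("%.", decimals, "f%%"),
          roundHalfUp(100 * fraction, decimals))
}
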