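#' Write the ranked candidate report as TSV and JSON
#'
#' The TSV mirrors the screening summary table: gene, CDS site loss
#' rendered as \code{"86\% (6/7)"}, abundance loss as a one-decimal
#' percentage, promoter loss (\code{"0"} when no promoter site was lost),
#' product, dense-region flag and rank. The JSON carries the same records
#' with full-precision fractions, so every printed percent string is
#' re-derivable from the JSON by the half-up rounding rule.
#'
#' @param records ranked candidates from \code{\link{rankCandidates}}.
#' @param pathTsv,pathJson output paths.
#' @param extra optional named list merged into the JSON document (e.g.
#'   the pipeline configuration echo).
#' @return Invisible list of the two paths.
#' @export
writeCandidateReport <- function(records, pathTsv, pathJson, extra = NULL) {
  if (nrow(records) && is.null(records$rank))
    stop("records must be ranked before writing (run rankCandidates)")
  lossCell <- function(lost, total, frac)
    ifelse(lost == 0, "0",
           paste0(formatLossPercent(frac, 0), " (", lost, "/", total, ")"))
  tsv <- data.frame(
    rank = records$rank,
    gene_id = records$gene_id,
    orf_ordinal = records$orf_ordinal,
    cds_site_loss = ifelse(
      records$cds_sites_wt == 0, "0",
      paste0(formatLossPercent(records$cds_loss_fraction, 0),
             " (", records$cds_sites_lost, "/", records$cds_sites_wt, ")")),
    abundance_loss = formatLossPercent(records$abundance_loss_fraction, 1),
    promoter_loss = lossCell(records$promoter_sites_lost,
                             records$promoter_sites_wt,
                             records$promoter_loss_fraction),
    in_dense_region = records$in_dense_region,
    product = records$product)
  if (!nrow(records))
    tsv <- tsv[0, , drop = FALSE]
  write.table(tsv, pathTsv, sep = "\t", quote = FALSE, row.names = FALSE)

  recs <- as.data.frame(records[, setdiff(colnames(records),
                                          "cds_lost_positions"),
                                drop = FALSE])
  recs$cds_lost_positions <- lapply(
    seq_len(nrow(records)), function(i)
      as.integer(records$cds_lost_positions[[i]]))
  doc <- c(list(candidates = recs), extra)
  jsonlite::write_json(doc, pathJson, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(tsv = pathTsv, json = pathJson))
}

#' Write dense regions as a BED track
#'
#' Ordinal regions are mapped to genomic coordinates through the gene
#' models: each region spans from the start of its first contained gene to
#' the end of its last. BED is 0-based half-open, so a gene span
#' [700000, 900999] (1-based inclusive) becomes \code{699999 901000};
#' this is the single coordinate-convention conversion point in the
#' package. The BED score is \code{round(1000 * max_density)}, capped at
#' 1000.
#'
#' @param regions data.frame from \code{\link{callDenseRegions}}.
#' @param genes gene models used to resolve genomic coordinates.
#' @param path output BED file.
#' @return \code{path}, invisibly.
#' @export
writeRegionsBed <- function(regions, genes, path) {
  lines <- character()
  for (i in seq_len(nrow(regions))) {
    inReg <- genes$orf_ordinal >= regions$start_ordinal[i] &
      genes$orf_ordinal < regions$end_ordinal[i]
    if (!any(inReg)) next
    sub <- genes[inReg]
    seqid <- unique(as.character(GenomeInfoDb::seqnames(sub)))
    if (length(seqid) > 1)
      stop("region [", regions$start_ordinal[i], ",",
           regions$end_ordinal[i], ") spans multiple contigs")
    lines <- c(lines, paste(
      seqid,
      min(BiocGenerics::start(sub)) - 1L,
      max(BiocGenerics::end(sub)),
      paste0("orf", regions$start_ordinal[i], "-orf",
             regions$end_ordinal[i]),
      min(1000L, as.integer(round(1000 * regions$max_density[i]))),
      ".", sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
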