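#' Significant genes of one differential-expression table
#'
#' A gene is differentially expressed when its absolute log2 fold change
#' reaches \code{minAbsLog2fc} and its adjusted p-value is at most
#' \code{maxPadj}. When a gene's adjusted p-value is unknown (\code{NA},
#' e.g. the column was absent from the input) the call falls back to the
#' fold-change rule alone; this fallback is logged.
#'
#' @param table DE table from \code{\link{readDeTable}}.
#' @param minAbsLog2fc minimum absolute log2 fold change (default 1).
#' @param maxPadj maximum adjusted p-value (default 0.05).
#' @return Character vector of significant gene ids.
#' @export
significantGenes <- function(table, minAbsLog2fc = 1.0, maxPadj = 0.05) {
  stopifnot(minAbsLog2fc > 0, maxPadj > 0)
  if (!nrow(table)) return(character())
  noP <- is.na(table$padj)
  if (any(noP))
    msg(sum(noP), " gene(s) without adjusted p-value; using the ",
        "|log2FC| >= ", minAbsLog2fc, " rule alone for them")
  keep <- abs(table$log2fc) >= minAbsLog2fc & (noP | table$padj <= maxPadj)
  table$gene_id[keep]
}

#' Crossover genes: differentially expressed at every time point
#'
#' @param tables non-empty list of DE tables (one per time point).
#' @param minAbsLog2fc,maxPadj thresholds passed to
#'   \code{\link{significantGenes}}.
#' @return Character vector, the intersection of the per-table significant
#'   sets (order of first table).
#' @export
crossoverGenes <- function(tables, minAbsLog2fc = 1.0, maxPadj = 0.05) {
  if (!length(tables))
    stop("at least one DE table is required")
  Reduce(intersect, lapply(tables, significantGenes,
                           minAbsLog2fc = minAbsLog2fc, maxPadj = maxPadj))
}

#' Cross-timepoint sign-consistency of crossover genes
#'
#' Classifies each crossover gene by the signs of its log2 fold changes
#' across all time points: \code{up} when every value is strictly
#' positive, \code{down} when every value is strictly negative, otherwise
#' \code{inconsistent} (a zero fold change can never be "the same
#' direction", so any zero yields \code{inconsistent}). Genes whose
#' expression does not move the same way at all time points are unlikely
#' to be direct targets of one regulator; the \code{up}/\code{down} subset
#' is the one selected for follow-up.
#'
#' @param crossover character vector of gene ids; every gene must be
#'   present in every table.
#' @param tables list of DE tables in time order; names or
#'   \code{"time_label"} attributes label the fold-change columns.
#' @return \code{data.frame} with \code{gene_id}, one \code{log2fc_<time>}
#'   column per table, and \code{direction} (factor up/down/inconsistent).
#' @export
filterConsistent <- function(crossover, tables) {
  stopifnot(length(tables) >= 1)
  labels <- vapply(seq_along(tables), function(i) {
    lab <- attr(tables[[i]], "time_label")
    if (is.null(lab)) lab <- names(tables)[i]
    if (is.null(lab) || !nzchar(lab)) lab <- paste0("t", i)
    lab
  }, character(1))
  fc <- vapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    hit <- match(crossover, tab$gene_id)
    if (anyNA(hit))
      stop("gene(s) missing from DE table '", labels[i], "': ",
           paste(crossover[is.na(hit)], collapse = ", "))
    tab$log2fc[hit]
  }, numeric(length(crossover)))
  fc <- matrix(fc, nrow = length(crossover),
               dimnames = list(NULL, paste0("log2fc_", labels)))
  direction <- rep("inconsistent", length(crossover))
  direction[rowSums(fc > 0) == ncol(fc)] <- "up"
  direction[rowSums(fc < 0) == ncol(fc)] <- "down"
  out <- data.frame(gene_id = as.character(crossover), fc,
                    direction = factor(direction,
                                       levels = c("up", "down",
                                                  "inconsistent")),
                    check.names = FALSE)
  out
}

#' @rdname filterConsistent
#' @param results data.frame from \code{filterConsistent}.
#' @param path output TSV path.
#' @export
writeConsistencyTable <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
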