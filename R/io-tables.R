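#' Read a pathway-assignment table
#'
#' Tab-separated table with columns \code{gene_id} and \code{in_category}
#' marking membership of the configured pathway category (by default the
#' KEGG "environmental information processing" category). Booleans are
#' accepted as \code{0/1} or \code{true/false} (any case).
#'
#' @param path TSV file.
#' @return \code{data.frame} with columns \code{gene_id} (character) and
#'   \code{in_category} (logical), one row per gene.
#' @export
readPathwayTable <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(c("gene_id", "in_category"), colnames(df))
  if (length(missing))
    stop("pathway table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in pathway table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  val <- tolower(trimws(df$in_category))
  ok <- val %in% c("0", "1", "true", "false")
  if (any(!ok))
    stop("unparseable in_category value(s) at row(s): ",
         paste(which(!ok), collapse = ", "))
  data.frame(gene_id = df$gene_id,
             in_category = val %in% c("1", "true"))
}

#' @rdname readPathwayTable
#' @param assignments data.frame as returned by \code{readPathwayTable}.
#' @export
writePathwayTable <- function(assignments, path) {
  out <- data.frame(gene_id = assignments$gene_id,
                    in_category = as.integer(assignments$in_category))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table for one time point
#'
#' Tab-separated table with columns \code{gene_id}, \code{log2fc} and
#' optionally \code{padj}. When the \code{padj} column is absent every
#' adjusted p-value is recorded as \code{NA} and downstream significance
#' calls fall back to the fold-change rule alone (see
#' \code{\link{significantGenes}}).
#'
#' @param path TSV file.
#' @param timeLabel label of the time point, e.g. \code{"48h"}; stored in
#'   the \code{"time_label"} attribute of the result.
#' @return \code{data.frame} with columns \code{gene_id}, \code{log2fc}
#'   (finite numeric) and \code{padj} (numeric in [0,1] or \code{NA}).
#' @export
readDeTable <- function(path, timeLabel) {
  stopifnot(file.exists(path))
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(c("gene_id", "log2fc"), colnames(df))
  if (length(missing))
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in DE table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  lfc <- suppressWarnings(as.numeric(df$log2fc))
  bad <- is.na(lfc) | !is.finite(lfc)
  if (nrow(df) && any(bad))
    stop("non-numeric or non-finite log2fc at row(s): ",
         paste(which(bad), collapse = ", "))
  padj <- if ("padj" %in% colnames(df)) {
    p <- suppressWarnings(as.numeric(df$padj))
    if (any(!is.na(p) & (p < 0 | p > 1)))
      stop("padj outside [0,1] at row(s): ",
           paste(which(!is.na(p) & (p < 0 | p > 1)), collapse = ", "))
    p
  } else rep(NA_real_, nrow(df))
  out <- data.frame(gene_id = df$gene_id, log2fc = lfc, padj = padj)
  attr(out, "time_label") <- as.character(timeLabel)
  out
}

#' @rdname readDeTable
#' @param table DE table to write (columns \code{gene_id}, \code{log2fc},
#'   optionally \code{padj}).
#' @export
writeDeTable <- function(table, path) {
  cols <- intersect(c("gene_id", "log2fc", "padj"), colnames(table))
  write.table(table[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
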