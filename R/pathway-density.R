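#' Pathway-member density over fixed ORF-ordinal bins
#'
#' Genes are placed into fixed, non-overlapping ordinal bins
#' \code{[origin + k*binSize, origin + (k+1)*binSize)} and each bin's
#' density is the fraction of its \emph{present} genes assigned to the
#' pathway category (0 when a bin holds no genes). Bins run from the origin
#' up to the bin containing the last gene; bins beyond it are not emitted.
#' The denominator is the genes present in the bin, not \code{binSize}, so
#' sparse annotations do not dilute density; the two coincide when every
#' ordinal is annotated.
#'
#' @param genes gene models from \code{\link{geneModels}}.
#' @param assignments pathway table (\code{\link{readPathwayTable}}).
#' @param binSize bin width in ordinals (default 100).
#' @param origin ordinal at which bin 0 starts (default 0).
#' @return \code{data.frame} with one row per bin: \code{bin_index},
#'   \code{start_ordinal}, \code{end_ordinal} (half-open span),
#'   \code{n_genes}, \code{n_assigned}, \code{density}.
#' @export
computeBinDensities <- function(genes, assignments, binSize = 100,
                                origin = 0) {
  stopifnot(binSize >= 1, length(genes) >= 1)
  member <- genes$gene_id %in% assignments$gene_id[assignments$in_category]
  idx <- (genes$orf_ordinal - origin) %/% binSize
  if (any(idx < 0))
    stop("gene ordinal(s) below the bin origin ", origin)
  nb <- max(idx) + 1L
  data.frame(
    bin_index = seq_len(nb) - 1L,
    start_ordinal = origin + (seq_len(nb) - 1L) * binSize,
    end_ordinal = origin + seq_len(nb) * binSize,
    n_genes = tabulate(idx + 1L, nbins = nb),
    n_assigned = tabulate((idx + 1L)[member], nbins = nb),
    density = ifelse(tabulate(idx + 1L, nbins = nb) > 0,
                     tabulate((idx + 1L)[member], nbins = nb) /
                       pmax(tabulate(idx + 1L, nbins = nb), 1L), 0))
}

#' Call dense regions by merging qualifying adjacent bins
#'
#' Bins whose density strictly exceeds \code{threshold} ("more than 10\%"
#' at the default) qualify; runs of adjacent qualifying bins merge into one
#' region whose span is the union of the merged bin spans (half-open
#' ordinal intervals).
#'
#' @param bins data.frame from \code{\link{computeBinDensities}}; must be
#'   contiguous and ordered by \code{bin_index}.
#' @param threshold density that must be strictly exceeded (default 0.10).
#' @return \code{data.frame} ordered by \code{start_ordinal} with columns
#'   \code{start_ordinal}, \code{end_ordinal}, \code{n_bins},
#'   \code{max_density}, \code{mean_density}; zero rows when no bin
#'   qualifies.
#' @export
callDenseRegions <- function(bins, threshold = 0.10) {
  empty <- data.frame(start_ordinal = integer(), end_ordinal = integer(),
                      n_bins = integer(), max_density = numeric(),
                      mean_density = numeric())
  if (!nrow(bins)) return(empty)
  if (is.unsorted(bins$bin_index, strictly = TRUE) ||
      any(diff(bins$bin_index) != 1L))
    stop("bins must be contiguous and ordered by bin_index")
  hot <- bins$density > threshold
  if (!any(hot)) return(empty)
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- do.call(rbind, lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    data.frame(start_ordinal = bins$start_ordinal[i[1]],
               end_ordinal = bins$end_ordinal[i[length(i)]],
               n_bins = length(i),
               max_density = max(bins$density[i]),
               mean_density = mean(bins$density[i]))
  }))
  out[order(out$start_ordinal), , drop = FALSE]
}

#' Is an ORF ordinal inside any called region?
#'
#' Regions are half-open \code{[start_ordinal, end_ordinal)} spans, so e.g.
#' ordinal 4900 is outside a region ending at 4900.
#'
#' @param ordinal integer ordinal(s) to test (vectorised).
#' @param regions data.frame from \code{\link{callDenseRegions}}.
#' @return Logical vector.
#' @export
ordinalInRegions <- function(ordinal, regions) {
  if (!nrow(regions)) return(rep(FALSE, length(ordinal)))
  vapply(ordinal, function(o)
    any(o >= regions$start_ordinal & o < regions$end_ordinal), logical(1))
}
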