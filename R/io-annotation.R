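#' Build a validated set of bacterial gene models
#'
#' Gene models are kept as a \link[GenomicRanges]{GRanges} (one
#' single-interval CDS per gene — the bacterial case; multi-part CDS are a
#' documented non-goal and rejected upstream) with metadata columns
#' \code{gene_id}, \code{orf_ordinal} (the integer embedded in the locus
#' tag, e.g. orf4759 -> 4759), \code{product} and \code{cds_length}.
#' Output is sorted by ordinal; duplicate ordinals are an error. A warning
#' (not an error) is raised for CDS lengths not divisible by 3.
#'
#' @param seqid,start,end,strand parallel vectors of 1-based inclusive CDS
#'   coordinates.
#' @param geneId locus tags; the ordinal is parsed with
#'   \code{ordinalPattern}.
#' @param product free-text functional annotation (recycled if length 1).
#' @param ordinalPattern regular expression with exactly one integer
#'   capture group applied to \code{geneId}.
#' @return \code{GRanges} of gene models sorted by \code{orf_ordinal}.
#' @export
geneModels <- function(seqid, start, end, strand, geneId, product = "",
                       ordinalPattern = "orf0*([0-9]+)") {
  n <- length(geneId)
  stopifnot(length(start) == n, length(end) == n)
  if (any(start > end))
    stop("CDS start > end for gene(s): ",
         paste(geneId[start > end], collapse = ", "))
  hit <- grepl(ordinalPattern, geneId)
  if (any(!hit))
    stop("locus tag(s) do not match the ordinal pattern '", ordinalPattern,
         "': ", paste(geneId[!hit], collapse = ", "))
  ordinal <- as.integer(sub(paste0(".*?", ordinalPattern, ".*"), "\\1",
                            geneId))
  if (anyDuplicated(ordinal))
    stop("duplicate ORF ordinal(s): ",
         paste(unique(ordinal[duplicated(ordinal)]), collapse = ", "))
  len <- end - start + 1L
  if (any(len %% 3 != 0))
    warning(sum(len %% 3 != 0), " CDS length(s) not a multiple of 3")
  gr <- GenomicRanges::GRanges(
    seqnames = rep_len(seqid, n),
    ranges = IRanges::IRanges(start = start, end = end),
    strand = rep_len(strand, n),
    gene_id = as.character(geneId),
    orf_ordinal = ordinal,
    product = rep_len(as.character(product), n),
    cds_length = as.integer(len))
  gr[order(ordinal)]
}

#' Read bacterial gene models from a GFF3 annotation
#'
#' Imports the annotation with \code{rtracklayer}, keeps features of the
#' requested kind, takes the locus tag from the \code{locus_tag} attribute
#' (falling back to \code{ID}) and parses the ORF ordinal from it. Genes
#' are returned sorted by ordinal; duplicate ordinals or tags that do not
#' match the pattern are errors. A locus tag occurring on more than one
#' feature (a multi-part CDS) is rejected.
#'
#' @param path GFF3 file.
#' @param featureKind feature type to keep (default \code{"CDS"}).
#' @param ordinalPattern regular expression with one integer capture used
#'   to extract the ordinal from the locus tag.
#' @return \code{GRanges} of gene models (see \code{\link{geneModels}}).
#' @export
readGeneAnnotation <- function(path, featureKind = "CDS",
                               ordinalPattern = "orf0*([0-9]+)") {
  stopifnot(file.exists(path))
  gff <- rtracklayer::import(path, format = "gff3")
  gff <- gff[as.character(gff$type) == featureKind]
  if (!length(gff))
    stop("no '", featureKind, "' features found in ", path)
  mc <- S4Vectors::mcols(gff)
  tag <- if ("locus_tag" %in% colnames(mc)) mc$locus_tag else mc$ID
  if (is.null(tag) || any(is.na(tag)))
    stop("feature(s) without locus_tag/ID attribute in ", path)
  tag <- as.character(tag)
  if (anyDuplicated(tag))
    stop("locus tag(s) on multiple features (multi-part CDS is not ",
         "supported): ", paste(unique(tag[duplicated(tag)]), collapse = ", "))
  product <- if ("product" %in% colnames(mc)) mc$product else ""
  if (is(product, "List"))   # GFF3 multi-valued attribute (embedded commas)
    product <- S4Vectors::unstrsplit(product, sep = ", ")
  product <- as.character(product)
  product[is.na(product)] <- ""
  genes <- geneModels(
    seqid = as.character(GenomeInfoDb::seqnames(gff)),
    start = BiocGenerics::start(gff), end = BiocGenerics::end(gff),
    strand = as.character(BiocGenerics::strand(gff)),
    geneId = tag, product = product, ordinalPattern = ordinalPattern)
  msg("read ", length(genes), " gene model(s) from ", basename(path))
  genes
}

#' Write gene models as a GFF3 annotation
#'
#' Inverse of \code{\link{readGeneAnnotation}} for the single-interval
#' bacterial case; used by the synthetic-data generator.
#'
#' @param genes gene models from \code{\link{geneModels}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGeneAnnotationGff <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(as.character(GenomeInfoDb::seqnames(genes)),
                   "methscreen", "CDS",
                   BiocGenerics::start(genes), BiocGenerics::end(genes),
                   ".", as.character(BiocGenerics::strand(genes)), "0",
                   paste0("ID=", genes$gene_id,
                          ";locus_tag=", genes$gene_id,
                          ";product=", gsub(",", "%2C", genes$product)),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
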