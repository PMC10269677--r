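#' Methylome: a keyed set of called modified bases for one sample
#'
#' A \code{Methylome} holds every base-modification call of one sample as a
#' width-1 \link[GenomicRanges]{GRanges} with metadata columns
#' \code{mod_type} (one of m4C, m6A, m5C), \code{score} (Phred-like
#' identification quality, \code{NA} when unknown) and \code{coverage}
#' (read depth, \code{NA} when unknown). The key
#' \code{(seqid, position, strand, mod_type)} is unique within one sample;
#' constructors collapse duplicates keeping the highest score.
#'
#' @slot sampleId single character, free-text sample label.
#' @slot calls \code{GRanges} of width-1 stranded positions with the
#'   metadata columns described above.
#'
#' @aliases Methylome-class
#' @exportClass Methylome
#' @export Methylome
setClass("Methylome",
  representation(sampleId = "character", calls = "GRanges"))

setValidity("Methylome", function(object) {
  msgs <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msgs <- c(msgs, "sampleId must be a single non-NA string")
  gr <- object@calls
  mc <- S4Vectors::mcols(gr)
  if (!all(c("mod_type", "score", "coverage") %in% colnames(mc)))
    msgs <- c(msgs, "calls must carry mod_type, score and coverage columns")
  else {
    if (!all(mc$mod_type %in% MOD_TYPES))
      msgs <- c(msgs, paste0("mod_type must be one of ",
                             paste(MOD_TYPES, collapse = ", ")))
    if (length(gr) && !all(BiocGenerics::width(gr) == 1L))
      msgs <- c(msgs, "all calls must be single-base (width 1)")
    if (length(gr) && any(as.character(BiocGenerics::strand(gr)) == "*"))
      msgs <- c(msgs, "call strand must be '+' or '-'")
    keys <- callKey(as.character(GenomeInfoDb::seqnames(gr)),
                    BiocGenerics::start(gr),
                    as.character(BiocGenerics::strand(gr)), mc$mod_type)
    if (anyDuplicated(keys))
      msgs <- c(msgs, "duplicate (seqid, position, strand, mod_type) keys")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Methylome-class Construct a \code{Methylome} from parallel
#'   vectors of call fields. Duplicate keys collapse to the call with the
#'   highest score (ties and all-\code{NA} scores keep the first).
#' @param sampleId sample label.
#' @param seqid,position,strand,modType,score,coverage parallel vectors
#'   describing one call each; \code{score} and \code{coverage} may be
#'   omitted (\code{NA}).
#' @return A \code{Methylome}.
#' @export
Methylome <- function(sampleId, seqid = character(), position = integer(),
                      strand = character(), modType = character(),
                      score = NA_real_, coverage = NA_integer_) {
  n <- length(position)
  stopifnot(length(seqid) == n, length(strand) == n, length(modType) == n)
  if (n && any(position < 1))
    stop("position must be >= 1")
  score <- rep_len(as.numeric(score), n)
  coverage <- rep_len(as.integer(coverage), n)
  keys <- callKey(seqid, position, strand, modType)
  if (anyDuplicated(keys)) {
    ## keep max score per key; NA scores sort last
    ord <- order(keys, -ifelse(is.na(score), -Inf, score))
    keep <- ord[!duplicated(keys[ord])]
    keep <- sort(keep)
    seqid <- seqid[keep]; position <- position[keep]; strand <- strand[keep]
    modType <- modType[keep]; score <- score[keep]; coverage <- coverage[keep]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = position, width = 1L),
    strand = strand,
    mod_type = modType, score = score, coverage = coverage)
  new("Methylome", sampleId = as.character(sampleId), calls = gr)
}

#' @describeIn Methylome-class Sample label accessor.
#' @param object,x a \code{Methylome}.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname Methylome-class
#' @export
setMethod("sampleId", "Methylome", function(object) object@sampleId)

#' @describeIn Methylome-class The underlying \code{GRanges} of calls.
#' @export
setGeneric("calls", function(object) standardGeneric("calls"))

#' @rdname Methylome-class
#' @export
setMethod("calls", "Methylome", function(object) object@calls)

#' @rdname Methylome-class
#' @export
setMethod("length", "Methylome", function(x) length(x@calls))

setMethod("show", "Methylome", function(object) {
  tab <- table(S4Vectors::mcols(object@calls)$mod_type)
  cat("Methylome '", object@sampleId, "': ", length(object@calls),
      " calls", sep = "")
  if (length(tab))
    cat(" (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")",
        sep = "")
  cat("\n")
})

#' Keys of every call in a methylome
#'
#' The unique identity of a call is the tuple
#' \code{(seqid, position, strand, mod_type)}; two samples are compared by
#' exact key membership.
#'
#' @param x a \code{Methylome}.
#' @return Character vector, one opaque key per call.
#' @export
methylomeKeys <- function(x) {
  stopifnot(is(x, "Methylome"))
  gr <- x@calls
  callKey(as.character(GenomeInfoDb::seqnames(gr)),
          BiocGenerics::start(gr),
          as.character(BiocGenerics::strand(gr)),
          S4Vectors::mcols(gr)$mod_type)
}

#' Restrict a methylome to given modification types or a score floor
#'
#' @param x a \code{Methylome}.
#' @param modTypes modification types to keep.
#' @param minScore drop calls with a known score below this value; calls
#'   with unknown score (\code{NA}) are kept.
#' @return A filtered \code{Methylome}.
#' @export
filterCalls <- function(x, modTypes = NULL, minScore = NULL) {
  stopifnot(is(x, "Methylome"))
  gr <- x@calls
  keep <- rep(TRUE, length(gr))
  if (!is.null(modTypes))
    keep <- keep & S4Vectors::mcols(gr)$mod_type %in% modTypes
  if (!is.null(minScore)) {
    sc <- S4Vectors::mcols(gr)$score
    keep <- keep & (is.na(sc) | sc >= minScore)
  }
  new("Methylome", sampleId = x@sampleId, calls = gr[keep])
}
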