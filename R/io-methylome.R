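#' Read a SMRT base-modification GFF3 file into a Methylome
#'
#' Parses the per-base modification report dialect emitted by SMRT
#' sequencing pipelines. Two layouts of the modification type are accepted:
#' the type token in column 3 (\code{m4C}, \code{m6A}, \code{m5C},
#' \code{modified_base}) or a \code{type=} key in the column-9 attributes
#' (which wins over a generic \code{modified_base} column 3).
#' Identification quality is taken from an \code{identificationQv=}
#' attribute and read depth from \code{coverage=} when present; column 6
#' is used as a score fallback. Records whose modification type is not one
#' of m4C/m6A/m5C are skipped with a warning; duplicate call keys collapse
#' keeping the higher score.
#'
#' @param path path to a GFF3 file; lines starting with \code{#} and blank
#'   lines are ignored.
#' @param modFilter modification types to retain (default \code{"m4C"}).
#' @param sampleId sample label for the returned object (default: file
#'   name without extension).
#' @return A \code{\link{Methylome}} of the retained calls.
#' @seealso [readMethylomeTsv()] for the equivalent tabular format.
#' @export
readBasemodsGff <- function(path, modFilter = "m4C",
                            sampleId = sub("\\.[^.]*$", "", basename(path))) {
  stopifnot(file.exists(path), length(modFilter) >= 1)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(Methylome(sampleId))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- lineNo[which(nf != 9L)[1]]
    stop("malformed GFF3 record at line ", bad, ": expected 9 tab-separated ",
         "columns, found ", nf[which(nf != 9L)[1]])
  }
  m <- do.call(rbind, fields)
  attrType <- attrValue(m[, 9], "type")
  modType <- ifelse(!is.na(attrType), attrType, m[, 3])
  known <- modType %in% MOD_TYPES
  if (any(!known)) {
    skipped <- unique(modType[!known])
    warning("skipped ", sum(!known), " record(s) with unknown mod_type ",
            "token(s): ", paste(skipped, collapse = ", "))
  }
  wanted <- known & modType %in% modFilter
  if (!any(wanted))
    return(Methylome(sampleId))
  score <- suppressWarnings(as.numeric(attrValue(m[wanted, 9],
                                                 "identificationQv")))
  fallback <- suppressWarnings(as.numeric(m[wanted, 6]))
  score[is.na(score)] <- fallback[is.na(score)]
  coverage <- suppressWarnings(as.integer(attrValue(m[wanted, 9],
                                                    "coverage")))
  pos <- as.integer(m[wanted, 4])
  out <- Methylome(sampleId,
                   seqid = m[wanted, 1], position = pos,
                   strand = m[wanted, 7], modType = modType[wanted],
                   score = score, coverage = coverage)
  msg("read ", length(out), " call(s) from ", basename(path),
      " (filter: ", paste(modFilter, collapse = ","), ")")
  out
}

## Extract `key=value` from semicolon-separated GFF3 attribute strings.
attrValue <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexpr(pat, attrs, perl = TRUE))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(pat, attrs, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' Read or write a methylome as tab-separated text
#'
#' The tabular methylome format has the header
#' \code{seqid position strand mod_type score coverage}; \code{score} and
#' \code{coverage} may be empty/NA. Reading applies the same contract as
#' \code{\link{readBasemodsGff}}: type filter, duplicate keys keep the
#' higher score. A write followed by a read reproduces the identical keyed
#' call set.
#'
#' @param path file path.
#' @param modFilter modification types to retain.
#' @param sampleId sample label (default: file name).
#' @return \code{readMethylomeTsv}: a \code{\link{Methylome}};
#'   \code{writeMethylomeTsv}: \code{path}, invisibly.
#' @export
readMethylomeTsv <- function(path, modFilter = "m4C",
                             sampleId = sub("\\.[^.]*$", "",
                                            basename(path))) {
  stopifnot(file.exists(path))
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  needed <- c("seqid", "position", "strand", "mod_type")
  missing <- setdiff(needed, colnames(df))
  if (length(missing))
    stop("methylome TSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(df))
    return(Methylome(sampleId))
  pos <- suppressWarnings(as.integer(df$position))
  if (any(is.na(pos)) || any(pos < 1))
    stop("position must be an integer >= 1 (first bad row: ",
         which(is.na(pos) | pos < 1)[1], ")")
  known <- df$mod_type %in% MOD_TYPES
  if (any(!known))
    warning("skipped ", sum(!known), " row(s) with unknown mod_type")
  keep <- known & df$mod_type %in% modFilter
  score <- if ("score" %in% colnames(df))
    suppressWarnings(as.numeric(df$score[keep])) else NA_real_
  coverage <- if ("coverage" %in% colnames(df))
    suppressWarnings(as.integer(df$coverage[keep])) else NA_integer_
  Methylome(sampleId, seqid = df$seqid[keep], position = pos[keep],
            strand = df$strand[keep], modType = df$mod_type[keep],
            score = score, coverage = coverage)
}

#' @rdname readMethylomeTsv
#' @param x a \code{Methylome} to write.
#' @export
writeMethylomeTsv <- function(x, path) {
  stopifnot(is(x, "Methylome"))
  gr <- calls(x)
  df <- data.frame(
    seqid = as.character(GenomeInfoDb::seqnames(gr)),
    position = BiocGenerics::start(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    mod_type = S4Vectors::mcols(gr)$mod_type,
    score = S4Vectors::mcols(gr)$score,
    coverage = S4Vectors::mcols(gr)$coverage)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
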