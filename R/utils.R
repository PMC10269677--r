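#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats rnorm rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

MOD_TYPES <- c("m4C", "m6A", "m5C")

## Round half-up on the given number of decimals. base::round() rounds
## half-to-even, which does not reproduce printed percentages like 87.5 -> 88
## for every input, so the rule is explicit here.
roundHalfUp <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

## Canonical call key: one modified base on one strand of one contig.
callKey <- function(seqid, position, strand, modType) {
  paste(seqid, position, strand, modType, sep = "\r")
}

msg <- function(...) {
  message("[methscreen] ", ...)
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards so generators never perturb user code.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Protein length encoded by a bacterial CDS
#'
#' Number of amino acids encoded by a single-interval CDS: the codon count
#' minus the stop codon. A 621 bp CDS therefore encodes 206 residues.
#'
#' @param cdsLength CDS length in bases (vectorised).
#' @return Integer vector of amino-acid counts.
#' @examples
#' cdsProteinLength(621)
#' @export
cdsProteinLength <- function(cdsLength) {
  stopifnot(is.numeric(cdsLength), all(cdsLength > 0))
  if (any(cdsLength %% 3 != 0)) {
    warning("CDS length not a multiple of 3 for ",
            sum(cdsLength %% 3 != 0), " input(s)")
  }
  as.integer(cdsLength %/% 3L - 1L)
}
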