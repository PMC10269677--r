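## Shared fixture builders; everything is constructed in code.

## A methylome from a compact position spec: positions on one contig,
## all m4C on '+' unless stated otherwise.
mkMeth <- function(pos, strand = "+", seqid = "chr", modType = "m4C",
                   score = NA_real_, sample = "s") {
  n <- length(pos)
  Methylome(sample, seqid = rep_len(seqid, n), position = pos,
            strand = rep_len(strand, n), modType = rep_len(modType, n),
            score = rep_len(score, n))
}

## A single gene model.
mkGene <- function(start, end, strand = "+", id = "orf1", seqid = "chr",
                   product = "Transcriptional regulator, TetR family") {
  suppressWarnings(geneModels(seqid = seqid, start = start, end = end,
                              strand = strand, geneId = id,
                              product = product))
}

## Brute-force oracle for the per-gene diff: double loop over all calls.
## Deliberately naive and independent of the package's vectorised path.
oracleDiff <- function(wt, mut, gene, promoterLen = 300) {
  wtDf <- as.data.frame(calls(wt))
  mutDf <- as.data.frame(calls(mut))
  gStart <- GenomicRanges::start(gene); gEnd <- GenomicRanges::end(gene)
  gSeq <- as.character(GenomeInfoDb::seqnames(gene))
  gStrand <- as.character(BiocGenerics::strand(gene))
  pStart <- if (gStrand == "+") max(1, gStart - promoterLen) else gEnd + 1
  pEnd <- if (gStrand == "+") gStart - 1 else gEnd + promoterLen
  inMut <- function(row) {
    any(mutDf$seqnames == row$seqnames & mutDf$start == row$start &
          mutDf$strand == row$strand & mutDf$mod_type == row$mod_type)
  }
  cdsWt <- 0; cdsLost <- 0; promWt <- 0; promLost <- 0; lostPos <- integer()
  for (i in seq_len(nrow(wtDf))) {
    row <- wtDf[i, ]
    if (row$seqnames != gSeq) next
    if (row$start >= gStart && row$start <= gEnd) {
      cdsWt <- cdsWt + 1
      if (!inMut(row)) {
        cdsLost <- cdsLost + 1
        rel <- if (gStrand == "+") row$start - gStart + 1
        else gEnd - row$start + 1
        lostPos <- c(lostPos, rel)
      }
    }
    if (pEnd >= pStart && row$start >= pStart && row$start <= pEnd) {
      promWt <- promWt + 1
      if (!inMut(row)) promLost <- promLost + 1
    }
  }
  list(cds_sites_wt = cdsWt, cds_sites_lost = cdsLost,
       cds_lost_positions = sort(lostPos),
       promoter_sites_wt = promWt, promoter_sites_lost = promLost)
}

## Brute-force oracle for region calling: label every bin, merge adjacency.
oracleRegions <- function(bins, threshold) {
  hot <- which(bins$density > threshold)
  if (!length(hot)) return(data.frame(start_ordinal = integer(),
                                      end_ordinal = integer()))
  groups <- cumsum(c(1, diff(hot) != 1))
  do.call(rbind, lapply(split(hot, groups), function(i)
    data.frame(start_ordinal = bins$start_ordinal[min(i)],
               end_ordinal = bins$end_ordinal[max(i)])))
}

## The printed log2FC triples of the twelve crossover genes (48/72/120 h),
## shipped as plain TSVs with the package.
crossoverTables <- function() {
  labs <- c("48h", "72h", "120h")
  paths <- vapply(labs, function(l)
    system.file("extdata", paste0("crossover_log2fc_", l, ".tsv"),
                package = "methscreen"), character(1))
  stopifnot(all(nzchar(paths)))
  setNames(Map(readDeTable, paths, labs), labs)
}
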