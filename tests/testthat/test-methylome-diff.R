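test_that("site assignment maps CDS and strand-aware promoter windows", {
  gene <- mkGene(1000, 1620, "+")
  # CDS call at genomic 1212 -> relative position 213 on the coding strand
  m <- mkMeth(1212)
  keys <- assignSitesToGene(m, gene)
  expect_length(keys$cds, 1L)
  expect_length(keys$promoter, 0L)
  d <- diffGeneMethylation(mkMeth(1212), mkMeth(integer()), gene)
  expect_equal(as.integer(d$cds_lost_positions[[1]]), 213L)

  # 9 bp upstream of a '+' gene falls in the 300 bp promoter window
  keys <- assignSitesToGene(mkMeth(991), gene, promoterLen = 300)
  expect_length(keys$promoter, 1L)
  expect_length(keys$cds, 0L)

  # strand mirror: just downstream of a '-' gene end is its promoter
  geneM <- mkGene(1000, 1620, "-")
  keys <- assignSitesToGene(mkMeth(1625), geneM, promoterLen = 300)
  expect_length(keys$promoter, 1L)

  # window clipped at contig position 1
  geneEdge <- mkGene(5, 400, "+")
  keys <- assignSitesToGene(mkMeth(c(1, 2, 3, 4)), geneEdge,
                            promoterLen = 300)
  expect_length(keys$promoter, 4L)
})

test_that("per-gene diff reproduces worked loss fractions", {
  gene <- mkGene(1000, 1620, "+")

  # 7 WT CDS sites, mutant retains exactly one -> 6/7 lost
  wtPos <- c(1050, 1100, 1150, 1212, 1300, 1400, 1500)
  d <- diffGeneMethylation(mkMeth(wtPos), mkMeth(1050), gene)
  expect_equal(d$cds_sites_wt, 7L)
  expect_equal(d$cds_sites_lost, 6L)
  expect_equal(d$cds_loss_fraction, 6 / 7)

  # identical samples -> nothing lost
  d0 <- diffGeneMethylation(mkMeth(wtPos), mkMeth(wtPos), gene)
  expect_equal(d0$cds_sites_lost, 0L)
  expect_equal(d0$cds_loss_fraction, 0)
  expect_equal(d0$promoter_loss_fraction, 0)

  # 5 sites on a 500 bp CDS all lost -> abundance loss exactly 1%
  g500 <- mkGene(2001, 2500, "+", "orf2")
  d5 <- diffGeneMethylation(mkMeth(c(2010, 2100, 2200, 2300, 2400)),
                            mkMeth(integer()), g500)
  expect_equal(d5$abundance_loss_fraction, 0.01)

  # full CDS + promoter loss -> both fractions 1.0
  wt <- mkMeth(c(991, 1050, 1100, 1150, 1212, 1237, 1300, 1400, 1500, 1553))
  dF <- diffGeneMethylation(wt, mkMeth(integer()), gene)
  expect_equal(dF$cds_loss_fraction, 1.0)
  expect_equal(dF$promoter_loss_fraction, 1.0)
  expect_equal(dF$promoter_sites_wt, 1L)
})

test_that("relative lost positions are reported on the coding strand", {
  # '-' gene: genomic position p maps to end - p + 1
  gene <- mkGene(1000, 1620, "-")
  d <- diffGeneMethylation(mkMeth(c(1608, 1384)), mkMeth(integer()), gene)
  expect_equal(as.integer(d$cds_lost_positions[[1]]), c(13L, 237L))
})

test_that("calls on either strand inside the CDS are counted", {
  gene <- mkGene(1000, 1620, "+")
  wt <- mkMeth(c(1475, 1476), strand = c("+", "-"))
  d <- diffGeneMethylation(wt, mkMeth(integer()), gene)
  expect_equal(d$cds_sites_wt, 2L)
  expect_equal(as.integer(d$cds_lost_positions[[1]]), c(476L, 477L))
})

test_that("genome-wide diff conserves counts and reports totals", {
  genes <- suppressWarnings(geneModels(
    "chr", c(1000, 5000), c(1999, 5999), c("+", "+"),
    c("orf1", "orf2")))
  wt <- mkMeth(c(1100, 1200, 1300, 5100, 5200, 5300, 5400))
  res <- suppressMessages(genomeWideDiff(wt, mkMeth(integer()), genes,
                                         promoterLen = 0))
  expect_equal(res$deltas$cds_sites_lost, c(3L, 4L))
  expect_equal(res$deltas$cds_loss_fraction, c(1, 1))
  expect_equal(unname(res$totals), c(7L, 0L))

  # empty mutant -> loss fraction 1 wherever WT has sites
  expect_true(all(res$deltas$cds_loss_fraction[
    res$deltas$cds_sites_wt > 0] == 1))

  # gene on a contig absent from both methylomes -> warning, zero delta
  far <- suppressWarnings(geneModels("plasmid", 100, 699, "+", "orf9"))
  expect_warning(
    resF <- genomeWideDiff(wt, mkMeth(1100), far, promoterLen = 0),
    "absent")
  expect_equal(resF$deltas$cds_sites_wt, 0L)
  expect_equal(resF$deltas$cds_loss_fraction, 0)
})

test_that("diff agrees with the brute-force double-loop oracle", {
  set.seed(42)
  for (rep in 1:25) {
    gStart <- sample(500:2000, 1)
    gLen <- sample(c(300, 600, 900), 1)
    strand <- sample(c("+", "-"), 1)
    gene <- mkGene(gStart, gStart + gLen - 1, strand)
    nWt <- sample(0:50, 1)
    pos <- sample(1:(gStart + gLen + 500), nWt, replace = TRUE)
    str <- sample(c("+", "-"), nWt, replace = TRUE)
    wt <- mkMeth(pos, strand = str)
    keepN <- sample(0:length(wt), 1)
    keep <- sort(sample(seq_len(length(wt)), keepN))
    mut <- new("Methylome", sampleId = "mut", calls = calls(wt)[keep])

    got <- diffGeneMethylation(wt, mut, gene)
    want <- oracleDiff(wt, mut, gene)
    expect_equal(got$cds_sites_wt, want$cds_sites_wt)
    expect_equal(got$cds_sites_lost, want$cds_sites_lost)
    expect_equal(sort(as.integer(got$cds_lost_positions[[1]])),
                 want$cds_lost_positions)
    expect_equal(got$promoter_sites_wt, want$promoter_sites_wt)
    expect_equal(got$promoter_sites_lost, want$promoter_sites_lost)
  }
})

test_that("diff invariants hold over randomized cases", {
  set.seed(7)
  for (rep in 1:50) {
    gene <- mkGene(1000, 1899, sample(c("+", "-"), 1))
    wt <- mkMeth(sample(500:2500, sample(1:60, 1)),
                 strand = sample(c("+", "-"), 1))
    keep <- sample(seq_len(length(wt)), sample(0:length(wt), 1))
    mut <- new("Methylome", sampleId = "m", calls = calls(wt)[sort(keep)])
    d <- diffGeneMethylation(wt, mut, gene)

    # conservation: lost + retained = wt within the CDS
    retained <- length(intersect(
      assignSitesToGene(wt, gene)$cds, assignSitesToGene(mut, gene)$cds))
    expect_equal(d$cds_sites_lost + retained, d$cds_sites_wt)
    expect_equal(length(d$cds_lost_positions[[1]]), d$cds_sites_lost)
    expect_true(all(d$cds_lost_positions[[1]] >= 1 &
                      d$cds_lost_positions[[1]] <= 900))

    # self-diff loses nothing
    expect_equal(diffGeneMethylation(wt, wt, gene)$cds_sites_lost, 0L)

    # symmetry: swapped inputs count the "gained" sites
    swapped <- diffGeneMethylation(mut, wt, gene)
    expect_equal(swapped$cds_sites_lost, 0L)  # mut is a subset of wt
  }
})

test_that("raising the score floor never increases WT site counts", {
  set.seed(11)
  gene <- mkGene(1000, 1899, "+")
  wt <- mkMeth(sample(900:2000, 40), score = sample(20:60, 40, TRUE))
  mut <- mkMeth(integer())
  prev <- Inf
  for (minScore in c(0, 30, 45, 60, 100)) {
    d <- diffGeneMethylation(wt, mut, gene, minScore = minScore)
    expect_lte(d$cds_sites_wt, prev)
    prev <- d$cds_sites_wt
  }
})

test_that("percent formatting reproduces every printed loss figure", {
  fr <- c(6 / 7, 7 / 8, 20 / 24, 12 / 13, 5 / 6, 9 / 9, 11 / 12)
  expect_equal(formatLossPercent(fr, 0),
               c("86%", "88%", "83%", "92%", "83%", "100%", "92%"))
  expect_equal(formatLossPercent(0.875, 0), "88%")  # half rounds up
  expect_equal(formatLossPercent(9 / 621, 1), "1.4%")
  expect_error(formatLossPercent(1.2), "\\[0, 1\\]")
  expect_error(formatLossPercent(-0.1), "\\[0, 1\\]")
})
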