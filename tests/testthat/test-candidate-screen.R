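## Minimal delta table builder for screening tests; only the columns the
## screen consumes are meaningful.
mkDeltas <- function(ids, ordinals, lost, wt, cdsLen = 621,
                     promLost = 0, promWt = 0) {
  n <- length(ids)
  S4Vectors::DataFrame(
    gene_id = ids, orf_ordinal = as.integer(ordinals),
    product = rep("x", n), mod_type = "m4C",
    cds_length = rep_len(as.integer(cdsLen), n),
    cds_sites_wt = as.integer(wt), cds_sites_lost = as.integer(lost),
    cds_loss_fraction = ifelse(wt > 0, lost / wt, 0),
    cds_lost_positions = IRanges::IntegerList(
      lapply(lost, function(k) seq_len(k))),
    abundance_loss_fraction = lost / rep_len(cdsLen, n),
    promoter_sites_wt = as.integer(rep_len(promWt, n)),
    promoter_sites_lost = as.integer(rep_len(promLost, n)),
    promoter_loss_fraction = ifelse(rep_len(promWt, n) > 0,
                                    rep_len(promLost, n) /
                                      pmax(rep_len(promWt, n), 1), 0))
}

allReg <- function(deltas) setNames(rep(TRUE, nrow(deltas)),
                                    deltas$gene_id)

test_that("regulator keywords match products case-insensitively", {
  genes <- suppressWarnings(geneModels(
    "chr", c(1, 1001, 2001), c(900, 1900, 2900), rep("+", 3),
    c("orf1", "orf2", "orf3"),
    c("Transcriptional regulator, TetR family",
      "ABC transporter, ATP-binding protein", "")))
  flags <- identifyRegulators(genes)
  expect_equal(unname(flags), c(TRUE, FALSE, FALSE))
  expect_true(identifyRegulators(genes[1], keywords = "tetr")[[1]])
  expect_error(identifyRegulators(genes, keywords = character()))
})

test_that("the screen applies strict site-loss and rounded abundance gates", {
  # 6/7 lost = 85.7% > 80%, abundance 6/600 = 1.0% -> kept
  d <- mkDeltas(c("a", "b", "c"), c(10, 20, 30),
                lost = c(6, 7, 9), wt = c(7, 9, 9), cdsLen = 600)
  kept <- screenByMethylation(d, allReg(d))
  # b: 7/9 = 77.8% fails the site gate despite abundance 1.2%
  expect_setequal(kept$gene_id, c("a", "c"))

  # the abundance gate compares the one-decimal-rounded percent:
  # 6/631 = 0.951% rounds to 1.0% -> kept; 6/640 = 0.938% -> dropped
  dr <- mkDeltas(c("r1", "r2"), c(1, 2), lost = c(6, 6), wt = c(7, 7),
                 cdsLen = c(631, 640))
  expect_equal(screenByMethylation(dr, allReg(dr))$gene_id, "r1")

  # non-regulators are gated out before thresholding
  d9 <- mkDeltas("tagR", 4759, lost = 9, wt = 9, cdsLen = 621)
  expect_equal(nrow(screenByMethylation(d9, setNames(FALSE, "tagR"))), 0L)
  expect_equal(nrow(screenByMethylation(d9, allReg(d9))), 1L)

  # exact 80% site loss does not pass the strict gate
  d8 <- mkDeltas("e", 1, lost = 8, wt = 10, cdsLen = 500)
  expect_equal(nrow(screenByMethylation(d8, allReg(d8))), 0L)

  # minimum WT site floor
  expect_equal(nrow(screenByMethylation(d9, allReg(d9), minWtSites = 10)),
               0L)
})

test_that("raising either screen threshold yields a subset", {
  set.seed(13)
  n <- 80
  d <- mkDeltas(sprintf("g%d", 1:n), 1:n,
                lost = sample(0:20, n, TRUE), wt = sample(1:20, n, TRUE),
                cdsLen = sample(c(300, 600, 900, 1200), n, TRUE))
  d$cds_sites_lost <- pmin(d$cds_sites_lost, d$cds_sites_wt)
  d$cds_loss_fraction <- d$cds_sites_lost / d$cds_sites_wt
  d$abundance_loss_fraction <- d$cds_sites_lost / d$cds_length
  base <- screenByMethylation(d, allReg(d), 0.5, 0.005)
  for (args in list(c(0.8, 0.005), c(0.5, 0.02), c(0.9, 0.03))) {
    sub <- screenByMethylation(d, allReg(d), args[1], args[2])
    expect_true(all(sub$gene_id %in% base$gene_id))
  }
})

test_that("region flags mark exactly the published in-region ordinals", {
  regions <- data.frame(
    start_ordinal = c(700, 1600, 2200, 4700),
    end_ordinal = c(900, 1700, 2300, 4900))
  ords <- c(199, 441, 1070, 1818, 2391, 4759, 4820)
  cand <- mkDeltas(sprintf("orf%d", ords), ords,
                   lost = rep(9, 7), wt = rep(9, 7))
  cand$is_regulator <- TRUE
  flagged <- flagInRegion(cand, regions)
  expect_equal(flagged$gene_id[flagged$in_dense_region],
               c("orf4759", "orf4820"))

  expect_false(any(flagInRegion(cand, regions[0, ])$in_dense_region))
  one <- flagInRegion(mkDeltas("x", 1650, 1, 1),
                      data.frame(start_ordinal = 1600,
                                 end_ordinal = 1700))
  expect_true(one$in_dense_region)
})

test_that("ranking orders by region, promoter loss, CDS loss, ordinal", {
  d <- mkDeltas(c("orf4759", "orf4820"), c(4759, 4820),
                lost = c(9, 11), wt = c(9, 12),
                promLost = c(1, 0), promWt = c(1, 0))
  d$in_dense_region <- TRUE
  r <- rankCandidates(d)
  expect_equal(r$gene_id[r$rank == 1], "orf4759")

  # in-region beats a higher promoter loss outside
  d2 <- mkDeltas(c("out", "in"), c(10, 1650), lost = c(9, 9),
                 wt = c(9, 9), promLost = c(1, 0), promWt = c(1, 0))
  d2$in_dense_region <- c(FALSE, TRUE)
  expect_equal(rankCandidates(d2)$gene_id[1], "in")

  # identical candidates tie-break on the lower ordinal
  d3 <- mkDeltas(c("g2", "g1"), c(20, 10), lost = c(9, 9), wt = c(9, 9))
  d3$in_dense_region <- FALSE
  expect_equal(rankCandidates(d3)$gene_id, c("g1", "g2"))

  # ranking is input-order invariant (total order)
  set.seed(31)
  n <- 40
  big <- mkDeltas(sprintf("g%d", 1:n), sample(1:5000, n),
                  lost = sample(5:9, n, TRUE), wt = 9,
                  promLost = sample(0:1, n, TRUE), promWt = 1)
  big$in_dense_region <- sample(c(TRUE, FALSE), n, TRUE)
  r1 <- rankCandidates(big)
  r2 <- rankCandidates(big[sample(n), ])
  expect_equal(as.data.frame(r1), as.data.frame(r2))

  # flags must be set before ranking
  expect_error(rankCandidates(mkDeltas("x", 1, 1, 1)), "flagInRegion")
})

test_that("noiseless planted truth is recovered end-to-end, exactly", {
  genes <- generateAnnotation(600, regulatorFraction = 0.1, seed = 19)
  spans <- data.frame(start_ordinal = 200, end_ordinal = 300)
  regIds <- names(which(identifyRegulators(genes)))
  inSpan <- genes$gene_id[ordinalInRegions(genes$orf_ordinal, spans)]
  planted <- intersect(regIds, inSpan)[1:2]
  sim <- generateMethylomes(genes, plantedCandidates = planted,
                            backgroundLossRate = 0, seed = 20)
  res <- suppressMessages(genomeWideDiff(sim$wt, sim$mut, genes))

  # zero background: loss is exactly 1 for planted genes, 0 elsewhere
  plantedRows <- res$deltas$gene_id %in% planted
  expect_true(all(res$deltas$cds_loss_fraction[plantedRows] == 1))
  neighborOk <- res$deltas$cds_loss_fraction[!plantedRows]
  ## promoter windows of planted genes may clip a neighbour's CDS edge;
  ## no non-planted gene may lose more than a boundary sliver
  expect_true(all(neighborOk < 0.5))

  tab <- generatePathwayTable(genes, spans, seed = 21)
  regions <- callDenseRegions(computeBinDensities(genes, tab))
  cand <- rankCandidates(flagInRegion(
    screenByMethylation(res$deltas, identifyRegulators(genes)), regions))
  expect_setequal(cand$gene_id[cand$in_dense_region], planted)
})
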