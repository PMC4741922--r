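mkGenes <- function(starts, ends, strands, names,
                    chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = starts + 1,
                                                       end = ends),
                               strand = strands)
  S4Vectors::mcols(gr)$gene <- names
  gr
}

test_that("the genic boundary is inclusive at exactly 2 kb upstream of the TSS", {
  gm <- tinyGenome(c(chr1 = 1e6))
  # plus-strand gene [10000, 20000); minus-strand gene [50000, 60000)
  genes <- mkGenes(c(10000, 50000), c(20000, 60000), c("+", "-"),
                   c("gPlus", "gMinus"))
  probe <- function(pos) {
    ev <- makeEvents("chr1", pos, "chr1", 900000L, svType = "DEL", genome = gm)
    genicBreakpoints(list(ev), genes, gm)$count
  }
  expect_equal(probe(8000L), 1L)   # exactly 2000 bp upstream: genic
  expect_equal(probe(7999L), 0L)   # 2001 bp upstream: not genic
  expect_equal(probe(61999L), 1L)  # minus strand: 2000 bp upstream of TSS
  expect_equal(probe(62000L), 0L)
  expect_equal(probe(19999L), 1L)  # last base of the gene body
  expect_equal(probe(20000L), 0L)  # half-open end
})

test_that("genic breakpoint counting reports fractions, genes and rearrangements", {
  gm <- tinyGenome(c(chr1 = 1e6))
  genes <- mkGenes(100000, 200000, "+", "gA")
  ev <- makeEvents("chr1", c(150000L, 150500L), "chr1", c(400000L, 160000L),
                   svType = "DEL", genome = gm)
  gb <- genicBreakpoints(list(ev), genes, gm)
  expect_equal(gb$count, 3L)
  expect_equal(gb$nTotal, 4L)
  expect_equal(gb$fractionPct, 75)
  expect_equal(gb$affectedGenes, "gA")
  expect_equal(gb$nRearrangementsWithGenic, 2L)
  empty <- genicBreakpoints(list(ev), GenomicRanges::GRanges())
  expect_equal(empty$fractionPct, 0)
})

test_that("genic null hits the closed-form extremes", {
  cfg <- SimConfig(seed = 3, chromLengths = c(chr1 = 1e6, chr2 = 1e6))
  gmAll <- GenomeModel(cfg@chromLengths,
                       genes = mkGenes(0, 1e6 - 2000, "+", "gAll"))
  # gene plus promoter covers chr1 entirely; chr2 is gene-free
  resAll <- simulateGenicNull(50, gmAll, genomeGenes(gmAll), nSims = 50,
                              seed = 5)
  expect_true(all(resAll@nullCounts <= 50 & resAll@nullCounts >= 0))
  gmNone <- GenomeModel(cfg@chromLengths)
  resNone <- simulateGenicNull(50, gmNone, genomeGenes(gmNone), nSims = 20,
                               seed = 5)
  expect_true(all(resNone@nullCounts == 0))
})

test_that("genic null mean matches the binomial closed form", {
  cfg <- SimConfig(seed = 101, genicFractionTarget = 0.4)
  gm <- simulateGenome(cfg)
  g <- 0.4
  n <- 1000L
  res <- simulateGenicNull(n, gm, genomeGenes(gm), nSims = 500, seed = 9)
  se <- sqrt(n * g * (1 - g) / 500)
  expect_lt(abs(mean(res@nullCounts) - n * g), 3 * se + n * 0.005)
})

test_that("masked regions are excluded from the random breakpoint space", {
  lens <- c(chr1 = 1e6, chr2 = 1e6)
  # chr1 fully genic, chr2 fully masked: every unmasked position is genic
  masks <- list(centromere = GenomicRanges::GRanges(
    "chr2", IRanges::IRanges(1, 1e6)))
  gm <- GenomeModel(lens, masks = masks,
                    genes = mkGenes(0, 1e6, "+", "g1"))
  res <- simulateGenicNull(100, gm, genomeGenes(gm), nSims = 30, seed = 11)
  expect_true(all(res@nullCounts == 100))
})

test_that("two-sided empirical p values follow the tail-doubling rule", {
  nullCounts <- c(rep(26, 9998), 46, 47)
  pr <- empiricalTwoSidedP(46, nullCounts)
  expect_equal(pr$p, 0.0004)
  expect_false(pr$bound)
  prB <- empiricalTwoSidedP(100, nullCounts)
  expect_equal(prB$p, 2 / 10000)
  expect_true(prB$bound)
  # mirror tail below the median
  prLow <- empiricalTwoSidedP(20, c(rep(30, 98), 20, 19))
  expect_equal(prLow$p, 0.04)
  # p is capped at 1
  expect_lte(empiricalTwoSidedP(26, nullCounts)$p, 1)
})

test_that("fold enrichment is reported to one decimal", {
  expect_equal(foldEnrichment(46, 26), 1.8)
  expect_equal(foldEnrichment(26, 26), 1.0)
})

test_that("cancer-gene null is hypergeometric", {
  universe <- sprintf("g%04d", 1:1000)
  cancer <- universe[1:80]
  affected <- universe[101:200]
  res <- cancerGeneEnrichment(affected, universe, cancer, nSims = 3000,
                              seed = 13)
  expect_equal(res@observed, 0)
  # goodness of fit of the simulated null against dhyper
  pHyper <- stats::dhyper(0:25, 80, 920, 100)
  cum <- cumsum(pHyper)
  lo <- max(which(cum < 0.01))  # collapse sparse tails into single bins
  hi <- min(which(cum > 0.99))
  brk <- c(-1, (lo - 1):(hi - 1), Inf)
  obs <- as.numeric(table(cut(res@nullCounts, breaks = brk)))
  expProb <- c(cum[lo], pHyper[(lo + 1):hi], 1 - cum[hi])
  gof <- suppressWarnings(stats::chisq.test(obs, p = expProb))
  expect_gt(gof$p.value, 0.01)
})

test_that("degenerate cancer-gene draws behave as expected", {
  universe <- sprintf("g%03d", 1:50)
  res <- cancerGeneEnrichment(universe[1:10], universe, universe,
                              nSims = 100, seed = 17)
  expect_true(all(res@nullCounts == 10))
  expect_equal(res@fold, 1.0)
  expect_error(cancerGeneEnrichment("missing", universe, universe), "subset")
})

test_that("affected-gene table deduplicates shared events across samples", {
  gm <- tinyGenome(c(chr1 = 1e6))
  genes <- mkGenes(c(100000, 500000), c(200000, 600000), c("+", "+"),
                   c("gA", "gB"))
  # one shared event in two samples of one patient: 1 unique rearrangement
  s1 <- makeEvents("chr1", 150000L, "chr1", 700000L, svType = "DEL",
                   sampleId = "P1_P", genome = gm)
  s2 <- makeEvents("chr1", 150100L, "chr1", 700100L, svType = "DEL",
                   sampleId = "P1_M", genome = gm)
  # gB hit by 3 distinct events in 2 patients
  s3 <- makeEvents("chr1", c(510000L, 550000L), "chr1", c(800000L, 820000L),
                   svType = "DEL", sampleId = "P2_P", genome = gm)
  s4 <- makeEvents("chr1", 590000L, "chr1", 900000L, svType = "DEL",
                   sampleId = "P3_P", genome = gm)
  patientOf <- c(P1_P = "P1", P1_M = "P1", P2_P = "P2", P3_P = "P3")
  tab <- affectedGeneTable(list(P1_P = s1, P1_M = s2, P2_P = s3, P3_P = s4),
                           genes, patientOf = patientOf)
  expect_equal(tab$gene, c("gB", "gA"))  # sorted by unique count desc
  expect_equal(tab$nRearrangements, c(3L, 1L))
  expect_equal(tab$nPatients, c(2L, 1L))
  empty <- affectedGeneTable(list(s = Rearrangements(genome = gm)), genes)
  expect_equal(nrow(empty), 0L)
})

test_that("validation summary reproduces the published percentages", {
  vs <- validationSummary(sharedTested = 62, sharedConfirmed = 62,
                          sharedGermline = 8, specificTested = 51,
                          specificConfirmed = 41)
  expect_equal(vs$sharedPct, 100)
  expect_equal(vs$specificPct, 80)
  # both germline-exclusion variants are emitted
  expect_equal(vs$overallPct[["subtract"]], 90)  # (62-8+41)/(62-8+51)
  expect_equal(vs$overallPct[["keep"]], 91)      # (62+41)/113
  none <- validationSummary(0, 0, 0, 10, 8)
  expect_true(is.na(none$sharedPct))
  expect_equal(none$specificPct, 80)
})
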