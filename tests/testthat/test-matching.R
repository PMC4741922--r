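test_that("windowed matching is inclusive at the 500 bp boundary", {
  a <- makeEvents("chr1", 10000L, "chr2", 20000L)
  expect_true(breakpointsMatch(a, makeEvents("chr1", 10000L, "chr2", 20000L)))
  expect_true(breakpointsMatch(a, makeEvents("chr1", 10500L, "chr2", 20500L)))
  expect_false(breakpointsMatch(a, makeEvents("chr1", 10000L, "chr2", 20501L)))
  expect_false(breakpointsMatch(a, makeEvents("chr1", 10000L, "chr3", 20000L)))
  # type labels do not matter
  expect_true(breakpointsMatch(makeEvents("chr1", 1e4, "chr1", 2e4, svType = "DEL"),
                               makeEvents("chr1", 1e4, "chr1", 2e4, svType = "INV")))
})

test_that("greedy matching picks the nearest candidate and breaks ties deterministically", {
  a <- makeEvents("chr1", 10000L, "chr1", 50000L, svType = "DEL")
  b2 <- makeEvents("chr1", c(10010L, 10400L), "chr1", c(50000L, 50000L),
                   svType = "DEL", sampleId = "b")
  m <- matchCatalogues(a, b2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$iB, 1L)  # distance 10 beats 400
  expect_equal(m$distLeft, 10L)

  # equal distances: the lower-coordinate b candidate wins, repeatably
  bTie <- makeEvents("chr1", c(10100L, 9900L), "chr1", c(50000L, 50000L),
                     svType = "DEL", sampleId = "b")
  for (i in 1:3) {
    mt <- matchCatalogues(a, bTie)
    expect_equal(eventTable(bTie)$pos1[mt$iB], 9900L)
  }
  expect_equal(nrow(matchCatalogues(a, makeEvents("chr3", 1e4, "chr3", 5e4))), 0L)
})

test_that("rescue reclassifies specific events with sub-threshold partner calls", {
  gm <- tinyGenome()
  catA <- makeEvents("chr1", 10000L, "chr2", 20000L, sampleId = "a", genome = gm)
  catB <- Rearrangements(genome = gm)
  rawHit <- makeEvents("chr1", 10100L, "chr2", 20100L, support = 2L,
                       sampleId = "b", genome = gm)
  pc <- classifyPair(catA, catB, rawB = rawHit)
  expect_equal(sharedCount(pc), 1L)
  expect_equal(sharedEvents(pc)$provenance, "rescued")
  expect_equal(sharedEvents(pc)$supportB, 2L)
  expect_equal(totalCounts(pc), c(a = 1L, b = 1L))

  rawMiss <- makeEvents("chr1", 10600L, "chr2", 20000L, support = 2L, genome = gm)
  pc2 <- classifyPair(catA, catB, rawB = rawMiss)
  expect_equal(sharedCount(pc2), 0L)
  pc3 <- classifyPair(catA, catB, rawB = Rearrangements(genome = gm))
  expect_equal(sharedCount(pc3), 0L)
})

test_that("look-up needs a single read pair supporting both ends", {
  gm <- tinyGenome()
  catA <- makeEvents("chr1", 10000L, "chr2", 20000L, sampleId = "a", genome = gm)
  catB <- Rearrangements(genome = gm)
  evHit <- EvidenceIndex(data.frame(readname = "rp1", chrom1 = "chr1",
                                    pos1 = 10200L, chrom2 = "chr2",
                                    pos2 = 19800L), gm)
  pc <- classifyPair(catA, catB, evB = evHit)
  expect_equal(sharedEvents(pc)$provenance, "looked_up")
  expect_equal(sharedEvents(pc)$supportB, 1L)

  oneEnd <- EvidenceIndex(data.frame(readname = "rp1", chrom1 = "chr1",
                                     pos1 = 10200L, chrom2 = "chr2",
                                     pos2 = 30000L), gm)
  pc2 <- classifyPair(catA, catB, evB = oneEnd)
  expect_equal(sharedCount(pc2), 0L)
  expect_equal(nrow(specificEvents(pc2)$a), 1L)
  pc3 <- classifyPair(catA, catB, evB = EvidenceIndex(genome = gm))
  expect_equal(sharedCount(pc3), 0L)
})

test_that("classification order is direct, then rescue, then look-up", {
  gm <- tinyGenome()
  catA <- makeEvents("chr1", c(10000L, 100000L, 300000L), "chr2",
                     c(10000L, 100000L, 300000L), sampleId = "a", genome = gm)
  catB <- makeEvents("chr1", 10100L, "chr2", 10100L, sampleId = "b", genome = gm)
  rawB <- makeEvents("chr1", c(10100L, 100200L), "chr2", c(10100L, 100200L),
                     support = c(8L, 2L), sampleId = "b", genome = gm)
  evB <- EvidenceIndex(data.frame(readname = "rp", chrom1 = "chr1",
                                  pos1 = 300100L, chrom2 = "chr2",
                                  pos2 = 300100L), gm)
  pc <- classifyPair(catA, catB, rawB = rawB, evB = evB)
  sh <- sharedEvents(pc)
  expect_setequal(sh$provenance, c("direct", "rescued", "looked_up"))
  expect_equal(sharedCount(pc), 3L)
  expect_equal(nrow(specificEvents(pc)$a), 0L)
})

test_that("pair ledger stays consistent and symmetric on synthetic pairs", {
  cfg <- SimConfig(seed = 17, nPrimaryEvents = 60L, nGermline = 0L)
  tr <- simulatePatient(cfg)
  pri <- renderObserved(tr, "primary")
  met <- renderObserved(tr, "metastasis")
  pc <- classifyPair(pri$catalogue, met$catalogue, rawA = pri$rawCalls,
                     rawB = met$rawCalls, evA = pri$evidence, evB = met$evidence)
  pcSwap <- classifyPair(met$catalogue, pri$catalogue, rawA = met$rawCalls,
                         rawB = pri$rawCalls, evA = met$evidence,
                         evB = pri$evidence)
  expect_equal(sharedCount(pc), sharedCount(pcSwap))
  expect_equal(totalCounts(pc)[["a"]], totalCounts(pcSwap)[["b"]])
  # ledger: catalogue size = direct + own-side recoveries + specific
  sh <- sharedEvents(pc)
  expect_equal(length(pri$catalogue),
               sum(sh$side == "both") + sum(sh$side == "a") +
                 nrow(specificEvents(pc)$a))
  expect_equal(length(met$catalogue),
               sum(sh$side == "both") + sum(sh$side == "b") +
                 nrow(specificEvents(pc)$b))
})

test_that("widening the window never loses shared events", {
  set.seed(23)
  gm <- tinyGenome()
  for (rep in 1:5) {
    a <- randomEvents(25, gm, sampleId = "a")
    evB <- eventTable(a)
    evB$pos1 <- pmax(0L, evB$pos1 + as.integer(round(rnorm(25, 0, 300))))
    evB$pos2 <- pmax(evB$pos1, evB$pos2 + as.integer(round(rnorm(25, 0, 300))))
    b <- Rearrangements(evB, gm)
    counts <- vapply(c(0, 100, 300, 500, 1000), function(w)
      sharedCount(classifyPair(a, b, window = w)), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("disjoint and identical synthetic pairs hit the expected extremes", {
  gm <- tinyGenome()
  set.seed(29)
  a <- randomEvents(15, gm, sampleId = "a")
  pcSame <- classifyPair(a, a)
  expect_equal(sharedCount(pcSame), 15L)
  expect_equal(nrow(specificEvents(pcSame)$a), 0L)

  b <- makeEvents("chr3", seq(1e5, 5e5, by = 1e5),
                  "chr3", seq(6e5, 9.9e5, length.out = 5), svType = "INV",
                  sampleId = "b", genome = gm)
  aSmall <- makeEvents("chr1", seq(1e4, 5e4, by = 1e4), "chr2",
                       seq(1e4, 5e4, by = 1e4), sampleId = "a", genome = gm)
  pcDis <- classifyPair(aSmall, b)
  expect_equal(sharedCount(pcDis), 0L)
  expect_equal(totalCounts(pcDis), c(a = 5L, b = 5L))
})

test_that("greedy matching attains the maximum matching on random fixtures", {
  set.seed(37)
  gm <- tinyGenome(c(chr1 = 1e6))
  for (rep in 1:50) {
    nA <- sample(5:30, 1)
    base <- sort(sample.int(9e5, nA))
    a <- makeEvents("chr1", base, "chr1", base + 50000L, svType = "DEL",
                    sampleId = "a", genome = gm)
    evB <- eventTable(a)[sample(nA, sample(3:nA, 1)), , drop = FALSE]
    evB$pos1 <- pmax(0L, evB$pos1 + as.integer(round(rnorm(nrow(evB), 0, 200))))
    evB$pos2 <- evB$pos2 + as.integer(round(rnorm(nrow(evB), 0, 200)))
    b <- Rearrangements(evB, gm)
    greedy <- nrow(matchCatalogues(a, b))
    expect_equal(greedy, oracleMaxMatching(a, b))
  }
})
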