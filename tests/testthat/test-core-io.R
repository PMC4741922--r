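test_that("bedpe reader canonicalizes breakpoint order and parses support", {
  gm <- tinyGenome()
  path <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\tscore",
               "chr2\t99\t100\tchr1\t49\t50\tr1\t7"), path)
  rr <- readRearrangements(path, "bedpe", gm)
  ev <- eventTable(rr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$chrom1, "chr1")
  expect_equal(ev$pos1, 49L)
  expect_equal(ev$chrom2, "chr2")
  expect_equal(ev$pos2, 99L)
  expect_equal(ev$svType, "CTX")
  expect_equal(ev$support, 7L)
})

test_that("breakdancer reader converts 1-based positions and keeps DEL spans", {
  gm <- tinyGenome()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#Chr1\tPos1\tOrientation1\tChr2\tPos2\tOrientation2\tType\tSize\tScore\tnum_Reads",
               "chr1\t1001\t12+3-\tchr1\t9001\t10+2-\tDEL\t8000\t99\t12",
               "chr1\t500\t5+\tchr2\t700\t6+\tCTX\t-1\t80\t6\textra\tcols"),
             path)
  rr <- readRearrangements(path, "breakdancer_tsv", gm)
  ev <- eventTable(rr)
  expect_equal(ev$pos1, c(1000L, 499L))
  expect_equal(ev$pos2, c(9000L, 699L))
  expect_equal(ev$svType, c("DEL", "CTX"))
  expect_equal(svSpan(rr), c(8000L, NA))
  expect_equal(ev$support, c(12L, 6L))
})

test_that("records on unknown chromosomes are dropped with a logged count", {
  gm <- tinyGenome(c(chr1 = 1e6))
  path <- withr::local_tempfile()
  writeLines(c("chr1\t10\t11\tchr1\t50000\t50001\tr1\t5",
               "chrUn\t10\t11\tchr1\t50000\t50001\tr2\t5"), path)
  withr::local_options(svconcord.quiet = FALSE)
  expect_message(rr <- readRearrangements(path, "bedpe", gm), "dropped 1")
  expect_equal(length(rr), 1L)
})

test_that("malformed lines raise an error naming the line number", {
  gm <- tinyGenome()
  path <- withr::local_tempfile()
  writeLines(c("chr1\t10\t11\tchr1\t50000\t50001\tr1\t5",
               "chr1\t10\t11"), path)
  expect_error(readRearrangements(path, "bedpe", gm), "line 2")
  writeLines(c("chr1\tten\t11\tchr1\t50000\t50001\tr1\t5"), path)
  expect_error(readRearrangements(path, "bedpe", gm), "line 1")
})

test_that("empty files yield empty objects, and writers emit a header", {
  gm <- tinyGenome()
  path <- withr::local_tempfile()
  writeLines(character(), path)
  expect_equal(length(readRearrangements(path, "bedpe", gm)), 0L)
  out <- withr::local_tempfile()
  writeRearrangements(Rearrangements(genome = gm), out)
  expect_true(startsWith(readLines(out)[1], "#chrom1"))
  expect_equal(length(readLines(out)), 1L)
})

test_that("write/read round-trips randomized event sets including origin", {
  gm <- tinyGenome()
  set.seed(42)
  for (rep in 1:10) {
    rr <- randomEvents(sample(0:25, 1), gm)
    ev <- eventTable(rr)
    if (nrow(ev)) ev$origin[sample(nrow(ev), 1)] <- "rescued"
    rr <- Rearrangements(ev, gm)
    path <- withr::local_tempfile(fileext = ".bedpe")
    writeRearrangements(rr, path)
    back <- readRearrangements(path, "bedpe", gm)
    cols <- c("chrom1", "pos1", "chrom2", "pos2", "svType", "support",
              "sampleId", "origin")
    expect_equal(eventTable(back)[cols], eventTable(rr)[cols])
  }
})

test_that("canonical ordering is idempotent and total", {
  gm <- tinyGenome()
  set.seed(7)
  rr <- randomEvents(50, gm)
  ev <- eventTable(rr)
  idx1 <- match(ev$chrom1, chromNames(gm))
  idx2 <- match(ev$chrom2, chromNames(gm))
  expect_true(all(idx1 < idx2 | (idx1 == idx2 & ev$pos1 <= ev$pos2)))
  again <- Rearrangements(ev, gm)
  expect_equal(eventTable(again), ev)
})

test_that("SEG reader accepts abutting segments and rejects overlaps", {
  gm <- tinyGenome()
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tcn",
               "s1\tchr1\t0\t100\t2.0",
               "s1\tchr1\t100\t200\t3"), path)
  prof <- readCnSegments(path, gm)
  expect_named(prof, "s1")
  expect_equal(cnSegments(prof$s1)$cn, c(2.0, 3.0))
  writeLines(c("sample\tchrom\tstart\tend\tcn",
               "s1\tchr1\t0\t150\t2",
               "s1\tchr1\t100\t200\t3"), path)
  expect_error(readCnSegments(path, gm), "overlapping")
})

test_that("BED interval and gene readers validate coordinates and strand", {
  gm <- tinyGenome()
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", bed)
  gr <- readIntervals(bed, gm)
  expect_equal(GenomicRanges::start(gr), 1L)  # 0-based half-open input
  expect_equal(GenomicRanges::end(gr), 100L)
  writeLines("chr1\t100\t100", bed)
  expect_error(readIntervals(bed, gm), "end <= start")
  genes <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t5000\tgeneA\t0\t-", genes)
  gg <- readGenes(genes, gm)
  expect_equal(as.character(GenomicRanges::strand(gg)), "-")
  expect_equal(S4Vectors::mcols(gg)$gene, "geneA")
})

test_that("evidence TSV round-trips and is queryable", {
  gm <- tinyGenome()
  ev <- EvidenceIndex(data.frame(readname = c("r1", "r2"),
                                 chrom1 = c("chr2", "chr1"),
                                 pos1 = c(5000L, 100L),
                                 chrom2 = c("chr1", "chr1"),
                                 pos2 = c(100L, 9000L),
                                 stringsAsFactors = FALSE), gm)
  # canonicalized: r1 becomes chr1:100 / chr2:5000
  expect_equal(ev@pairs$chrom1, c("chr1", "chr1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEvidence(ev, path)
  back <- readEvidence(path, gm)
  expect_equal(back@pairs, ev@pairs)
  expect_equal(queryEvidence(ev, "chr1", 300, "chr2", 5100, window = 500), 1L)
  expect_equal(queryEvidence(ev, "chr1", 300, "chr2", 5100, window = 100), 0L)
})
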