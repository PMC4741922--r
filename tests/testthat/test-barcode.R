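test_that("identical events from two samples collapse into one shared column", {
  gm <- tinyGenome()
  a <- makeEvents("chr1", 1e4, "chr2", 2e4, sampleId = "s1", genome = gm)
  b <- makeEvents("chr1", 1e4 + 100, "chr2", 2e4 - 100, sampleId = "s2",
                  genome = gm)
  bm <- buildNonredundant(list(s1 = a, s2 = b))
  expect_equal(dim(barcodeMatrix(bm)), c(2L, 1L))
  expect_true(all(barcodeMatrix(bm) == 1L))
})

test_that("single-linkage chains events beyond the pairwise window", {
  gm <- tinyGenome()
  # left offsets 0/400/800: 0-800 exceeds the window but chains through 400
  cats <- list(
    s1 = makeEvents("chr1", 10000L, "chr2", 20000L, sampleId = "s1", genome = gm),
    s2 = makeEvents("chr1", 10400L, "chr2", 20000L, sampleId = "s2", genome = gm),
    s3 = makeEvents("chr1", 10800L, "chr2", 20000L, sampleId = "s3", genome = gm))
  bm <- buildNonredundant(cats)
  expect_equal(ncol(barcodeMatrix(bm)), 1L)
  expect_equal(barcodeColumns(bm)$nMembers, 3L)
  # representative is the member with the median left coordinate
  expect_equal(barcodeColumns(bm)$posLeft, 10400L)
})

test_that("disjoint catalogues give an identity-like matrix ordered by genome position", {
  gm <- tinyGenome()
  cats <- list(
    s1 = makeEvents("chr2", 5e5, "chr3", 5e5, sampleId = "s1", genome = gm),
    s2 = makeEvents("chr1", 1e4, "chr2", 1e4, sampleId = "s2", genome = gm))
  bm <- buildNonredundant(cats)
  m <- barcodeMatrix(bm)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(sum(m), 2L)
  expect_equal(barcodeColumns(bm)$chrom1, c("chr1", "chr2"))
  expect_equal(unname(m["s2", 1]), 1L)  # column 1 is the chr1 event
})

test_that("column count never exceeds event count, equality iff nothing matches", {
  gm <- tinyGenome()
  set.seed(53)
  cats <- list(s1 = randomEvents(20, gm, "s1"), s2 = randomEvents(20, gm, "s2"))
  bm <- buildNonredundant(cats)
  expect_lte(ncol(barcodeMatrix(bm)), 40L)
  # permuting input order changes only row order
  bm2 <- buildNonredundant(rev(cats))
  expect_equal(barcodeMatrix(bm2)[c("s1", "s2"), ], barcodeMatrix(bm))
  expect_equal(barcodeColumns(bm2), barcodeColumns(bm))
})

test_that("barcode intersections reproduce direct pair classification", {
  cfg <- SimConfig(seed = 59, nPrimaryEvents = 40L, nGermline = 0L,
                   jitterSd = 30)
  tr <- simulatePatient(cfg)
  pri <- renderObserved(tr, "primary", sampleId = "P")
  met <- renderObserved(tr, "metastasis", sampleId = "M")
  bm <- buildNonredundant(list(P = pri$catalogue, M = met$catalogue))
  m <- barcodeMatrix(bm)
  pc <- classifyPair(pri$catalogue, met$catalogue)  # direct matches only
  expect_equal(sum(m["P", ] & m["M", ]), sharedCount(pc))
})

test_that("binary distance agrees with base R's binary dist and handles zero unions", {
  m <- rbind(x = c(1, 1, 0), y = c(1, 0, 0))
  expect_equal(as.numeric(binaryDistance(m)), 0.5)
  expect_equal(as.numeric(binaryDistance(rbind(a = c(1, 0), b = c(1, 0)))), 0)
  expect_equal(as.numeric(binaryDistance(rbind(a = c(1, 0), b = c(0, 1)))), 1)
  set.seed(61)
  r <- matrix(rbinom(60, 1, 0.4), nrow = 6)
  r[rowSums(r) == 0, 1] <- 1  # keep unions non-empty for the oracle
  expect_equal(as.numeric(binaryDistance(r)),
               as.numeric(dist(r, method = "binary")))
  zeros <- rbind(a = c(0, 0), b = c(0, 0))
  expect_equal(as.numeric(binaryDistance(zeros)), 0)
})

test_that("ward clustering merges trivial cases at the expected heights", {
  d2 <- binaryDistance(rbind(a = c(1, 1, 0), b = c(1, 0, 0)))
  hc <- wardCluster(d2)
  expect_equal(nrow(hc$merge), 1L)
  expect_equal(hc$height, 0.5)
  same <- binaryDistance(matrix(1, 4, 3, dimnames = list(letters[1:4], NULL)))
  hcSame <- wardCluster(same)
  expect_true(all(hcSame$height == 0))
})

test_that("true synthetic pairs merge before any cross-patient merge", {
  cohort <- simulateCohort(SimConfig(seed = 67, nPrimaryEvents = 40L,
                                     sharedFraction = 0.9, nGermline = 0L),
                           nPatients = 4)
  cats <- list()
  for (p in cohort$patients) {
    cats[[p$primary$meta$sample_id]] <- p$primary$catalogue
    cats[[p$met$meta$sample_id]] <- p$met$catalogue
  }
  bm <- buildNonredundant(cats)
  hc <- wardCluster(binaryDistance(bm))
  labs <- hc$labels
  for (p in cohort$patients) {
    i <- match(p$primary$meta$sample_id, labs)
    j <- match(p$met$meta$sample_id, labs)
    pairRows <- apply(hc$merge, 1, function(r) setequal(r, c(-i, -j)))
    expect_true(any(pairRows), info = p$patientId)
  }
})

test_that("dendrograms serialize to Newick and read back", {
  m <- matrix(rbinom(30, 1, 0.5), nrow = 6,
              dimnames = list(paste0("s", 1:6), NULL))
  m[, 1] <- 1
  hc <- wardCluster(binaryDistance(m))
  path <- withr::local_tempfile(fileext = ".nwk")
  writeDendrogram(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, paste0("s", 1:6))
})
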