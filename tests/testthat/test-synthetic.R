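test_that("the generator is deterministic given the seed", {
  cfg <- SimConfig(seed = 11, nPrimaryEvents = 40L)
  t1 <- simulatePatient(cfg)
  t2 <- simulatePatient(cfg)
  expect_identical(truthEvents(t1), truthEvents(t2))
  r1 <- renderObserved(t1, "metastasis")
  r2 <- renderObserved(t2, "metastasis")
  expect_identical(eventTable(r1$catalogue), eventTable(r2$catalogue))
  expect_identical(r1$evidence@pairs, r2$evidence@pairs)
})

test_that("shared fraction controls the overlap of the true event lists", {
  full <- simulatePatient(SimConfig(seed = 2, nPrimaryEvents = 30L,
                                    sharedFraction = 1, nMetPrivate = 0L,
                                    nGermline = 0L))
  ev <- truthEvents(full)
  expect_true(all(ev$class == "shared"))

  none <- simulatePatient(SimConfig(seed = 2, nPrimaryEvents = 30L,
                                    sharedFraction = 0))
  expect_equal(sum(truthEvents(none)$class == "shared"), 0L)

  part <- simulatePatient(SimConfig(seed = 3, nPrimaryEvents = 80L,
                                    sharedFraction = 0.6))
  expect_equal(sum(truthEvents(part)$class == "shared"), round(0.6 * 80))
})

test_that("with full sharing and no jitter the two catalogues coincide", {
  cfg <- SimConfig(seed = 9, nPrimaryEvents = 40L, sharedFraction = 1,
                   nMetPrivate = 0L, nGermline = 0L, jitterSd = 0,
                   subclonalFraction = 0, lookupOnlyFraction = 0,
                   physCoveragePrimary = 60, physCoverageMet = 60,
                   clonalShape1 = 50, clonalShape2 = 1)
  tr <- simulatePatient(cfg)
  pri <- renderObserved(tr, "primary")
  met <- renderObserved(tr, "metastasis")
  cols <- c("chrom1", "pos1", "chrom2", "pos2")
  expect_equal(eventTable(pri$catalogue)[cols], eventTable(met$catalogue)[cols])
})

test_that("observed support follows the Poisson coverage x clonal-fraction model", {
  cfg <- SimConfig(seed = 5, chromLengths = c(chr1 = 5e8),
                   physCoveragePrimary = 20, jitterSd = 0)
  n <- 1000L
  set.seed(1)
  pos1 <- sort(sample.int(4.9e8, n))
  ev <- data.frame(chrom1 = "chr1", pos1 = pos1, chrom2 = "chr1",
                   pos2 = pos1 + 20000L, svType = "DEL",
                   eventId = seq_len(n), class = "primary_only",
                   cfPrimary = 0.5, cfMet = 0, metMode = "normal",
                   stringsAsFactors = FALSE)
  truth <- new("PatientTruth", events = ev, chromOrder = "chr1", config = cfg)
  raw <- renderObserved(truth, "primary")$rawCalls
  # raw calls omit support-0 events: compare the mean over all n events
  totalSupport <- sum(svSupport(raw))
  se <- sqrt(10 / n)  # Poisson(10) mean, n events
  expect_lt(abs(totalSupport / n - 10), 3 * se)
})

test_that("fully clonal events at high coverage essentially always reach the catalogue", {
  cfg <- SimConfig(seed = 6, nPrimaryEvents = 200L, sharedFraction = 0,
                   nGermline = 0L, nMetPrivate = 0L,
                   physCoveragePrimary = 20, seqCoveragePrimary = 21,
                   clonalShape1 = 1e6, clonalShape2 = 1e-3)
  # threshold 7 at 21x; Poisson(20) < 7 has probability < 1e-3
  tr <- simulatePatient(cfg)
  pri <- renderObserved(tr, "primary")
  expect_gte(length(pri$catalogue), 197L)
})

test_that("zero clonal fraction leaves no trace in calls or evidence", {
  cfg <- SimConfig(seed = 8, nPrimaryEvents = 20L, sharedFraction = 1,
                   nMetPrivate = 0L, nGermline = 0L)
  tr <- simulatePatient(cfg)
  ev <- truthEvents(tr)
  ev$cfMet <- 0
  ev$metMode <- "normal"
  truth0 <- new("PatientTruth", events = ev, chromOrder = tr@chromOrder,
                config = cfg)
  met <- renderObserved(truth0, "metastasis")
  expect_equal(length(met$catalogue), 0L)
  expect_equal(length(met$rawCalls), 0L)
  expect_equal(length(met$evidence), 0L)
})

test_that("germline events are present in both tumors and the normal pool", {
  cfg <- SimConfig(seed = 4, nPrimaryEvents = 20L, nGermline = 8L)
  tr <- simulatePatient(cfg)
  germIds <- truthEvents(tr)$eventId[truthEvents(tr)$class == "germline"]
  for (role in c("primary", "metastasis", "normal_pool")) {
    r <- renderObserved(tr, role)
    expect_true(all(germIds %in% eventTable(r$rawCalls)$eventId),
                info = role)
  }
})

test_that("event placement rejects configurations beyond genome capacity", {
  expect_error(simulatePatient(SimConfig(seed = 1, chromLengths = c(chr1 = 2e4),
                                         nPrimaryEvents = 500L)),
               "capacity")
})

test_that("CN profile sharing is recovered by the event-based similarity", {
  gmBig <- GenomeModel(SimConfig()@chromLengths)
  cfg <- SimConfig(seed = 13, cnNSegments = 200L, cnAberrantFraction = 0.5,
                   cnSharedFraction = 0.4)
  prof <- simulateCnProfiles(cfg)
  win <- unionWindows(prof$primary, prof$metastasis, gmBig)
  expect_equal(cnEventSimilarity(win), 40, tolerance = 0.02)

  ident <- simulateCnProfiles(SimConfig(seed = 13, cnSharedFraction = 1))
  expect_equal(cnSegments(ident$primary)$cn, cnSegments(ident$metastasis)$cn)

  flat <- simulateCnProfiles(SimConfig(seed = 13, cnAberrantFraction = 0))
  expect_true(all(cnSegments(flat$primary)$cn == 2))
  expect_true(all(cnSegments(flat$metastasis)$cn == 2))
})

test_that("synthetic annotation hits the genic footprint target exactly", {
  cfg <- SimConfig(seed = 21, genicFractionTarget = 0.433)
  ann <- simulateAnnotation(cfg)
  ext <- extendedGeneSpans(ann$genes)
  footprint <- sum(GenomicRanges::width(GenomicRanges::reduce(ext,
                                                              ignore.strand = TRUE)))
  target <- 0.433 * sum(SimConfig()@chromLengths)
  expect_lt(abs(footprint - target) / target, 0.01)
  expect_equal(length(ann$cancerGenes), 50L)
  expect_true(all(ann$cancerGenes %in% S4Vectors::mcols(ann$genes)$gene))

  none <- simulateAnnotation(SimConfig(seed = 21, genicFractionTarget = 0))
  expect_equal(length(none$genes), 0L)
  gb <- genicBreakpoints(list(randomEvents(10)), none$genes)
  expect_equal(gb$fractionPct, 0)
})

test_that("cancer subset size is configurable and exact", {
  ann <- simulateAnnotation(SimConfig(seed = 3, nCancerGenes = 7L))
  expect_equal(length(ann$cancerGenes), 7L)
})
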