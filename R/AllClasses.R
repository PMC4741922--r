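#' @import methods
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomicRanges GRanges seqnames start end strand findOverlaps countOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqnames
NULL

# required columns of the event table backing a Rearrangements object
.EVENT_COLS <- c("chrom1", "pos1", "chrom2", "pos2", "svType", "support",
                 "sampleId", "origin")
.SV_TYPES <- c("CTX", "ITX", "DEL", "INV")
.ORIGINS <- c("called", "rescued", "looked_up", "synthetic")

#' Genome model: chromosomes, masks, genes and cancer-gene subset
#'
#' Holds the ordered chromosome names and lengths that define canonical
#' event ordering, named interval masks (e.g. centromeres, segmental
#' duplications), a gene annotation with strand, and the subset of gene names
#' regarded as cancer-associated.
#'
#' @slot seqinfo [GenomeInfoDb::Seqinfo] with chromosome names and lengths;
#'   the order given here is the canonical chromosome order.
#' @slot masks named list of `GRanges` interval masks.
#' @slot genes `GRanges` with a `gene` metadata column and strand.
#' @slot cancerGenes character vector of cancer-associated gene names.
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(seqinfo = "Seqinfo", masks = "list", genes = "GRanges",
                 cancerGenes = "character"))

setValidity("GenomeModel", function(object) {
  msgs <- character()
  sl <- seqlengths(object@seqinfo)
  if (length(sl) == 0L) msgs <- c(msgs, "at least one chromosome required")
  if (anyNA(sl) || any(sl <= 0)) msgs <- c(msgs, "chromosome lengths must be positive")
  for (nm in names(object@masks)) {
    gr <- object@masks[[nm]]
    if (!is(gr, "GRanges")) { msgs <- c(msgs, sprintf("mask '%s' is not a GRanges", nm)); next }
    bad <- !as.character(seqnames(gr)) %in% names(sl)
    if (any(bad)) msgs <- c(msgs, sprintf("mask '%s' on unknown chromosome", nm))
    idx <- match(as.character(seqnames(gr)), names(sl))
    if (any(!bad & end(gr) > sl[idx])) msgs <- c(msgs, sprintf("mask '%s' outside chromosome bounds", nm))
  }
  if (length(object@genes) > 0 && is.null(mcols(object@genes)$gene))
    msgs <- c(msgs, "genes must carry a 'gene' metadata column")
  if (length(msgs)) msgs else TRUE
})

#' Set of chromosomal rearrangements
#'
#' A rearrangement is a pair of breakpoints `(chrom1, pos1)` and
#' `(chrom2, pos2)` in canonical order (chromosome order of the genome model,
#' then position), with an SV class (`CTX`, `ITX`, `DEL`, `INV`), a read-pair
#' support count, a sample id and a provenance label. Coordinates are 0-based
#' breakpoint positions.
#'
#' @slot events data.frame with at least the columns `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `svType`, `support`, `sampleId`, `origin`.
#' @slot chromOrder character vector defining chromosome order.
#' @exportClass Rearrangements
setClass("Rearrangements",
  representation(events = "data.frame", chromOrder = "character"))

setValidity("Rearrangements", function(object) {
  ev <- object@events
  msgs <- character()
  miss <- setdiff(.EVENT_COLS, names(ev))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(ev)) {
    if (!all(ev$svType %in% .SV_TYPES)) msgs <- c(msgs, "invalid svType")
    if (!all(ev$origin %in% .ORIGINS)) msgs <- c(msgs, "invalid origin")
    if (any(ev$support < 0)) msgs <- c(msgs, "negative support")
    if (any(ev$pos1 < 0) || any(ev$pos2 < 0)) msgs <- c(msgs, "negative position")
    i1 <- match(ev$chrom1, object@chromOrder)
    i2 <- match(ev$chrom2, object@chromOrder)
    if (anyNA(i1) || anyNA(i2)) msgs <- c(msgs, "chromosome not in chromOrder")
    else {
      if (any(i1 > i2 | (i1 == i2 & ev$pos1 > ev$pos2)))
        msgs <- c(msgs, "events not in canonical (left <= right) order")
      ctx <- i1 != i2
      if (any(ctx != (ev$svType == "CTX")))
        msgs <- c(msgs, "svType CTX must coincide with interchromosomal coordinates")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Piecewise-constant copy-number profile of one sample
#'
#' @slot sampleId sample identifier.
#' @slot segments data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `cn` (non-negative copy number), sorted and non-overlapping
#'   per chromosome.
#' @exportClass CnProfile
setClass("CnProfile",
  representation(sampleId = "character", segments = "data.frame"))

setValidity("CnProfile", function(object) {
  seg <- object@segments
  need <- c("chrom", "start", "end", "cn")
  miss <- setdiff(need, names(seg))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(seg)) {
    if (any(seg$start >= seg$end)) return("segment with start >= end")
    if (any(seg$cn < 0)) return("negative copy number")
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        return(sprintf("overlapping segments on %s", ch))
    }
  }
  TRUE
})

#' Discordant read-pair evidence store
#'
#' Queryable index of discordant read pairs, one row per pair, used by the
#' look-up step to find reads supporting a rearrangement in the raw sequencing
#' data of the partner sample.
#'
#' @slot pairs data.frame with columns `readname`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2` (mates in canonical order).
#' @slot chromOrder character chromosome order used for canonicalization.
#' @exportClass EvidenceIndex
setClass("EvidenceIndex",
  representation(pairs = "data.frame", chromOrder = "character"))

setValidity("EvidenceIndex", function(object) {
  need <- c("readname", "chrom1", "pos1", "chrom2", "pos2")
  miss <- setdiff(need, names(object@pairs))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  TRUE
})

#' Accounting of catalogue filtering
#'
#' @slot inputCount number of raw calls entering the filter.
#' @slot removed named integer vector of removal counts, in filter order
#'   (`below_support`, `normal_pool`, `small_itx`, `centromere`, `segdup`);
#'   attribution is first-matching-filter.
#' @slot outputCount number of calls in the filtered catalogue.
#' @exportClass FilterReport
setClass("FilterReport",
  representation(inputCount = "integer", removed = "integer",
                 outputCount = "integer"))

setValidity("FilterReport", function(object) {
  if (object@inputCount - sum(object@removed) != object@outputCount)
    return("inputCount - sum(removed) != outputCount")
  TRUE
})

#' Shared/specific ledger for one ordered tumor pair
#'
#' Result of [classifyPair()]: matched (shared) rearrangements with their
#' provenance (`direct`, `rescued`, `looked_up`), and the remaining
#' sample-specific events of each catalogue. The per-sample total is
#' `sharedCount + nrow(specific)`: it counts every rearrangement present in
#' that sample, including events discovered there only through the partner's
#' rescue or look-up evidence.
#'
#' @slot sampleA,sampleB sample identifiers.
#' @slot shared data.frame of shared rearrangements with coordinates, support
#'   in both samples, provenance and the catalogue side(s) that contributed.
#' @slot specificA,specificB data.frames of unmatched catalogue events.
#' @slot window matching half-width in bp.
#' @exportClass PairComparison
setClass("PairComparison",
  representation(sampleA = "character", sampleB = "character",
                 shared = "data.frame", specificA = "data.frame",
                 specificB = "data.frame", window = "numeric"))

#' Presence/absence rearrangement barcode matrix
#'
#' @slot matrix 0/1 integer matrix, samples in rows, non-redundant
#'   rearrangement clusters in columns (ordered by genome position of the
#'   representative left breakpoint).
#' @slot columnInfo data.frame describing each cluster's representative
#'   coordinates and member count.
#' @exportClass BarcodeMatrix
setClass("BarcodeMatrix",
  representation(matrix = "matrix", columnInfo = "data.frame"))

#' Genome-wide breakpoint density track
#'
#' @slot track data.frame with columns `chrom`, `pos` (grid position, bp) and
#'   `density` (per bp); the genome-wide trapezoid integral is 1.
#' @slot bandwidth Gaussian kernel standard deviation in bp.
#' @slot gridStep grid spacing in bp.
#' @slot nBreakpoints number of breakpoints the track was computed from.
#' @exportClass DensityTrack
setClass("DensityTrack",
  representation(track = "data.frame", bandwidth = "numeric",
                 gridStep = "numeric", nBreakpoints = "integer"))

#' Result of a simulation-based enrichment test
#'
#' @slot observed observed count.
#' @slot nTotal size of the drawn set (breakpoints or genes).
#' @slot nullMedian,nullMin,nullMax summary of the simulated null counts.
#' @slot nSims number of simulations.
#' @slot pTwoSided two-sided empirical p value, `2 * tail / nSims`; when no
#'   simulated draw is as extreme as the observation this is the upper bound
#'   `2 / nSims` and `pIsBound` is `TRUE`.
#' @slot pIsBound logical, see above.
#' @slot fold observed / null median, rounded to one decimal.
#' @slot nullCounts the simulated null counts (for diagnostics).
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(observed = "numeric", nTotal = "numeric",
                 nullMedian = "numeric", nullMin = "numeric",
                 nullMax = "numeric", nSims = "integer",
                 pTwoSided = "numeric", pIsBound = "logical",
                 fold = "numeric", nullCounts = "numeric"))

setValidity("EnrichmentResult", function(object) {
  if (!(object@nullMin <= object@nullMedian && object@nullMedian <= object@nullMax))
    return("null summary out of order")
  if (object@pTwoSided <= 0 || object@pTwoSided > 1)
    return("p must lie in (0, 1]")
  TRUE
})

#' Configuration of the synthetic clonal tumor-pair generator
#'
#' Defaults emulate the structure of a low-coverage WGS breast cancer
#' primary/metastasis cohort: a median-sized catalogue of 100 events per
#' primary, 89% of them retained by the metastasis, 14 metastasis-private
#' events, physical coverage ~22x with sequence coverage ~9x, and per-event
#' clonal fractions drawn from Beta(5, 2).
#'
#' @slot seed integer RNG seed; all generator functions are deterministic
#'   given the seed.
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot nPrimaryEvents number of somatic events in the primary tumor.
#' @slot sharedFraction fraction of primary events retained in the metastasis.
#' @slot nMetPrivate number of metastasis-private events.
#' @slot nGermline number of germline SVs (present in both tumors and in the
#'   normal pool).
#' @slot physCoveragePrimary,physCoverageMet physical (fragment) coverage,
#'   fold; read-pair support is Poisson with mean physical coverage x clonal
#'   fraction.
#' @slot seqCoveragePrimary,seqCoverageMet sequence coverage, fold; the
#'   catalogue support threshold is one third of this (floored at 2).
#' @slot jitterSd sd (bp) of the Gaussian noise applied independently per
#'   sample per breakpoint to the observed coordinates.
#' @slot evidenceJitterSd sd (bp) of per-read-pair coordinate noise in the
#'   evidence index.
#' @slot subclonalFraction fraction of shared events forced sub-threshold in
#'   the metastasis (they appear only in its raw calls, exercising rescue).
#' @slot lookupOnlyFraction fraction of shared events whose metastasis
#'   evidence exists only in the read-pair index (exercising look-up).
#' @slot clonalShape1,clonalShape2 Beta parameters of per-event clonal
#'   fractions.
#' @slot minSpan minimum intrachromosomal span (bp) of simulated events.
#' @slot pCtx probability a simulated event is interchromosomal.
#' @slot cnNSegments total number of CN segments across the genome.
#' @slot cnStates integer vector of aberrant CN states (ploidy is 2).
#' @slot cnAberrantFraction fraction of CN segments that are aberrant.
#' @slot cnSharedFraction fraction of aberrant CN segments shared between
#'   primary and metastasis.
#' @slot genicFractionTarget target fraction of the genome covered by
#'   extended gene footprints in the synthetic annotation.
#' @slot nCancerGenes size of the flagged cancer-gene subset.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(seed = "integer", chromLengths = "numeric",
    nPrimaryEvents = "integer", sharedFraction = "numeric",
    nMetPrivate = "integer", nGermline = "integer",
    physCoveragePrimary = "numeric", physCoverageMet = "numeric",
    seqCoveragePrimary = "numeric", seqCoverageMet = "numeric",
    jitterSd = "numeric", evidenceJitterSd = "numeric",
    subclonalFraction = "numeric", lookupOnlyFraction = "numeric",
    clonalShape1 = "numeric", clonalShape2 = "numeric",
    minSpan = "numeric", pCtx = "numeric",
    cnNSegments = "integer", cnStates = "numeric",
    cnAberrantFraction = "numeric", cnSharedFraction = "numeric",
    genicFractionTarget = "numeric", nCancerGenes = "integer"),
  prototype(seed = 1L,
    chromLengths = c(chr1 = 5e7, chr2 = 5e7, chr3 = 5e7, chr4 = 5e7, chr5 = 5e7),
    nPrimaryEvents = 100L, sharedFraction = 0.89, nMetPrivate = 14L,
    nGermline = 10L,
    physCoveragePrimary = 22.3, physCoverageMet = 22.3,
    seqCoveragePrimary = 9.3, seqCoverageMet = 9.3,
    jitterSd = 100, evidenceJitterSd = 100,
    subclonalFraction = 0.1, lookupOnlyFraction = 0.05,
    clonalShape1 = 5, clonalShape2 = 2,
    minSpan = 10000, pCtx = 0.28,
    cnNSegments = 40L, cnStates = c(1, 3),
    cnAberrantFraction = 0.5, cnSharedFraction = 0.35,
    genicFractionTarget = 0.433, nCancerGenes = 50L))

setValidity("SimConfig", function(object) {
  msgs <- character()
  fr <- c(sharedFraction = object@sharedFraction,
          subclonalFraction = object@subclonalFraction,
          lookupOnlyFraction = object@lookupOnlyFraction,
          cnAberrantFraction = object@cnAberrantFraction,
          cnSharedFraction = object@cnSharedFraction,
          genicFractionTarget = object@genicFractionTarget,
          pCtx = object@pCtx)
  bad <- fr < 0 | fr > 1
  if (any(bad)) msgs <- c(msgs, paste(names(fr)[bad], "must lie in [0, 1]"))
  if (any(object@chromLengths <= 0)) msgs <- c(msgs, "chromosome lengths must be > 0")
  if (is.null(names(object@chromLengths))) msgs <- c(msgs, "chromLengths must be named")
  if (object@jitterSd < 0) msgs <- c(msgs, "jitterSd must be >= 0")
  if (object@subclonalFraction + object@lookupOnlyFraction > 1)
    msgs <- c(msgs, "subclonalFraction + lookupOnlyFraction must be <= 1")
  if (length(msgs)) msgs else TRUE
})

#' Ground truth for one simulated patient
#'
#' @slot events data.frame with the true (un-jittered) coordinates, SV type,
#'   class (`shared`, `primary_only`, `met_only`, `germline`), per-sample
#'   clonal fractions and the metastasis observation mode of every event.
#' @slot chromOrder chromosome order of the simulated genome.
#' @slot config the [SimConfig] that produced it.
#' @exportClass PatientTruth
setClass("PatientTruth",
  representation(events = "data.frame", chromOrder = "character",
                 config = "SimConfig"))
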