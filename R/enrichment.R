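#' Two-sided empirical p value from simulated null counts
#'
#' `p = 2 * tail / nSims` where the tail counts simulations at least as
#' extreme as the observation on the side it falls (counts `>= observed`
#' when the observation exceeds the null median, `<= observed` otherwise),
#' capped at 1. A zero tail is reported as the upper bound `2 / nSims` with
#' `bound = TRUE` (an empirical p of exactly 0 would misstate the resolution
#' of the simulation).
#'
#' @param observed observed count.
#' @param nullCounts numeric vector of simulated null counts.
#' @return list with `p` and `bound`.
#' @examples
#' empiricalTwoSidedP(46, c(rep(26, 9998), 46, 47))  # p = 0.0004
#' @export
empiricalTwoSidedP <- function(observed, nullCounts) {
  n <- length(nullCounts)
  med <- stats::median(nullCounts)
  tail <- if (observed > med) sum(nullCounts >= observed)
          else sum(nullCounts <= observed)
  if (tail == 0L) list(p = 2 / n, bound = TRUE)
  else list(p = min(1, 2 * tail / n), bound = FALSE)
}

#' Fold enrichment over the null median
#'
#' @param observed observed count.
#' @param nullMedian median of the simulated null counts.
#' @return observed / nullMedian rounded to one decimal (half away from
#'   zero).
#' @examples
#' foldEnrichment(46, 26)  # 1.8
#' @export
foldEnrichment <- function(observed, nullMedian) {
  .roundHalfUp(observed / nullMedian, 1)
}

.enrichmentResult <- function(observed, nTotal, nullCounts) {
  p <- empiricalTwoSidedP(observed, nullCounts)
  new("EnrichmentResult", observed = as.numeric(observed),
      nTotal = as.numeric(nTotal),
      nullMedian = stats::median(nullCounts), nullMin = min(nullCounts),
      nullMax = max(nullCounts), nSims = length(nullCounts),
      pTwoSided = p$p, pIsBound = p$bound,
      fold = foldEnrichment(observed, stats::median(nullCounts)),
      nullCounts = as.numeric(nullCounts))
}

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(paste0("EnrichmentResult: observed %g of %g; null median %g ",
                     "(range %g-%g, %d sims); fold %.1f; p %s%.4g\n"),
              object@observed, object@nTotal, object@nullMedian,
              object@nullMin, object@nullMax, object@nSims, object@fold,
              if (object@pIsBound) "< " else "= ", object@pTwoSided))
})

#' Breakpoints in genic areas
#'
#' A breakpoint is genic when it lies within some gene's strand-aware
#' extended span (2 kb upstream of the transcription start through the gene
#' end, [extendedGeneSpans()]); the promoter boundary is inclusive at exactly
#' 2000 bp upstream. Both ends of every rearrangement are tested.
#'
#' @param catalogues list of [Rearrangements-class] objects.
#' @param genes gene `GRanges` with a `gene` metadata column.
#' @param genome optional [GenomeModel-class] used to clip extensions.
#' @return list with `count` and `nTotal` (genic / total breakpoints),
#'   `fractionPct` (percent, one decimal), `affectedGenes` (distinct gene
#'   names hit) and `nRearrangementsWithGenic` (rearrangements with at least
#'   one genic breakpoint).
#' @export
genicBreakpoints <- function(catalogues, genes, genome = NULL) {
  pool <- do.call(rbind, lapply(catalogues, eventTable))
  if (is.null(pool)) pool <- .emptyEventFrame()
  n <- nrow(pool)
  bpChrom <- c(pool$chrom1, pool$chrom2)
  bpPos <- c(pool$pos1, pool$pos2)
  if (length(genes) == 0L || n == 0L)
    return(list(count = 0L, nTotal = 2L * n, fractionPct = if (n) 0 else NA_real_,
                affectedGenes = character(), nRearrangementsWithGenic = 0L))
  ext <- extendedGeneSpans(genes, genome)
  pts <- .grFromPoints0(bpChrom, bpPos)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pts, ext))
  genic <- logical(2L * n)
  genic[unique(S4Vectors::queryHits(hits))] <- TRUE
  affected <- unique(mcols(ext)$gene[S4Vectors::subjectHits(hits)])
  rearr <- genic[seq_len(n)] | genic[n + seq_len(n)]
  list(count = sum(genic), nTotal = 2L * n,
       fractionPct = .roundHalfUp(100 * sum(genic) / (2 * n), 1),
       affectedGenes = sort(affected),
       nRearrangementsWithGenic = sum(rearr))
}

# flatten the unmasked genome into one coordinate line; returns per-chromosome
# offsets and the genic intervals mapped onto that line
.flattenGenome <- function(genome, genes, avoidMasks = TRUE) {
  lens <- chromLengths(genome)
  masks <- if (avoidMasks) genomeMasks(genome) else list()
  ext <- if (length(genes)) extendedGeneSpans(genes, genome) else GenomicRanges::GRanges()
  offset <- 0
  starts <- numeric(0); ends <- numeric(0)
  segs <- list()
  for (ch in chromNames(genome)) {
    keep <- .grFromBed0(ch, 0, lens[[ch]])
    for (m in masks) {
      mm <- m[as.character(seqnames(m)) == ch]
      if (length(mm))
        keep <- suppressWarnings(GenomicRanges::setdiff(keep, mm))
    }
    if (length(keep) == 0L) next
    kw <- GenomicRanges::width(keep)
    g <- ext[as.character(seqnames(ext)) == ch]
    if (length(g)) {
      gi <- suppressWarnings(GenomicRanges::intersect(g, keep,
                                                      ignore.strand = TRUE))
      if (length(gi)) {
        # map genic intervals into the flattened coordinate of `keep`
        cumw <- cumsum(c(0, kw))[seq_along(keep)]
        ov <- suppressWarnings(GenomicRanges::findOverlaps(gi, keep,
                                                           ignore.strand = TRUE))
        idx <- S4Vectors::queryHits(ov)
        within <- S4Vectors::subjectHits(ov)
        s0 <- GenomicRanges::start(gi)[idx] - GenomicRanges::start(keep)[within] + cumw[within]
        e0 <- s0 + GenomicRanges::width(gi)[idx]
        starts <- c(starts, offset + s0)
        ends <- c(ends, offset + e0)
      }
    }
    segs[[ch]] <- sum(kw)
    offset <- offset + sum(kw)
  }
  list(totalLen = offset, genicStarts = starts, genicEnds = ends)
}

#' Null distribution of genic breakpoint counts
#'
#' Each simulation draws `nBreakpoints` positions uniformly over the
#' unmasked genome and counts how many fall in genic areas; the observed
#' count (when given) is compared against this null with a two-sided
#' empirical p value. Deterministic given `seed`.
#'
#' @param nBreakpoints breakpoints per simulation.
#' @param genome [GenomeModel-class].
#' @param genes gene `GRanges`.
#' @param nSims number of simulations.
#' @param seed RNG seed.
#' @param observed observed genic count, or `NULL` (null summary only; the
#'   null median then serves as the reference point).
#' @param avoidMasks draw positions outside the genome masks, mirroring the
#'   catalogue filters (default `TRUE`).
#' @return an [EnrichmentResult-class].
#' @export
simulateGenicNull <- function(nBreakpoints, genome, genes, nSims = 10000,
                              seed = 1, observed = NULL, avoidMasks = TRUE) {
  stopifnot(nSims >= 1)
  set.seed(seed)
  fl <- .flattenGenome(genome, genes, avoidMasks)
  if (fl$totalLen <= 0) stop("empty unmasked genome")
  bounds <- as.vector(rbind(fl$genicStarts, fl$genicEnds))
  counts <- integer(nSims)
  for (s in seq_len(nSims)) {
    u <- stats::runif(nBreakpoints, 0, fl$totalLen)
    counts[s] <- if (length(bounds)) sum(findInterval(u, bounds) %% 2 == 1L) else 0L
  }
  if (is.null(observed)) observed <- stats::median(counts)
  .enrichmentResult(observed, nBreakpoints, counts)
}

#' Cancer-gene enrichment among rearrangement-affected genes
#'
#' Simulates `nSims` random draws of `length(affectedGenes)` genes without
#' replacement from the universe and counts cancer-gene hits per draw (a
#' hypergeometric null); the observed overlap is compared with a two-sided
#' empirical p and the fold enrichment over the null median.
#'
#' @param affectedGenes character vector of genes hit by rearrangements
#'   (must be a subset of `universe`).
#' @param universe character vector of all annotated genes.
#' @param cancerGenes character vector of cancer-associated gene names.
#' @param nSims number of random draws.
#' @param seed RNG seed.
#' @return an [EnrichmentResult-class].
#' @export
cancerGeneEnrichment <- function(affectedGenes, universe, cancerGenes,
                                 nSims = 10000, seed = 1) {
  if (!all(affectedGenes %in% universe))
    stop("affectedGenes must be a subset of universe")
  set.seed(seed)
  N <- length(universe)
  k <- length(affectedGenes)
  m <- sum(universe %in% cancerGenes)
  observed <- sum(affectedGenes %in% cancerGenes)
  # cancer genes occupy the first m indices of a fixed permutation
  counts <- vapply(seq_len(nSims),
                   function(i) sum(sample.int(N, k) <= m), integer(1))
  .enrichmentResult(observed, k, counts)
}

#' Per-gene table of affecting rearrangements
#'
#' Events are deduplicated across samples through the non-redundant cohort
#' catalogue ([buildNonredundant()]); a gene is affected by a cluster when
#' the cluster representative has a breakpoint in the gene's extended span.
#' Rows are sorted by unique-rearrangement count (descending), ties by gene
#' name.
#'
#' @param catalogues named list of [Rearrangements-class] per sample.
#' @param genes gene `GRanges` with `gene` metadata.
#' @param patientOf named character vector mapping sample ids to patient
#'   ids (defaults to sample ids, i.e. one patient per sample).
#' @param window clustering window in bp.
#' @param genome optional [GenomeModel-class].
#' @return data.frame with `gene`, `nRearrangements`, `nPatients`,
#'   `cancer` (logical, filled when `genome` carries cancer genes).
#' @export
affectedGeneTable <- function(catalogues, genes, patientOf = NULL,
                              window = 500, genome = NULL) {
  empty <- data.frame(gene = character(), nRearrangements = integer(),
                      nPatients = integer(), cancer = logical())
  if (length(genes) == 0L) return(empty)
  bm <- buildNonredundant(catalogues, window)
  info <- barcodeColumns(bm)
  if (nrow(info) == 0L) return(empty)
  if (is.null(patientOf)) {
    ids <- rownames(barcodeMatrix(bm))
    patientOf <- stats::setNames(ids, ids)
  }
  ext <- extendedGeneSpans(genes, genome)
  pts <- .grFromPoints0(c(info$chrom1, info$chrom2),
                        c(info$posLeft, info$posRight))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pts, ext))
  nC <- nrow(info)
  clusterOf <- ((S4Vectors::queryHits(hits) - 1L) %% nC) + 1L
  geneOf <- mcols(ext)$gene[S4Vectors::subjectHits(hits)]
  if (length(clusterOf) == 0L) return(empty)
  hitDf <- unique(data.frame(cluster = clusterOf, gene = geneOf,
                             stringsAsFactors = FALSE))
  m <- barcodeMatrix(bm)
  patientsOfCluster <- lapply(seq_len(nC), function(k)
    unique(patientOf[rownames(m)[m[, k] == 1L]]))
  rows <- lapply(split(hitDf$cluster, hitDf$gene), function(cl) {
    data.frame(nRearrangements = length(unique(cl)),
               nPatients = length(unique(unlist(patientsOfCluster[cl]))))
  })
  out <- do.call(rbind, rows)
  out$gene <- names(rows)
  cg <- if (!is.null(genome)) cancerGenes(genome) else character()
  out$cancer <- out$gene %in% cg
  out <- out[order(-out$nRearrangements, out$gene),
             c("gene", "nRearrangements", "nPatients", "cancer")]
  rownames(out) <- NULL
  out
}

#' Summary of PCR validation counts
#'
#' Per-category validation percentages (rounded to integer) plus two
#' variants of the overall accuracy excluding germline findings: `subtract`
#' removes the germline-positive shared assays from both numerator and
#' denominator, `keep` leaves them in (they validated as present in both
#' tumors).
#'
#' @param sharedTested,sharedConfirmed counts for rearrangements predicted
#'   shared.
#' @param sharedGermline how many confirmed shared assays were also germline.
#' @param specificTested,specificConfirmed counts for rearrangements
#'   predicted specific.
#' @return list with `sharedPct`, `specificPct` (NA when a category has no
#'   informative assays) and `overallPct` (named vector, both variants).
#' @export
validationSummary <- function(sharedTested, sharedConfirmed, sharedGermline = 0,
                              specificTested, specificConfirmed) {
  pct <- function(num, den) if (den > 0) .roundHalfUp(100 * num / den) else NA_real_
  list(
    sharedPct = pct(sharedConfirmed, sharedTested),
    specificPct = pct(specificConfirmed, specificTested),
    overallPct = c(
      subtract = pct(sharedConfirmed - sharedGermline + specificConfirmed,
                     sharedTested - sharedGermline + specificTested),
      keep = pct(sharedConfirmed + specificConfirmed,
                 sharedTested + specificTested)))
}
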