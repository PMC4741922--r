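#' Catalogue support threshold
#'
#' The minimum read-pair support for a call to enter the filtered catalogue:
#' one third of the sample's average sequence coverage, rounded up and floored
#' at 2 read pairs (so a 9x sample requires 3 read pairs).
#'
#' @param sequenceCoverage average sequence coverage, fold (> 0).
#' @return integer threshold.
#' @examples
#' supportThreshold(9)   # 3
#' supportThreshold(3)   # 2 (floor applies)
#' @export
supportThreshold <- function(sequenceCoverage) {
  if (any(sequenceCoverage <= 0)) stop("sequence coverage must be > 0")
  pmax(2L, as.integer(ceiling(sequenceCoverage / 3)))
}

#' @describeIn filterCatalogue accessor for the removal counts of a
#'   [FilterReport-class].
#' @param report a `FilterReport`.
#' @export
removedCounts <- function(report) report@removed

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d in, %d out\n", object@inputCount,
              object@outputCount))
  for (nm in names(object@removed))
    cat(sprintf("  %-14s %d\n", nm, object@removed[[nm]]))
})

# rows of `ev` (event frame) with a two-sided windowed match in `ref`
.hasWindowedMatch <- function(ev, ref, window) {
  if (nrow(ev) == 0L) return(logical(0))
  if (nrow(ref) == 0L) return(rep(FALSE, nrow(ev)))
  key <- paste(ref$chrom1, ref$chrom2)
  split_ref <- split(seq_len(nrow(ref)), key)
  vapply(seq_len(nrow(ev)), function(i) {
    idx <- split_ref[[paste(ev$chrom1[i], ev$chrom2[i])]]
    if (is.null(idx)) return(FALSE)
    any(abs(ref$pos1[idx] - ev$pos1[i]) <= window &
        abs(ref$pos2[idx] - ev$pos2[i]) <= window)
  }, logical(1))
}

#' Filter a raw call list into the tumor catalogue
#'
#' Applies, in order: (1) the read-pair support threshold
#' ([supportThreshold()] of the sample's sequence coverage); (2) removal of
#' calls matching a normal-pool call within the two-sided `window` (germline
#' filter); (3) removal of intrachromosomal events with span strictly below
#' `minItxSpan`; (4, 5) removal of events with a breakpoint inside a
#' `centromere` or `segdup` mask of the genome model. Removals are attributed
#' to the first matching filter.
#'
#' @param rawCalls a [Rearrangements-class] of unfiltered calls.
#' @param meta one manifest row for the sample (needs `sequence_coverage`).
#' @param normalPool [Rearrangements-class] of normal-pool calls, or `NULL`;
#'   a missing pool skips the germline filter with a warning (partial-normal
#'   designs).
#' @param genome [GenomeModel-class] whose `masks` may contain `centromere`
#'   and `segdup`.
#' @param minItxSpan minimum intrachromosomal span in bp (default 7000;
#'   "smaller than 7 kb" is read strictly, so a 7000 bp span is retained).
#' @param window two-sided matching half-width for the pool filter (bp).
#' @return list with `catalogue` ([Rearrangements-class]) and `report`
#'   ([FilterReport-class]).
#' @export
filterCatalogue <- function(rawCalls, meta, normalPool = NULL, genome,
                            minItxSpan = 7000, window = 500) {
  ev <- eventTable(rawCalls)
  thr <- supportThreshold(meta$sequence_coverage[1])
  removed <- c(below_support = 0L, normal_pool = 0L, small_itx = 0L,
               centromere = 0L, segdup = 0L)
  inputCount <- nrow(ev)
  keep <- rep(TRUE, inputCount)

  drop <- keep & ev$support < thr
  removed["below_support"] <- sum(drop)
  keep <- keep & !drop

  if (is.null(normalPool)) {
    warning("no normal pool provided; germline filter skipped")
  } else {
    pool <- eventTable(normalPool)
    hit <- .hasWindowedMatch(ev, pool, window)
    drop <- keep & hit
    removed["normal_pool"] <- sum(drop)
    keep <- keep & !drop
  }

  intra <- ev$chrom1 == ev$chrom2
  drop <- keep & intra & (ev$pos2 - ev$pos1) < minItxSpan
  removed["small_itx"] <- sum(drop)
  keep <- keep & !drop

  for (maskName in c("centromere", "segdup")) {
    m <- genomeMasks(genome)[[maskName]]
    if (is.null(m) || length(m) == 0L || nrow(ev) == 0L) next
    inMask <- suppressWarnings(
      GenomicRanges::countOverlaps(.grFromPoints0(ev$chrom1, ev$pos1), m) > 0 |
      GenomicRanges::countOverlaps(.grFromPoints0(ev$chrom2, ev$pos2), m) > 0)
    drop <- keep & inMask
    removed[maskName] <- sum(drop)
    keep <- keep & !drop
  }

  report <- new("FilterReport", inputCount = inputCount, removed = removed,
                outputCount = as.integer(sum(keep)))
  list(catalogue = Rearrangements(ev[keep, , drop = FALSE], rawCalls@chromOrder),
       report = report)
}
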