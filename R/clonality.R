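#' Coverage-normalized clonality table of shared rearrangements
#'
#' One row per shared rearrangement of a classified pair, with the read
#' support in each sample normalized by that sample's overall sequence
#' coverage (`norm_support = support / sequence_coverage`) — the data behind
#' a metastasis-vs-primary clonality scatter. For looked-up events the
#' partner-side support is the evidence read-pair count recorded at
#' classification. Interchromosomal events contribute one row, flagged
#' `two_sided` so a plot can mark both breakpoint sides.
#'
#' @param pc a [PairComparison-class].
#' @param metaA,metaB one manifest row per sample (needs
#'   `sequence_coverage` > 0; set `usePhysical = TRUE` to normalize by
#'   `physical_coverage` instead).
#' @param usePhysical normalize by physical rather than sequence coverage.
#' @return data.frame with coordinates, `svType`, `provenance`, raw supports,
#'   `normA`, `normB` and `two_sided`.
#' @export
clonalityTable <- function(pc, metaA, metaB, usePhysical = FALSE) {
  col <- if (usePhysical) "physical_coverage" else "sequence_coverage"
  covA <- metaA[[col]][1]; covB <- metaB[[col]][1]
  if (is.na(covA) || is.na(covB) || covA <= 0 || covB <= 0)
    stop("coverage must be > 0")
  sh <- sharedEvents(pc)
  supA <- sh$supportA
  supB <- sh$supportB
  # partner-side support of a looked-up event is its evidence count (>= 1)
  supA[is.na(supA)] <- 1L
  supB[is.na(supB)] <- 1L
  data.frame(
    chrom1 = sh$chrom1, posLeft = ifelse(is.na(sh$posLeftA), sh$posLeftB, sh$posLeftA),
    chrom2 = sh$chrom2, posRight = ifelse(is.na(sh$posRightA), sh$posRightB, sh$posRightA),
    svType = sh$svType, provenance = sh$provenance,
    supportA = supA, supportB = supB,
    normA = supA / covA, normB = supB / covB,
    two_sided = sh$chrom1 != sh$chrom2,
    stringsAsFactors = FALSE)
}
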