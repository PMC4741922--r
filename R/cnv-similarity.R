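#' Copy-number comparison windows from the union of segmentation breaks
#'
#' Window boundaries are the sorted union of both samples' segment boundaries
#' (plus chromosome ends); within each window both samples have a constant
#' copy number, categorized against the ploidy as `loss` (cn < ploidy),
#' `normal` (cn = ploidy) or `gain` (cn > ploidy). Regions not covered by a
#' sample's segments are treated as normal (FREEC-style outputs omit normal
#' regions in some dialects); this is logged once per call.
#'
#' @param profileA,profileB [CnProfile-class] objects.
#' @param genome [GenomeModel-class]; windows are built for every chromosome
#'   with a segment in either profile (the full genome partition is used for
#'   the length-weighted metric only through those chromosomes).
#' @param ploidy reference copy number (default 2).
#' @param allChromosomes build windows for every genome chromosome, including
#'   ones with no segments (default `FALSE`).
#' @return data.frame with columns `chrom`, `start`, `end`, `cnA`, `cnB`,
#'   `stateA`, `stateB`.
#' @export
unionWindows <- function(profileA, profileB, genome, ploidy = 2,
                         allChromosomes = FALSE) {
  segA <- cnSegments(profileA); segB <- cnSegments(profileB)
  chroms <- if (allChromosomes) chromNames(genome)
            else intersect(chromNames(genome), union(segA$chrom, segB$chrom))
  lens <- chromLengths(genome)
  gapSeen <- FALSE
  out <- list()
  for (ch in chroms) {
    L <- lens[[ch]]
    a <- segA[segA$chrom == ch, , drop = FALSE]
    b <- segB[segB$chrom == ch, , drop = FALSE]
    bounds <- sort(unique(c(0, L, a$start, a$end, b$start, b$end)))
    bounds <- bounds[bounds >= 0 & bounds <= L]
    st <- bounds[-length(bounds)]
    en <- bounds[-1]
    mid <- (st + en) / 2
    lookup <- function(seg) {
      cn <- rep(ploidy, length(mid))
      if (nrow(seg)) {
        idx <- findInterval(mid, seg$start)
        hit <- idx >= 1 & mid < seg$end[pmax(idx, 1)]
        cn[hit] <- seg$cn[idx[hit]]
        if (any(!hit)) gapSeen <<- TRUE
      } else gapSeen <<- TRUE
      cn
    }
    cnA <- lookup(a); cnB <- lookup(b)
    out[[ch]] <- data.frame(chrom = ch, start = st, end = en,
                            cnA = cnA, cnB = cnB, stringsAsFactors = FALSE)
  }
  win <- if (length(out)) do.call(rbind, out) else NULL
  if (is.null(win))
    win <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      cnA = numeric(), cnB = numeric())
  if (gapSeen) .log("unionWindows: uncovered regions treated as cn = %g", ploidy)
  categorize <- function(cn) c("loss", "normal", "gain")[sign(cn - ploidy) + 2]
  win$stateA <- categorize(win$cnA)
  win$stateB <- categorize(win$cnB)
  win
}

#' Event-based copy-number similarity
#'
#' The percentage of comparison windows with the same aberrant state in both
#' samples, among windows where at least one sample is aberrant; windows that
#' are normal in both samples are excluded, and windows are counted, not
#' length-weighted.
#'
#' @param windows window table from [unionWindows()].
#' @return percentage, or `NA` with a warning when no window is aberrant
#'   (the similarity is undefined).
#' @export
cnEventSimilarity <- function(windows) {
  aberrant <- windows$stateA != "normal" | windows$stateB != "normal"
  if (!any(aberrant)) {
    warning("no aberrant window; event-based CN similarity undefined")
    return(NA_real_)
  }
  matched <- aberrant & windows$stateA == windows$stateB
  100 * sum(matched) / sum(aberrant)
}

#' Length-weighted copy-number similarity
#'
#' The percentage of compared genome length over which both samples have the
#' same CN state, including windows that are normal in both (large shared
#' stretches of normal or aberrant copy number both raise this metric).
#'
#' @param windows window table from [unionWindows()].
#' @return percentage of total window length with concordant state.
#' @export
cnLengthSimilarity <- function(windows) {
  len <- windows$end - windows$start
  if (sum(len) == 0) {
    warning("empty window set; length-weighted CN similarity undefined")
    return(NA_real_)
  }
  100 * sum(len[windows$stateA == windows$stateB]) / sum(len)
}
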