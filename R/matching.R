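#' Two-sided windowed breakpoint match
#'
#' Two rearrangements match when their (canonical) chromosome pairs are
#' identical and each breakpoint lies within `window` bp of its counterpart;
#' the boundary is inclusive (an offset of exactly `window` matches). SV type
#' labels are not required to agree: caller class labels are unstable between
#' samples, so chromosome identity plus coordinates govern.
#'
#' @param r1,r2 single-event [Rearrangements-class] objects or 1-row event
#'   data.frames in canonical order.
#' @param window matching half-width in bp (default 500).
#' @return logical.
#' @export
breakpointsMatch <- function(r1, r2, window = 500) {
  e1 <- if (is(r1, "Rearrangements")) eventTable(r1) else r1
  e2 <- if (is(r2, "Rearrangements")) eventTable(r2) else r2
  stopifnot(nrow(e1) == 1L, nrow(e2) == 1L)
  e1$chrom1 == e2$chrom1 && e1$chrom2 == e2$chrom2 &&
    abs(e1$pos1 - e2$pos1) <= window && abs(e1$pos2 - e2$pos2) <= window
}

# all windowed candidate pairs between two event frames:
# data.frame(iA, iB, dist, distLeft, distRight)
.windowedCandidates <- function(evA, evB, window) {
  empty <- data.frame(iA = integer(), iB = integer(), dist = integer(),
                      distLeft = integer(), distRight = integer())
  if (nrow(evA) == 0L || nrow(evB) == 0L) return(empty)
  keyA <- paste(evA$chrom1, evA$chrom2)
  keyB <- paste(evB$chrom1, evB$chrom2)
  out <- list(empty)
  for (key in intersect(unique(keyA), unique(keyB))) {
    ia <- which(keyA == key)
    ib <- which(keyB == key)
    dl <- abs(outer(evA$pos1[ia], evB$pos1[ib], `-`))
    dr <- abs(outer(evA$pos2[ia], evB$pos2[ib], `-`))
    ok <- which(dl <= window & dr <= window, arr.ind = TRUE)
    if (nrow(ok)) {
      out[[length(out) + 1L]] <- data.frame(
        iA = ia[ok[, 1]], iB = ib[ok[, 2]],
        dist = dl[ok] + dr[ok], distLeft = dl[ok], distRight = dr[ok])
    }
  }
  do.call(rbind, out)
}

#' Greedy one-to-one matching of two catalogues
#'
#' Candidate pairs (two-sided windowed matches, see [breakpointsMatch()]) are
#' taken in ascending order of summed two-side distance; each event is
#' matched at most once. Equal-distance ties are broken by the lower left
#' then right coordinate of the b-side candidate (then of the a-side), which
#' makes the matching deterministic.
#'
#' @param catA,catB [Rearrangements-class] catalogues.
#' @param window matching half-width in bp.
#' @return data.frame with one row per matched pair: `iA`, `iB` (row indices
#'   into the two event tables), `distLeft`, `distRight`.
#' @export
matchCatalogues <- function(catA, catB, window = 500) {
  evA <- eventTable(catA); evB <- eventTable(catB)
  cand <- .windowedCandidates(evA, evB, window)
  if (nrow(cand) == 0L)
    return(data.frame(iA = integer(), iB = integer(), distLeft = integer(),
                      distRight = integer()))
  o <- order(cand$dist, evB$pos1[cand$iB], evB$pos2[cand$iB],
             evA$pos1[cand$iA], evA$pos2[cand$iA])
  cand <- cand[o, , drop = FALSE]
  usedA <- rep(FALSE, nrow(evA)); usedB <- rep(FALSE, nrow(evB))
  pick <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    a <- cand$iA[k]; b <- cand$iB[k]
    if (!usedA[a] && !usedB[b]) {
      pick[k] <- TRUE
      usedA[a] <- TRUE; usedB[b] <- TRUE
    }
  }
  m <- cand[pick, c("iA", "iB", "distLeft", "distRight"), drop = FALSE]
  rownames(m) <- NULL
  m
}

# for each row of ev, index of the nearest windowed match in ref (or NA);
# ties by lower ref coordinates
.bestWindowedMatch <- function(ev, ref, window) {
  res <- rep(NA_integer_, nrow(ev))
  cand <- .windowedCandidates(ev, ref, window)
  if (nrow(cand) == 0L) return(res)
  o <- order(cand$iA, cand$dist, ref$pos1[cand$iB], ref$pos2[cand$iB])
  cand <- cand[o, , drop = FALSE]
  first <- !duplicated(cand$iA)
  res[cand$iA[first]] <- cand$iB[first]
  res
}

#' Classify a tumor pair's rearrangements as shared or specific
#'
#' Pipeline order: (1) direct greedy one-to-one matching of the two filtered
#' catalogues ([matchCatalogues()]); (2) the rescue step - each remaining
#' specific event is searched for a sub-threshold windowed match (support >=
#' 1) in the other sample's raw call list and reclassified as shared if
#' found; (3) the look-up step - each still-specific event is searched in the
#' other sample's read-pair evidence, and one read pair supporting both ends
#' within the window suffices to reclassify it as shared.
#'
#' A rescued or looked-up event counts toward both samples' totals: it is
#' present in the partner sample even though it never entered the partner's
#' catalogue, so `totalCounts()` returns catalogue size plus the partner-side
#' events recovered this way, and `sharedCount + nrow(specific)` equals the
#' total on each side.
#'
#' @param catA,catB filtered catalogues ([Rearrangements-class]).
#' @param rawA,rawB unfiltered call lists for the rescue step, or `NULL` to
#'   skip it.
#' @param evA,evB [EvidenceIndex-class] objects for the look-up step, or
#'   `NULL` to skip it.
#' @param window matching half-width in bp.
#' @return a [PairComparison-class] object.
#' @export
classifyPair <- function(catA, catB, rawA = NULL, rawB = NULL,
                         evA = NULL, evB = NULL, window = 500) {
  eA <- eventTable(catA); eB <- eventTable(catB)
  idA <- if (nrow(eA)) unique(eA$sampleId)[1] else "a"
  idB <- if (nrow(eB)) unique(eB$sampleId)[1] else "b"
  m <- matchCatalogues(catA, catB, window)
  sharedRows <- list()
  if (nrow(m)) {
    sharedRows[[1]] <- data.frame(
      chrom1 = eA$chrom1[m$iA], chrom2 = eA$chrom2[m$iA],
      posLeftA = eA$pos1[m$iA], posRightA = eA$pos2[m$iA],
      posLeftB = eB$pos1[m$iB], posRightB = eB$pos2[m$iB],
      svType = eA$svType[m$iA],
      supportA = eA$support[m$iA], supportB = eB$support[m$iB],
      provenance = "direct", side = "both",
      distLeft = m$distLeft, distRight = m$distRight,
      stringsAsFactors = FALSE)
  }
  specA <- eA[setdiff(seq_len(nrow(eA)), m$iA), , drop = FALSE]
  specB <- eB[setdiff(seq_len(nrow(eB)), m$iB), , drop = FALSE]

  reclass <- function(spec, raw, evIdx, side) {
    if (nrow(spec) == 0L) return(list(spec = spec))
    prov <- rep(NA_character_, nrow(spec))
    partnerSupport <- rep(NA_integer_, nrow(spec))
    if (!is.null(raw)) {
      rawEv <- eventTable(raw)
      rawEv <- rawEv[rawEv$support >= 1L, , drop = FALSE]
      hit <- .bestWindowedMatch(spec, rawEv, window)
      found <- !is.na(hit)
      prov[found] <- "rescued"
      partnerSupport[found] <- rawEv$support[hit[found]]
    }
    if (!is.null(evIdx)) {
      todo <- is.na(prov)
      if (any(todo)) {
        cnt <- queryEvidence(evIdx, spec$chrom1[todo], spec$pos1[todo],
                             spec$chrom2[todo], spec$pos2[todo], window)
        found <- cnt >= 1L
        prov[todo][found] <- "looked_up"
        partnerSupport[todo][found] <- cnt[found]
      }
    }
    moved <- !is.na(prov)
    movedRows <- NULL
    if (any(moved)) {
      s <- spec[moved, , drop = FALSE]
      movedRows <- data.frame(
        chrom1 = s$chrom1, chrom2 = s$chrom2,
        posLeftA = s$pos1, posRightA = s$pos2,
        posLeftB = NA_integer_, posRightB = NA_integer_,
        svType = s$svType,
        supportA = s$support, supportB = partnerSupport[moved],
        provenance = prov[moved], side = side,
        distLeft = NA_integer_, distRight = NA_integer_,
        stringsAsFactors = FALSE)
      if (side == "b") {
        # keep A/B orientation of the support and coordinate columns
        movedRows[c("posLeftB", "posRightB")] <- movedRows[c("posLeftA", "posRightA")]
        movedRows[c("posLeftA", "posRightA")] <- NA_integer_
        tmp <- movedRows$supportA
        movedRows$supportA <- movedRows$supportB
        movedRows$supportB <- tmp
      }
    }
    list(spec = spec[!moved, , drop = FALSE], moved = movedRows)
  }

  ra <- reclass(specA, rawB, evB, side = "a")
  rb <- reclass(specB, rawA, evA, side = "b")
  sharedRows <- c(sharedRows, list(ra$moved), list(rb$moved))
  shared <- do.call(rbind, Filter(Negate(is.null), sharedRows))
  if (is.null(shared))
    shared <- data.frame(chrom1 = character(), chrom2 = character(),
                         posLeftA = integer(), posRightA = integer(),
                         posLeftB = integer(), posRightB = integer(),
                         svType = character(), supportA = integer(),
                         supportB = integer(), provenance = character(),
                         side = character(), distLeft = integer(),
                         distRight = integer(), stringsAsFactors = FALSE)
  rownames(shared) <- NULL
  new("PairComparison", sampleA = idA, sampleB = idB, shared = shared,
      specificA = ra$spec, specificB = rb$spec, window = window)
}

#' @describeIn classifyPair number of shared rearrangements of a
#'   [PairComparison-class].
#' @param pc a `PairComparison`.
#' @export
sharedCount <- function(pc) nrow(pc@shared)

#' @describeIn classifyPair shared-event table.
#' @export
sharedEvents <- function(pc) pc@shared

#' @describeIn classifyPair specific-event tables, a list with `a` and `b`.
#' @export
specificEvents <- function(pc) list(a = pc@specificA, b = pc@specificB)

#' @describeIn classifyPair per-sample totals (shared + specific), named
#'   `a` and `b`.
#' @export
totalCounts <- function(pc) {
  c(a = nrow(pc@shared) + nrow(pc@specificA),
    b = nrow(pc@shared) + nrow(pc@specificB))
}

setMethod("show", "PairComparison", function(object) {
  tot <- totalCounts(object)
  cat(sprintf("PairComparison %s vs %s (window %d bp)\n", object@sampleA,
              object@sampleB, as.integer(object@window)))
  cat(sprintf("  shared %d | specific %s: %d, %s: %d | totals %d / %d\n",
              nrow(object@shared), object@sampleA, nrow(object@specificA),
              object@sampleB, nrow(object@specificB), tot[["a"]], tot[["b"]]))
  if (nrow(object@shared)) {
    tab <- table(object@shared$provenance)
    cat("  provenance:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})
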