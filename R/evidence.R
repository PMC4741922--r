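#' Construct a discordant read-pair evidence index
#'
#' @param pairs data.frame with columns `readname`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2` (0-based mate positions); mates are put in canonical
#'   order on construction.
#' @param genome [GenomeModel-class] or character vector of chromosome names.
#' @return an [EvidenceIndex-class] object.
#' @export
EvidenceIndex <- function(pairs = data.frame(readname = character(),
                                             chrom1 = character(), pos1 = integer(),
                                             chrom2 = character(), pos2 = integer(),
                                             stringsAsFactors = FALSE),
                          genome) {
  chromOrder <- if (is(genome, "GenomeModel")) chromNames(genome) else as.character(genome)
  pairs$pos1 <- as.integer(pairs$pos1)
  pairs$pos2 <- as.integer(pairs$pos2)
  pairs$svType <- rep("ITX", nrow(pairs))
  pairs <- .canonicalizeEvents(pairs, chromOrder)
  pairs$svType <- NULL
  rownames(pairs) <- NULL
  new("EvidenceIndex", pairs = pairs, chromOrder = chromOrder)
}

setMethod("show", "EvidenceIndex", function(object) {
  cat(sprintf("EvidenceIndex: %d read pair(s) on %d chromosome pair(s)\n",
              nrow(object@pairs),
              nrow(unique(object@pairs[c("chrom1", "chrom2")]))))
})

setMethod("length", "EvidenceIndex", function(x) nrow(x@pairs))

#' Count read pairs supporting both ends of a rearrangement
#'
#' A read pair supports a rearrangement when the two mates fall on the same
#' (canonical) chromosome pair and each mate lies within `window` bp of the
#' corresponding breakpoint.
#'
#' @param ev an [EvidenceIndex-class] object.
#' @param chrom1,pos1,chrom2,pos2 canonical breakpoint coordinates of the
#'   query rearrangement (vectors are recycled to equal length).
#' @param window half-width of the matching window in bp (inclusive).
#' @return integer vector of supporting read-pair counts, one per query.
#' @export
queryEvidence <- function(ev, chrom1, pos1, chrom2, pos2, window = 500) {
  p <- ev@pairs
  n <- max(length(chrom1), length(pos1))
  chrom1 <- rep_len(chrom1, n); pos1 <- rep_len(pos1, n)
  chrom2 <- rep_len(chrom2, n); pos2 <- rep_len(pos2, n)
  vapply(seq_len(n), function(i) {
    sum(p$chrom1 == chrom1[i] & p$chrom2 == chrom2[i] &
        abs(p$pos1 - pos1[i]) <= window & abs(p$pos2 - pos2[i]) <= window)
  }, integer(1))
}

#' Read or write a read-pair evidence TSV
#'
#' Tab-separated with header `readname chrom1 pos1 chrom2 pos2`.
#'
#' @param path file path.
#' @param genome [GenomeModel-class].
#' @return [EvidenceIndex-class] (reader) or `path` invisibly (writer).
#' @export
readEvidence <- function(path, genome) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("readname", "chrom1", "pos1", "chrom2", "pos2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  EvidenceIndex(df[need], genome)
}

#' @rdname readEvidence
#' @param ev an [EvidenceIndex-class] object.
#' @export
writeEvidence <- function(ev, path) {
  utils::write.table(ev@pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
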