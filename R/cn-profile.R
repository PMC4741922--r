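#' Construct a copy-number profile
#'
#' @param sampleId sample identifier.
#' @param segments data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `cn`; sorted per chromosome on construction.
#' @return a [CnProfile-class] object.
#' @export
CnProfile <- function(sampleId, segments) {
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments$cn <- as.numeric(segments$cn)
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  new("CnProfile", sampleId = sampleId, segments = segments)
}

#' @describeIn CnProfile segment table as a data.frame.
#' @param x a `CnProfile`.
#' @export
cnSegments <- function(x) x@segments

#' @describeIn CnProfile sample identifier.
#' @export
cnSampleId <- function(x) x@sampleId

setMethod("show", "CnProfile", function(object) {
  seg <- object@segments
  cat(sprintf("CnProfile '%s': %d segment(s), %d aberrant (cn != 2)\n",
              object@sampleId, nrow(seg), sum(seg$cn != 2)))
})

#' Read SEG-like copy-number segment tables
#'
#' Expects a tab-separated file with header `sample chrom start end cn`
#' (0-based half-open intervals, FREEC-style piecewise-constant output).
#' Overlapping segments within a sample are an error naming the offending
#' pair; abutting segments are accepted. Segments on chromosomes absent from
#' the genome model are dropped with a logged count.
#'
#' @param path input file.
#' @param genome [GenomeModel-class].
#' @return named list of [CnProfile-class] objects, one per sample.
#' @export
readCnSegments <- function(path, genome) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "chrom", "start", "end", "cn")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) return(list())
  drop <- !(df$chrom %in% chromNames(genome))
  if (any(drop))
    .log("readCnSegments: dropped %d segment(s) on unknown chromosomes", sum(drop))
  df <- df[!drop, , drop = FALSE]
  out <- list()
  for (id in unique(df$sample)) {
    seg <- df[df$sample == id, c("chrom", "start", "end", "cn"), drop = FALSE]
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1) {
        bad <- which(s$start[-1] < s$end[-nrow(s)])
        if (length(bad))
          stop(sprintf("%s: overlapping segments for sample %s on %s: [%d,%d) and [%d,%d)",
                       path, id, ch, s$start[bad[1]], s$end[bad[1]],
                       s$start[bad[1] + 1], s$end[bad[1] + 1]))
      }
    }
    out[[id]] <- CnProfile(id, seg)
  }
  out
}

#' Write copy-number profiles as a SEG-like TSV
#'
#' @param profiles list of [CnProfile-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCnSegments <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    cbind(sample = cnSampleId(p), cnSegments(p)))
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
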