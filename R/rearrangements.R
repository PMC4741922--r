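#' Construct a Rearrangements object
#'
#' Canonicalizes the event table: for each event the left breakpoint precedes
#' the right one under (chromosome order, position); interchromosomal events
#' are labelled `CTX` and an intrachromosomal `CTX` label is corrected to
#' `ITX` (coordinates are authoritative over caller labels).
#'
#' @param events data.frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `svType`, `support`, `sampleId`, `origin` (extra columns are preserved).
#' @param genome [GenomeModel-class] or a character vector of chromosome
#'   names giving the canonical order.
#' @return a [Rearrangements-class] object.
#' @export
Rearrangements <- function(events = .emptyEventFrame(), genome) {
  chromOrder <- if (is(genome, "GenomeModel")) chromNames(genome) else as.character(genome)
  for (col in setdiff(.EVENT_COLS, names(events))) {
    events[[col]] <- switch(col,
      support = 0L, sampleId = "", origin = "called",
      stop(sprintf("missing required column '%s'", col)))
  }
  events$pos1 <- as.integer(events$pos1)
  events$pos2 <- as.integer(events$pos2)
  events$support <- as.integer(events$support)
  events <- .canonicalizeEvents(events, chromOrder)
  rownames(events) <- NULL
  new("Rearrangements", events = events, chromOrder = chromOrder)
}

#' @describeIn Rearrangements event table as a data.frame.
#' @param x a `Rearrangements` object.
#' @export
eventTable <- function(x) x@events

#' @describeIn Rearrangements read-pair support counts.
#' @export
svSupport <- function(x) x@events$support

#' @describeIn Rearrangements SV class labels.
#' @export
svType <- function(x) x@events$svType

#' @describeIn Rearrangements spans of intrachromosomal events (`NA` for CTX).
#' @export
svSpan <- function(x) {
  ev <- x@events
  ifelse(ev$chrom1 == ev$chrom2, ev$pos2 - ev$pos1, NA_integer_)
}

setMethod("length", "Rearrangements", function(x) nrow(x@events))

setMethod("show", "Rearrangements", function(object) {
  ev <- object@events
  cat(sprintf("Rearrangements: %d event(s)", nrow(ev)))
  if (nrow(ev)) {
    tab <- table(factor(ev$svType, levels = .SV_TYPES))
    cat(" [", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "]", sep = "")
    ids <- unique(ev$sampleId)
    if (length(ids) == 1L && nzchar(ids)) cat(" sample", ids)
  }
  cat("\n")
})

setMethod("[", "Rearrangements", function(x, i, j, ..., drop = FALSE) {
  new("Rearrangements", events = x@events[i, , drop = FALSE],
      chromOrder = x@chromOrder)
})

#' Read rearrangement calls from BEDPE or BreakDancer-style TSV
#'
#' Both dialects are converted to 0-based breakpoint positions and canonical
#' left/right ordering. Records on chromosomes absent from the genome model
#' are dropped with a logged count; a malformed line raises an error naming
#' the line number. An empty file yields an empty object.
#'
#' `bedpe` expects at least `chrom1 start1 end1 chrom2 start2 end2 name
#' score`; `score` is read as the support count. Columns 11-13, if present,
#' are read back as `svType`, `sampleId` and `origin` (the layout written by
#' [writeRearrangements()]).
#'
#' `breakdancer_tsv` targets the canonical 12-column caller output
#' (`Chr1 Pos1 Orientation1 Chr2 Pos2 Orientation2 Type Size Score num_Reads
#' ...`), is permissive about trailing columns, and ignores the orientation
#' columns; positions are 1-based in this dialect. Support is `num_Reads`.
#'
#' @param path input file.
#' @param dialect `"bedpe"` or `"breakdancer_tsv"`.
#' @param genome [GenomeModel-class].
#' @param sampleId sample id to assign when the file does not carry one.
#' @return a [Rearrangements-class] object.
#' @export
readRearrangements <- function(path, dialect = c("bedpe", "breakdancer_tsv"),
                               genome, sampleId = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(Rearrangements(genome = genome))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  minCols <- if (dialect == "bedpe") 8L else 10L
  if (any(nf < minCols)) {
    i <- which(nf < minCols)[1]
    stop(sprintf("%s: malformed line %d (%d field(s), expected >= %d)",
                 path, lineNo[i], nf[i], minCols))
  }
  field <- function(k) vapply(parts, `[[`, character(1), k)
  num <- function(k, what) {
    v <- suppressWarnings(as.numeric(field(k)))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("%s: malformed line %d (non-numeric %s)", path, lineNo[i], what))
    }
    v
  }
  if (dialect == "bedpe") {
    ev <- data.frame(
      chrom1 = field(1), pos1 = as.integer(num(2, "start1")),
      chrom2 = field(4), pos2 = as.integer(num(5, "start2")),
      svType = if (all(nf >= 11)) field(11) else NA_character_,
      support = as.integer(round(num(8, "score"))),
      sampleId = if (all(nf >= 12)) field(12) else sampleId,
      origin = if (all(nf >= 13)) field(13) else "called",
      stringsAsFactors = FALSE)
  } else {
    ev <- data.frame(
      chrom1 = field(1), pos1 = as.integer(num(2, "Pos1")) - 1L,
      chrom2 = field(4), pos2 = as.integer(num(5, "Pos2")) - 1L,
      svType = field(7),
      support = as.integer(round(num(10, "num_Reads"))),
      sampleId = sampleId, origin = "called",
      stringsAsFactors = FALSE)
  }
  miss <- is.na(ev$svType)
  if (any(miss))
    ev$svType[miss] <- ifelse(ev$chrom1[miss] != ev$chrom2[miss], "CTX", "ITX")
  known <- chromNames(genome)
  drop <- !(ev$chrom1 %in% known) | !(ev$chrom2 %in% known)
  if (any(drop))
    .log("readRearrangements: dropped %d record(s) on unknown chromosomes", sum(drop))
  Rearrangements(ev[!drop, , drop = FALSE], genome)
}

#' Write rearrangements as BEDPE
#'
#' Writes a 13-column BEDPE (`chrom1 start1 end1 chrom2 start2 end2 name
#' score strand1 strand2 svType sampleId origin`) that round-trips through
#' [readRearrangements()]. Breakpoints are written as 1 bp features; strand
#' columns are `"."` (end orientation is not modelled).
#'
#' @param x a [Rearrangements-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRearrangements <- function(x, path) {
  ev <- eventTable(x)
  header <- paste(c("#chrom1", "start1", "end1", "chrom2", "start2", "end2",
                    "name", "score", "strand1", "strand2", "svType",
                    "sampleId", "origin"), collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(ev)) {
    recs <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t.\t.\t%s\t%s\t%s",
                    ev$chrom1, ev$pos1, ev$pos1 + 1L,
                    ev$chrom2, ev$pos2, ev$pos2 + 1L,
                    sprintf("r%04d", seq_len(nrow(ev))), ev$support,
                    ev$svType, ev$sampleId, ev$origin)
    writeLines(recs, con)
  }
  invisible(path)
}
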