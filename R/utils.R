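# shared internal helpers

# round half away from zero (reporting convention for percentages);
# base round() rounds half to even
.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Round half away from zero
#'
#' Reporting convention for similarity percentages: 94.5 rounds to 95, not 94.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- .roundHalfUp

# stderr log line, suppressible with options(svconcord.quiet = TRUE)
.log <- function(fmt, ...) {
  if (!isTRUE(getOption("svconcord.quiet", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}

# canonicalize an event table: left breakpoint <= right breakpoint under
# (chromosome index, position) order; svType forced consistent with the
# coordinates (interchromosomal => CTX, intrachromosomal CTX relabelled ITX)
.canonicalizeEvents <- function(ev, chromOrder) {
  if (nrow(ev) == 0L) return(ev)
  i1 <- match(ev$chrom1, chromOrder)
  i2 <- match(ev$chrom2, chromOrder)
  swap <- i1 > i2 | (i1 == i2 & ev$pos1 > ev$pos2)
  if (any(swap)) {
    tmpc <- ev$chrom1[swap]; ev$chrom1[swap] <- ev$chrom2[swap]; ev$chrom2[swap] <- tmpc
    tmpp <- ev$pos1[swap]; ev$pos1[swap] <- ev$pos2[swap]; ev$pos2[swap] <- tmpp
  }
  inter <- ev$chrom1 != ev$chrom2
  ev$svType[inter] <- "CTX"
  ev$svType[!inter & ev$svType == "CTX"] <- "ITX"
  ev
}

# sort events by canonical genome position (stable)
.orderEvents <- function(ev, chromOrder) {
  if (nrow(ev) == 0L) return(ev)
  o <- order(match(ev$chrom1, chromOrder), ev$pos1,
             match(ev$chrom2, chromOrder), ev$pos2)
  ev[o, , drop = FALSE]
}

.emptyEventFrame <- function() {
  data.frame(chrom1 = character(), pos1 = integer(), chrom2 = character(),
             pos2 = integer(), svType = character(), support = integer(),
             sampleId = character(), origin = character(),
             stringsAsFactors = FALSE)
}

# 0-based half-open intervals -> GRanges (1-based closed) and back
.grFromBed0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1, end = end0), ...)
}
.grFromPoints0 <- function(chrom, pos0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos0 + 1, width = 1))
}
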