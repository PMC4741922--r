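#' Construct a genome model
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp; the
#'   order defines the canonical chromosome order used throughout.
#' @param masks named list of `GRanges` interval masks (e.g. `centromere`,
#'   `segdup`).
#' @param genes `GRanges` with a `gene` metadata column and strand, or `NULL`.
#' @param cancerGenes character vector of cancer-associated gene names. Names
#'   absent from the annotation are kept but flagged with a warning (they may
#'   refer to genes outside the annotation).
#' @return a [GenomeModel-class] object.
#' @examples
#' gm <- GenomeModel(c(chr1 = 1e6, chr2 = 5e5))
#' chromLengths(gm)
#' @export
GenomeModel <- function(chromLengths, masks = list(), genes = NULL,
                        cancerGenes = character()) {
  si <- GenomeInfoDb::Seqinfo(seqnames = names(chromLengths),
                              seqlengths = as.integer(chromLengths))
  if (is.null(genes)) genes <- GenomicRanges::GRanges()
  gm <- new("GenomeModel", seqinfo = si, masks = masks, genes = genes,
            cancerGenes = as.character(cancerGenes))
  known <- if (length(genes)) mcols(genes)$gene else character()
  extern <- setdiff(cancerGenes, known)
  if (length(extern))
    warning(sprintf("%d cancer gene name(s) not present in the gene annotation",
                    length(extern)))
  gm
}

#' @describeIn GenomeModel ordered chromosome names.
#' @param x a `GenomeModel`.
#' @export
chromNames <- function(x) GenomeInfoDb::seqnames(x@seqinfo)

#' @describeIn GenomeModel named vector of chromosome lengths (bp).
#' @export
chromLengths <- function(x) GenomeInfoDb::seqlengths(x@seqinfo)

#' @describeIn GenomeModel named list of mask `GRanges`.
#' @export
genomeMasks <- function(x) x@masks

#' @describeIn GenomeModel gene annotation `GRanges`.
#' @export
genomeGenes <- function(x) x@genes

#' @describeIn GenomeModel cancer-associated gene names.
#' @export
cancerGenes <- function(x) x@cancerGenes

setMethod("show", "GenomeModel", function(object) {
  sl <- chromLengths(object)
  cat(sprintf("GenomeModel: %d chromosome(s), %.1f Mb total\n",
              length(sl), sum(sl) / 1e6))
  if (length(object@masks))
    cat("  masks:", paste(names(object@masks), collapse = ", "), "\n")
  cat(sprintf("  genes: %d (%d cancer-associated)\n",
              length(object@genes), length(object@cancerGenes)))
})

#' Strand-aware extended gene spans
#'
#' Extends each gene 2 kb upstream of its transcription start (towards lower
#' coordinates on the + strand, higher coordinates on the - strand), through
#' its 3' end. This is the "genic area" definition used by the genic
#' breakpoint analyses. The extension boundary is inclusive at exactly 2000 bp
#' upstream.
#'
#' @param genes `GRanges` gene annotation with strand.
#' @param genome [GenomeModel-class], used to clip extensions to chromosome
#'   bounds.
#' @param promoter upstream extension in bp (default 2000).
#' @return `GRanges` of extended spans, same order and metadata as `genes`.
#' @export
extendedGeneSpans <- function(genes, genome = NULL, promoter = 2000) {
  if (length(genes) == 0L) return(genes)
  ext <- genes
  plus <- as.character(strand(ext)) != "-"
  GenomicRanges::start(ext)[plus] <- pmax(1L, GenomicRanges::start(ext)[plus] - as.integer(promoter))
  minus <- !plus
  newEnd <- GenomicRanges::end(ext)[minus] + as.integer(promoter)
  if (!is.null(genome)) {
    lim <- chromLengths(genome)[as.character(seqnames(ext))[minus]]
    newEnd <- pmin(newEnd, as.integer(lim))
  }
  GenomicRanges::end(ext)[minus] <- newEnd
  ext
}

#' Read a BED3 interval file
#'
#' BED intervals are 0-based half-open. Records on chromosomes absent from the
#' genome model are dropped with a logged count; records extending past the
#' chromosome end are an error, as is `end <= start`.
#'
#' @param path BED file path.
#' @param genome [GenomeModel-class].
#' @return `GRanges` of the retained intervals.
#' @export
readIntervals <- function(path, genome) {
  df <- .readTsv(path, c("chrom", "start", "end"), minCols = 3)
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  df$start <- .asInt(df$start, path, "start")
  df$end <- .asInt(df$end, path, "end")
  if (any(df$end <= df$start))
    stop(sprintf("%s: interval with end <= start at record %d", path,
                 which(df$end <= df$start)[1]))
  keep <- df$chrom %in% chromNames(genome)
  if (any(!keep))
    .log("readIntervals: dropped %d record(s) on unknown chromosomes", sum(!keep))
  df <- df[keep, , drop = FALSE]
  .grFromBed0(df$chrom, df$start, df$end)
}

#' Read a BED6 gene annotation
#'
#' Expects `chrom start end name score strand`; start/end are 0-based
#' half-open. Records on unknown chromosomes are dropped with a logged count.
#'
#' @inheritParams readIntervals
#' @return `GRanges` with a `gene` metadata column and strand.
#' @export
readGenes <- function(path, genome) {
  df <- .readTsv(path, c("chrom", "start", "end", "name", "score", "strand"),
                 minCols = 6)
  if (nrow(df) == 0L)
    return(GenomicRanges::GRanges(gene = character()))
  df$start <- .asInt(df$start, path, "start")
  df$end <- .asInt(df$end, path, "end")
  if (any(df$end <= df$start))
    stop(sprintf("%s: gene with end <= start at record %d", path,
                 which(df$end <= df$start)[1]))
  if (!all(df$strand %in% c("+", "-")))
    stop(sprintf("%s: strand must be '+' or '-'", path))
  keep <- df$chrom %in% chromNames(genome)
  if (any(!keep))
    .log("readGenes: dropped %d record(s) on unknown chromosomes", sum(!keep))
  df <- df[keep, , drop = FALSE]
  gr <- .grFromBed0(df$chrom, df$start, df$end, strand = df$strand)
  mcols(gr)$gene <- df$name
  gr
}

#' Read a plain-text gene list (one name per line)
#'
#' @param path file path.
#' @return character vector of gene names.
#' @export
readGeneList <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

# headerless/commented TSV reader used by the BED-style readers
.readTsv <- function(path, colNames, minCols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    df <- as.data.frame(matrix(character(), ncol = length(colNames), nrow = 0),
                        stringsAsFactors = FALSE)
    names(df) <- colNames
    return(df)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < minCols))
    stop(sprintf("%s: malformed line %d (%d field(s), expected >= %d)",
                 path, which(nf < minCols)[1], nf[which(nf < minCols)[1]], minCols))
  df <- as.data.frame(do.call(rbind, lapply(parts, function(p) p[seq_len(minCols)])),
                      stringsAsFactors = FALSE)
  names(df) <- colNames[seq_len(minCols)]
  df
}

.asInt <- function(x, path, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v))
    stop(sprintf("%s: non-numeric %s at record %d", path, what, which(is.na(v))[1]))
  as.integer(round(v))
}
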