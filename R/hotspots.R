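#' Chromosome-pair rearrangement heatmap
#'
#' Off-diagonal cell (i, j) is the number of interchromosomal events joining
#' chromosomes i and j divided by their combined length in `bin` units
#' (default 50 Mb); diagonal cell (i, i) is the number of intrachromosomal
#' events on i divided by its length in `bin` units — rearrangements per
#' chromosome per 50 Mb.
#'
#' @param catalogues list of [Rearrangements-class] objects (pooled).
#' @param genome [GenomeModel-class].
#' @param bin normalization unit in bp (default 5e7).
#' @param splitByRole optional named character vector mapping sample ids to
#'   `"primary"` / `"metastasis"`; when given, a list of two matrices is
#'   returned (the figure's two triangles).
#' @return symmetric numeric matrix, or a named list of two such matrices.
#' @export
pairHeatmap <- function(catalogues, genome, bin = 5e7, splitByRole = NULL) {
  chroms <- chromNames(genome)
  lens <- chromLengths(genome)
  build <- function(ev) {
    m <- matrix(0, length(chroms), length(chroms),
                dimnames = list(chroms, chroms))
    if (nrow(ev)) {
      for (k in seq_len(nrow(ev))) {
        i <- ev$chrom1[k]; j <- ev$chrom2[k]
        if (i == j) m[i, i] <- m[i, i] + 1
        else { m[i, j] <- m[i, j] + 1; m[j, i] <- m[j, i] + 1 }
      }
    }
    norm <- outer(lens, lens, `+`) / bin
    diag(norm) <- lens / bin
    m / norm
  }
  pool <- do.call(rbind, lapply(catalogues, eventTable))
  if (is.null(pool)) pool <- .emptyEventFrame()
  if (is.null(splitByRole)) return(build(pool))
  list(primary = build(pool[splitByRole[pool$sampleId] == "primary", , drop = FALSE]),
       metastasis = build(pool[splitByRole[pool$sampleId] == "metastasis", , drop = FALSE]))
}

#' Genome-wide breakpoint density track
#'
#' Gaussian kernel density of all breakpoints (both ends of every
#' rearrangement contribute) with kernel standard deviation `bandwidth`,
#' evaluated on a per-chromosome grid of spacing `gridStep`. Each
#' chromosome's curve is weighted by its share of the total breakpoints and
#' the track is normalized so its genome-wide trapezoid integral is exactly 1
#' (the per-chromosome computation keeps kernels from leaking mass across
#' chromosome boundaries; the small mass lost past chromosome ends is
#' restored by the normalization).
#'
#' @param catalogues list of [Rearrangements-class] objects.
#' @param genome [GenomeModel-class].
#' @param bandwidth kernel standard deviation in bp (default 10 kb).
#' @param gridStep grid spacing in bp (default 10 kb).
#' @return a [DensityTrack-class] object.
#' @export
breakpointDensity <- function(catalogues, genome, bandwidth = 1e4,
                              gridStep = 1e4) {
  pool <- do.call(rbind, lapply(catalogues, eventTable))
  if (is.null(pool)) pool <- .emptyEventFrame()
  bp <- data.frame(chrom = c(pool$chrom1, pool$chrom2),
                   pos = c(pool$pos1, pool$pos2), stringsAsFactors = FALSE)
  N <- nrow(bp)
  if (N == 0L) stop("no breakpoints")
  lens <- chromLengths(genome)
  out <- list()
  for (ch in chromNames(genome)) {
    grid <- seq(0, lens[[ch]], by = gridStep)
    dens <- numeric(length(grid))
    pos <- bp$pos[bp$chrom == ch]
    for (p in pos) {
      lo <- max(1L, floor((p - 6 * bandwidth) / gridStep) + 1L)
      hi <- min(length(grid), ceiling((p + 6 * bandwidth) / gridStep) + 1L)
      idx <- lo:hi
      dens[idx] <- dens[idx] + stats::dnorm(grid[idx], p, bandwidth)
    }
    out[[ch]] <- data.frame(chrom = ch, pos = grid, density = dens / N,
                            stringsAsFactors = FALSE)
  }
  track <- if (length(out)) do.call(rbind, out) else NULL
  integral <- sum(vapply(split(track, track$chrom), function(tr) {
    sum(diff(tr$pos) * (utils::head(tr$density, -1) + utils::tail(tr$density, -1)) / 2)
  }, numeric(1)))
  track$density <- track$density / integral
  new("DensityTrack", track = track, bandwidth = bandwidth,
      gridStep = gridStep, nBreakpoints = as.integer(N))
}

#' @describeIn breakpointDensity grid table of a [DensityTrack-class].
#' @param x a `DensityTrack`.
#' @export
densityTrack <- function(x) x@track

#' @describeIn breakpointDensity genome-wide trapezoid integral of the track.
#' @export
densityIntegral <- function(x) {
  sum(vapply(split(x@track, x@track$chrom), function(tr) {
    sum(diff(tr$pos) * (utils::head(tr$density, -1) + utils::tail(tr$density, -1)) / 2)
  }, numeric(1)))
}

setMethod("show", "DensityTrack", function(object) {
  cat(sprintf("DensityTrack: %d breakpoint(s), bandwidth %g bp, grid %g bp, max %.3g/bp\n",
              object@nBreakpoints, object@bandwidth, object@gridStep,
              max(object@track$density)))
})

#' Write a density track as bedGraph
#'
#' Each grid interval `[pos, pos + gridStep)` carries the density at its left
#' grid point.
#'
#' @param x a [DensityTrack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDensityBedGraph <- function(x, path) {
  tr <- x@track
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph name=breakpoint_density", con)
  writeLines(sprintf("%s\t%d\t%d\t%.6g", tr$chrom, as.integer(tr$pos),
                     as.integer(tr$pos + x@gridStep), tr$density), con)
  invisible(path)
}

#' Call hotspot regions from a density track
#'
#' Maximal runs of grid points with density strictly above `threshold`,
#' reported as half-open intervals snapped to the grid (`[first grid point,
#' last grid point + gridStep)`, clipped to the chromosome). Runs separated
#' by a sub-threshold grid point are not merged.
#'
#' @param x a [DensityTrack-class].
#' @param threshold density threshold per bp (default 3e-6).
#' @param genome optional [GenomeModel-class] for clipping to chromosome
#'   ends.
#' @return data.frame of regions (`chrom`, `start`, `end`, `maxDensity`).
#' @export
callHotspots <- function(x, threshold = 3e-6, genome = NULL) {
  out <- list()
  for (tr in split(x@track, x@track$chrom)) {
    above <- tr$density > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      st <- tr$pos[starts[k]]
      en <- tr$pos[ends[k]] + x@gridStep
      if (!is.null(genome)) en <- min(en, chromLengths(genome)[[tr$chrom[1]]])
      out[[length(out) + 1L]] <- data.frame(
        chrom = tr$chrom[1], start = st, end = en,
        maxDensity = max(tr$density[starts[k]:ends[k]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else NULL
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      maxDensity = numeric())
  res
}

#' Annotate hotspot regions with overlapping genes
#'
#' A gene is reported for a region when its strand-aware extended span
#' (2 kb upstream of the transcription start through the gene end,
#' [extendedGeneSpans()]) intersects the region.
#'
#' @param regions region data.frame from [callHotspots()] (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param genes gene `GRanges` with a `gene` metadata column.
#' @param genome optional [GenomeModel-class] used to clip extensions.
#' @return list of character vectors of gene names, one per region.
#' @export
annotateRegions <- function(regions, genes, genome = NULL) {
  if (nrow(regions) == 0L) return(list())
  if (length(genes) == 0L) return(rep(list(character()), nrow(regions)))
  ext <- extendedGeneSpans(genes, genome)
  gr <- .grFromBed0(regions$chrom, regions$start, regions$end)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, ext))
  out <- rep(list(character()), nrow(regions))
  for (q in unique(S4Vectors::queryHits(hits))) {
    out[[q]] <- unique(mcols(ext)$gene[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == q]])
  }
  out
}
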