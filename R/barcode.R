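#' Build the non-redundant cohort catalogue and barcode matrix
#'
#' All events of all samples are single-linkage clustered under the
#' two-sided windowed match ([breakpointsMatch()]): any chain of pairwise
#' matches merges into one cluster, so members further apart than the window
#' can end up in one column (chaining is accepted and logged). Each cluster
#' becomes one column of the presence/absence matrix; a cell is 1 when the
#' sample contributed at least one member. The cluster representative is the
#' member with the median left coordinate (lower median for even cluster
#' sizes); columns are ordered by genome position of the representative left
#' breakpoint.
#'
#' @param catalogues named list of filtered [Rearrangements-class], one per
#'   sample (names are the row names of the matrix).
#' @param window matching half-width in bp.
#' @return a [BarcodeMatrix-class] object.
#' @export
buildNonredundant <- function(catalogues, window = 500) {
  stopifnot(length(catalogues) > 0, !is.null(names(catalogues)))
  chromOrder <- catalogues[[1]]@chromOrder
  evs <- lapply(names(catalogues), function(id) {
    ev <- eventTable(catalogues[[id]])
    if (nrow(ev)) ev$sampleId <- id
    ev
  })
  pool <- do.call(rbind, evs)
  samples <- names(catalogues)
  if (is.null(pool) || nrow(pool) == 0L) {
    m <- matrix(0L, nrow = length(samples), ncol = 0,
                dimnames = list(samples, NULL))
    return(new("BarcodeMatrix", matrix = m,
               columnInfo = data.frame(chrom1 = character(), posLeft = integer(),
                                       chrom2 = character(), posRight = integer(),
                                       nMembers = integer())))
  }
  rownames(pool) <- NULL
  cand <- .windowedCandidates(pool, pool, window)
  cand <- cand[cand$iA < cand$iB, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(pool), directed = FALSE)
  if (nrow(cand))
    g <- igraph::add_edges(g, rbind(cand$iA, cand$iB))
  comp <- igraph::components(g)$membership
  nClust <- max(comp)
  if (nClust < nrow(pool))
    .log("buildNonredundant: %d events collapsed into %d non-redundant cluster(s)",
         nrow(pool), nClust)
  reps <- vapply(seq_len(nClust), function(k) {
    idx <- which(comp == k)
    idx[order(pool$pos1[idx])][ceiling(length(idx) / 2)]
  }, integer(1))
  info <- data.frame(chrom1 = pool$chrom1[reps], posLeft = pool$pos1[reps],
                     chrom2 = pool$chrom2[reps], posRight = pool$pos2[reps],
                     nMembers = as.integer(tabulate(comp, nClust)),
                     stringsAsFactors = FALSE)
  o <- order(match(info$chrom1, chromOrder), info$posLeft,
             match(info$chrom2, chromOrder), info$posRight)
  info <- info[o, , drop = FALSE]
  rownames(info) <- NULL
  clustOf <- match(comp, (seq_len(nClust))[o])
  m <- matrix(0L, nrow = length(samples), ncol = nClust,
              dimnames = list(samples, NULL))
  for (i in seq_len(nrow(pool)))
    m[pool$sampleId[i], clustOf[i]] <- 1L
  new("BarcodeMatrix", matrix = m, columnInfo = info)
}

#' @describeIn buildNonredundant the 0/1 matrix of a [BarcodeMatrix-class].
#' @param x a `BarcodeMatrix`.
#' @export
barcodeMatrix <- function(x) x@matrix

#' @describeIn buildNonredundant per-cluster representative coordinates.
#' @export
barcodeColumns <- function(x) x@columnInfo

setMethod("show", "BarcodeMatrix", function(object) {
  cat(sprintf("BarcodeMatrix: %d sample(s) x %d non-redundant rearrangement(s)\n",
              nrow(object@matrix), ncol(object@matrix)))
})

#' Binary (asymmetric Jaccard) distance between barcode rows
#'
#' `d(x, y) = 1 - |x AND y| / |x OR y|`; two rows with an empty union are at
#' distance 0.
#'
#' @param x a [BarcodeMatrix-class] or a 0/1 matrix with samples in rows.
#' @return a `dist` object.
#' @export
binaryDistance <- function(x) {
  m <- if (is(x, "BarcodeMatrix")) barcodeMatrix(x) else x
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    inter <- sum(m[i, ] & m[j, ])
    uni <- sum(m[i, ] | m[j, ])
    d[i, j] <- d[j, i] <- if (uni == 0) 0 else 1 - inter / uni
  }
  stats::as.dist(d)
}

#' Ward hierarchical clustering of barcode distances
#'
#' Agglomerative Ward linkage ([stats::hclust()]) applied directly to the
#' binary distance matrix. `"ward.D"` reproduces the classic R `"ward"`
#' behavior on a plain distance matrix; `hclust` merges are deterministic
#' (lower-index pair first on ties).
#'
#' @param d a `dist` object from [binaryDistance()].
#' @param method linkage method (default `"ward.D"`).
#' @return an `hclust` tree.
#' @export
wardCluster <- function(d, method = "ward.D") {
  stats::hclust(d, method = method)
}

#' Serialize a dendrogram as Newick
#'
#' @param hc an `hclust` tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
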