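options(svconcord.quiet = TRUE)

# small genome for constructed fixtures
tinyGenome <- function(lengths = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                       masks = list(), genes = NULL, cancerGenes = character()) {
  GenomeModel(lengths, masks = masks, genes = genes, cancerGenes = cancerGenes)
}

# quick event-set builder; positions given as canonical left/right
makeEvents <- function(chrom1, pos1, chrom2 = chrom1, pos2, svType = NULL,
                       support = 10L, sampleId = "s", origin = "called",
                       genome = tinyGenome()) {
  n <- max(length(chrom1), length(pos1), length(pos2))
  if (is.null(svType)) {
    c1 <- rep_len(chrom1, n); c2 <- rep_len(chrom2, n)
    svType <- ifelse(c1 != c2, "CTX", "DEL")
  }
  Rearrangements(data.frame(
    chrom1 = rep_len(chrom1, n), pos1 = rep_len(pos1, n),
    chrom2 = rep_len(chrom2, n), pos2 = rep_len(pos2, n),
    svType = rep_len(svType, n), support = rep_len(support, n),
    sampleId = rep_len(sampleId, n), origin = rep_len(origin, n),
    stringsAsFactors = FALSE), genome)
}

# random valid event table on a genome (used by round-trip/matching properties)
randomEvents <- function(n, genome = tinyGenome(), sampleId = "s",
                         maxSupport = 30L) {
  if (n == 0L) return(Rearrangements(genome = genome))
  lens <- chromLengths(genome)
  chroms <- names(lens)
  c1 <- sample(chroms, n, replace = TRUE)
  c2 <- sample(chroms, n, replace = TRUE)
  p1 <- vapply(c1, function(ch) sample.int(lens[[ch]], 1) - 1L, integer(1))
  p2 <- vapply(c2, function(ch) sample.int(lens[[ch]], 1) - 1L, integer(1))
  Rearrangements(data.frame(
    chrom1 = c1, pos1 = p1, chrom2 = c2, pos2 = p2,
    svType = sample(c("CTX", "ITX", "DEL", "INV"), n, replace = TRUE),
    support = sample.int(maxSupport, n, replace = TRUE),
    sampleId = sampleId, origin = "called", stringsAsFactors = FALSE), genome)
}

# independent maximum-cardinality windowed matching oracle (bipartite
# maximum matching via igraph), built from its own candidate enumeration
oracleMaxMatching <- function(catA, catB, window = 500) {
  ea <- eventTable(catA); eb <- eventTable(catB)
  nA <- nrow(ea); nB <- nrow(eb)
  if (nA == 0 || nB == 0) return(0L)
  edges <- integer(0)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    if (ea$chrom1[i] == eb$chrom1[j] && ea$chrom2[i] == eb$chrom2[j] &&
        abs(ea$pos1[i] - eb$pos1[j]) <= window &&
        abs(ea$pos2[i] - eb$pos2[j]) <= window)
      edges <- c(edges, i, nA + j)
  }
  if (length(edges) == 0) return(0L)
  g <- igraph::make_empty_graph(n = nA + nB, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  igraph::V(g)$type <- c(rep(FALSE, nA), rep(TRUE, nB))
  igraph::max_bipartite_match(g)$matching_size
}
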