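#' Directional and combined similarity percentages
#'
#' `directionalPercent` is the percentage of one tumor's rearrangements found
#' in the other: `100 * shared / total`, reported rounded to the nearest
#' integer (half away from zero). `combinedPercent` is the union-based
#' similarity `100 * shared / (totalA + totalB - shared)`.
#'
#' @param shared shared rearrangement count(s).
#' @param total,totalA,totalB per-sample totals (shared + specific).
#' @param rounded return the integer reporting value (default) or the raw
#'   percentage.
#' @return numeric percentage vector; `NA` with a warning where a total is 0
#'   (the percentage is undefined, not 0).
#' @examples
#' directionalPercent(212, 216)  # 98
#' combinedPercent(82, 82, 87)   # 94
#' @export
directionalPercent <- function(shared, total, rounded = TRUE) {
  pct <- ifelse(total > 0, 100 * shared / total, NA_real_)
  if (anyNA(pct)) warning("similarity undefined for zero totals")
  if (rounded) .roundHalfUp(pct) else pct
}

#' @rdname directionalPercent
#' @export
combinedPercent <- function(shared, totalA, totalB, rounded = TRUE) {
  union <- totalA + totalB - shared
  pct <- ifelse(union > 0, 100 * shared / union, NA_real_)
  if (anyNA(pct)) warning("similarity undefined for empty union")
  if (rounded) .roundHalfUp(pct) else pct
}

#' Similarity statistics of a classified pair
#'
#' @param pc a [PairComparison-class].
#' @return list with unrounded `pctA`, `pctB`, `pctCombined` and their
#'   integer reporting values `roundedA`, `roundedB`, `roundedCombined`.
#' @export
directionalSimilarity <- function(pc) {
  tot <- totalCounts(pc)
  s <- sharedCount(pc)
  pctA <- directionalPercent(s, tot[["a"]], rounded = FALSE)
  pctB <- directionalPercent(s, tot[["b"]], rounded = FALSE)
  list(pctA = pctA, pctB = pctB,
       roundedA = .roundHalfUp(pctA), roundedB = .roundHalfUp(pctB))
}

#' @rdname directionalSimilarity
#' @export
combinedSimilarity <- function(pc) {
  tot <- totalCounts(pc)
  combinedPercent(sharedCount(pc), tot[["a"]], tot[["b"]], rounded = FALSE)
}

#' Rearrangements gained and lost by the metastasis
#'
#' `gained` is the number of metastasis-specific events, `lost` the number of
#' primary-specific events of a primary-metastasis comparison.
#'
#' @param pc a [PairComparison-class].
#' @param roles named character vector mapping the two sample ids to
#'   `"primary"` / `"metastasis"`.
#' @return named integer vector `c(gained = , lost = )`.
#' @export
gainedLost <- function(pc, roles) {
  ra <- roles[[pc@sampleA]]; rb <- roles[[pc@sampleB]]
  if (is.null(ra) || is.null(rb) || !setequal(c(ra, rb), c("primary", "metastasis")))
    stop("roles must map one sample to 'primary' and the other to 'metastasis'")
  spec <- specificEvents(pc)
  if (ra == "metastasis") c(gained = nrow(spec$a), lost = nrow(spec$b))
  else c(gained = nrow(spec$b), lost = nrow(spec$a))
}

#' Convert classified pairs to a cohort counts table
#'
#' Produces two rows (one per direction) for every comparison, in the layout
#' consumed by [cohortSummary()].
#'
#' @param pcs list of [PairComparison-class] objects.
#' @param manifest sample manifest (see [asSampleMeta()]).
#' @return data.frame with columns `patient`, `sample`, `paired`,
#'   `role_sample`, `role_paired`, `total`, `shared`, `specific`, `set`
#'   (`matched` within a patient, `random` otherwise).
#' @export
pairComparisonsToCounts <- function(pcs, manifest) {
  manifest <- asSampleMeta(manifest)
  look <- function(id, col) manifest[[col]][match(id, manifest$sample_id)]
  rows <- lapply(pcs, function(pc) {
    tot <- totalCounts(pc); s <- sharedCount(pc)
    ids <- c(pc@sampleA, pc@sampleB)
    pats <- look(ids, "patient_id")
    data.frame(
      patient = pats,
      sample = ids, paired = rev(ids),
      role_sample = look(ids, "role"),
      role_paired = look(rev(ids), "role"),
      total = c(tot[["a"]], tot[["b"]]), shared = s,
      specific = c(tot[["a"]], tot[["b"]]) - s,
      set = if (pats[1] == pats[2]) "matched" else "random",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort-level summary of pairwise similarity
#'
#' Summarizes a cohort counts table (two directional rows per comparison, as
#' produced by [pairComparisonsToCounts()] or loaded from a published
#' counts file): per-row directional percentages, median/min/max of totals,
#' shared, specific and percentages per set (`matched` and, when present,
#' `random` cross-patient pairings), gained/lost statistics over the
#' primary-vs-metastasis comparisons, CN percentage summaries when a `cn_pct`
#' column is present, and both aggregations of the conditional likelihood
#' that a primary rearrangement is found in the metastasis (pooled ratio and
#' per-pair mean). Medians over an even count are the mean of the two central
#' values.
#'
#' @param counts cohort counts data.frame; required columns `patient`,
#'   `sample`, `paired`, `role_sample`, `role_paired`, `total`, `shared`,
#'   `specific`; optional `cn_pct` and `set` (defaults to `"matched"`).
#' @return list with `rows` (the input plus a `pct` column), `stats`
#'   (long data.frame of median/min/max by metric and set), `gainedLost`
#'   (summary over primary-metastasis comparisons) and `pMetGivenPrim`
#'   (named vector, `pooled` and `perPairMean`).
#' @export
cohortSummary <- function(counts) {
  need <- c("patient", "sample", "paired", "role_sample", "role_paired",
            "total", "shared", "specific")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop(sprintf("counts table missing column(s): %s", paste(miss, collapse = ", ")))
  if (is.null(counts$set)) counts$set <- "matched"
  counts$pct <- directionalPercent(counts$shared, counts$total)
  summarize <- function(x) c(median = stats::median(x), min = min(x), max = max(x))
  stats <- list()
  for (s in unique(counts$set)) {
    sub <- counts[counts$set == s, , drop = FALSE]
    for (metric in c("total", "shared", "specific", "pct")) {
      v <- summarize(sub[[metric]])
      stats[[length(stats) + 1L]] <- data.frame(
        set = s, metric = metric, median = v[["median"]], min = v[["min"]],
        max = v[["max"]], stringsAsFactors = FALSE)
    }
    if (!is.null(sub$cn_pct) && any(!is.na(sub$cn_pct))) {
      v <- summarize(sub$cn_pct[!is.na(sub$cn_pct)])
      stats[[length(stats) + 1L]] <- data.frame(
        set = s, metric = "cn_pct", median = v[["median"]], min = v[["min"]],
        max = v[["max"]], stringsAsFactors = FALSE)
    }
  }
  matched <- counts[counts$set == "matched", , drop = FALSE]
  pm <- matched[matched$role_sample == "primary" &
                matched$role_paired == "metastasis", , drop = FALSE]
  mp <- matched[matched$role_sample == "metastasis" &
                matched$role_paired == "primary", , drop = FALSE]
  none <- c(median = NA_real_, min = NA_real_, max = NA_real_)
  gl <- list(
    gained = if (nrow(mp)) summarize(mp$specific) else none,
    lost = if (nrow(pm)) summarize(pm$specific) else none,
    nComparisons = nrow(pm))
  pMet <- if (nrow(pm)) c(pooled = sum(pm$shared) / sum(pm$total),
                          perPairMean = mean(pm$shared / pm$total))
          else c(pooled = NA_real_, perPairMean = NA_real_)
  list(rows = counts, stats = do.call(rbind, stats), gainedLost = gl,
       pMetGivenPrim = pMet)
}
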