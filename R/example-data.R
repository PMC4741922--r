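#' Bundled example cohort counts
#'
#' Pairwise rearrangement counts from an 11-patient breast cancer cohort of
#' primary tumors and matched distant metastases (11 primaries, 13
#' metastases; two directional rows per comparison), in the layout consumed
#' by [cohortSummary()]: per-sample totals, shared and specific counts plus
#' the event-based CN similarity of each comparison (one value per unordered
#' pair). These printed counts serve as worked-example inputs for the
#' similarity arithmetic.
#'
#' @return data.frame, see [cohortSummary()] for the columns.
#' @examples
#' counts <- exampleCohortCounts()
#' cohortSummary(counts)$stats
#' @export
exampleCohortCounts <- function() {
  path <- system.file("extdata", "breast_cohort_pair_counts.tsv",
                      package = "svconcord", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Bundled example PCR validation counts
#'
#' Informative PCR assay counts for rearrangements predicted shared or
#' specific in the same cohort, inputs for [validationSummary()].
#'
#' @return data.frame with columns `category`, `tested`, `confirmed`,
#'   `germline`.
#' @export
exampleValidationCounts <- function() {
  path <- system.file("extdata", "pcr_validation_counts.tsv",
                      package = "svconcord", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Bundled example enrichment counts
#'
#' Observed genic-breakpoint and cancer-gene overlap counts with their
#' simulated-null summaries (median and extreme-tail counts) for the same
#' cohort, inputs for [foldEnrichment()] and [empiricalTwoSidedP()]-style
#' arithmetic.
#'
#' @return data.frame with columns `metric`, `observed`, `n_total`,
#'   `null_median`, `tail_count`, `n_sims`.
#' @export
exampleEnrichmentCounts <- function() {
  path <- system.file("extdata", "enrichment_observed_counts.tsv",
                      package = "svconcord", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
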