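#' Validate a sample manifest
#'
#' A manifest is a plain data.frame with one row per sample and columns
#' `sample_id`, `patient_id`, `role` (`primary`, `metastasis` or
#' `normal_pool`), `physical_coverage` and `sequence_coverage` (fold).
#' Tumor samples must have positive coverages.
#'
#' @param df data.frame to validate.
#' @return the validated data.frame (invisibly usable as-is).
#' @export
asSampleMeta <- function(df) {
  need <- c("sample_id", "patient_id", "role", "physical_coverage",
            "sequence_coverage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("manifest missing column(s): %s", paste(miss, collapse = ", ")))
  if (!all(df$role %in% c("primary", "metastasis", "normal_pool")))
    stop("role must be one of primary, metastasis, normal_pool")
  tum <- df$role != "normal_pool"
  if (any(df$physical_coverage[tum] <= 0) || any(df$sequence_coverage[tum] <= 0))
    stop("tumor samples must have positive coverages")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in manifest")
  df
}

#' Read / write a sample manifest TSV
#'
#' @param path file path.
#' @return validated manifest data.frame.
#' @export
readSampleMeta <- function(path) {
  asSampleMeta(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname readSampleMeta
#' @param df manifest data.frame.
#' @export
writeSampleMeta <- function(df, path) {
  utils::write.table(asSampleMeta(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
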