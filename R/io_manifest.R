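#' Read a sample-group manifest
#'
#' The manifest is a tab-separated table with columns `sample_id`, `group`
#' and, for metabolomics runs, an optional `injection_order` column. Group
#' labels for the sequencing cohort are `RC` (recurrence), `RM` (remission)
#' and `HC` (healthy control); metabolite tables may additionally carry
#' pooled `QC` injections and use arbitrary two-group condition labels.
#'
#' @param path Path to the manifest TSV.
#' @param allowed_groups Optional character vector of permitted group labels
#'   (`"QC"` is always allowed); `NULL` skips the check.
#' @return A tibble with one row per sample.
#' @export
read_manifest <- function(path, allowed_groups = NULL) {
  manifest <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      group = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_manifest(manifest, allowed_groups)
}

#' Write a sample-group manifest
#'
#' @param manifest Tibble with `sample_id`, `group` and optional
#'   `injection_order`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}
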