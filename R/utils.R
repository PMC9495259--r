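# Internal helpers shared across modules.

# fixed (non-sample) columns of a variant table
VARIANT_META_COLS <- c(
  "variant_id", "chrom", "pos", "ref", "alt", "rsid", "gene", "function_class"
)

ZYGOSITY_LEVELS <- c("absent", "het", "hom")

FUNCTION_CLASSES <- c(
  "nonsynonymous_SNV", "synonymous_SNV", "stopgain", "stoploss", "other"
)

variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @noRd
sample_cols <- function(variants) {
  setdiff(names(variants), VARIANT_META_COLS)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_probability <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    abort(sprintf("%s must be numeric in [0, 1]", what))
  }
  invisible(p)
}

#' Validate a sample manifest
#'
#' Checks sample-id uniqueness and, optionally, that every group label is in
#' an allowed set. `QC` is always an admissible label for metabolomics
#' manifests.
#'
#' @param manifest A data frame with columns `sample_id`, `group`, and
#'   optionally `injection_order`.
#' @param allowed_groups Optional character vector of permitted group labels
#'   (in addition to `"QC"`).
#' @return The manifest as a tibble, invisibly usable downstream.
#' @export
validate_manifest <- function(manifest, allowed_groups = NULL) {
  assert_cols(manifest, c("sample_id", "group"), "manifest")
  manifest <- as_tibble(manifest)
  if (anyDuplicated(manifest$sample_id) > 0) {
    abort("manifest sample_ids must be unique")
  }
  if (!is.null(allowed_groups)) {
    bad <- setdiff(unique(manifest$group), c(allowed_groups, "QC"))
    if (length(bad) > 0) {
      abort(sprintf(
        "manifest contains unknown group label(s): %s",
        paste(bad, collapse = ", ")
      ))
    }
  }
  if ("injection_order" %in% names(manifest)) {
    io <- manifest$injection_order
    if (!all(is.na(io) | (io > 0 & io == round(io)))) {
      abort("injection_order must be positive integers (or NA)")
    }
  }
  manifest
}

group_samples <- function(manifest, group) {
  manifest$sample_id[manifest$group == group]
}

# stage-count logging used by the pipeline audit trail
log_stage <- function(stage, n_in, n_out, log_lines = NULL) {
  line <- sprintf("[%s] in=%d out=%d", stage, n_in, n_out)
  inform(line)
  c(log_lines, line)
}
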