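#' Read a GMT gene-set database
#'
#' GMT is the gene-matrix-transposed format: one tab-separated line per gene
#' set (`id`, `description`, then member gene symbols). Duplicate members
#' within a set are removed; duplicate set ids are an error.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `pathway_id`, `pathway_name` and a `genes`
#'   list-column of unique member symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(sprintf("GMT file '%s' contains no gene sets", path))
    return(tibble(
      pathway_id = character(), pathway_name = character(),
      genes = list()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf(
      "GMT line %d has fewer than 3 tab-separated fields", short[1]
    ))
  }
  db <- tibble(
    pathway_id = purrr::map_chr(fields, 1),
    pathway_name = purrr::map_chr(fields, 2),
    genes = purrr::map(fields, ~ unique(.x[-(1:2)][nzchar(.x[-(1:2)])]))
  )
  dup <- db$pathway_id[duplicated(db$pathway_id)]
  if (length(dup) > 0) {
    abort(sprintf(
      "duplicate gene-set id(s) in GMT: %s", paste(unique(dup), collapse = ", ")
    ))
  }
  if (any(lengths(db$genes) == 0)) {
    abort("GMT contains an empty gene set")
  }
  db
}

#' Write a GMT gene-set database
#'
#' @param db Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  lines <- purrr::pmap_chr(
    db[c("pathway_id", "pathway_name", "genes")],
    function(pathway_id, pathway_name, genes) {
      paste(c(pathway_id, pathway_name, genes), collapse = "\t")
    }
  )
  writeLines(lines, path)
  invisible(path)
}
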