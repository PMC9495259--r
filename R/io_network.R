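#' Export a pathway crosstalk network
#'
#' Writes the crosstalk edge list for external viewers such as Cytoscape.
#' Three formats are supported: `"sif"` (simple interaction format with the
#' relation tag `crosstalk`), `"graphml"` (via igraph, with `jc`, `oc`,
#' `score` and `shared_gene_count` edge attributes and a logical `snp_gene`
#' node attribute distinguishing pathways that contain variant-mapped
#' genes), and `"tsv"` (flat edge table).
#'
#' @param edges Crosstalk edge tibble from [build_crosstalk()].
#' @param path Output path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @param snp_pathways Optional character vector of pathway ids containing
#'   variant-mapped genes, used for the node attribute flag.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path,
                          format = c("tsv", "sif", "graphml"),
                          snp_pathways = character()) {
  format <- match.arg(format)
  if (nrow(edges) == 0) {
    warn("writing an empty crosstalk network")
  }
  if (format == "sif") {
    lines <- sprintf("%s\tcrosstalk\t%s", edges$pathway_a, edges$pathway_b)
    writeLines(lines, path)
  } else if (format == "tsv") {
    edges %>%
      mutate(
        shared_genes = purrr::map_chr(.data$shared_genes, paste, collapse = ";")
      ) %>%
      select(all_of(c("pathway_a", "pathway_b", "shared_genes",
                      "n_shared", "jc", "oc", "score"))) %>%
      readr::write_tsv(path, progress = FALSE)
  } else {
    nodes <- sort(unique(c(edges$pathway_a, edges$pathway_b)))
    g <- igraph::graph_from_data_frame(
      edges %>%
        transmute(
          from = .data$pathway_a, to = .data$pathway_b,
          jc = .data$jc, oc = .data$oc, score = .data$score,
          shared_gene_count = .data$n_shared
        ),
      directed = FALSE,
      vertices = tibble(name = nodes, snp_gene = nodes %in% snp_pathways)
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a crosstalk edge TSV written by [write_network()]
#'
#' @param path Path to the edge TSV.
#' @return Edge tibble with `shared_genes` restored as a list-column.
#' @export
read_network_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      pathway_a = readr::col_character(),
      pathway_b = readr::col_character(),
      shared_genes = readr::col_character(),
      n_shared = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  ) %>%
    mutate(shared_genes = strsplit(.data$shared_genes, ";", fixed = TRUE))
}
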