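# Jaccard and overlap coefficients between two gene lists.
set_coefficients <- function(a, b) {
  a <- unique(a); b <- unique(b)
  shared <- intersect(a, b)
  list(
    shared = sort(shared),
    jc = length(shared) / length(union(a, b)),
    oc = length(shared) / min(length(a), length(b))
  )
}

#' Pathways eligible for crosstalk analysis
#'
#' Keeps significantly enriched pathways (`p_bh < alpha`) that contain at
#' least `min_genes` candidate genes; pathways with fewer carry too little
#' information to anchor a crosstalk edge.
#'
#' @param enriched Enrichment tibble from [hypergeom_enrich()].
#' @param alpha Adjusted p-value threshold.
#' @param min_genes Minimum candidate-gene overlap per pathway.
#' @return The eligible subset.
#' @export
eligible_pathways <- function(enriched, alpha = 0.05, min_genes = 3) {
  enriched %>%
    filter(.data$p_bh < alpha, .data$k >= min_genes) %>%
    arrange(.data$p_bh, desc(.data$k), .data$pathway_id)
}

#' Build the pathway crosstalk network
#'
#' Scores every unordered pair of eligible pathways with the Jaccard
#' coefficient `JC = |A n B| / |A u B|` and the overlap coefficient
#' `OC = |A n B| / min(|A|, |B|)`, where `A` and `B` are the two pathways'
#' gene lists; the edge score is their average. Pairs sharing fewer than
#' `min_shared` genes are removed. By default the gene lists are each
#' pathway's candidate-gene overlap (the same genes the eligibility filter
#' counts); `gene_scope = "full_pathway"` instead uses the pathways' full
#' catalog membership, for which `gene_sets` must be supplied.
#'
#' @param eligible Eligible pathway tibble from [eligible_pathways()].
#' @param min_shared Minimum number of shared genes per retained edge.
#' @param gene_scope `"candidate_overlap"` (default) or `"full_pathway"`.
#' @param gene_sets Gene-set tibble (required for `"full_pathway"`).
#' @return An edge tibble sorted by descending score (ties: shared-gene
#'   count, then lexical pair id): `pathway_a`, `pathway_b`, `shared_genes`
#'   (list-column), `n_shared`, `jc`, `oc`, `score`.
#' @export
build_crosstalk <- function(eligible, min_shared = 2,
                            gene_scope = c("candidate_overlap", "full_pathway"),
                            gene_sets = NULL) {
  gene_scope <- match.arg(gene_scope)
  empty <- tibble(
    pathway_a = character(), pathway_b = character(),
    shared_genes = list(), n_shared = integer(),
    jc = double(), oc = double(), score = double()
  )
  if (nrow(eligible) < 2) {
    warn("fewer than 2 eligible pathways: empty crosstalk network")
    return(empty)
  }
  lists <- if (gene_scope == "candidate_overlap") {
    setNames(eligible$overlap, eligible$pathway_id)
  } else {
    if (is.null(gene_sets)) {
      abort("gene_sets is required when gene_scope = 'full_pathway'")
    }
    idx <- match(eligible$pathway_id, gene_sets$pathway_id)
    if (anyNA(idx)) abort("eligible pathway missing from gene_sets")
    setNames(gene_sets$genes[idx], eligible$pathway_id)
  }

  ids <- sort(names(lists))
  pairs <- combn(ids, 2)
  edges <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    co <- set_coefficients(lists[[a]], lists[[b]])
    tibble(
      pathway_a = a, pathway_b = b,
      shared_genes = list(co$shared),
      n_shared = length(co$shared),
      jc = co$jc, oc = co$oc, score = (co$jc + co$oc) / 2
    )
  }) %>% bind_rows()

  edges <- edges %>%
    filter(.data$n_shared >= min_shared) %>%
    arrange(desc(.data$score), desc(.data$n_shared),
            .data$pathway_a, .data$pathway_b)
  if (nrow(edges) == 0) empty else edges
}

#' Flag network pathways containing variant-mapped genes
#'
#' @param edges Crosstalk edge tibble.
#' @param snp_genes Character vector of variant-mapped gene symbols.
#' @param gene_sets Gene-set tibble giving full pathway membership.
#' @return Tibble `pathway_id`, `has_snp_gene` over the network's nodes.
#' @export
snp_pathway_flags <- function(edges, snp_genes, gene_sets) {
  nodes <- sort(unique(c(edges$pathway_a, edges$pathway_b)))
  idx <- match(nodes, gene_sets$pathway_id)
  tibble(
    pathway_id = nodes,
    has_snp_gene = purrr::map_lgl(
      gene_sets$genes[idx], ~ length(intersect(.x, snp_genes)) > 0
    )
  )
}

#' Triangulate variant, expression and crosstalk evidence
#'
#' Combines the three evidence channels into one ranked candidate report.
#' For every gene that survived the stage-2 variant filter or belongs to the
#' disease-related DEG set, three flags are evaluated: `snp_hit` (stage-2
#' survivor), `is_deg` (member of the DEG set) and `in_crosstalk` (member of
#' at least one pathway node of the crosstalk network, by full catalog
#' membership — variant genes are overlaid on the DEG-built network, not
#' used to build it). Genes are ranked by number of true flags, then
#' `snp_hit`, then `|log2fc|` in the RC-vs-RM comparison; tier-1 candidates
#' carry all three flags.
#'
#' @param snp_genes Character vector of stage-2 survivor genes
#'   (e.g. `variants_to_genes()$gene`).
#' @param deg_set DEG-set tibble from [rfsgs_deg_set()] (or a character
#'   vector of gene symbols).
#' @param edges Crosstalk edge tibble from [build_crosstalk()].
#' @param gene_sets Gene-set tibble giving full pathway membership.
#' @param de_rc_rm `de_test()` result for RC vs RM, used for the expression
#'   direction and ranking magnitude.
#' @param flat_band Flat band for [direction_check()].
#' @return A ranked tibble: `gene`, `snp_hit`, `is_deg`, `in_crosstalk`,
#'   `n_evidence`, `tier`, `direction`, `log2fc_rc_rm`, `pathways`
#'   (list-column of containing network pathways), `rank`.
#' @export
triangulate <- function(snp_genes, deg_set, edges, gene_sets, de_rc_rm,
                        flat_band = 0.1) {
  deg_genes <- if (is.data.frame(deg_set)) deg_set$gene else deg_set
  genes <- union(snp_genes, deg_genes)
  if (length(genes) == 0) {
    return(tibble(
      gene = character(), snp_hit = logical(), is_deg = logical(),
      in_crosstalk = logical(), n_evidence = integer(), tier = integer(),
      direction = character(), log2fc_rc_rm = double(),
      pathways = list(), rank = integer()
    ))
  }
  nodes <- unique(c(edges$pathway_a, edges$pathway_b))
  node_sets <- gene_sets[gene_sets$pathway_id %in% nodes, ]
  membership <- purrr::map(genes, function(g) {
    sort(node_sets$pathway_id[purrr::map_lgl(node_sets$genes, ~ g %in% .x)])
  })

  lfc <- de_rc_rm$log2fc[match(genes, de_rc_rm$gene)]
  known <- genes %in% de_rc_rm$gene
  direction <- rep(NA_character_, length(genes))
  if (any(known)) {
    direction[known] <- direction_check(genes[known], de_rc_rm, flat_band)
  }

  tibble(
    gene = genes,
    snp_hit = genes %in% snp_genes,
    is_deg = genes %in% deg_genes,
    in_crosstalk = lengths(membership) > 0,
    direction = direction,
    log2fc_rc_rm = lfc,
    pathways = membership
  ) %>%
    mutate(
      n_evidence = as.integer(.data$snp_hit) + as.integer(.data$is_deg) +
        as.integer(.data$in_crosstalk),
      tier = 4L - .data$n_evidence
    ) %>%
    arrange(desc(.data$n_evidence), desc(.data$snp_hit),
            desc(abs(tidyr::replace_na(.data$log2fc_rc_rm, 0))),
            .data$gene) %>%
    mutate(rank = row_number()) %>%
    select(all_of(c("gene", "snp_hit", "is_deg", "in_crosstalk",
                    "n_evidence", "tier", "direction", "log2fc_rc_rm",
                    "pathways", "rank")))
}
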