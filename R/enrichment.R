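#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` when drawing `n` genes without replacement from a universe of
#' `N` genes of which `K` belong to the pathway — the over-representation
#' p-value.
#'
#' @param k Observed overlap size.
#' @param K Pathway size within the universe.
#' @param n Candidate list size within the universe.
#' @param N Universe size.
#' @return The tail probability.
#' @export
phyper_tail <- function(k, K, n, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric gene-set over-representation
#'
#' Tests each gene set for over-representation of the candidate genes with a
#' one-sided hypergeometric test, followed by Benjamini-Hochberg correction
#' across the pathways actually tested (those with at least one overlapping
#' candidate, matching the behaviour of enrichment servers that only report
#' overlapping terms). Set members outside the universe are dropped with a
#' warning, as are candidates outside the universe. The universe should be
#' the measured genes (e.g. all genes in the expression matrix), not the
#' whole genome.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param gene_sets Gene-set tibble from [read_gmt()].
#' @param universe Character vector of all assayed gene symbols.
#' @return A tibble with one row per pathway with `k >= 1`: `pathway_id`,
#'   `pathway_name`, `overlap` (list-column of overlapping candidates), `k`,
#'   `K`, `n`, `N`, `p_raw`, `p_bh`.
#' @export
hypergeom_enrich <- function(candidates, gene_sets, universe) {
  if (length(universe) == 0) abort("universe must be non-empty")
  if (length(candidates) == 0) abort("candidate gene list must be non-empty")
  universe <- unique(universe)
  candidates <- unique(candidates)
  outside <- setdiff(candidates, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d candidate gene(s) outside the universe dropped",
                 length(outside)))
    candidates <- intersect(candidates, universe)
  }
  if (length(candidates) == 0) {
    abort("no candidate genes remain inside the universe")
  }

  members <- purrr::map(gene_sets$genes, intersect, universe)
  n_outside <- sum(lengths(gene_sets$genes) - lengths(members))
  if (n_outside > 0) {
    warn(sprintf("%d gene-set member(s) outside the universe dropped",
                 n_outside))
  }

  res <- gene_sets %>%
    mutate(
      overlap = purrr::map(members, ~ sort(intersect(.x, candidates))),
      k = lengths(.data$overlap),
      K = lengths(members),
      n = length(candidates),
      N = length(universe)
    ) %>%
    filter(.data$k >= 1) %>%
    mutate(p_raw = phyper_tail(.data$k, .data$K, .data$n, .data$N)) %>%
    select(all_of(c("pathway_id", "pathway_name", "overlap",
                    "k", "K", "n", "N", "p_raw")))
  res$p_bh <- bh_adjust(res$p_raw)
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  assert_probability(p, "p-values")
  p.adjust(p, method = "BH")
}

#' Significantly enriched pathways
#'
#' Filters to `p_bh < alpha` (strict inequality) and sorts ascending by
#' `p_bh`, breaking ties by larger overlap then pathway id, so output order
#' is byte-stable.
#'
#' @param enriched Enrichment tibble from [hypergeom_enrich()].
#' @param alpha Adjusted p-value threshold.
#' @return The significant subset, sorted.
#' @export
significant <- function(enriched, alpha = 0.05) {
  enriched %>%
    filter(.data$p_bh < alpha) %>%
    arrange(.data$p_bh, desc(.data$k), .data$pathway_id)
}
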