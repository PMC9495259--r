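#' Two-group differential expression from a TPM matrix
#'
#' Per gene, computes `log2fc = log2((mean TPM in a + c) / (mean TPM in b +
#' c))` with pseudo-count `c`, and a two-sided Welch t-test on `log2(TPM +
#' c)`. Welch's unequal-variance form is used because group sizes of three
#' give no power to verify variance homogeneity. Genes with zero variance in
#' both groups are untestable and get `p = 1`. A gene is called a DEG when
#' `p_value < p_threshold` and `|log2fc| > lfc_threshold`.
#'
#' @param expr Expression tibble: a `gene` column plus one TPM column per
#'   sample. Duplicate gene symbols are collapsed by summing with a warning.
#' @param manifest Sample manifest supplying group labels.
#' @param group_a,group_b Group labels to compare (log2fc is a over b).
#' @param p_threshold Raw p-value cutoff for the DEG call.
#' @param lfc_threshold Absolute log2 fold-change cutoff for the DEG call.
#' @param pseudo Pseudo-count added to TPM before ratios and logs.
#' @param adjust Use BH-adjusted p-values for the DEG call instead of raw.
#' @return A tibble with one row per gene: `gene`, `comparison`,
#'   `mean_tpm_a`, `mean_tpm_b`, `log2fc`, `t`, `df`, `p_value` and
#'   `is_deg`.
#' @export
de_test <- function(expr, manifest, group_a, group_b,
                    p_threshold = 0.05, lfc_threshold = 1,
                    pseudo = 1, adjust = FALSE) {
  manifest <- validate_manifest(manifest)
  mat <- expression_matrix(expr)
  a <- intersect(colnames(mat), group_samples(manifest, group_a))
  b <- intersect(colnames(mat), group_samples(manifest, group_b))
  if (length(a) < 2 || length(b) < 2) {
    abort(sprintf(
      "each group needs at least 2 samples (%s: %d, %s: %d)",
      group_a, length(a), group_b, length(b)
    ))
  }

  la <- log2(mat[, a, drop = FALSE] + pseudo)
  lb <- log2(mat[, b, drop = FALSE] + pseudo)
  na <- length(a); nb <- length(b)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, var); vb <- apply(lb, 1, var)

  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), NA_real_)
  df <- ifelse(
    se2 > 0,
    se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
    NA_real_
  )
  p <- ifelse(is.na(tstat), 1, 2 * pt(-abs(tstat), df))

  mean_a <- rowMeans(mat[, a, drop = FALSE])
  mean_b <- rowMeans(mat[, b, drop = FALSE])
  log2fc <- log2((mean_a + pseudo) / (mean_b + pseudo))

  p_call <- if (adjust) p.adjust(p, method = "BH") else p
  tibble(
    gene = rownames(mat),
    comparison = paste(group_a, "vs", group_b),
    mean_tpm_a = unname(mean_a),
    mean_tpm_b = unname(mean_b),
    log2fc = unname(log2fc),
    t = unname(tstat),
    df = unname(df),
    p_value = unname(p),
    is_deg = unname(p_call < p_threshold & abs(log2fc) > lfc_threshold)
  )
}

# gene-column tibble -> numeric matrix with gene rownames; duplicates
# collapsed by sum (TPM is additive across rows of the same symbol)
expression_matrix <- function(expr) {
  assert_cols(expr, "gene", "expression table")
  if (anyDuplicated(expr$gene) > 0) {
    warn("duplicate gene symbols collapsed by summing TPM")
    expr <- expr %>%
      group_by(.data$gene) %>%
      summarize(across(where(is.numeric), sum), .groups = "drop")
  }
  mat <- as.matrix(expr[setdiff(names(expr), "gene")])
  if (any(mat < 0)) abort("TPM values must be non-negative")
  rownames(mat) <- expr$gene
  mat
}

#' rFSGS-related DEG set by three-cohort set algebra
#'
#' Combines three pairwise comparisons into the disease-related gene set:
#' `DEG(RC, RM) union (DEG(RC, HC) minus DEG(RM, HC))` — genes different
#' between recurrence and remission, plus genes different between
#' recurrence and healthy controls unless they also differ between
#' remission and controls (those reflect transplantation or therapy, not
#' recurrence). Venn region cardinalities of the three DEG sets are
#' attached as the `"venn"` attribute.
#'
#' @param de_rc_rm,de_rc_hc,de_rm_hc `de_test()` results over the same gene
#'   universe for RC vs RM, RC vs HC and RM vs HC.
#' @return A tibble with one row per gene in the combined set: `gene`,
#'   membership flags `in_rc_rm`, `in_rc_hc`, `in_rm_hc`, and `log2fc_rc_rm`.
#' @export
rfsgs_deg_set <- function(de_rc_rm, de_rc_hc, de_rm_hc) {
  universes <- list(de_rc_rm$gene, de_rc_hc$gene, de_rm_hc$gene)
  if (!all(purrr::map_lgl(universes[-1], setequal, universes[[1]]))) {
    abort("the three comparisons must cover the same gene universe")
  }
  d1 <- de_rc_rm$gene[de_rc_rm$is_deg]
  d2 <- de_rc_hc$gene[de_rc_hc$is_deg]
  d3 <- de_rm_hc$gene[de_rm_hc$is_deg]
  genes <- union(d1, setdiff(d2, d3))
  out <- tibble(
    gene = genes,
    in_rc_rm = genes %in% d1,
    in_rc_hc = genes %in% d2,
    in_rm_hc = genes %in% d3
  ) %>%
    left_join(de_rc_rm[c("gene", "log2fc")], by = "gene") %>%
    rename(log2fc_rc_rm = "log2fc")
  attr(out, "venn") <- c(
    rc_rm = length(d1), rc_hc = length(d2), rm_hc = length(d3),
    rc_rm_and_rc_hc = length(intersect(d1, d2)),
    rc_rm_and_rm_hc = length(intersect(d1, d3)),
    rc_hc_and_rm_hc = length(intersect(d2, d3)),
    all_three = length(Reduce(intersect, list(d1, d2, d3))),
    rfsgs_related = length(genes)
  )
  out
}

#' Expression direction of a gene in recurrence vs remission
#'
#' Classifies the RC-over-RM log2 fold change as `down_in_rc`, `up_in_rc`,
#' or `flat` within a configurable band around zero.
#'
#' @param gene Gene symbol(s).
#' @param de_rc_rm `de_test()` result for RC vs RM.
#' @param flat_band Absolute log2fc below which the gene is called flat.
#' @return Character vector of direction calls, one per gene.
#' @export
direction_check <- function(gene, de_rc_rm, flat_band = 0.1) {
  idx <- match(gene, de_rc_rm$gene)
  if (anyNA(idx)) {
    abort(sprintf(
      "gene(s) not in DE results: %s",
      paste(gene[is.na(idx)], collapse = ", ")
    ))
  }
  lfc <- de_rc_rm$log2fc[idx]
  dplyr::case_when(
    abs(lfc) < flat_band ~ "flat",
    lfc < 0 ~ "down_in_rc",
    TRUE ~ "up_in_rc"
  )
}
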