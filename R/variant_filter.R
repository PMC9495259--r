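#' Keep nonsynonymous variants only
#'
#' Restricts an annotated variant table to exonic nonsynonymous SNVs:
#' synonymous and nonsense (stopgain/stoploss) calls are excluded, as are
#' records annotated with any other function class. Set `keep_nonsense =
#' TRUE` to retain stopgain/stoploss calls for a more conventional
#' pathogenicity screen.
#'
#' @param variants Annotated variant tibble from [read_variants()].
#' @param keep_nonsense Retain `stopgain`/`stoploss` classes as well.
#' @return The filtered tibble (possibly zero rows).
#' @export
filter_functional <- function(variants, keep_nonsense = FALSE) {
  keep <- "nonsynonymous_SNV"
  if (keep_nonsense) keep <- c(keep, "stopgain", "stoploss")
  filter(variants, .data$function_class %in% keep)
}

#' Summarize per-group variant presence
#'
#' A sample carries a variant when its genotype is `het` or `hom`. For each
#' variant the carrier counts in the recurrence (RC), remission (RM) and
#' healthy-control (HC) groups are tabulated, together with the per-group
#' zygosity pattern and the number of homozygous RC carriers (used by the
#' optional strict-homozygote filter mode).
#'
#' @param variants Annotated variant tibble; every genotype column must name
#'   a sample in the manifest.
#' @param manifest Sample manifest with groups `RC`, `RM`, `HC`.
#' @return A tibble with the variant annotation columns plus
#'   `n_rc_present`, `n_rm_present`, `n_hc_present`, `n_rc_hom` and
#'   `zygosity_pattern`.
#' @export
summarize_presence <- function(variants, manifest) {
  manifest <- validate_manifest(manifest, allowed_groups = c("RC", "RM", "HC"))
  samples <- sample_cols(variants)
  unknown <- setdiff(samples, manifest$sample_id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "genotype column(s) for sample(s) not in manifest: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  if (nrow(variants) == 0) {
    return(variants %>%
             select(all_of(VARIANT_META_COLS)) %>%
             mutate(n_rc_present = integer(), n_rm_present = integer(),
                    n_hc_present = integer(), n_rc_hom = integer(),
                    zygosity_pattern = character()))
  }
  long <- variants %>%
    tidyr::pivot_longer(all_of(samples),
                        names_to = "sample_id", values_to = "zygosity") %>%
    left_join(manifest[c("sample_id", "group")], by = "sample_id")

  patterns <- long %>%
    filter(.data$group %in% c("RC", "RM", "HC")) %>%
    arrange(.data$group, .data$sample_id) %>%
    group_by(.data$variant_id, .data$group) %>%
    summarize(pat = paste(.data$zygosity, collapse = ","), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "pat") %>%
    mutate(zygosity_pattern = sprintf("RC=%s|RM=%s|HC=%s",
                                      .data$RC, .data$RM, .data$HC)) %>%
    select(all_of(c("variant_id", "zygosity_pattern")))

  counts <- long %>%
    group_by(across(all_of(VARIANT_META_COLS))) %>%
    summarize(
      n_rc_present = sum(.data$group == "RC" & .data$zygosity != "absent"),
      n_rm_present = sum(.data$group == "RM" & .data$zygosity != "absent"),
      n_hc_present = sum(.data$group == "HC" & .data$zygosity != "absent"),
      n_rc_hom = sum(.data$group == "RC" & .data$zygosity == "hom"),
      .groups = "drop"
    )

  variants %>%
    select(all_of(VARIANT_META_COLS)) %>%
    left_join(counts, by = VARIANT_META_COLS) %>%
    left_join(patterns, by = "variant_id")
}

#' Stage-1 presence filter
#'
#' Keeps variants carried by at least `min_carriers` subjects of the chosen
#' case group (recurrence or remission) and absent from every healthy
#' control.
#'
#' @param presence Presence summary from [summarize_presence()].
#' @param group `"RC"` or `"RM"`.
#' @param min_carriers Minimum carrier count in the chosen group.
#' @return Filtered presence tibble.
#' @export
stage1_filter <- function(presence, group = c("RC", "RM"), min_carriers = 2) {
  group <- match.arg(group)
  n_grp <- if (group == "RC") presence$n_rc_present else presence$n_rm_present
  presence[n_grp >= min_carriers & presence$n_hc_present == 0, ]
}

#' Stage-2 recurrence-association filter
#'
#' Keeps variants present in every recurrence subject, in at most `max_rm`
#' remission subjects, and in no healthy control. The recurrence group size
#' is taken from the manifest rather than hard-coded. The rule is stated in
#' carrier (presence) terms; `require_hom = TRUE` additionally demands that
#' every recurrence carrier be homozygous.
#'
#' @param presence Presence summary from [summarize_presence()].
#' @param manifest Sample manifest (provides the RC group size).
#' @param max_rm Maximum allowed remission carriers.
#' @param require_hom Require homozygosity in all recurrence subjects.
#' @return Filtered presence tibble (the stage-2 survivors).
#' @export
stage2_filter <- function(presence, manifest, max_rm = 1, require_hom = FALSE) {
  manifest <- validate_manifest(manifest, allowed_groups = c("RC", "RM", "HC"))
  n_rc <- length(group_samples(manifest, "RC"))
  keep <- presence$n_rc_present == n_rc &
    presence$n_rm_present <= max_rm &
    presence$n_hc_present == 0
  if (require_hom) keep <- keep & presence$n_rc_hom == n_rc
  presence[keep, ]
}

#' Collapse surviving variants to unique genes
#'
#' Maps stage-2 survivors to their genes, keeping one row per gene in
#' first-occurrence genomic order (chromosome, then position) with
#' back-references to the supporting variants.
#'
#' @param survivors Presence tibble of surviving variants.
#' @return A tibble with `gene`, `n_variants`, `variant_ids`, `rsids` and
#'   `zygosity_patterns` (semicolon-joined back-references).
#' @export
variants_to_genes <- function(survivors) {
  if (nrow(survivors) == 0) {
    return(tibble(
      gene = character(), n_variants = integer(),
      variant_ids = character(), rsids = character(),
      zygosity_patterns = character()
    ))
  }
  survivors %>%
    arrange(.data$chrom, .data$pos) %>%
    group_by(.data$gene) %>%
    summarize(
      n_variants = n(),
      variant_ids = paste(.data$variant_id, collapse = ";"),
      rsids = paste(tidyr::replace_na(.data$rsid, "."), collapse = ";"),
      zygosity_patterns = paste(.data$zygosity_pattern, collapse = ";"),
      first_chrom = first(.data$chrom),
      first_pos = first(.data$pos),
      .groups = "drop"
    ) %>%
    arrange(.data$first_chrom, .data$first_pos) %>%
    select(-all_of(c("first_chrom", "first_pos")))
}
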