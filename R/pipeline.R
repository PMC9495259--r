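default_thresholds <- function() {
  list(
    de_p = 0.05, de_lfc = 1, de_pseudo = 1,
    enrich_alpha = 0.05, min_genes = 3, min_shared = 2,
    min_carriers = 2, max_rm = 1, flat_band = 0.1,
    prevalence_qc = 0.5, prevalence_test = 0.8, knn_k = 10,
    vip = 1, metabo_p = 0.05
  )
}

#' Run the full candidate-prioritization pipeline
#'
#' Orchestrates variants -> differential expression -> enrichment ->
#' crosstalk -> triangulation (and, when a metabolite table is configured,
#' the metabolomics cascade) and writes every artifact plus a
#' machine-readable run report. The configuration is a YAML file or an
#' equivalent list with either a `simulate:` block (`seed`, plus any
#' [sim_config()] override) or an `inputs:` block naming `vcf`,
#' `annotation`, `tpm`, `manifest`, `gmt` and optionally `metabolites` /
#' `metabo_manifest`; a `thresholds:` block may override any default
#' threshold, and `metabo_groups` names the two metabolomics condition
#' labels. Reruns with the same config and seed produce byte-identical
#' artifacts.
#'
#' @param config Path to a YAML config, or a list.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return The run report (a list), invisibly; written as `report.json`.
#' @export
run_all <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir %||%
    abort("an output directory is required (out_dir)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  log_lines <- character()

  # ---- inputs ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config, config$simulate)
    cohort <- simulate_cohort(cfg, dir = file.path(out_dir, "simulated"))
    inputs <- cohort$paths
    seed <- cfg$seed
  } else {
    inputs <- config$inputs
    needed <- c("vcf", "annotation", "tpm", "manifest", "gmt")
    missing_in <- needed[!purrr::map_lgl(inputs[needed],
                                         ~ !is.null(.x) && file.exists(.x))]
    if (length(missing_in) > 0) {
      abort(sprintf("missing input file(s): %s",
                    paste(missing_in, collapse = ", ")))
    }
    seed <- config$seed %||% NA
  }
  manifest <- read_manifest(inputs$manifest,
                            allowed_groups = c("RC", "RM", "HC"))
  gene_sets <- read_gmt(inputs$gmt)

  # ---- stage: variants ---------------------------------------------------
  stage <- function(expr, name) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  variants <- stage(read_variants(inputs$vcf, inputs$annotation), "variants")
  functional <- filter_functional(variants)
  presence <- summarize_presence(functional, manifest)
  s1_rc <- stage1_filter(presence, "RC", thr$min_carriers)
  s1_rm <- stage1_filter(presence, "RM", thr$min_carriers)
  survivors <- stage2_filter(presence, manifest, max_rm = thr$max_rm)
  snp_gene_tbl <- variants_to_genes(survivors)
  log_lines <- log_stage("variants/functional", nrow(variants),
                         nrow(functional), log_lines)
  log_lines <- log_stage("variants/stage1_rc", nrow(presence),
                         nrow(s1_rc), log_lines)
  log_lines <- log_stage("variants/stage2", nrow(presence),
                         nrow(survivors), log_lines)
  readr::write_tsv(
    survivors, file.path(out_dir, "stage2_survivors.tsv"), progress = FALSE
  )
  readr::write_tsv(
    snp_gene_tbl, file.path(out_dir, "snp_genes.tsv"), progress = FALSE
  )

  # ---- stage: differential expression ------------------------------------
  expr <- stage(readr::read_tsv(
    inputs$tpm,
    col_types = readr::cols(gene = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE
  ), "de")
  de <- purrr::map(
    list(rc_rm = c("RC", "RM"), rc_hc = c("RC", "HC"), rm_hc = c("RM", "HC")),
    ~ stage(de_test(expr, manifest, .x[1], .x[2],
                    p_threshold = thr$de_p, lfc_threshold = thr$de_lfc,
                    pseudo = thr$de_pseudo), "de")
  )
  deg_set <- rfsgs_deg_set(de$rc_rm, de$rc_hc, de$rm_hc)
  for (nm in names(de)) {
    readr::write_tsv(de[[nm]], file.path(out_dir, sprintf("de_%s.tsv", nm)),
                     progress = FALSE)
  }
  jsonlite::write_json(
    as.list(attr(deg_set, "venn")), file.path(out_dir, "venn.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  log_lines <- log_stage("de/rfsgs_deg_set", nrow(expr), nrow(deg_set),
                         log_lines)

  # ---- stage: enrichment + crosstalk -------------------------------------
  universe <- unique(expr$gene)
  if (nrow(deg_set) > 0) {
    enriched <- stage(
      hypergeom_enrich(deg_set$gene, gene_sets, universe), "enrich"
    )
    eligible <- eligible_pathways(enriched, thr$enrich_alpha, thr$min_genes)
    edges <- build_crosstalk(
      eligible, min_shared = thr$min_shared,
      gene_scope = config$gene_scope %||% "candidate_overlap",
      gene_sets = gene_sets
    )
  } else {
    warn("empty DEG set: enrichment and crosstalk skipped")
    enriched <- tibble(pathway_id = character(), pathway_name = character(),
                       overlap = list(), k = integer(), K = integer(),
                       n = integer(), N = integer(),
                       p_raw = double(), p_bh = double())
    eligible <- enriched
    edges <- build_crosstalk(eligible)
  }
  readr::write_tsv(
    enriched %>%
      mutate(overlap = purrr::map_chr(.data$overlap, paste, collapse = ";")),
    file.path(out_dir, "enrichment.tsv"), progress = FALSE
  )
  snp_flags <- snp_pathway_flags(edges, snp_gene_tbl$gene, gene_sets)
  write_network(edges, file.path(out_dir, "crosstalk.tsv"), "tsv")
  write_network(edges, file.path(out_dir, "crosstalk.sif"), "sif",
                snp_pathways = snp_flags$pathway_id[snp_flags$has_snp_gene])
  log_lines <- log_stage("enrich/eligible", nrow(enriched), nrow(eligible),
                         log_lines)
  log_lines <- log_stage("crosstalk/edges", nrow(eligible), nrow(edges),
                         log_lines)

  # ---- stage: triangulation ----------------------------------------------
  candidates <- triangulate(snp_gene_tbl$gene, deg_set, edges, gene_sets,
                            de$rc_rm, flat_band = thr$flat_band)
  readr::write_tsv(
    candidates %>%
      mutate(pathways = purrr::map_chr(.data$pathways, paste, collapse = ";")),
    file.path(out_dir, "candidates.tsv"), progress = FALSE
  )
  log_lines <- log_stage("triangulate/candidates", nrow(candidates),
                         sum(candidates$tier == 1), log_lines)

  # ---- stage: metabolomics (optional) ------------------------------------
  metabo_report <- NULL
  if (!is.null(inputs$metabolites)) {
    metabo_manifest <- read_manifest(inputs$metabo_manifest)
    groups <- unlist(config$metabo_groups %||% c("MUT", "WT"))
    features <- stage(read_metabolites(inputs$metabolites), "metabo")
    kept <- prevalence_filter(features, metabo_manifest,
                              thr$prevalence_qc, thr$prevalence_test)
    imputed <- knn_impute(kept, k = thr$knn_k)
    corrected <- qc_correct(imputed, metabo_manifest)
    results <- stage(
      plsda_vip(corrected, metabo_manifest, groups,
                vip_cut = thr$vip, p_cut = thr$metabo_p), "metabo"
    )
    readr::write_tsv(results, file.path(out_dir, "metabo_results.tsv"),
                     progress = FALSE)
    readr::write_tsv(attr(results, "fit")$scores,
                     file.path(out_dir, "plsda_scores.tsv"), progress = FALSE)
    ratio <- tryCatch(
      metabolite_ratio(corrected, metabo_manifest, groups),
      error = function(e) NULL
    )
    if (!is.null(ratio)) {
      readr::write_tsv(ratio, file.path(out_dir, "metabolite_ratio.tsv"),
                       progress = FALSE)
    }
    log_lines <- log_stage("metabo/prevalence", nrow(features), nrow(kept),
                           log_lines)
    log_lines <- log_stage("metabo/differential", nrow(results),
                           sum(results$is_differential), log_lines)
    metabo_report <- list(
      n_features = nrow(features), n_kept = nrow(kept),
      n_differential = sum(results$is_differential),
      malate_citrate_p = if (!is.null(ratio)) ratio$p_value else NA
    )
  }

  report <- list(
    seed = seed,
    thresholds = thr,
    stages = list(
      variants = list(
        n_input = nrow(variants), n_functional = nrow(functional),
        n_stage1_rc = nrow(s1_rc), n_stage1_rm = nrow(s1_rm),
        n_stage2 = nrow(survivors), n_snp_genes = nrow(snp_gene_tbl)
      ),
      de = as.list(attr(deg_set, "venn")),
      enrichment = list(
        n_tested = nrow(enriched),
        n_significant = sum(enriched$p_bh < thr$enrich_alpha),
        n_eligible = nrow(eligible)
      ),
      crosstalk = list(n_edges = nrow(edges),
                       n_nodes = length(unique(c(edges$pathway_a,
                                                 edges$pathway_b)))),
      candidates = list(n_total = nrow(candidates),
                        n_tier1 = sum(candidates$tier == 1)),
      metabolomics = metabo_report
    ),
    top_candidates = head(candidates, 10) %>%
      select(all_of(c("gene", "snp_hit", "is_deg", "in_crosstalk",
                      "tier", "direction"))) %>%
      purrr::transpose(),
    artifacts = as.list(list.files(out_dir, recursive = TRUE))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(report)
}
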