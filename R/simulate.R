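#' Synthetic cohort configuration
#'
#' Parameters of the synthetic multi-omics cohort generator. Defaults
#' emulate a 3+3+3 transplant cohort (recurrence / remission / healthy
#' control) profiled for exonic variants and TPM expression, plus a
#' two-condition LC-MS experiment (6 mutant-line vs 6 wild-type injections
#' with 4 pooled QCs). A causal gene is planted with the full evidence
#' pattern: a homozygous nonsynonymous variant in every recurrence subject
#' (absent from remission and controls), correlated under-expression in
#' recurrence, and membership in two overlapping pathways that pass
#' enrichment.
#'
#' @param n_rc,n_rm,n_hc Group sizes of the sequencing cohort.
#' @param n_genes Number of genes.
#' @param n_background_variants Background variants whose presence patterns
#'   are drawn uniformly over patterns that do not satisfy the stage-2 rule.
#' @param n_decoy_variants Decoy variants that pass the stage-1 filter but
#'   not stage-2 (two recurrence carriers, nobody else).
#' @param plant_causal_variant Plant the causal variant (disable for null
#'   cohorts).
#' @param n_pathways Number of gene sets.
#' @param pathway_size_range Integer pair: min/max genes per set.
#' @param pathway_overlap_fraction Fraction of each set shared with the
#'   previous set, creating crosstalk structure.
#' @param causal_gene_down_log2fc Planted log2 fold change of the causal
#'   gene in recurrence (negative = under-expressed).
#' @param de_fraction Fraction of genes differentially expressed in
#'   recurrence.
#' @param de_log2fc_range Magnitude range of planted DE log2 fold changes
#'   (signs alternate).
#' @param tpm_lognormal_mu,tpm_lognormal_sigma Natural-log mean / sd of the
#'   per-gene baseline TPM.
#' @param expr_noise_sd_log2 Per-sample replicate noise sd on the log2
#'   scale.
#' @param n_metabo_features Number of LC-MS features.
#' @param n_metabo_per_group Samples per metabolomics condition group.
#' @param n_qc Pooled QC injections.
#' @param metabo_missing_rate Missing-at-random rate applied to background
#'   features (planted and annotated features stay complete so the planted
#'   signal's composition is deterministic).
#' @param metabo_noise_sd_log2 Per-sample intensity noise sd (log2).
#' @param n_discriminant_metabolites Features shifted between the two
#'   conditions; includes the designated malate- and citrate-role features.
#' @param metabo_effect_sd Discriminant shift in units of the noise sd.
#' @param seed Integer RNG seed; identical seeds give identical cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_rc = 3, n_rm = 3, n_hc = 3,
                       n_genes = 500,
                       n_background_variants = 400,
                       n_decoy_variants = 3,
                       plant_causal_variant = TRUE,
                       n_pathways = 40,
                       pathway_size_range = c(10, 50),
                       pathway_overlap_fraction = 0.3,
                       causal_gene_down_log2fc = -1.5,
                       de_fraction = 0.1,
                       de_log2fc_range = c(1.5, 2.5),
                       tpm_lognormal_mu = 3,
                       tpm_lognormal_sigma = 1.2,
                       expr_noise_sd_log2 = 0.4,
                       n_metabo_features = 300,
                       n_metabo_per_group = 6,
                       n_qc = 4,
                       metabo_missing_rate = 0.15,
                       metabo_noise_sd_log2 = 0.5,
                       n_discriminant_metabolites = 10,
                       metabo_effect_sd = 2,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_rc, n_rm, n_hc, n_genes, n_pathways, n_metabo_features,
              n_metabo_per_group)
  if (any(counts < 1)) abort("all group/feature counts must be >= 1")
  if (n_pathways < 2) abort("planted crosstalk needs at least 2 pathways")
  if (pathway_overlap_fraction < 0 || pathway_overlap_fraction > 1 ||
      metabo_missing_rate < 0 || metabo_missing_rate > 1 ||
      de_fraction < 0 || de_fraction > 1) {
    abort("fractions must lie in [0, 1]")
  }
  if (pathway_size_range[2] > n_genes) {
    abort("pathway_size_range exceeds the number of genes")
  }
  structure(cfg, class = "sim_config")
}

#' Null cohort configuration
#'
#' Convenience wrapper: no planted variant, no expression perturbation, no
#' discriminant metabolites — for calibration checks.
#'
#' @param seed Integer RNG seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config` list.
#' @export
null_sim_config <- function(seed = 1, ...) {
  sim_config(
    plant_causal_variant = FALSE, de_fraction = 0,
    causal_gene_down_log2fc = 0, metabo_effect_sd = 0,
    seed = seed, ...
  )
}

#' Simulate a complete multi-omics cohort
#'
#' Generates the sample manifests, annotated variant table, TPM expression
#' matrix, pathway gene sets, and metabolite feature table described by a
#' [sim_config()], together with a truth record listing everything planted.
#' With `dir` set, all objects are additionally written in the exact
#' formats the package readers consume (VCF + annotation TSV, TPM TSV, GMT,
#' metabolite TSV, manifest TSVs, truth JSON).
#'
#' @param cfg A `sim_config` list.
#' @param dir Optional output directory (created if needed).
#' @return A list: `manifest`, `variants`, `expression`, `gene_sets`,
#'   `metabolites`, `metabo_manifest`, `truth`, and `paths` (when `dir`
#'   given).
#' @export
simulate_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  samples <- c(
    paste0("RC", seq_len(cfg$n_rc)),
    paste0("RM", seq_len(cfg$n_rm)),
    paste0("HC", seq_len(cfg$n_hc))
  )
  manifest <- tibble(
    sample_id = samples,
    group = rep(c("RC", "RM", "HC"), c(cfg$n_rc, cfg$n_rm, cfg$n_hc))
  )

  # -- planted genes -------------------------------------------------------
  causal_gene <- sample(genes, 1)
  n_de_other <- round(cfg$de_fraction * cfg$n_genes)
  de_other <- sample(setdiff(genes, causal_gene), n_de_other)
  de_lfc <- stats::setNames(
    runif(n_de_other, cfg$de_log2fc_range[1], cfg$de_log2fc_range[2]) *
      rep_len(c(1, -1), n_de_other),
    de_other
  )
  planted_lfc <- c(
    stats::setNames(cfg$causal_gene_down_log2fc, causal_gene), de_lfc
  )
  planted_lfc <- planted_lfc[planted_lfc != 0]

  # -- pathways ------------------------------------------------------------
  sizes <- sample(
    seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
    cfg$n_pathways, replace = TRUE
  )
  ids <- sprintf("P%03d", seq_len(cfg$n_pathways))
  sets <- vector("list", cfg$n_pathways)
  # two anchor pathways carry the causal gene plus overlapping planted DE
  # genes, guaranteeing crosstalk structure when a signal is planted
  anchor_a <- c(causal_gene, de_other[seq_len(min(9, length(de_other)))])
  extra_b <- de_other[seq(10, 13)[seq(10, 13) <= length(de_other)]]
  anchor_b <- c(causal_gene, de_other[seq_len(min(5, length(de_other)))], extra_b)
  for (i in seq_len(cfg$n_pathways)) {
    core <- if (i == 1) {
      anchor_a
    } else if (i == 2) {
      anchor_b
    } else {
      prev <- sets[[i - 1]]
      sample(prev, min(length(prev), round(cfg$pathway_overlap_fraction * sizes[i])))
    }
    core <- unique(core[core %in% genes])
    fill <- sample(setdiff(genes, core), max(0, sizes[i] - length(core)))
    sets[[i]] <- sort(unique(c(core, fill)))
  }
  gene_sets <- tibble(
    pathway_id = ids,
    pathway_name = paste0("pathway_", ids),
    genes = sets
  )

  # -- variants ------------------------------------------------------------
  variants <- simulate_variants(cfg, genes, causal_gene, manifest)

  # -- expression ----------------------------------------------------------
  mu <- rnorm(cfg$n_genes, cfg$tpm_lognormal_mu, cfg$tpm_lognormal_sigma)
  names(mu) <- genes
  # the causal gene sits at median abundance: a well-expressed metabolic
  # enzyme, and the planted fold change is not eroded by the pseudo-count
  mu[causal_gene] <- cfg$tpm_lognormal_mu
  shift <- matrix(0, cfg$n_genes, length(samples),
                  dimnames = list(genes, samples))
  rc_samples <- group_samples(manifest, "RC")
  if (length(planted_lfc) > 0) {
    shift[names(planted_lfc), rc_samples] <- planted_lfc
  }
  noise <- matrix(
    rnorm(cfg$n_genes * length(samples), 0, cfg$expr_noise_sd_log2),
    cfg$n_genes, length(samples)
  )
  tpm <- exp(mu) * 2^(shift + noise)
  expression <- as_tibble(tpm) %>% mutate(gene = genes, .before = 1)

  # -- metabolites ---------------------------------------------------------
  metabo <- simulate_metabolites(cfg)

  truth <- list(
    seed = cfg$seed,
    causal_gene = causal_gene,
    causal_variant_id = attr(variants, "causal_variant_id"),
    causal_rsid = attr(variants, "causal_rsid"),
    decoy_variant_ids = attr(variants, "decoy_variant_ids"),
    planted_de_genes = names(planted_lfc),
    planted_log2fc = as.list(planted_lfc),
    anchor_pathways = ids[1:2],
    discriminant_features = metabo$discriminant_features,
    annotated_features = metabo$annotated_features
  )

  out <- list(
    manifest = manifest,
    variants = variants,
    expression = expression,
    gene_sets = gene_sets,
    metabolites = metabo$features,
    metabo_manifest = metabo$manifest,
    truth = truth
  )
  if (!is.null(dir)) out$paths <- write_cohort(out, dir)
  out
}

# background patterns are rejection-sampled so that none satisfies the
# stage-2 rule (all RC, <=1 RM, 0 HC); decoys satisfy stage 1 only
simulate_variants <- function(cfg, genes, causal_gene, manifest) {
  samples <- manifest$sample_id
  n_causal <- as.integer(cfg$plant_causal_variant)
  n_total <- cfg$n_background_variants + cfg$n_decoy_variants + n_causal
  pos <- sort(sample(1e7, n_total))
  chrom <- as.character(sample(1:22, n_total, replace = TRUE))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- purrr::map_chr(ref, ~ sample(setdiff(bases, .x), 1))

  rc <- manifest$group == "RC"
  rm_ <- manifest$group == "RM"
  hc <- manifest$group == "HC"

  draw_background <- function() {
    repeat {
      present <- runif(length(samples)) < 0.25
      if (!any(present)) next
      zyg <- ifelse(present,
                    ifelse(runif(length(samples)) < 0.3, "hom", "het"),
                    "absent")
      carriers <- zyg != "absent"
      stage2 <- all(carriers[rc]) && sum(carriers[rm_]) <= 1 &&
        sum(carriers[hc]) == 0
      if (!stage2) return(zyg)
    }
  }
  draw_decoy <- function() {
    zyg <- rep("absent", length(samples))
    zyg[sample(which(rc), 2)] <- "het"
    zyg
  }

  geno <- vector("list", n_total)
  class_pool <- c("nonsynonymous_SNV", "synonymous_SNV", "stopgain", "other")
  fclass <- sample(class_pool, n_total, replace = TRUE,
                   prob = c(0.5, 0.3, 0.1, 0.1))
  gene_of <- sample(genes, n_total, replace = TRUE)
  rsid <- sprintf("rs%07d", sample(9999999, n_total))

  i_causal <- if (n_causal == 1) 1L else integer()
  i_decoy <- seq_len(cfg$n_decoy_variants) + n_causal
  for (i in seq_len(n_total)) {
    if (i %in% i_causal) {
      geno[[i]] <- ifelse(rc, "hom", "absent")
      fclass[i] <- "nonsynonymous_SNV"
      gene_of[i] <- causal_gene
    } else if (i %in% i_decoy) {
      geno[[i]] <- draw_decoy()
      fclass[i] <- "nonsynonymous_SNV"
      gene_of[i] <- sample(setdiff(genes, causal_gene), 1)
    } else {
      geno[[i]] <- draw_background()
    }
  }
  gmat <- do.call(rbind, geno)
  colnames(gmat) <- samples

  variants <- tibble(
    variant_id = variant_id(chrom, pos, ref, alt),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    rsid = rsid, gene = gene_of, function_class = fclass
  ) %>%
    bind_cols(as_tibble(gmat)) %>%
    arrange(.data$chrom, .data$pos)
  attr(variants, "causal_variant_id") <-
    if (n_causal == 1) variant_id(chrom[1], pos[1], ref[1], alt[1]) else NA
  attr(variants, "causal_rsid") <- if (n_causal == 1) rsid[1] else NA
  attr(variants, "decoy_variant_ids") <-
    variant_id(chrom[i_decoy], pos[i_decoy], ref[i_decoy], alt[i_decoy])
  variants
}

simulate_metabolites <- function(cfg) {
  n <- cfg$n_metabo_features
  mut <- paste0("MUT", seq_len(cfg$n_metabo_per_group))
  wt <- paste0("WT", seq_len(cfg$n_metabo_per_group))
  qc <- paste0("QC", seq_len(cfg$n_qc), recycle0 = TRUE)
  samples <- c(mut, wt, qc)
  n_test <- length(mut) + length(wt)
  # pooled QCs spread across the run, test samples randomized between them
  order_all <- numeric(length(samples))
  qc_slots <- round(seq(1, length(samples), length.out = length(qc)))
  order_all[match(qc, samples)] <- qc_slots
  order_all[match(c(mut, wt), samples)] <-
    sample(setdiff(seq_along(samples), qc_slots))
  metabo_manifest <- tibble(
    sample_id = samples,
    group = rep(c("MUT", "WT", "QC"), c(length(mut), length(wt), length(qc))),
    injection_order = as.integer(order_all)
  )

  feature_id <- sprintf("F%04d", seq_len(n))
  mz <- round(runif(n, 80, 1000), 4)
  rt <- round(runif(n, 30, 1200), 2)
  base <- rnorm(n, 17, 2)

  n_disc <- min(cfg$n_discriminant_metabolites, n)
  disc <- seq_len(n_disc)
  annotation <- rep(NA_character_, n)
  ann_map <- character()
  if (n_disc >= 2) {
    annotation[1] <- "malate"
    annotation[2] <- "citrate"
    ann_map <- c(malate = feature_id[1], citrate = feature_id[2])
  }
  if (n >= n_disc + 2) {
    annotation[n_disc + 1] <- "fumarate"
    annotation[n_disc + 2] <- "succinate"
    ann_map <- c(ann_map, fumarate = feature_id[n_disc + 1],
                 succinate = feature_id[n_disc + 2])
  }

  shift <- numeric(n)  # log2 shift in MUT relative to WT
  eff <- cfg$metabo_effect_sd * cfg$metabo_noise_sd_log2
  if (eff != 0 && n_disc > 0) {
    shift[disc] <- eff * rep_len(c(1, -1), n_disc)
    if (n_disc >= 2) {
      shift[1] <- eff   # malate up in mutant
      shift[2] <- -eff  # citrate down in mutant
    }
    if (n >= n_disc + 2) {
      shift[n_disc + 1] <- 0.3   # fumarate mildly up, not reliably called
      shift[n_disc + 2] <- -0.3  # succinate mildly down
    }
  }

  val <- matrix(0, n, length(samples), dimnames = list(feature_id, samples))
  for (s in seq_along(samples)) {
    is_qc <- samples[s] %in% qc
    is_mut <- samples[s] %in% mut
    noise_sd <- if (is_qc) 0.3 * cfg$metabo_noise_sd_log2 else cfg$metabo_noise_sd_log2
    centre <- base + if (is_qc) shift / 2 else if (is_mut) shift else 0
    val[, s] <- 2^(centre + rnorm(n, 0, noise_sd))
  }

  # missing-at-random masking on background features only; planted and
  # annotated features stay complete by design
  background <- setdiff(seq_len(n), c(disc, which(!is.na(annotation))))
  if (cfg$metabo_missing_rate > 0 && length(background) > 0) {
    for (i in background) {
      mask <- runif(length(samples)) < cfg$metabo_missing_rate
      if (all(mask)) mask[sample(length(samples), 1)] <- FALSE
      val[i, mask] <- NA
    }
  }

  features <- tibble(
    feature_id = feature_id, mz = mz, rt = rt, annotation = annotation
  ) %>% bind_cols(as_tibble(val))

  list(
    features = features,
    manifest = metabo_manifest,
    discriminant_features = feature_id[disc],
    annotated_features = as.list(ann_map)
  )
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the formats the package readers consume.
#'
#' @param cohort List returned by [simulate_cohort()].
#' @param dir Output directory.
#' @return Named list of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    manifest = file.path(dir, "manifest.tsv"),
    vcf = file.path(dir, "variants.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    tpm = file.path(dir, "tpm.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    metabolites = file.path(dir, "metabolites.tsv"),
    metabo_manifest = file.path(dir, "metabo_manifest.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_manifest(cohort$manifest, paths$manifest)
  write_variants(cohort$variants, paths$vcf, paths$annotation)
  readr::write_tsv(cohort$expression, paths$tpm, progress = FALSE)
  write_gmt(cohort$gene_sets, paths$gmt)
  write_metabolites(cohort$metabolites, paths$metabolites)
  write_manifest(cohort$metabo_manifest, paths$metabo_manifest)
  jsonlite::write_json(cohort$truth, paths$truth, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths
}
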