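#' Build the packaged hand-readable fixture cohort
#'
#' A deliberately tiny cohort — 9 samples, 20 genes, 10 variants, 4
#' pathways — whose expected output at every stage can be computed by hand:
#' exactly one variant (in gene `G01`) survives the stage-2 presence
#' filter; genes `G01`, `G11`, `G12`, `G13` carry planted expression shifts
#' in the recurrence group; pathways `PWA` and `PWB` are the only
#' enrichment-eligible sets and form the single crosstalk edge with
#' JC = 2/4 and OC = 2/3. The variant table also plants one stage-1-only
#' decoy, a synonymous and a stopgain variant (removed by the functional
#' filter), a healthy-control carrier, and assorted background patterns.
#'
#' The bundle is regenerated bit-identically from seed 42; the copy under
#' `inst/extdata/fixture/` was written by this function.
#'
#' @param dir Optional directory to write the fixture files into
#'   (`manifest.tsv`, `variants.vcf`, `annotation.tsv`, `tpm.tsv`,
#'   `pathways.gmt`, `truth.json`).
#' @return A list with `manifest`, `variants`, `expression`, `gene_sets`,
#'   `truth` (and `paths` when `dir` is given).
#' @export
make_fixture <- function(dir = NULL) {
  set.seed(42)
  samples <- c(paste0("RC", 1:3), paste0("RM", 1:3), paste0("HC", 1:3))
  manifest <- tibble(
    sample_id = samples,
    group = rep(c("RC", "RM", "HC"), each = 3)
  )
  genes <- sprintf("G%02d", 1:20)

  A <- "absent"; H <- "het"; O <- "hom"
  zyg <- rbind(
    c(O, O, O, A, A, A, A, A, A),  # causal: hom in all RC
    c(H, H, A, A, A, A, A, A, A),  # decoy: stage 1 only
    c(H, H, H, H, H, A, A, A, A),  # (3,2,0): too many RM carriers
    c(O, O, O, A, A, A, A, A, A),  # synonymous: functional filter
    c(H, H, H, H, A, A, A, A, A),  # stopgain: functional filter
    c(O, O, O, A, A, A, H, A, A),  # (3,0,1): HC carrier
    c(H, A, A, H, A, A, A, A, A),  # (1,1,0)
    c(A, A, A, H, H, H, A, A, A),  # (0,3,0): stage 1 for RM only
    c(O, O, O, A, A, A, A, A, A),  # 'other' class: functional filter
    c(H, A, A, A, A, A, O, O, A)   # (1,0,2)
  )
  colnames(zyg) <- samples
  variants <- tibble(
    chrom = as.character(1:10),
    pos = 1000L + 1:10,
    ref = c("C", "G", "A", "C", "T", "G", "A", "C", "G", "T"),
    alt = c("T", "A", "G", "G", "C", "T", "T", "A", "C", "G"),
    rsid = sprintf("rs10000%02d", 1:10),
    gene = sprintf("G%02d", 1:10),
    function_class = c(
      "nonsynonymous_SNV", "nonsynonymous_SNV", "nonsynonymous_SNV",
      "synonymous_SNV", "stopgain", "nonsynonymous_SNV",
      "nonsynonymous_SNV", "nonsynonymous_SNV", "other",
      "nonsynonymous_SNV"
    )
  ) %>%
    mutate(variant_id = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt),
           .before = 1) %>%
    bind_cols(as_tibble(zyg))

  base_log2 <- rep(c(5, 6, 7, 4, 8), 4)
  planted <- c(G01 = -2, G11 = 2.5, G12 = -2.2, G13 = 1.8)
  shift <- matrix(0, 20, 9, dimnames = list(genes, samples))
  shift[names(planted), paste0("RC", 1:3)] <- planted
  noise <- matrix(round(rnorm(180, 0, 0.25), 3), 20, 9)
  tpm <- round(2^(base_log2 + shift + noise), 3)
  expression <- as_tibble(tpm) %>% mutate(gene = genes, .before = 1)

  gene_sets <- tibble(
    pathway_id = c("PWA", "PWB", "PWC", "PWD"),
    pathway_name = c("anchor_a", "anchor_b", "background_1", "background_2"),
    genes = list(
      c("G01", "G11", "G12", "G14", "G15"),
      c("G01", "G12", "G13", "G16", "G17"),
      c("G05", "G06", "G07", "G08"),
      c("G10", "G18", "G19", "G20")
    )
  )

  truth <- list(
    seed = 42,
    causal_gene = "G01",
    causal_variant_id = "1:1001:C:T",
    causal_rsid = "rs1000001",
    decoy_variant_ids = "2:1002:G:A",
    planted_de_genes = names(planted),
    planted_log2fc = as.list(planted),
    anchor_pathways = c("PWA", "PWB"),
    expected_edge = list(
      pathway_a = "PWA", pathway_b = "PWB",
      shared_genes = c("G01", "G12"), jc = 0.5, oc = 2 / 3
    )
  )

  out <- list(
    manifest = manifest, variants = variants, expression = expression,
    gene_sets = gene_sets, truth = truth
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      manifest = file.path(dir, "manifest.tsv"),
      vcf = file.path(dir, "variants.vcf"),
      annotation = file.path(dir, "annotation.tsv"),
      tpm = file.path(dir, "tpm.tsv"),
      gmt = file.path(dir, "pathways.gmt"),
      truth = file.path(dir, "truth.json")
    )
    write_manifest(manifest, paths$manifest)
    write_variants(variants, paths$vcf, paths$annotation)
    readr::write_tsv(expression, paths$tpm, progress = FALSE)
    write_gmt(gene_sets, paths$gmt)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Path to the packaged fixture directory
#'
#' @return The installed `extdata/fixture` directory.
#' @export
fixture_dir <- function() {
  system.file("extdata", "fixture", package = "fsgsomics", mustWork = TRUE)
}
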