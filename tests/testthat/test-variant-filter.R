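test_that("functional filter keeps nonsynonymous SNVs only", {
  v <- dplyr::bind_rows(
    toy_variant("G1", "synonymous_SNV", toy_pattern(3, 0, 0), pos = 1),
    toy_variant("G2", "stopgain", toy_pattern(3, 0, 0), pos = 2),
    toy_variant("G3", "stoploss", toy_pattern(3, 0, 0), pos = 3),
    toy_variant("G4", "other", toy_pattern(3, 0, 0), pos = 4),
    toy_variant("G5", "nonsynonymous_SNV", toy_pattern(3, 0, 0), pos = 5)
  )
  expect_equal(filter_functional(v)$gene, "G5")
  expect_setequal(filter_functional(v, keep_nonsense = TRUE)$gene,
                  c("G2", "G3", "G5"))
})

test_that("presence summaries count carriers per group", {
  m <- toy_manifest()
  v <- dplyr::bind_rows(
    toy_variant("G1", "nonsynonymous_SNV",
                c("hom", "hom", "hom", rep("absent", 6)), pos = 1),
    toy_variant("G2", "nonsynonymous_SNV",
                c("het", rep("absent", 2), "het", rep("absent", 5)), pos = 2),
    toy_variant("G3", "nonsynonymous_SNV", rep("absent", 9), pos = 3)
  )
  p <- summarize_presence(v, m)
  expect_equal(p$n_rc_present, c(3, 1, 0))
  expect_equal(p$n_rm_present, c(0, 1, 0))
  expect_equal(p$n_hc_present, c(0, 0, 0))
  expect_equal(p$n_rc_hom, c(3, 0, 0))
  expect_match(p$zygosity_pattern[1], "RC=hom,hom,hom")

  v_bad <- v %>% dplyr::rename(ZZ9 = "HC3")
  expect_error(summarize_presence(v_bad, m), "ZZ9")
})

test_that("stage filters implement the two presence rules", {
  m <- toy_manifest()
  mk <- function(gene, rc, rm, hc, pos) {
    toy_variant(gene, "nonsynonymous_SNV", toy_pattern(rc, rm, hc), pos = pos)
  }
  v <- dplyr::bind_rows(
    mk("A", 2, 1, 0, 1),  # stage1 RC keeps
    mk("B", 3, 0, 1, 2),  # HC carrier: both stages remove
    mk("C", 1, 3, 0, 3),  # stage1 RM only
    mk("D", 3, 1, 0, 4),  # stage2 keeps
    mk("E", 3, 2, 0, 5),  # stage2 removes (RM > 1)
    mk("F", 3, 0, 0, 6)   # stage2 keeps
  )
  p <- summarize_presence(v, m)
  expect_setequal(stage1_filter(p, "RC")$gene, c("A", "D", "E", "F"))
  expect_setequal(stage1_filter(p, "RM")$gene, c("C", "E"))
  expect_setequal(stage2_filter(p, m)$gene, c("D", "F"))

  # strict homozygote mode: only fully hom RC carriers survive
  v2 <- dplyr::bind_rows(
    toy_variant("H", "nonsynonymous_SNV", toy_pattern(3, 0, 0, "hom"), pos = 7),
    mk("I", 3, 0, 0, 8)
  )
  p2 <- summarize_presence(v2, m)
  expect_equal(stage2_filter(p2, m, require_hom = TRUE)$gene, "H")
})

test_that("stage2 is a subset of stage1(RC) and filters are idempotent", {
  m <- toy_manifest()
  set.seed(7)
  v <- purrr::map(1:60, function(i) {
    toy_variant(sprintf("G%02d", sample(30, 1)), "nonsynonymous_SNV",
                sample(c("absent", "het", "hom"), 9, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15)),
                chrom = as.character(sample(5, 1)), pos = i)
  }) %>% dplyr::bind_rows()
  p <- summarize_presence(v, m)
  s1 <- stage1_filter(p, "RC")
  s2 <- stage2_filter(p, m)
  expect_true(all(s2$variant_id %in% s1$variant_id))
  expect_equal(stage2_filter(s2, m), s2)
  expect_equal(stage1_filter(s1, "RC"), s1)
  # permutation invariance of the row set
  perm <- p[sample(nrow(p)), ]
  expect_setequal(stage2_filter(perm, m)$variant_id, s2$variant_id)
})

test_that("survivors collapse to unique genes in genomic order", {
  m <- toy_manifest()
  v <- dplyr::bind_rows(
    toy_variant("G1", "nonsynonymous_SNV", toy_pattern(3, 0, 0),
                chrom = "2", pos = 10),
    toy_variant("G1", "nonsynonymous_SNV", toy_pattern(3, 1, 0),
                chrom = "2", pos = 30),
    toy_variant("G2", "nonsynonymous_SNV", toy_pattern(3, 0, 0),
                chrom = "2", pos = 20)
  )
  g <- variants_to_genes(summarize_presence(v, m))
  expect_equal(g$gene, c("G1", "G2"))
  expect_equal(g$n_variants, c(2L, 1L))
  expect_equal(g$variant_ids[1], "2:10:A:T;2:30:A:T")
  expect_equal(nrow(variants_to_genes(summarize_presence(v, m)[0, ])), 0)
})

test_that("a 32-variant table over 29 genes collapses to 29 unique genes", {
  m <- toy_manifest()
  genes <- c(sprintf("G%02d", 1:29), "G01", "G02", "G03")
  v <- purrr::imap(genes, function(g, i) {
    toy_variant(g, "nonsynonymous_SNV", toy_pattern(3, 0, 0),
                chrom = "1", pos = i)
  }) %>% dplyr::bind_rows()
  surv <- stage2_filter(summarize_presence(v, m), m)
  expect_equal(nrow(surv), 32)
  expect_equal(nrow(variants_to_genes(surv)), 29)
})
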