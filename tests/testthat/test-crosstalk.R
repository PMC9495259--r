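toy_enriched <- function(...) {
  rows <- list(...)
  ov <- purrr::map(rows, 2)
  tibble::tibble(
    pathway_id = purrr::map_chr(rows, 1),
    pathway_name = purrr::map_chr(rows, 1),
    overlap = ov,
    k = lengths(ov),
    K = 10L, n = 5L, N = 100L,
    p_raw = purrr::map_dbl(rows, 3),
    p_bh = purrr::map_dbl(rows, 3)
  )
}

test_that("eligibility needs significance and three candidate genes", {
  enr <- toy_enriched(
    list("P1", c("a", "b", "c"), 0.01),
    list("P2", c("a", "b"), 0.01),
    list("P3", letters[1:10], 0.2)
  )
  expect_equal(eligible_pathways(enr)$pathway_id, "P1")
})

test_that("JC/OC edge scoring follows the set formulas", {
  enr <- toy_enriched(
    list("P1", c("g1", "g2", "g3"), 0.01),
    list("P2", c("g2", "g3", "g4"), 0.01),
    list("P3", c("g1", "g2", "g3"), 0.01),
    list("P4", c("g7", "g8", "g9"), 0.01)
  )
  edges <- build_crosstalk(eligible_pathways(enr))
  e12 <- edges[edges$pathway_a == "P1" & edges$pathway_b == "P2", ]
  expect_equal(e12$jc, 0.5)
  expect_equal(e12$oc, 2 / 3, tolerance = 1e-12)
  expect_equal(e12$score, (0.5 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(e12$shared_genes[[1]], c("g2", "g3"))
  # identical gene lists: jc = oc = score = 1 and it sorts first
  e13 <- edges[edges$pathway_a == "P1" & edges$pathway_b == "P3", ]
  expect_equal(c(e13$jc, e13$oc, e13$score), c(1, 1, 1))
  expect_equal(edges$pathway_a[1], "P1")
  expect_equal(edges$pathway_b[1], "P3")
  # P4 shares nothing: appears in no edge
  expect_false("P4" %in% c(edges$pathway_a, edges$pathway_b))
  # pairs sharing a single gene are dropped
  enr2 <- toy_enriched(
    list("P1", c("g1", "g2", "x1"), 0.01),
    list("P2", c("g2", "g5", "x2"), 0.01)
  )
  expect_equal(nrow(build_crosstalk(eligible_pathways(enr2))), 0)
})

test_that("edge set is independent of pathway input order", {
  enr <- toy_enriched(
    list("P1", c("a", "b", "c", "d"), 0.01),
    list("P2", c("b", "c", "d", "e"), 0.02),
    list("P3", c("a", "c", "e", "f"), 0.03)
  )
  e1 <- build_crosstalk(eligible_pathways(enr))
  e2 <- build_crosstalk(eligible_pathways(enr[c(3, 1, 2), ]))
  expect_equal(e1, e2)
})

test_that("jc <= oc on random set pairs, both 1 iff equal sets", {
  set.seed(9)
  pool <- sprintf("g%03d", 1:60)
  for (i in 1:200) {
    a <- sample(pool, sample(3:30, 1))
    b <- sample(pool, sample(3:30, 1))
    enr <- toy_enriched(list("PA", a, 0.01), list("PB", b, 0.01))
    edges <- build_crosstalk(eligible_pathways(enr), min_shared = 0)
    if (nrow(edges) == 0) next
    expect_lte(edges$jc, edges$oc + 1e-15)
    if (edges$jc == 1) expect_setequal(a, b)
  }
})

test_that("full_pathway scope uses catalog membership", {
  enr <- toy_enriched(
    list("P1", c("a", "b", "c"), 0.01),
    list("P2", c("a", "b", "d"), 0.01)
  )
  db <- tibble::tibble(
    pathway_id = c("P1", "P2"), pathway_name = c("P1", "P2"),
    genes = list(c("a", "b", "c", "z1", "z2", "z3"),
                 c("a", "b", "d", "z1", "z2", "z9"))
  )
  cand <- build_crosstalk(eligible_pathways(enr))
  full <- build_crosstalk(eligible_pathways(enr), gene_scope = "full_pathway",
                          gene_sets = db)
  expect_equal(cand$jc, 2 / 4)
  expect_equal(full$jc, 4 / 8)  # a, b, z1, z2 shared among 8 total
  expect_equal(full$n_shared, 4L)
  expect_error(
    build_crosstalk(eligible_pathways(enr), gene_scope = "full_pathway"),
    "gene_sets"
  )
  expect_warning(build_crosstalk(enr[0, ]), "fewer than 2")
})

test_that("triangulation ranks the full-evidence gene first", {
  db <- tibble::tibble(
    pathway_id = c("P1", "P2"), pathway_name = c("P1", "P2"),
    genes = list(c("MDH2like", "NOS2like", "d1", "d2"),
                 c("MDH2like", "d1", "d3"))
  )
  edges <- tibble::tibble(
    pathway_a = "P1", pathway_b = "P2",
    shared_genes = list(c("MDH2like", "d1")), n_shared = 2L,
    jc = 0.4, oc = 0.5, score = 0.45
  )
  de <- tibble::tibble(
    gene = c("MDH2like", "NOS2like", "d1", "d2", "d3", "d4"),
    comparison = "RC vs RM",
    log2fc = c(-1.5, -0.05, 2, 1.2, -1.1, 3),
    p_value = 0.01, is_deg = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
  cand <- triangulate(
    snp_genes = c("MDH2like", "NOS2like"),
    deg_set = c("d1", "d2", "d3", "d4", "MDH2like"),
    edges = edges, gene_sets = db, de_rc_rm = de
  )
  # the MDH2 pattern: variant + DEG + crosstalk = unique tier 1
  expect_equal(cand$gene[cand$tier == 1], "MDH2like")
  expect_equal(cand$direction[cand$gene == "MDH2like"], "down_in_rc")
  # the NOS2 pattern: variant + crosstalk but no DEG ranks below tier 1
  nos <- cand[cand$gene == "NOS2like", ]
  expect_true(nos$snp_hit && nos$in_crosstalk && !nos$is_deg)
  expect_equal(nos$tier, 2L)
  expect_equal(nos$rank, 2L)  # snp_hit breaks the tie with d1
  # d4 is a DEG in no network pathway
  expect_equal(cand$tier[cand$gene == "d4"], 3L)
  expect_equal(cand$pathways[cand$gene == "MDH2like"][[1]], c("P1", "P2"))

  expect_equal(nrow(triangulate(character(), character(), edges, db, de)), 0)
})

test_that("network pathways containing variant genes are flagged", {
  db <- tibble::tibble(
    pathway_id = c("P1", "P2"), pathway_name = c("P1", "P2"),
    genes = list(c("s1", "x"), c("y", "z"))
  )
  edges <- tibble::tibble(
    pathway_a = "P1", pathway_b = "P2", shared_genes = list("x"),
    n_shared = 1L, jc = 0.1, oc = 0.2, score = 0.15
  )
  flags <- snp_pathway_flags(edges, "s1", db)
  expect_equal(flags$has_snp_gene, c(TRUE, FALSE))
})
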