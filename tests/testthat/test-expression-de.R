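de_toy_expr <- function(mat) {
  tibble::as_tibble(mat) %>%
    dplyr::mutate(gene = sprintf("g%02d", seq_len(nrow(mat))), .before = 1)
}

test_that("de_test matches the per-gene Welch t-test oracle", {
  m <- toy_manifest()
  set.seed(11)
  mat <- matrix(2^rnorm(40 * 9, 5, 1), 40,
                dimnames = list(NULL, m$sample_id))
  expr <- de_toy_expr(mat)
  de <- de_test(expr, m, "RC", "RM")
  for (i in c(1, 7, 23, 40)) {
    x <- log2(mat[i, 1:3] + 1)
    y <- log2(mat[i, 4:6] + 1)
    ref <- stats::t.test(x, y)
    expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-12)
    expect_equal(de$log2fc[i],
                 log2((mean(mat[i, 1:3]) + 1) / (mean(mat[i, 4:6]) + 1)),
                 tolerance = 1e-12)
  }
})

test_that("clearly separated groups are called DEGs, flat genes are not", {
  m <- toy_manifest()
  mat <- rbind(
    c(2^c(3.9, 4.0, 4.1) - 1, 2^c(5.9, 6.0, 6.1) - 1, rep(10, 3)),
    rep(c(5, 5, 5), 3),
    rep(0, 9)
  )
  colnames(mat) <- m$sample_id
  de <- de_test(de_toy_expr(mat), m, "RC", "RM")
  # hand-checked: log2 means differ by 2, pooled sd 0.1
  expect_lt(de$p_value[1], 0.001)
  expect_equal(de$log2fc[1], log2((mean(2^c(3.9, 4, 4.1) - 1) + 1) /
                                    (mean(2^c(5.9, 6, 6.1) - 1) + 1)))
  expect_lt(abs(de$log2fc[1] + 2), 0.01)
  expect_true(de$is_deg[1])
  # identical vectors in both groups
  expect_equal(de$log2fc[2], 0)
  expect_equal(de$p_value[2], 1)
  expect_false(de$is_deg[2])
  # all-zero gene: pseudo-count makes the ratio exactly 1
  expect_equal(de$log2fc[3], 0)
  expect_equal(de$p_value[3], 1)
})

test_that("group order antisymmetry and small-group errors hold", {
  m <- toy_manifest()
  set.seed(3)
  mat <- matrix(2^rnorm(20 * 9, 5, 1), 20, dimnames = list(NULL, m$sample_id))
  expr <- de_toy_expr(mat)
  ab <- de_test(expr, m, "RC", "RM")
  ba <- de_test(expr, m, "RM", "RC")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(de_test(expr, m[-(1:2), ], "RC", "RM"), "at least 2")
})

test_that("DEG count is monotone in both thresholds", {
  m <- toy_manifest()
  set.seed(5)
  mat <- matrix(2^rnorm(100 * 9, 5, 1.5), 100,
                dimnames = list(NULL, m$sample_id))
  mat[1:10, 1:3] <- mat[1:10, 1:3] * 2^2
  expr <- de_toy_expr(mat)
  counts_fc <- purrr::map_int(
    c(0, 0.5, 1, 1.5, 2),
    ~ sum(de_test(expr, m, "RC", "RM", lfc_threshold = .x)$is_deg)
  )
  expect_true(all(diff(counts_fc) <= 0))
  counts_p <- purrr::map_int(
    c(0.1, 0.05, 0.01, 0.001),
    ~ sum(de_test(expr, m, "RC", "RM", p_threshold = .x)$is_deg)
  )
  expect_true(all(diff(counts_p) <= 0))
})

test_that("duplicate gene symbols are collapsed by summing", {
  m <- toy_manifest()
  mat <- matrix(1, 2, 9, dimnames = list(NULL, m$sample_id))
  expr <- de_toy_expr(mat) %>% dplyr::mutate(gene = c("gX", "gX"))
  expect_warning(de <- de_test(expr, m, "RC", "RM"), "duplicate")
  expect_equal(nrow(de), 1)
  expect_equal(de$mean_tpm_a, 2)
})

test_that("the three-comparison set algebra follows the union/exclusion rule", {
  fake_de <- function(degs, universe = LETTERS[1:6]) {
    tibble::tibble(
      gene = universe, comparison = "x vs y",
      log2fc = ifelse(universe %in% degs, -1.5, 0),
      p_value = ifelse(universe %in% degs, 0.001, 0.9),
      is_deg = universe %in% degs
    )
  }
  out <- rfsgs_deg_set(fake_de(c("A", "B")), fake_de(c("B", "C", "D")),
                       fake_de("D"))
  expect_setequal(out$gene, c("A", "B", "C"))
  venn <- attr(out, "venn")
  expect_equal(unname(venn["rfsgs_related"]), 3)
  expect_equal(unname(venn["rc_hc_and_rm_hc"]), 1)

  expect_equal(nrow(rfsgs_deg_set(fake_de(character()), fake_de(character()),
                                  fake_de(character()))), 0)
  # identical RC/HC and RM/HC sets cancel
  same <- rfsgs_deg_set(fake_de(c("A", "B")), fake_de(c("C", "D")),
                        fake_de(c("C", "D")))
  expect_setequal(same$gene, c("A", "B"))
  expect_error(
    rfsgs_deg_set(fake_de("A"), fake_de("A", universe = LETTERS[1:5]),
                  fake_de("A")),
    "universe"
  )
})

test_that("direction calls respect the flat band", {
  de <- tibble::tibble(
    gene = c("down", "flat", "up"), comparison = "RC vs RM",
    log2fc = c(-1.5, 0.05, 2), p_value = 0.01, is_deg = TRUE
  )
  expect_equal(direction_check(c("down", "flat", "up"), de),
               c("down_in_rc", "flat", "up_in_rc"))
  expect_error(direction_check("missing", de), "missing")
})
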