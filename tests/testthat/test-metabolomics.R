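metabo_toy_manifest <- function(n_a = 5, n_b = 5, n_qc = 4) {
  tibble::tibble(
    sample_id = c(paste0("A", seq_len(n_a)), paste0("B", seq_len(n_b)),
                  paste0("QC", seq_len(n_qc), recycle0 = TRUE)),
    group = rep(c("MUT", "WT", "QC"), c(n_a, n_b, n_qc)),
    # QC injections bracket the run, as in a real LC-MS sequence
    injection_order = as.integer(rank(c(
      seq(2, 2 * (n_a + n_b), by = 2),
      seq(0.5, 2 * (n_a + n_b) - 0.5, length.out = max(n_qc, 2))[seq_len(n_qc)]
    )))
  )
}

test_that("prevalence filter applies the QC-and-test detection rule", {
  m <- metabo_toy_manifest(5, 5, 4)
  f <- toy_features(3, samples = m$sample_id)
  # feature 1: 3/4 QC, 9/10 test -> kept
  f[1, c("QC1")] <- NA
  f[1, "A1"] <- NA
  # feature 2: 1/4 QC -> removed
  f[2, c("QC1", "QC2", "QC3")] <- NA
  # feature 3: 4/4 QC but 5/10 test -> removed
  f[3, c("A1", "A2", "A3", "B1", "B2")] <- NA
  kept <- prevalence_filter(f, m)
  expect_equal(kept$feature_id, "F001")
  # without QC samples the QC criterion is skipped
  expect_warning(
    kept2 <- prevalence_filter(f, dplyr::filter(m, group != "QC")),
    "QC"
  )
  expect_setequal(kept2$feature_id, c("F001", "F002"))
  # idempotence
  expect_equal(prevalence_filter(kept, m), kept)
})

test_that("kNN imputation uses nearest-feature donors", {
  m <- metabo_toy_manifest(2, 2, 0)
  samples <- m$sample_id[1:4]
  f <- tibble::tibble(
    feature_id = c("target", "near", "far"),
    mz = c(100, 101, 102), rt = c(10, 20, 30),
    annotation = NA_character_,
    A1 = c(NA, 5, 50), A2 = c(10, 10.2, 80),
    B1 = c(11, 11.1, 90), B2 = c(9, 9.3, 70)
  )
  out <- knn_impute(f, k = 1)
  # the single nearest neighbour ("near") donates its value at A1
  expect_equal(out$A1[1], 5)
  # complete features pass through untouched; imputation is idempotent
  expect_equal(out[2:3, ], f[2:3, ])
  expect_equal(knn_impute(out, k = 1), out)
  f_bad <- f
  f_bad[1, c("A1", "A2", "B1", "B2")] <- NA
  expect_error(knn_impute(f_bad), "all values missing")
})

test_that("kNN imputation beats mean imputation on masked data", {
  rmse_knn <- rmse_mean <- numeric(10)
  for (s in 1:10) {
    f <- toy_features(40, seed = s)
    samples <- setdiff(names(f), c("feature_id", "mz", "rt", "annotation"))
    truth <- as.matrix(f[samples])
    set.seed(s + 100)
    # correlated feature blocks so neighbours are informative
    block <- matrix(2^rnorm(8 * length(samples), 10, 1), 8,
                    dimnames = list(NULL, samples))
    for (rep_i in 0:3) {
      f[seq_len(8) + rep_i * 8, samples] <-
        tibble::as_tibble(block * 2^rnorm(8, 0, 0.1))
    }
    truth <- as.matrix(f[samples])
    mask <- matrix(runif(length(truth)) < 0.1, nrow(truth))
    mask[rowSums(mask) == ncol(truth), 1] <- FALSE
    fm <- f
    fm[samples][mask] <- NA
    imp <- as.matrix(knn_impute(fm, k = 5)[samples])
    mimp <- as.matrix(fm[samples])
    rmean <- rowMeans(mimp, na.rm = TRUE)
    mimp[mask] <- rmean[row(mimp)[mask]]
    rmse_knn[s] <- sqrt(mean((imp[mask] - truth[mask])^2))
    rmse_mean[s] <- sqrt(mean((mimp[mask] - truth[mask])^2))
  }
  expect_lt(mean(rmse_knn), mean(rmse_mean))
})

test_that("QC drift correction is identity on flat trends, shrinks drift", {
  m <- metabo_toy_manifest(5, 5, 6)
  f <- toy_features(10, samples = m$sample_id, seed = 2)
  samples <- m$sample_id
  # flat QC: correction must be identity to numerical precision
  f_flat <- f
  f_flat[, paste0("QC", 1:6)] <- 100
  out <- qc_correct(f_flat, m)
  expect_equal(as.matrix(out[samples]), as.matrix(f_flat[samples]),
               tolerance = 1e-9)

  # planted 2x linear drift across injection order
  io <- m$injection_order
  drift <- 2^(seq(0, 1, length.out = length(io)))[io]
  f_drift <- f
  f_drift[samples] <- tibble::as_tibble(
    t(t(as.matrix(f[samples])) * drift)
  )
  corr <- qc_correct(f_drift, m)
  cv <- function(x) sd(x) / mean(x)
  qc_cols <- paste0("QC", 1:6)
  cv_pre <- apply(as.matrix(f_drift[qc_cols]), 1, cv)
  cv_post <- apply(as.matrix(corr[qc_cols]), 1, cv)
  expect_lt(mean(cv_post), mean(cv_pre))

  # missing injection order or too few QCs: pass-through with warning
  m_noio <- dplyr::select(m, -"injection_order")
  expect_warning(out2 <- qc_correct(f, m_noio), "injection_order")
  expect_equal(out2, f)
  m_fewqc <- dplyr::filter(m, !sample_id %in% paste0("QC", 3:6))
  f_few <- dplyr::select(f, -dplyr::all_of(paste0("QC", 3:6)))
  expect_warning(out3 <- qc_correct(f_few, m_fewqc), "fewer than 4 QC")
  expect_equal(out3, f_few)
})

test_that("metabolite ratios compare groups with a Welch test", {
  m <- metabo_toy_manifest(3, 3, 0)[1:6, ]
  f <- tibble::tibble(
    feature_id = c("Fm", "Fc"), mz = c(133.01, 191.02), rt = c(300, 400),
    annotation = c("malate", "citrate"),
    A1 = c(10, 5), A2 = c(12, 5), A3 = c(11, 5),
    B1 = c(5, 5), B2 = c(5.5, 5), B3 = c(4.5, 5)
  )
  r <- metabolite_ratio(f, m, c("MUT", "WT"))
  expect_equal(r$mean_a, mean(c(10, 12, 11) / 5))
  expect_equal(r$mean_b, mean(c(5, 5.5, 4.5) / 5))
  ratios <- attr(r, "ratios")
  expect_equal(ratios$ratio[ratios$sample_id == "A1"], 2)
  expect_lt(r$p_value, 0.05)

  # numerator identical to denominator: all ratios 1, p = 1
  f_same <- f
  f_same[1, 5:10] <- f_same[2, 5:10]
  r_same <- metabolite_ratio(f_same, m, c("MUT", "WT"))
  expect_equal(r_same$p_value, 1)
  expect_true(all(attr(r_same, "ratios")$ratio == 1))

  expect_error(metabolite_ratio(f, m, c("MUT", "WT"), numerator = "fumarate"),
               "fumarate")
  f_zero <- f
  f_zero[2, "A1"] <- 0
  expect_error(metabolite_ratio(f_zero, m, c("MUT", "WT")), "non-positive")
})
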