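METABO_META_COLS <- c("feature_id", "mz", "rt", "annotation")

metabo_sample_cols <- function(features) {
  setdiff(names(features), METABO_META_COLS)
}

metabo_matrix <- function(features) {
  mat <- as.matrix(features[metabo_sample_cols(features)])
  rownames(mat) <- features$feature_id
  mat
}

#' Read an LC-MS metabolite feature table
#'
#' Tab-separated: `feature_id`, `mz` (mass-to-charge), `rt` (retention time,
#' seconds), `annotation` (optional metabolite name, blank if unknown), then
#' one intensity column per sample. Missing intensities are blank cells and
#' are kept as `NA` — never zero-coded, since zero is a valid (if unlikely)
#' intensity while missingness means the peak was not detected.
#'
#' @param path Path to the feature TSV.
#' @return A tibble with one row per feature.
#' @export
read_metabolites <- function(path) {
  features <- readr::read_tsv(
    path,
    col_types = readr::cols(
      feature_id = readr::col_character(),
      mz = readr::col_double(),
      rt = readr::col_double(),
      annotation = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  assert_cols(features, METABO_META_COLS, "metabolite table")
  if (anyDuplicated(features[c("mz", "rt")]) > 0) {
    abort("duplicate (mz, rt) feature coordinates")
  }
  features
}

#' Write a metabolite feature table
#'
#' @param features Feature tibble as returned by [read_metabolites()].
#' @param path Output TSV path (missing values written as blanks).
#' @return `path`, invisibly.
#' @export
write_metabolites <- function(features, path) {
  readr::write_tsv(features, path, na = "", progress = FALSE)
  invisible(path)
}

#' Detection-prevalence filter
#'
#' Removes features detected in fewer than `qc_min` of the pooled QC
#' injections or fewer than `test_min` of the test (non-QC) samples; i.e. a
#' feature is kept only when it passes both criteria. With no QC samples in
#' the manifest the QC criterion is skipped with a warning.
#'
#' @param features Feature tibble.
#' @param manifest Sample manifest with a `QC` group labelling pooled
#'   injections.
#' @param qc_min Minimum detected fraction among QC samples.
#' @param test_min Minimum detected fraction among test samples.
#' @return The filtered feature tibble.
#' @export
prevalence_filter <- function(features, manifest, qc_min = 0.5,
                              test_min = 0.8) {
  manifest <- validate_manifest(manifest)
  samples <- intersect(metabo_sample_cols(features), manifest$sample_id)
  qc <- intersect(samples, group_samples(manifest, "QC"))
  test <- setdiff(samples, qc)
  mat <- metabo_matrix(features)
  keep <- rowMeans(!is.na(mat[, test, drop = FALSE])) >= test_min
  if (length(qc) == 0) {
    warn("no QC samples in manifest: QC prevalence criterion skipped")
  } else {
    keep <- keep & rowMeans(!is.na(mat[, qc, drop = FALSE])) >= qc_min
  }
  features[keep, ]
}

#' k-nearest-neighbour imputation of missing intensities
#'
#' For a missing entry (feature `f`, sample `s`), the `k` features nearest
#' to `f` — Euclidean distance over the samples where both features are
#' observed — are found; their observed intensities at `s` are averaged
#' with inverse-distance weights. When none of the `k` neighbours is
#' observed at `s`, the feature's own observed mean is used. Neighbours are
#' features (rows), not samples, following standard metabolomics practice.
#'
#' @param features Feature tibble (post prevalence filtering).
#' @param k Number of neighbouring features.
#' @return The feature tibble with all intensities observed.
#' @export
knn_impute <- function(features, k = 10) {
  mat <- metabo_matrix(features)
  if (!any(is.na(mat))) return(features)
  if (any(rowSums(!is.na(mat)) == 0)) {
    abort("feature with all values missing; run prevalence_filter first")
  }
  obs <- !is.na(mat)
  filled <- mat
  need <- which(rowSums(!obs) > 0)
  for (i in need) {
    both <- obs & rep(obs[i, ], each = nrow(mat))
    diffs <- sweep(mat, 2, mat[i, ])
    diffs[!both] <- NA
    d <- sqrt(rowSums(diffs^2, na.rm = TRUE))
    d[rowSums(both) == 0] <- Inf
    d[i] <- Inf
    ord <- order(d)
    neighbours <- ord[seq_len(min(k, sum(is.finite(d[ord]))))]
    for (s in which(!obs[i, ])) {
      donors <- neighbours[obs[neighbours, s]]
      if (length(donors) == 0) {
        filled[i, s] <- mean(mat[i, obs[i, ]])
      } else {
        w <- 1 / pmax(d[donors], .Machine$double.eps)
        filled[i, s] <- sum(w * mat[donors, s]) / sum(w)
      }
    }
  }
  out <- features
  out[metabo_sample_cols(features)] <- as_tibble(filled)
  out
}

#' QC-based injection-order drift correction
#'
#' A simplified QC-robust signal correction: per feature, a smoothing
#' spline of intensity versus injection order is fitted on the pooled QC
#' injections only; every sample is then divided by the fitted trend
#' normalized to its mean over the QC injections. With fewer than 4 QC
#' samples, or no `injection_order` in the manifest, the table is passed
#' through unchanged with a warning.
#'
#' @param features Feature tibble (complete; run [knn_impute()] first).
#' @param manifest Manifest with `injection_order` for every sample and a
#'   `QC` group.
#' @param df Spline degrees of freedom (capped by the number of distinct QC
#'   injection orders minus one).
#' @return The drift-corrected feature tibble.
#' @export
qc_correct <- function(features, manifest, df = 4) {
  manifest <- validate_manifest(manifest)
  samples <- metabo_sample_cols(features)
  if (!"injection_order" %in% names(manifest) ||
      anyNA(manifest$injection_order[manifest$sample_id %in% samples])) {
    warn("no injection_order available: QC drift correction skipped")
    return(features)
  }
  qc <- intersect(samples, group_samples(manifest, "QC"))
  if (length(qc) < 4) {
    warn("fewer than 4 QC samples: QC drift correction skipped")
    return(features)
  }
  io <- setNames(manifest$injection_order, manifest$sample_id)
  mat <- metabo_matrix(features)
  x_qc <- io[qc]
  x_all <- io[samples]
  df_use <- max(2, min(df, length(unique(x_qc)) - 1))
  corrected <- mat
  for (i in seq_len(nrow(mat))) {
    y <- mat[i, qc]
    if (sd(y) == 0) next  # flat trend: identity correction
    fit <- smooth.spline(x_qc, y, df = df_use)
    # hold the trend constant outside the QC-bracketed injection range
    # rather than extrapolating the spline
    x_clamped <- pmin(pmax(as.numeric(x_all), min(x_qc)), max(x_qc))
    trend <- predict(fit, x_clamped)$y
    trend_qc <- predict(fit, as.numeric(x_qc))$y
    factor <- trend / mean(trend_qc)
    if (any(factor <= 0)) {
      warn(sprintf(
        "non-positive fitted trend for feature %s: left uncorrected",
        features$feature_id[i]
      ))
      next
    }
    corrected[i, ] <- mat[i, ] / factor
  }
  out <- features
  out[samples] <- as_tibble(corrected)
  out
}

#' Metabolite ratio comparison between two groups
#'
#' Computes a per-sample ratio of two annotated metabolites (e.g. malate /
#' citrate) and compares the two condition groups with a two-sided Welch
#' t-test. Presets of interest in Krebs-cycle work are malate/citrate,
#' fumarate/citrate and succinate/citrate.
#'
#' @param features Complete feature tibble with an `annotation` column.
#' @param manifest Sample manifest.
#' @param groups Length-2 character vector of condition group labels
#'   (first over second in the reported difference).
#' @param numerator,denominator Annotation names of the two metabolites.
#' @return A one-row tibble: `numerator`, `denominator`, `group_a`,
#'   `group_b`, `n_a`, `n_b`, `mean_a`, `sem_a`, `mean_b`, `sem_b`,
#'   `p_value`. Per-sample ratios are attached as the `"ratios"` attribute.
#' @export
metabolite_ratio <- function(features, manifest, groups,
                             numerator = "malate", denominator = "citrate") {
  stopifnot(length(groups) == 2)
  manifest <- validate_manifest(manifest)
  find_feature <- function(name) {
    idx <- which(!is.na(features$annotation) & features$annotation == name)
    if (length(idx) == 0) {
      abort(sprintf("no feature annotated as '%s'", name))
    }
    if (length(idx) > 1) {
      abort(sprintf("multiple features annotated as '%s'", name))
    }
    idx
  }
  samples <- intersect(
    metabo_sample_cols(features),
    manifest$sample_id[manifest$group %in% groups]
  )
  num <- unlist(features[find_feature(numerator), samples], use.names = FALSE)
  den <- unlist(features[find_feature(denominator), samples], use.names = FALSE)
  if (anyNA(num) || anyNA(den)) {
    abort("ratio metabolites must be complete; impute first")
  }
  if (any(den <= 0)) abort("denominator metabolite has non-positive values")
  ratio <- num / den
  grp <- manifest$group[match(samples, manifest$sample_id)]
  ra <- ratio[grp == groups[1]]
  rb <- ratio[grp == groups[2]]
  p <- if (sd(ra) == 0 && sd(rb) == 0 && mean(ra) == mean(rb)) {
    1
  } else {
    t.test(ra, rb)$p.value
  }
  out <- tibble(
    numerator = numerator, denominator = denominator,
    group_a = groups[1], group_b = groups[2],
    n_a = length(ra), n_b = length(rb),
    mean_a = mean(ra), sem_a = sd(ra) / sqrt(length(ra)),
    mean_b = mean(rb), sem_b = sd(rb) / sqrt(length(rb)),
    p_value = p
  )
  attr(out, "ratios") <- tibble(sample_id = samples, group = grp, ratio = ratio)
  out
}
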