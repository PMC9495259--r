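#' Fit a two-class PLS-DA model
#'
#' Partial least squares discriminant analysis with a 0/1 class response,
#' fitted by the NIPALS procedure on autoscaled (centered, unit-variance)
#' predictors. Two components are extracted by default, matching the usual
#' two-dimensional score plot. Variable importance in projection (VIP) is
#' computed per feature from the component weights and the per-component
#' explained response variance; squared VIPs average to 1 by construction,
#' and features with VIP >= 1 are conventionally called important.
#'
#' @param features Complete metabolite feature tibble (no missing values).
#' @param manifest Sample manifest.
#' @param groups Length-2 character vector of condition labels; the first is
#'   coded 1.
#' @param n_components Number of PLS components (capped at samples - 1 and
#'   at the feature count).
#' @return A `plsda_fit` object: list with `scores` (tibble of per-sample
#'   component scores and group), `vip` (named vector), `weights`,
#'   `loadings`, `r2y` (per-component explained response variance fraction),
#'   `features_used`, `dropped` (zero-variance features), `groups`.
#' @export
fit_plsda <- function(features, manifest, groups, n_components = 2) {
  stopifnot(length(groups) == 2)
  manifest <- validate_manifest(manifest)
  samples <- intersect(
    metabo_sample_cols(features),
    manifest$sample_id[manifest$group %in% groups]
  )
  grp <- manifest$group[match(samples, manifest$sample_id)]
  if (any(table(factor(grp, levels = groups)) < 3)) {
    abort("each group needs at least 3 samples for PLS-DA")
  }
  x <- t(metabo_matrix(features)[, samples, drop = FALSE])
  if (anyNA(x)) abort("features must be complete; run knn_impute first")

  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0) {
    warn(sprintf("%d zero-variance feature(s) excluded from PLS-DA",
                 length(dropped)))
    x <- x[, sds > 0, drop = FALSE]
  }
  x <- scale(x)
  y <- as.numeric(grp == groups[1])
  y <- y - mean(y)
  ssy0 <- sum(y^2)

  n <- nrow(x); p <- ncol(x)
  a_max <- min(n_components, n - 1, p)
  w_mat <- matrix(0, p, a_max)
  p_mat <- matrix(0, p, a_max)
  t_mat <- matrix(0, n, a_max)
  ssy <- numeric(a_max)
  xr <- x; yr <- y
  a_used <- 0
  for (a in seq_len(a_max)) {
    w <- crossprod(xr, yr)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_ <- xr %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    c_ <- sum(t_ * yr) / tt
    p_ <- crossprod(xr, t_) / tt
    xr <- xr - t_ %*% t(p_)
    yr <- yr - c_ * t_
    a_used <- a
    w_mat[, a] <- w
    p_mat[, a] <- p_
    t_mat[, a] <- t_
    ssy[a] <- c_^2 * tt
  }
  if (a_used == 0) abort("PLS-DA could not extract any component")
  idx <- seq_len(a_used)
  w_mat <- w_mat[, idx, drop = FALSE]
  p_mat <- p_mat[, idx, drop = FALSE]
  t_mat <- t_mat[, idx, drop = FALSE]
  ssy <- ssy[idx]

  vip <- sqrt(p * as.vector(w_mat^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(x)

  scores <- as_tibble(t_mat, .name_repair = ~ paste0("comp", idx)) %>%
    mutate(sample_id = samples, group = grp, .before = 1)

  structure(
    list(
      scores = scores, vip = vip,
      weights = w_mat, loadings = p_mat,
      r2y = ssy / ssy0, features_used = colnames(x), dropped = dropped,
      groups = groups, n_components = a_used
    ),
    class = "plsda_fit"
  )
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat(sprintf(
    "PLS-DA fit: %d samples (%s vs %s), %d features, %d component(s)\n",
    nrow(x$scores), x$groups[1], x$groups[2],
    length(x$features_used), x$n_components
  ))
  cat(sprintf("cumulative R2Y = %.3f; %d feature(s) with VIP >= 1\n",
              sum(x$r2y), sum(x$vip >= 1)))
  invisible(x)
}

#' Tidy per-feature PLS-DA results
#'
#' @param x A `plsda_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per feature: `feature_id`, `vip`, and one
#'   weight column per component.
#' @method tidy plsda_fit
#' @export
tidy.plsda_fit <- function(x, ...) {
  out <- tibble(feature_id = x$features_used, vip = unname(x$vip))
  for (a in seq_len(x$n_components)) {
    out[[paste0("weight", a)]] <- x$weights[, a]
  }
  out
}

#' One-row PLS-DA model summary
#'
#' @param x A `plsda_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: sample/feature counts, components, cumulative
#'   R2Y and the number of VIP >= 1 features.
#' @method glance plsda_fit
#' @export
glance.plsda_fit <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_features = length(x$features_used),
    n_components = x$n_components,
    r2y = sum(x$r2y),
    n_vip_ge_1 = sum(x$vip >= 1)
  )
}

#' PLS-DA score plot
#'
#' @param object A `plsda_fit` object.
#' @param ... Unused.
#' @return A ggplot of the first two component scores coloured by group.
#' @method autoplot plsda_fit
#' @export
autoplot.plsda_fit <- function(object, ...) {
  sc <- object$scores
  if (object$n_components < 2) sc$comp2 <- 0
  ggplot2::ggplot(sc, ggplot2::aes(.data$comp1, .data$comp2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::stat_ellipse(level = 0.95, na.rm = TRUE) +
    ggplot2::labs(
      x = sprintf("Component 1 (R2Y %.1f%%)", 100 * object$r2y[1]),
      y = if (object$n_components >= 2) {
        sprintf("Component 2 (R2Y %.1f%%)", 100 * object$r2y[2])
      } else "Component 2",
      title = "PLS-DA scores"
    ) +
    ggplot2::theme_minimal()
}

#' PLS-DA with VIP feature selection and univariate statistics
#'
#' Fits [fit_plsda()] and pairs the VIP of each feature with a two-sided
#' Welch t-test on log2 intensities and BH-adjusted p-values. A feature is
#' called differential when `vip >= vip_cut` and `p_raw < p_cut`; the FDR
#' is reported alongside.
#'
#' @inheritParams fit_plsda
#' @param vip_cut VIP threshold for the differential call.
#' @param p_cut Raw p-value threshold for the differential call.
#' @return A tibble with one row per feature used in the model:
#'   `feature_id`, `log2fc` (first group over second, difference of group
#'   means of log2 intensity), `p_raw`, `p_fdr`, `vip`,
#'   `is_differential`. The fit is attached as the `"fit"` attribute.
#' @export
plsda_vip <- function(features, manifest, groups, n_components = 2,
                      vip_cut = 1, p_cut = 0.05) {
  fit <- fit_plsda(features, manifest, groups, n_components)
  features <- features[features$feature_id %in% fit$features_used, ]
  mat <- metabo_matrix(features)[fit$features_used, , drop = FALSE]
  samples <- fit$scores$sample_id
  grp <- fit$scores$group
  la <- log2(mat[, samples[grp == groups[1]], drop = FALSE])
  lb <- log2(mat[, samples[grp == groups[2]], drop = FALSE])
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, var); vb <- apply(lb, 1, var)
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               NA_real_)
  p <- ifelse(is.na(tstat), 1, 2 * pt(-abs(tstat), df))
  out <- tibble(
    feature_id = fit$features_used,
    log2fc = unname(ma - mb),
    p_raw = unname(p),
    p_fdr = unname(bh_adjust(p)),
    vip = unname(fit$vip),
    is_differential = unname(fit$vip >= vip_cut & p < p_cut)
  )
  attr(out, "fit") <- fit
  out
}

#' Permutation test of PLS-DA class separation
#'
#' Compares the fitted model's cumulative R2Y against the distribution
#' obtained by refitting on permuted class labels — the standard guard
#' against PLS-DA's tendency to separate even random labels at small n.
#'
#' @inheritParams fit_plsda
#' @param n_perm Number of label permutations.
#' @return A list with `r2y_observed`, `r2y_null` (vector) and `p_value`
#'   (share of permutations reaching the observed R2Y, add-one corrected).
#' @export
plsda_permutation_test <- function(features, manifest, groups,
                                   n_components = 2, n_perm = 99) {
  fit <- fit_plsda(features, manifest, groups, n_components)
  obs <- sum(fit$r2y)
  test_ids <- fit$scores$sample_id
  null <- purrr::map_dbl(seq_len(n_perm), function(i) {
    perm <- manifest
    sel <- match(test_ids, perm$sample_id)
    perm$group[sel] <- sample(perm$group[sel])
    sum(fit_plsda(features, perm, groups, n_components)$r2y)
  })
  list(
    r2y_observed = obs,
    r2y_null = null,
    p_value = (1 + sum(null >= obs)) / (n_perm + 1)
  )
}
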