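# Independent oracles and tiny in-code fixtures used across the suite.
# Each oracle deliberately avoids the package's own code path.

# step-up BH, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive upper-tail hypergeometric: enumerate all size-n draws from a
# universe 1..N in which 1..K is the pathway
oracle_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Jaccard / overlap coefficients via explicit membership vectors
oracle_set_coef <- function(a, b) {
  u <- union(a, b)
  av <- u %in% a
  bv <- u %in% b
  list(
    jc = sum(av & bv) / sum(av | bv),
    oc = sum(av & bv) / min(sum(av), sum(bv))
  )
}

toy_manifest <- function() {
  tibble::tibble(
    sample_id = c(paste0("RC", 1:3), paste0("RM", 1:3), paste0("HC", 1:3)),
    group = rep(c("RC", "RM", "HC"), each = 3)
  )
}

# one-row annotated variant with an explicit 9-sample zygosity vector
toy_variant <- function(gene, class, zyg, chrom = "1", pos = 100L) {
  stopifnot(length(zyg) == 9)
  tibble::tibble(
    variant_id = paste(chrom, pos, "A", "T", sep = ":"),
    chrom = chrom, pos = as.integer(pos), ref = "A", alt = "T",
    rsid = NA_character_, gene = gene, function_class = class,
    !!!stats::setNames(
      as.list(zyg),
      c(paste0("RC", 1:3), paste0("RM", 1:3), paste0("HC", 1:3))
    )
  )
}

# presence-count shorthand: c(rc, rm, hc) carriers, het by default
toy_pattern <- function(n_rc, n_rm, n_hc, zyg = "het") {
  c(rep(zyg, n_rc), rep("absent", 3 - n_rc),
    rep(zyg, n_rm), rep("absent", 3 - n_rm),
    rep(zyg, n_hc), rep("absent", 3 - n_hc))
}

# small complete metabolite table: n features x given samples, log-normal
toy_features <- function(n = 20, samples = c(paste0("A", 1:4), paste0("B", 1:4)),
                         seed = 1) {
  set.seed(seed)
  mat <- matrix(2^rnorm(n * length(samples), 10, 1), n,
                dimnames = list(NULL, samples))
  tibble::tibble(
    feature_id = sprintf("F%03d", seq_len(n)),
    mz = seq(100, by = 1.37, length.out = n),
    rt = seq(60, by = 5.1, length.out = n),
    annotation = NA_character_
  ) %>% dplyr::bind_cols(tibble::as_tibble(mat))
}
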