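#' Read annotated variant calls
#'
#' Parses a VCF 4.x file (per-sample `GT` genotypes required) and joins each
#' record to a sidecar annotation table keyed by `(chrom, pos, ref, alt)`,
#' in the style of ANNOVAR refGene output. Multi-allelic records are split
#' into one row per ALT allele before annotation, since all downstream
#' presence filtering is per-allele. Coordinates keep the VCF's own 1-based
#' convention.
#'
#' Diploid genotypes are coded per sample as `absent` (no copy of the ALT,
#' including no-calls), `het` (one copy) or `hom` (two copies).
#'
#' @param vcf_path Path to a VCF file with a GT FORMAT field.
#' @param annotation_path Path to a TSV with columns `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `function_class` and optionally `rsid`. Function classes
#'   outside `nonsynonymous_SNV`, `synonymous_SNV`, `stopgain`, `stoploss`
#'   are coerced to `other`.
#' @return A tibble with one row per (record, ALT allele) retained after the
#'   annotation join: columns `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `rsid`, `gene`, `function_class`, then one zygosity column per sample.
#' @export
read_variants <- function(vcf_path, annotation_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2) {
    abort("VCF has no per-sample genotype columns")
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    abort("VCF FORMAT is missing the GT field on one or more records")
  }

  samples <- setdiff(colnames(vcf@gt), "FORMAT")
  if (nrow(vcf@fix) == 0) {
    empty <- tibble(
      variant_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), rsid = character(),
      gene = character(), function_class = character()
    )
    empty[samples] <- list(character())
    return(empty)
  }
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    tokens <- strsplit(gt[i, ], "[/|]")
    purrr::map(seq_along(alts), function(a) {
      zyg <- purrr::map_chr(tokens, function(tok) {
        n_alt <- sum(tok == as.character(a), na.rm = TRUE)
        if (n_alt >= 2) "hom" else if (n_alt == 1) "het" else "absent"
      })
      tibble(
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts[a],
        !!!setNames(as.list(zyg), samples)
      )
    })
  })
  variants <- bind_rows(purrr::flatten(rows))

  ann <- read_variant_annotation(annotation_path)
  joined <- inner_join(variants, ann, by = c("chrom", "pos", "ref", "alt"))
  n_dropped <- nrow(variants) - nrow(joined)
  if (n_dropped > 0) {
    warn(sprintf(
      "%d of %d variant allele(s) had no annotation and were dropped",
      n_dropped, nrow(variants)
    ))
  }
  joined %>%
    mutate(variant_id = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt)) %>%
    select(all_of(VARIANT_META_COLS), all_of(samples))
}

read_variant_annotation <- function(path) {
  ann <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      gene = readr::col_character(),
      function_class = readr::col_character(),
      rsid = readr::col_character()
    ),
    progress = FALSE
  )
  assert_cols(
    ann, c("chrom", "pos", "ref", "alt", "gene", "function_class"),
    "variant annotation"
  )
  if (!"rsid" %in% names(ann)) ann$rsid <- NA_character_
  ann %>%
    mutate(
      rsid = if_else(.data$rsid %in% c(".", ""), NA_character_, .data$rsid),
      function_class = if_else(
        .data$function_class %in% FUNCTION_CLASSES,
        .data$function_class, "other"
      )
    )
}

#' Write a variant table as VCF plus annotation sidecar
#'
#' Emits a minimal VCF 4.2 file (GT-only FORMAT) and the matching annotation
#' TSV consumed by [read_variants()]. Used by the synthetic cohort generator
#' so that simulated data flow through the same readers as real data.
#'
#' @param variants Variant tibble in the layout produced by [read_variants()].
#' @param vcf_path,annotation_path Output paths.
#' @return `vcf_path`, invisibly.
#' @export
write_variants <- function(variants, vcf_path, annotation_path) {
  samples <- sample_cols(variants)
  gt_code <- c(absent = "0/0", het = "0/1", hom = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(
      c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", samples),
      collapse = "\t"
    )
  )
  body <- purrr::map_chr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    paste(
      c(v$chrom, v$pos, if (is.na(v$rsid)) "." else v$rsid, v$ref, v$alt,
        ".", "PASS", ".", "GT",
        unname(gt_code[unlist(v[samples], use.names = FALSE)])),
      collapse = "\t"
    )
  })
  writeLines(c(header, body), vcf_path)
  variants %>%
    select(all_of(c("chrom", "pos", "ref", "alt", "gene",
                    "function_class", "rsid"))) %>%
    readr::write_tsv(annotation_path, na = ".", progress = FALSE)
  invisible(vcf_path)
}
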