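#' Controlled consequence vocabulary
#'
#' The eight functional consequence categories the panel reports.
#' @return Character vector of the accepted values.
#' @export
consequence_vocabulary <- function() {
  c("missense", "stop gain", "stop lost", "start lost", "frameshift",
    "inframe insertion", "inframe deletion", "splice region")
}

#' Controlled clinical classification vocabulary
#' @return Character vector of the accepted values.
#' @export
clinical_class_vocabulary <- function() {
  c("pathogenic", "likely pathogenic", "VUS", "benign", "likely benign")
}

# Synonym table mapping sequence-ontology-style and free-text terms onto the
# controlled vocabulary.
consequence_synonyms <- function() {
  c(
    "missense" = "missense",
    "missense_variant" = "missense",
    "stop gain" = "stop gain",
    "stop_gained" = "stop gain",
    "nonsense" = "stop gain",
    "stop lost" = "stop lost",
    "stop_lost" = "stop lost",
    "start lost" = "start lost",
    "start_lost" = "start lost",
    "initiator_codon_variant" = "start lost",
    "frameshift" = "frameshift",
    "frameshift_variant" = "frameshift",
    "inframe insertion" = "inframe insertion",
    "inframe_insertion" = "inframe insertion",
    "conservative_inframe_insertion" = "inframe insertion",
    "disruptive_inframe_insertion" = "inframe insertion",
    "in-frame insertion" = "inframe insertion",
    "inframe deletion" = "inframe deletion",
    "inframe_deletion" = "inframe deletion",
    "conservative_inframe_deletion" = "inframe deletion",
    "disruptive_inframe_deletion" = "inframe deletion",
    "in-frame deletion" = "inframe deletion",
    "splice region" = "splice region",
    "splice_region_variant" = "splice region",
    "splice_acceptor_variant" = "splice region",
    "splice_donor_variant" = "splice region"
  )
}

#' Normalize annotation terms onto the panel's consequence vocabulary
#'
#' Maps sequence-ontology-style terms (e.g. `"missense_variant"`,
#' `"stop_gained"`) and common free-text spellings onto the eight-value
#' controlled vocabulary of [consequence_vocabulary()].
#'
#' @param raw_term Character vector of annotation terms.
#' @return Character vector of controlled vocabulary values.
#' @examples
#' normalize_consequence(c("missense_variant", "stop_gained"))
#' @export
normalize_consequence <- function(raw_term) {
  syn <- consequence_synonyms()
  out <- unname(syn[tolower(raw_term)])
  if (any(is.na(out))) {
    bad <- unique(raw_term[is.na(out)])
    abort(sprintf(
      "unmappable consequence term(s): %s\naccepted dialects: %s",
      paste(head(bad, 5), collapse = ", "),
      paste(sort(unique(names(syn))), collapse = ", ")
    ), class = "panelval_vocabulary_error")
  }
  out
}

# Left-normalizes a variant key: trims the shared allele suffix, then the
# shared prefix (advancing pos), always leaving at least one base on each
# allele.  Makes indel representations from the two pool callers comparable.
normalize_variant_key <- function(pos, ref, alt) {
  n <- length(pos)
  out_pos <- as.integer(pos)
  out_ref <- ref
  out_alt <- alt
  for (i in seq_len(n)) {
    r <- strsplit(out_ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(out_alt[i], "", fixed = TRUE)[[1]]
    # suffix trim
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # prefix trim
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      out_pos[i] <- out_pos[i] + 1L
    }
    out_ref[i] <- paste(r, collapse = "")
    out_alt[i] <- paste(a, collapse = "")
  }
  list(pos = out_pos, ref = out_ref, alt = out_alt)
}

#' Merge the pool-A and pool-B call sets of one sample
#'
#' The panel amplifies each sample in two independent primer pools; the
#' pipeline receives one call set per pool and merges them on the
#' left-normalized variant key (contig, position, ref, alt — shared allele
#' prefix/suffix trimmed so the two callers' indel representations match).
#' Per-pool provenance (depth, VAF, strand-bias flag) is retained; the
#' cumulative depth is the sum over present pools and the combined VAF their
#' depth-weighted mean.
#'
#' @param calls_a,calls_b Data frames of per-pool calls with columns
#'   `contig`, `pos` (1-based), `ref`, `alt`, `depth`, `vaf`,
#'   `strand_bias_flagged` (and optionally `pool`, which is validated).
#'   Optional annotation columns `consequence` and `clinical_class` are
#'   carried through (pool A preferred when both annotate).
#' @return Tibble with one row per distinct variant key: per-pool
#'   `depth_a`/`vaf_a`/`depth_b`/`vaf_b`, presence flags `in_pool_a`/
#'   `in_pool_b`, `cumulative_depth`, `combined_vaf`,
#'   `strand_bias_flagged`.
#' @examples
#' a <- tibble::tibble(contig = "chr12", pos = 100L, ref = "G", alt = "A",
#'                     depth = 620, vaf = 0.12, strand_bias_flagged = FALSE)
#' b <- tibble::tibble(contig = "chr12", pos = 100L, ref = "G", alt = "A",
#'                     depth = 540, vaf = 0.10, strand_bias_flagged = FALSE)
#' merge_pools(a, b)
#' @export
merge_pools <- function(calls_a, calls_b) {
  prep <- function(calls, expect_pool) {
    calls <- as_tibble(calls)
    if (nrow(calls) == 0) {
      return(tibble(contig = character(), pos = integer(), ref = character(),
                    alt = character(), depth = numeric(), vaf = numeric(),
                    strand_bias_flagged = logical(),
                    consequence = character(), clinical_class = character()))
    }
    check_columns(calls, c("contig", "pos", "ref", "alt", "depth", "vaf",
                           "strand_bias_flagged"),
                  sprintf("pool %s calls", expect_pool))
    if ("pool" %in% names(calls) && any(calls$pool != expect_pool)) {
      abort(sprintf("pool label mismatch: expected all '%s'", expect_pool),
            class = "panelval_validation_error")
    }
    if (any(calls$depth < 0) || any(calls$vaf < 0 | calls$vaf > 1)) {
      abort("per-pool calls need depth >= 0 and vaf in [0, 1]",
            class = "panelval_validation_error")
    }
    if (!"consequence" %in% names(calls)) calls$consequence <- NA_character_
    if (!"clinical_class" %in% names(calls)) calls$clinical_class <- NA_character_
    key <- normalize_variant_key(calls$pos, calls$ref, calls$alt)
    calls |>
      mutate(pos = key$pos, ref = key$ref, alt = key$alt) |>
      select("contig", "pos", "ref", "alt", "depth", "vaf",
             "strand_bias_flagged", "consequence", "clinical_class")
  }
  a <- prep(calls_a, "A")
  b <- prep(calls_b, "B")
  merged <- full_join(
    a, b,
    by = c("contig", "pos", "ref", "alt"), suffix = c("_a", "_b")
  )
  merged |>
    mutate(
      in_pool_a = !is.na(.data$depth_a),
      in_pool_b = !is.na(.data$depth_b),
      cumulative_depth = dplyr::coalesce(.data$depth_a, 0) +
        dplyr::coalesce(.data$depth_b, 0),
      combined_vaf = ifelse(
        .data$cumulative_depth > 0,
        (dplyr::coalesce(.data$depth_a, 0) * dplyr::coalesce(.data$vaf_a, 0) +
           dplyr::coalesce(.data$depth_b, 0) * dplyr::coalesce(.data$vaf_b, 0)) /
          .data$cumulative_depth,
        rowMeans(cbind(.data$vaf_a, .data$vaf_b), na.rm = TRUE)
      ),
      strand_bias_flagged = dplyr::coalesce(.data$strand_bias_flagged_a, FALSE) |
        dplyr::coalesce(.data$strand_bias_flagged_b, FALSE),
      consequence = dplyr::coalesce(.data$consequence_a, .data$consequence_b),
      clinical_class = dplyr::coalesce(.data$clinical_class_a, .data$clinical_class_b)
    ) |>
    select("contig", "pos", "ref", "alt",
           "depth_a", "vaf_a", "depth_b", "vaf_b",
           "in_pool_a", "in_pool_b",
           "cumulative_depth", "combined_vaf", "strand_bias_flagged",
           "consequence", "clinical_class") |>
    arrange(.data$contig, .data$pos, .data$ref, .data$alt)
}

#' Apply the dual-pool PASS / REVIEW / EXCLUDED filter
#'
#' Implements the panel's reporting rule.  Variants with a combined
#' (depth-weighted) VAF below 3% are `EXCLUDED` before review.  Of the rest,
#' a variant earns `PASS` when it is present in both pools, reaches the
#' cumulative depth threshold (1000x across both pools, equivalently an
#' average of 500x per pool) and carries no strand-bias flag; everything
#' else is `REVIEW`, i.e. kept for manual interpretation.
#'
#' @param merged Tibble from [merge_pools()].
#' @param min_vaf Exclusion threshold on the combined VAF (fraction,
#'   default 0.03).
#' @param min_cumulative_depth PASS threshold on the summed depth
#'   (default 1000).
#' @param per_pool_min If `TRUE`, require each pool individually to reach
#'   `min_cumulative_depth / 2` instead of the cumulative sum — the strict
#'   per-pool reading of the depth rule.  Default `FALSE` (cumulative
#'   reading; identical for balanced pools).
#' @return `merged` with a `filter_status` column
#'   (`"PASS"`/`"REVIEW"`/`"EXCLUDED"`).
#' @examples
#' a <- tibble::tibble(contig = "chr12", pos = 100L, ref = "G", alt = "A",
#'                     depth = 620, vaf = 0.12, strand_bias_flagged = FALSE)
#' b <- tibble::tibble(contig = "chr12", pos = 100L, ref = "G", alt = "A",
#'                     depth = 540, vaf = 0.10, strand_bias_flagged = FALSE)
#' apply_pass_filter(merge_pools(a, b))$filter_status  # "PASS"
#' @export
apply_pass_filter <- function(merged, min_vaf = 0.03,
                              min_cumulative_depth = 1000,
                              per_pool_min = FALSE) {
  check_columns(merged, c("in_pool_a", "in_pool_b", "cumulative_depth",
                          "combined_vaf", "strand_bias_flagged"),
                "merged calls")
  depth_ok <- if (per_pool_min) {
    dplyr::coalesce(merged$depth_a, 0) >= min_cumulative_depth / 2 &
      dplyr::coalesce(merged$depth_b, 0) >= min_cumulative_depth / 2
  } else {
    merged$cumulative_depth >= min_cumulative_depth
  }
  merged |>
    mutate(filter_status = dplyr::case_when(
      .data$combined_vaf < min_vaf ~ "EXCLUDED",
      .data$in_pool_a & .data$in_pool_b & depth_ok &
        !.data$strand_bias_flagged ~ "PASS",
      TRUE ~ "REVIEW"
    ))
}

#' Frequency spectrum of merged variant calls
#'
#' Tabulates calls at the requested annotation level, with percentages and a
#' deterministic ordering (descending count, then lexical).
#'
#' @param calls Tibble of merged calls carrying the requested column
#'   (`gene`, `consequence` or `clinical_class`).
#' @param level One of `"gene"`, `"consequence"`, `"clinical_class"`.
#' @return Tibble with columns `level`, `value`, `n`, `percent`.
#' @examples
#' calls <- tibble::tibble(consequence = rep(c("missense", "stop gain"), c(8, 2)))
#' summarize_spectrum(calls, "consequence")
#' @export
summarize_spectrum <- function(calls, level = c("gene", "consequence",
                                                "clinical_class")) {
  level <- arg_match(level)
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    return(tibble(level = character(), value = character(),
                  n = integer(), percent = numeric()))
  }
  check_columns(calls, level, "calls")
  calls |>
    count(value = .data[[level]], name = "n") |>
    mutate(level = level, percent = 100 * .data$n / sum(.data$n)) |>
    arrange(desc(.data$n), .data$value) |>
    select("level", "value", "n", "percent")
}

#' Read a single-sample, single-pool VCF
#'
#' Parses a plain-text VCF (one sample, one pool) into the per-pool call
#' tibble consumed by [merge_pools()].  Depth and allele fraction are read
#' from the `DP` and `VF` genotype fields; the strand-bias condition is an
#' upstream caller flag, recognised as the token `sb_key` in FILTER or a key
#' in INFO.  Consequence (`CSQ`) and clinical class (`CLIN`) INFO keys are
#' carried through when present.
#'
#' @param path VCF file path.
#' @param pool `"A"` or `"B"`.
#' @param sb_key FILTER/INFO key marking strand bias (default `"SB"`).
#' @return Tibble of per-pool calls.
#' @export
read_pool_vcf <- function(path, pool = c("A", "B"), sb_key = "SB") {
  pool <- arg_match(pool)
  if (!file.exists(path)) {
    abort(sprintf("VCF not found: %s", path), class = "panelval_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), pool = character(), depth = numeric(),
                  vaf = numeric(), strand_bias_flagged = logical(),
                  consequence = character(), clinical_class = character()))
  }
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    abort(sprintf("multi-allelic records are not supported: %s", path),
          class = "panelval_parse_error")
  }
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, "DP")[, 1]))
  vf <- suppressWarnings(as.numeric(vcfR::extract.gt(v, "VF")[, 1]))
  if (any(is.na(dp)) || any(is.na(vf))) {
    abort(sprintf("missing DP/VF genotype fields in %s", path),
          class = "panelval_parse_error")
  }
  filt <- fix$FILTER
  info <- fix$INFO
  sb <- purrr::map_lgl(strsplit(filt, ";", fixed = TRUE),
                       ~ sb_key %in% .x) |
    grepl(paste0("(^|;)", sb_key, "($|;|=)"), info)
  get_info <- function(key) {
    m <- regmatches(info, regexec(paste0("(^|;)", key, "=([^;]+)"), info))
    decode_info(purrr::map_chr(m, ~ if (length(.x) == 3) .x[3] else NA_character_))
  }
  tibble(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    pool = pool,
    depth = dp,
    vaf = vf,
    strand_bias_flagged = sb,
    consequence = get_info("CSQ"),
    clinical_class = get_info("CLIN")
  )
}

# Writes a per-pool call tibble as a minimal plain-text VCF (used by the
# simulator and round-trip tests).
write_pool_vcf <- function(calls, path, sample_id = "SAMPLE") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelval",
    "##FILTER=<ID=SB,Description=\"Strand bias flagged by the caller\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=CLIN,Number=1,Type=String,Description=\"Clinical class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=VF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- character(0)
  if (nrow(calls) > 0) {
    info <- paste0(
      ifelse(is.na(calls$consequence), "", paste0("CSQ=", encode_info(calls$consequence))),
      ifelse(is.na(calls$consequence) | is.na(calls$clinical_class), "", ";"),
      ifelse(is.na(calls$clinical_class), "", paste0("CLIN=", encode_info(calls$clinical_class)))
    )
    info[info == ""] <- "."
    body <- paste(
      calls$contig, calls$pos, ".", calls$ref, calls$alt, ".",
      ifelse(calls$strand_bias_flagged, "SB", "PASS"),
      info, "GT:DP:VF",
      sprintf("0/1:%d:%s", as.integer(round(calls$depth)),
              formatC(calls$vaf, digits = 10, format = "g")),
      sep = "\t"
    )
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a merged, filtered call set as VCF
#'
#' One record per merged variant with `filter_status` in FILTER and the
#' combined VAF (`CVAF`), cumulative depth (`CDP`), per-pool provenance
#' (`POOLS`, `DPA`, `DPB`), consequence (`CSQ`) and clinical class (`CLIN`)
#' as INFO keys.
#'
#' @param filtered Tibble from [apply_pass_filter()].
#' @param path Output path (plain-text VCF).
#' @param sample_id Sample name for the header.
#' @return Invisibly, `path`.
#' @export
write_merged_vcf <- function(filtered, path, sample_id = "SAMPLE") {
  check_columns(filtered, c("contig", "pos", "ref", "alt", "filter_status",
                            "cumulative_depth", "combined_vaf"),
                "filtered calls")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelval",
    sprintf("##sample=%s", sample_id),
    "##FILTER=<ID=PASS,Description=\"Present in both pools, cumulative depth >= 1000x, VAF >= 3%, no strand bias\">",
    "##FILTER=<ID=REVIEW,Description=\"Kept for manual interpretation\">",
    "##FILTER=<ID=EXCLUDED,Description=\"Combined VAF < 3%\">",
    "##INFO=<ID=CVAF,Number=1,Type=Float,Description=\"Depth-weighted combined VAF\">",
    "##INFO=<ID=CDP,Number=1,Type=Integer,Description=\"Cumulative depth over pools\">",
    "##INFO=<ID=POOLS,Number=1,Type=String,Description=\"Pools with a call\">",
    "##INFO=<ID=DPA,Number=1,Type=Integer,Description=\"Pool A depth\">",
    "##INFO=<ID=DPB,Number=1,Type=Integer,Description=\"Pool B depth\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=CLIN,Number=1,Type=String,Description=\"Clinical class\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- character(0)
  if (nrow(filtered) > 0) {
    pools <- paste0(ifelse(filtered$in_pool_a, "A", ""),
                    ifelse(filtered$in_pool_b, "B", ""))
    info <- sprintf(
      "CVAF=%.6f;CDP=%d;POOLS=%s", filtered$combined_vaf,
      as.integer(round(filtered$cumulative_depth)), pools
    )
    info <- paste0(
      info,
      ifelse(filtered$in_pool_a,
             sprintf(";DPA=%d", as.integer(round(filtered$depth_a))), ""),
      ifelse(filtered$in_pool_b,
             sprintf(";DPB=%d", as.integer(round(filtered$depth_b))), ""),
      ifelse(is.na(filtered$consequence), "",
             paste0(";CSQ=", encode_info(filtered$consequence))),
      ifelse(is.na(filtered$clinical_class), "",
             paste0(";CLIN=", encode_info(filtered$clinical_class)))
    )
    body <- paste(filtered$contig, filtered$pos, ".", filtered$ref,
                  filtered$alt, ".", filtered$filter_status, info, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

# INFO values may not contain spaces/semicolons/equals; percent-encode them
# (the VCF convention) on write and decode on read.
encode_info <- function(x) {
  x <- gsub("%", "%25", x)
  x <- gsub(" ", "%20", x)
  x <- gsub(";", "%3B", x)
  gsub("=", "%3D", x)
}

decode_info <- function(x) {
  x <- gsub("%20", " ", x)
  x <- gsub("%3B", ";", x)
  x <- gsub("%3D", "=", x)
  gsub("%25", "%", x)
}
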