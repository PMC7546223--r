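#' Score a validation cohort through merge, filter and concordance
#'
#' Runs the analysis pipeline over per-outcome dual-pool call sets: merges
#' the pools of each (sample, center) outcome, applies the PASS filter, and
#' declares the panel result "detected" when at least one PASS variant
#' falls in one of the `genes` of interest (REVIEW calls need manual
#' interpretation and are not auto-detected).  Joining with the
#' reference-standard design yields the outcome records for
#' [diagnostic_accuracy()].
#'
#' @param calls Pool-call tibble keyed by `sample_id`, `center_id` (as from
#'   [simulate_validation_calls()] or read from per-outcome VCF pairs).
#' @param design Reference-standard design tibble with `sample_id`,
#'   `center_id`, `reference_result`.
#' @param genes Genes whose variants count as a detection (default
#'   KRAS/NRAS/BRAF); detection is restricted by genomic position using
#'   `panel`.
#' @param panel A [panel_def].
#' @return Outcome records: `design` plus a `panel_result` column.
#' @export
score_validation_calls <- function(calls, design,
                                   genes = c("KRAS", "NRAS", "BRAF"),
                                   panel = tst26_panel()) {
  check_columns(design, c("sample_id", "center_id", "reference_result"),
                "design")
  regions <- panel$exons |> filter(.data$gene_symbol %in% genes)
  detected_keys <- character(0)
  if (!is.null(calls) && nrow(calls) > 0) {
    check_columns(calls, c("sample_id", "center_id", "pool", "contig", "pos",
                           "ref", "alt", "depth", "vaf",
                           "strand_bias_flagged"), "calls")
    scored <- calls |>
      tidyr::nest(data = -c("sample_id", "center_id")) |>
      mutate(pass_hit = purrr::map_lgl(.data$data, function(d) {
        merged <- merge_pools(
          d |> filter(.data$pool == "A"),
          d |> filter(.data$pool == "B")
        )
        flt <- apply_pass_filter(merged) |> filter(.data$filter_status == "PASS")
        if (nrow(flt) == 0) return(FALSE)
        hit <- dplyr::inner_join(
          flt, regions |> select("contig", r_start = "start", r_end = "end"),
          by = "contig", relationship = "many-to-many"
        ) |>
          filter(.data$pos > .data$r_start, .data$pos <= .data$r_end)
        nrow(hit) > 0
      }))
    detected_keys <- with(scored[scored$pass_hit, ],
                          paste(sample_id, center_id))
  }
  design |>
    mutate(panel_result = ifelse(
      paste(.data$sample_id, .data$center_id) %in% detected_keys,
      "detected", "not_detected"
    ))
}

#' Run the end-to-end panel pipeline
#'
#' Orchestrates all stages from a YAML (or list) configuration: simulate or
#' load the cohort, run the QC workflow, merge and filter every sequenced
#' sample's pool calls, summarize the variant spectrum, assess coverage,
#' and — when a validation block or truth file is present — compute the
#' concordance analysis.  The consolidated report is internally
#' consistency-checked (sequenced + ngs_fail = cohort size; filter-status
#' counts sum to the merged-call count) and can be serialized with
#' [write_report()].
#'
#' Configuration keys: `seed`; either `cohort:` (arguments to
#' [cohort_config()]) or `inputs:` with paths `sample_sheet`, `vcf_dir`
#' (files `<sample>.poolA.vcf` / `<sample>.poolB.vcf`), `coverage`;
#' optional `validation:` (arguments to [simulate_validation_calls()]) or
#' `inputs$truth` (outcome TSV); optional `out:` directory.
#'
#' @param config Path to a YAML file or a named list.
#' @param panel A [panel_def].
#' @return A `pipeline_report` object (list of tibbles).
#' @examples
#' report <- run_pipeline(list(seed = 7, cohort = list(n_samples = 30)))
#' report$qc_summary
#' @export
run_pipeline <- function(config, panel = tst26_panel()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "panelval_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L

  if (!is.null(config$cohort)) {
    cfg <- do.call(cohort_config,
                   modifyList(list(seed = seed), config$cohort))
    cohort <- simulate_cohort(cfg, panel)
    sample_sheet <- cohort$sample_sheet
    pool_calls <- cohort$pool_calls
    coverage <- cohort$coverage
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (p in unlist(inp[c("sample_sheet", "coverage")])) {
      if (!is.null(p) && !file.exists(p)) {
        abort(sprintf("input not found: %s", p), class = "panelval_io_error")
      }
    }
    sample_sheet <- read_sample_sheet(inp$sample_sheet)
    coverage <- readr::read_tsv(inp$coverage, col_types = readr::cols(),
                                progress = FALSE)
    pool_calls <- read_cohort_vcfs(inp$vcf_dir)
  } else {
    abort("config needs either a 'cohort' (simulate) or 'inputs' block",
          class = "panelval_config_error")
  }

  ledger <- qc_workflow(sample_sheet)
  sequenced <- ledger$sample_id[ledger$terminal_status == "sequenced"]

  seq_calls <- pool_calls |> filter(.data$sample_id %in% sequenced)
  if (nrow(seq_calls) > 0) {
    filtered <- seq_calls |>
      tidyr::nest(data = -"sample_id") |>
      mutate(merged = purrr::map(.data$data, function(d) {
        apply_pass_filter(merge_pools(
          d |> filter(.data$pool == "A"),
          d |> filter(.data$pool == "B")
        ))
      })) |>
      select("sample_id", "merged") |>
      tidyr::unnest("merged")
  } else {
    filtered <- tibble(sample_id = character(), contig = character(),
                       pos = integer(), ref = character(), alt = character(),
                       cumulative_depth = numeric(), combined_vaf = numeric(),
                       consequence = character(), clinical_class = character(),
                       filter_status = character())
  }

  reported <- filtered |> filter(.data$filter_status == "PASS")
  detected_ids <- unique(reported$sample_id)
  n_det <- length(detected_ids)
  n_not <- length(sequenced) - n_det

  spectrum <- list(
    consequence = summarize_spectrum(reported, "consequence"),
    clinical_class = summarize_spectrum(reported, "clinical_class")
  )

  cov_report <- coverage_report(panel, amplicon_means(coverage, panel))

  concordance <- NULL
  if (!is.null(config$validation)) {
    val <- do.call(simulate_validation_calls,
                   modifyList(list(seed = seed, panel = panel),
                              config$validation))
    records <- score_validation_calls(val$calls, val$design, panel = panel)
    concordance <- diagnostic_accuracy(records)
  } else if (!is.null(config$inputs$truth)) {
    records <- readr::read_tsv(config$inputs$truth,
                               col_types = readr::cols(), progress = FALSE)
    concordance <- diagnostic_accuracy(records)
  }

  report <- structure(list(
    qc_ledger = ledger,
    qc_summary = tibble(
      cohort_size = nrow(ledger),
      sequenced = length(sequenced),
      ngs_fail = sum(ledger$terminal_status == "ngs_fail"),
      detected = n_det,
      not_detected = n_not,
      detected_percent = if (length(sequenced) > 0)
        round_half_up(detected_fraction(n_det, n_not)) else NA_real_
    ),
    variants = filtered,
    filter_counts = filtered |> count(.data$filter_status, name = "n"),
    spectrum = spectrum,
    coverage = cov_report,
    concordance = concordance,
    provenance = tibble(seed = seed,
                        tool_version = as.character(utils::packageVersion("panelval")))
  ), class = "pipeline_report")
  validate_report(report)
  if (!is.null(config$out)) write_report(report, config$out)
  report
}

# Reads every <sample>.poolA.vcf / <sample>.poolB.vcf pair from a directory.
read_cohort_vcfs <- function(vcf_dir) {
  if (is.null(vcf_dir) || !dir.exists(vcf_dir)) {
    abort(sprintf("VCF directory not found: %s", vcf_dir %||% "<missing>"),
          class = "panelval_io_error")
  }
  files <- list.files(vcf_dir, pattern = "\\.pool[AB]\\.vcf$",
                      full.names = TRUE)
  purrr::map(files, function(f) {
    pool <- sub("^.*\\.pool([AB])\\.vcf$", "\\1", f)
    sid <- sub("\\.pool[AB]\\.vcf$", "", basename(f))
    read_pool_vcf(f, pool) |> mutate(sample_id = sid)
  }) |>
    purrr::list_rbind()
}

validate_report <- function(report) {
  qs <- report$qc_summary
  stopifnot(
    qs$sequenced + qs$ngs_fail == qs$cohort_size,
    qs$detected + qs$not_detected == qs$sequenced,
    sum(report$filter_counts$n) == nrow(report$variants)
  )
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  qs <- x$qc_summary
  cat(sprintf(
    "<pipeline_report> %d samples: %d sequenced, %d NGS fail\n",
    qs$cohort_size, qs$sequenced, qs$ngs_fail
  ))
  if (qs$sequenced > 0) {
    cat(sprintf("  detected variants in %d samples (%s of sequenced)\n",
                qs$detected, percent_label(qs$detected_percent)))
  }
  fc <- setNames(x$filter_counts$n, x$filter_counts$filter_status)
  cat(sprintf("  merged calls: %d (PASS %d, REVIEW %d, EXCLUDED %d)\n",
              nrow(x$variants), fc["PASS"] %|0|% 0, fc["REVIEW"] %|0|% 0,
              fc["EXCLUDED"] %|0|% 0))
  cat(sprintf("  coverage: %d exon regions, %d fail, %d by compensation\n",
              nrow(x$coverage), sum(x$coverage$status == "fail"),
              sum(x$coverage$status == "pass_by_compensation")))
  if (!is.null(x$concordance)) print(x$concordance)
  invisible(x)
}

`%|0|%` <- function(a, b) if (is.na(a)) b else a

#' Serialize a pipeline report
#'
#' Writes the machine-readable JSON report (versioned schema: integer
#' counts, full-precision fractions plus rounded-percent presentation
#' fields) and TSV summaries of each stage into `dir`.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$qc_ledger, file.path(dir, "qc_ledger.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$variants, file.path(dir, "variants.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$coverage, file.path(dir, "coverage_report.tsv"),
                   progress = FALSE)
  payload <- list(
    schema_version = 1L,
    provenance = as.list(report$provenance),
    qc = as.list(report$qc_summary),
    filter_counts = setNames(as.list(report$filter_counts$n),
                             report$filter_counts$filter_status),
    spectrum = purrr::map(report$spectrum, ~ as.list(as.data.frame(.x))),
    coverage_status = as.list(table(report$coverage$status))
  )
  if (!is.null(report$concordance)) {
    m <- report$concordance$metrics
    payload$concordance <- list(
      table = as.list(report$concordance$table),
      metrics = purrr::map(seq_len(nrow(m)), function(i) {
        list(metric = m$metric[i], estimate = m$estimate[i],
             ci_low = m$ci_low[i], ci_high = m$ci_high[i],
             percent = m$percent[i], percent_low = m$percent_low[i],
             percent_high = m$percent_high[i],
             numerator = m$numerator[i], denominator = m$denominator[i])
      })
    )
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Spectrum and coverage plots
#'
#' `plot_spectrum()` draws the variant frequency spectrum from
#' [summarize_spectrum()]; `plot_coverage()` draws per-exon pool coverage
#' from [coverage_report()] with the minimum-coverage threshold marked.
#'
#' @param spectrum Tibble from [summarize_spectrum()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  check_columns(spectrum, c("value", "percent"), "spectrum")
  spectrum <- spectrum |>
    mutate(value = factor(.data$value, levels = rev(.data$value)))
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$percent, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "% of reported variants", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_spectrum
#' @param cov_report Tibble from [coverage_report()].
#' @param min_depth Threshold line (default 1000).
#' @export
plot_coverage <- function(cov_report, min_depth = 1000) {
  check_columns(cov_report, c("gene", "exon_label", "cumulative_mean",
                              "status"), "coverage report")
  cov_report <- cov_report |>
    mutate(region = paste(.data$gene, .data$exon_label))
  ggplot2::ggplot(cov_report,
                  ggplot2::aes(x = .data$cumulative_mean,
                               y = stats::reorder(.data$region,
                                                  .data$cumulative_mean),
                               colour = .data$status)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = min_depth, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cumulative mean depth (x)", y = NULL,
                  colour = "status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 4))
}
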