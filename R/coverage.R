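#' Per-amplicon mean coverage
#'
#' Accepts either a per-amplicon table (`sample_id`, `amplicon_id`,
#' `mean_depth`) — passed through after validation — or a per-position depth
#' table (`sample_id`, `contig`, `pos`, `depth`), in which case each 1-based
#' position is assigned to every amplicon interval containing it and the
#' arithmetic mean over the amplicon's positions is taken.
#'
#' @param records Coverage data frame in either of the two layouts.  A
#'   missing `sample_id` column is treated as a single cohort-level set.
#' @param panel A [panel_def]; amplicon ids / intervals are validated
#'   against it.
#' @return Tibble with `sample_id`, `amplicon_id`, `pool`, `mean_depth`.
#' @examples
#' panel <- tst26_panel()
#' amp <- panel$amplicons$amplicon_id[1]
#' amplicon_means(tibble::tibble(amplicon_id = amp, mean_depth = 1200), panel)
#' @export
amplicon_means <- function(records, panel) {
  stopifnot(inherits(panel, "panel_def"))
  records <- as_tibble(records)
  if (!"sample_id" %in% names(records)) records$sample_id <- "cohort"
  amps <- panel$amplicons

  if ("mean_depth" %in% names(records)) {
    check_columns(records, c("amplicon_id", "mean_depth"), "coverage table")
    unknown <- setdiff(records$amplicon_id, amps$amplicon_id)
    if (length(unknown) > 0) {
      abort(sprintf("unknown amplicon_id(s): %s",
                    paste(head(unknown, 5), collapse = ", ")),
            class = "panelval_validation_error")
    }
    if (any(records$mean_depth < 0)) {
      abort("mean_depth must be >= 0", class = "panelval_validation_error")
    }
    out <- records |>
      group_by(.data$sample_id, .data$amplicon_id) |>
      summarise(mean_depth = mean(.data$mean_depth), .groups = "drop")
  } else {
    check_columns(records, c("contig", "pos", "depth"), "coverage table")
    # position p (1-based) lies in the half-open amplicon [start, end)
    # iff start < p <= end
    out <- records |>
      inner_join(
        amps |> select("amplicon_id", "contig", amp_start = "start",
                       amp_end = "end"),
        by = "contig", relationship = "many-to-many"
      ) |>
      filter(.data$pos > .data$amp_start, .data$pos <= .data$amp_end) |>
      group_by(.data$sample_id, .data$amplicon_id) |>
      summarise(mean_depth = mean(.data$depth), .groups = "drop")
    if (nrow(out) == 0) {
      abort("no position overlaps any panel amplicon",
            class = "panelval_validation_error")
    }
  }
  out |>
    left_join(amps |> select("amplicon_id", "pool"), by = "amplicon_id") |>
    select("sample_id", "amplicon_id", "pool", "mean_depth") |>
    arrange(.data$sample_id, .data$amplicon_id)
}

# Exon-level pool means and status for a coverage set that is already
# cohort-aggregated (one mean per amplicon).
exon_status_table <- function(panel, cov, min_depth) {
  amp_meta <- panel$amplicons |>
    select("amplicon_id", "gene_symbol", "exon_label")
  cov |>
    group_by(.data$amplicon_id, .data$pool) |>
    summarise(mean_depth = mean(.data$mean_depth), .groups = "drop") |>
    inner_join(amp_meta, by = "amplicon_id") |>
    group_by(gene = .data$gene_symbol, exon_label = .data$exon_label) |>
    summarise(
      pool_a_mean = ifelse(any(.data$pool == "A"),
                           mean(.data$mean_depth[.data$pool == "A"]), NA_real_),
      pool_b_mean = ifelse(any(.data$pool == "B"),
                           mean(.data$mean_depth[.data$pool == "B"]), NA_real_),
      .groups = "drop"
    ) |>
    mutate(
      cumulative_mean = dplyr::coalesce(.data$pool_a_mean, 0) +
        dplyr::coalesce(.data$pool_b_mean, 0),
      status = dplyr::case_when(
        pmax(dplyr::coalesce(.data$pool_a_mean, 0),
             dplyr::coalesce(.data$pool_b_mean, 0)) >= min_depth ~ "pass",
        .data$cumulative_mean >= min_depth ~ "pass_by_compensation",
        TRUE ~ "fail"
      )
    ) |>
    select("gene", "exon_label", "pool_a_mean", "pool_b_mean",
           "cumulative_mean", "status")
}

#' Exon-level coverage status with cross-pool compensation
#'
#' An exon region passes when a single pool's mean amplicon coverage reaches
#' the panel's minimum (1000x by default); if neither pool reaches it alone
#' but the cumulative (pool A + pool B) mean does, the shortfall is
#' compensated by the second pool (`"pass_by_compensation"`); below the
#' threshold cumulatively, the region fails.  The exon pool mean is the
#' unweighted mean of that pool's amplicon means for the region.
#'
#' @param panel A [panel_def].
#' @param cov Per-amplicon coverage tibble from [amplicon_means()].
#' @param gene,exon_label Region to assess.
#' @param min_depth Coverage threshold (default 1000).
#' @return One-row tibble: `gene`, `exon_label`, `pool_a_mean`,
#'   `pool_b_mean`, `cumulative_mean`, `status`.
#' @export
exon_coverage_status <- function(panel, cov, gene, exon_label,
                                 min_depth = 1000) {
  stopifnot(inherits(panel, "panel_def"))
  region <- panel$exons |>
    filter(.data$gene_symbol == gene, .data$exon_label == !!exon_label)
  if (nrow(region) == 0) {
    abort(sprintf("unknown exon region: %s %s", gene, exon_label),
          class = "panelval_lookup_error")
  }
  ids <- panel$amplicons |>
    filter(.data$gene_symbol == gene, .data$exon_label == !!exon_label) |>
    dplyr::pull("amplicon_id")
  cov <- filter(as_tibble(cov), .data$amplicon_id %in% ids)
  if (nrow(cov) == 0) {
    abort(sprintf("no coverage records for %s exon %s", gene, exon_label),
          class = "panelval_missing_data_error")
  }
  exon_status_table(panel, cov, min_depth)
}

#' Cohort coverage report over all exon regions
#'
#' One row per exon region of the panel, failing regions first (then
#' compensated, then passing; within a status, by gene and label) so that
#' problem regions lead the report.  Coverage is aggregated to cohort level
#' (mean over samples per amplicon) unless `by_sample = TRUE`, in which case
#' the report is computed per sample.
#'
#' @param panel A [panel_def].
#' @param cov Per-amplicon coverage tibble from [amplicon_means()].
#' @param min_depth Coverage threshold (default 1000).
#' @param by_sample Compute one report row per (sample, exon region)?
#' @return Tibble of exon statuses; with `by_sample`, prefixed by
#'   `sample_id`.
#' @export
coverage_report <- function(panel, cov, min_depth = 1000, by_sample = FALSE) {
  stopifnot(inherits(panel, "panel_def"))
  cov <- as_tibble(cov)
  check_columns(cov, c("amplicon_id", "mean_depth"), "coverage table")
  run_one <- function(cov_one) {
    res <- exon_status_table(panel, cov_one, min_depth)
    missing <- anti_join(
      panel$exons |> select(gene = "gene_symbol", "exon_label"),
      res, by = c("gene", "exon_label")
    )
    if (nrow(missing) > 0) {
      abort(sprintf("no coverage records for exon region(s): %s",
                    paste(head(paste(missing$gene, missing$exon_label), 5),
                          collapse = ", ")),
            class = "panelval_missing_data_error")
    }
    res |>
      mutate(.rank = match(.data$status,
                           c("fail", "pass_by_compensation", "pass"))) |>
      arrange(.data$.rank, .data$gene, .data$exon_label) |>
      select(-".rank")
  }
  if (by_sample) {
    check_columns(cov, "sample_id", "coverage table")
    cov |>
      tidyr::nest(data = -"sample_id") |>
      mutate(report = purrr::map(.data$data, run_one)) |>
      select("sample_id", "report") |>
      tidyr::unnest("report")
  } else {
    run_one(cov)
  }
}
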