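#' Tumor-cell content gate (QC1)
#'
#' First pre-sequencing gate.  Specimens need at least 30% tumor-cell
#' content (TCC) as scored by a pathologist; between 10% and 30% the tumor
#' area is macrodissected when possible, otherwise DNA is isolated directly
#' from the whole section; below 10% the specimen fails.
#'
#' @param tcc_percent Numeric vector of TCC percentages in \[0, 100\].
#' @param macrodissectable Logical vector (recycled): can the tumor area be
#'   enriched with a scalpel?
#' @return Character vector with values `"pass"`, `"macrodissect_then_pass"`,
#'   `"direct_isolation"`, `"fail"`.
#' @examples
#' assess_tcc(c(45, 20, 20, 8), c(TRUE, TRUE, FALSE, FALSE))
#' @export
assess_tcc <- function(tcc_percent, macrodissectable = FALSE) {
  if (any(is.na(tcc_percent)) || any(tcc_percent < 0 | tcc_percent > 100)) {
    abort("tcc_percent must be within [0, 100] and non-missing",
          class = "panelval_validation_error")
  }
  n <- length(tcc_percent)
  macrodissectable <- rep_len(as.logical(macrodissectable), n)
  dplyr::case_when(
    tcc_percent >= 30 ~ "pass",
    tcc_percent >= 10 & macrodissectable ~ "macrodissect_then_pass",
    tcc_percent >= 10 ~ "direct_isolation",
    TRUE ~ "fail"
  )
}

#' Delta-Cq DNA amplifiability score (QC2)
#'
#' `compute_delta_cq()` scores FFPE DNA quality as the difference between the
#' mean qPCR quantification cycle of the sample and that of a non-FFPE
#' reference: delta-Cq = mean(sample Cq) - mean(control Cq).  Reactions are
#' run in triplicate; a mean over the available replicates is accepted as
#' long as at least two are present (dropout of a single qPCR well does not
#' invalidate the score).
#'
#' @param sample_cq,control_cq Numeric vectors of replicate Cq values
#'   (typically length 3); `NA` marks a failed replicate.
#' @return Single numeric delta-Cq (dimensionless cycle difference).
#' @examples
#' compute_delta_cq(c(30, 30, 30), c(27, 27, 27))  # 3
#' @export
compute_delta_cq <- function(sample_cq, control_cq) {
  for (v in list(sample_cq, control_cq)) {
    if (sum(!is.na(v)) < 2) {
      abort("each Cq triplicate needs at least 2 non-missing replicates",
            class = "panelval_replicate_error")
    }
    if (any(v <= 0, na.rm = TRUE)) {
      abort("Cq values must be positive", class = "panelval_validation_error")
    }
  }
  mean(sample_cq, na.rm = TRUE) - mean(control_cq, na.rm = TRUE)
}

#' @describeIn compute_delta_cq Classify a delta-Cq value against the two
#'   cut-offs: `< 4` is `"good"` (the vendor-recommended band), `[4, 6)` is
#'   `"acceptable"` (the extended laboratory cut-off), `>= 6` is `"fail"`
#'   unless an explicit clinical request overrides it (`"overridden"`).
#'   Both inequalities are strict, so exactly 6 fails.
#' @param delta_cq Numeric vector of delta-Cq values.
#' @param clinical_override Logical vector (recycled): sequence despite a
#'   failing delta-Cq upon explicit clinical request.
#' @export
classify_delta_cq <- function(delta_cq, clinical_override = FALSE) {
  if (any(!is.finite(delta_cq))) {
    abort("delta_cq must be finite", class = "panelval_validation_error")
  }
  override <- rep_len(as.logical(clinical_override), length(delta_cq))
  dplyr::case_when(
    delta_cq < 4 ~ "good",
    delta_cq < 6 ~ "acceptable",
    override ~ "overridden",
    TRUE ~ "fail"
  )
}

#' Library fragment-size gate (QC3)
#'
#' Libraries whose fragment-size peak falls in the closed 300-330 bp band are
#' suitable for sequencing; anything outside (notably products under 300 bp,
#' typical of over-fragmented FFPE input) fails.
#'
#' @param library_size_bp Numeric vector of library sizes in base pairs.
#' @param band Length-2 numeric, the acceptable inclusive range.
#' @return Character vector, `"pass"` or `"fail"`.
#' @examples
#' assess_library(c(315, 280, 300, 331))
#' @export
assess_library <- function(library_size_bp, band = c(300, 330)) {
  if (any(is.na(library_size_bp)) || any(library_size_bp <= 0)) {
    abort("library_size_bp must be positive and non-missing",
          class = "panelval_validation_error")
  }
  ifelse(library_size_bp >= band[1] & library_size_bp <= band[2],
         "pass", "fail")
}

#' Run-level flow-cell quality summary
#'
#' Annotates each sequencing run with a cluster-density verdict against the
#' manufacturer's optimal window of 1000-1400 clusters/mm^2, carrying the Q30
#' fraction and cluster-passing-filter percentage alongside.
#'
#' @param runs Data frame with columns `run_id`, `chemistry`
#'   (`"v2_300"`/`"v3_600"`), `cluster_density` (clusters/mm^2),
#'   `cluster_passing_filter` and `q30_fraction` (percent).
#' @param optimal_range Length-2 numeric, the optimal density window.
#' @return The input as a tibble with a `verdict` column:
#'   `"optimal"`, `"undercluster_warn"` or `"overcluster_warn"`.
#' @examples
#' runs <- tibble::tibble(
#'   run_id = c("r1", "r2"), chemistry = c("v3_600", "v2_300"),
#'   cluster_density = c(1230, 887),
#'   cluster_passing_filter = c(91, 94), q30_fraction = c(93, 95)
#' )
#' evaluate_run(runs)
#' @export
evaluate_run <- function(runs, optimal_range = c(1000, 1400)) {
  check_columns(runs, c("run_id", "cluster_density",
                        "cluster_passing_filter", "q30_fraction"), "runs")
  pct <- c(runs$cluster_passing_filter, runs$q30_fraction)
  if (any(is.na(pct)) || any(pct < 0 | pct > 100) ||
      any(runs$cluster_density < 0, na.rm = TRUE)) {
    abort("run metrics out of range: percentages in [0,100], density >= 0",
          class = "panelval_validation_error")
  }
  runs |>
    as_tibble() |>
    mutate(verdict = dplyr::case_when(
      .data$cluster_density < optimal_range[1] ~ "undercluster_warn",
      .data$cluster_density > optimal_range[2] ~ "overcluster_warn",
      TRUE ~ "optimal"
    ))
}

#' Run the full per-sample QC workflow
#'
#' Applies the three gates in order and derives the terminal workflow status
#' for each specimen.  A sample is `"sequenced"` iff QC1 did not fail, QC2 is
#' good/acceptable/overridden or was skipped (no Cq measurements, modelling
#' specimens that never underwent DNA quality assessment), and QC3 passed.
#' QC3 is only assessed when the earlier gates allow library preparation;
#' otherwise it is `"not_assessed"`.
#'
#' @param samples Sample sheet: a data frame with columns `sample_id`,
#'   `tcc_percent`, `macrodissectable`, `sample_cq_1..3`, `control_cq_1..3`,
#'   `library_size_bp`, `clinical_override` (missing override/macrodissect
#'   columns default to `FALSE`).  Extra columns are ignored.
#' @return A QC ledger tibble: one row per sample with `qc1`, `delta_cq`,
#'   `qc2`, `qc3` and `terminal_status` (`"sequenced"`/`"ngs_fail"`).
#' @examples
#' sheet <- tibble::tibble(
#'   sample_id = "s1", tcc_percent = 50, macrodissectable = FALSE,
#'   sample_cq_1 = 29, sample_cq_2 = 29.1, sample_cq_3 = 28.9,
#'   control_cq_1 = 27, control_cq_2 = 27, control_cq_3 = 27,
#'   library_size_bp = 320, clinical_override = FALSE
#' )
#' qc_workflow(sheet)
#' @export
qc_workflow <- function(samples) {
  check_columns(samples, c("sample_id", "tcc_percent",
                           paste0("sample_cq_", 1:3),
                           paste0("control_cq_", 1:3),
                           "library_size_bp"), "sample sheet")
  samples <- as_tibble(samples)
  if (!"macrodissectable" %in% names(samples)) samples$macrodissectable <- FALSE
  if (!"clinical_override" %in% names(samples)) samples$clinical_override <- FALSE

  scq <- as.matrix(samples[paste0("sample_cq_", 1:3)])
  ccq <- as.matrix(samples[paste0("control_cq_", 1:3)])
  qc2_skipped <- rowSums(!is.na(scq)) == 0 | rowSums(!is.na(ccq)) == 0

  delta <- rep(NA_real_, nrow(samples))
  for (i in which(!qc2_skipped)) {
    delta[i] <- compute_delta_cq(scq[i, ], ccq[i, ])
  }

  qc1 <- assess_tcc(samples$tcc_percent, samples$macrodissectable)
  qc2 <- rep("not_assessed", nrow(samples))
  qc2[!qc2_skipped] <- classify_delta_cq(delta[!qc2_skipped],
                                         samples$clinical_override[!qc2_skipped])
  qc2_ok <- qc2 %in% c("good", "acceptable", "overridden", "not_assessed")

  qc3 <- rep("not_assessed", nrow(samples))
  assess3 <- qc1 != "fail" & qc2_ok & !is.na(samples$library_size_bp)
  qc3[assess3] <- assess_library(samples$library_size_bp[assess3])

  tibble(
    sample_id = samples$sample_id,
    qc1 = qc1,
    delta_cq = delta,
    qc2 = qc2,
    qc3 = qc3,
    terminal_status = ifelse(qc1 != "fail" & qc2_ok & qc3 == "pass",
                             "sequenced", "ngs_fail")
  )
}

#' Read a sample sheet / write a QC ledger
#'
#' Plain-TSV I/O for the QC stage: the sample sheet is the workflow input
#' contract of [qc_workflow()], the ledger its output.
#'
#' @param path File path.
#' @return `read_sample_sheet()` returns a tibble.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("sample sheet not found: %s", path), class = "panelval_io_error")
  }
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' @rdname read_sample_sheet
#' @param ledger QC ledger tibble from [qc_workflow()].
#' @export
write_qc_ledger <- function(ledger, path) {
  readr::write_tsv(ledger, path, progress = FALSE)
  invisible(path)
}
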