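#' Configuration for the synthetic FFPE cohort generator
#'
#' Bundles the statistical structure of the emulated clinical cohort: the
#' tumor-type and specimen mixes, the joint distribution of delta-Cq band
#' and terminal outcome, the per-gene and per-consequence variant spectra,
#' the observed VAF range, and the sequencing-noise knobs.  Defaults encode
#' the 399-sample clinical cohort the package emulates: a gastrointestinal-
#' dominated tumor mix, roughly two-thirds of samples sequencing
#' successfully, a TP53/KRAS/APC/PIK3CA-led gene spectrum and an
#' 81/9/7-percent missense/stop-gain/frameshift consequence split with the
#' minor in-frame/splice/start-lost classes filling the residual mass.
#'
#' @param n_samples Cohort size (default 399).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @param tumor_type_mix,specimen_mix Named probability vectors.
#' @param qc_strata Named probability vector over `"<band>:<outcome>"` cells,
#'   bands `good` (delta-Cq < 4), `acceptable` (4-6), `fail` (> 6),
#'   `unassessed`; outcomes `detected`, `not_detected`, `ngs_fail`.
#' @param gene_mix Named probability vector over panel genes.
#' @param consequence_mix,clinical_class_mix Named probability vectors over
#'   the controlled vocabularies.
#' @param vaf_range Length-2 interval for planted VAFs (default the observed
#'   detection range 3.23-68.97%).
#' @param depth_model `list(meanlog, sdlog)` of the log-normal per-pool
#'   depth distribution (default centred on 2500x per pool).
#' @param dropout_rate Probability that a non-primary planted variant is
#'   missed in one pool (exercises the present-in-both-pools rule).
#' @param strand_bias_rate Probability that a non-primary planted variant
#'   carries an upstream strand-bias flag.
#' @param fp_rate Per-sample probability of a spurious artifact call (always
#'   defective: sub-3% VAF or single-pool, the kind the dual-pool filter is
#'   designed to stop).
#' @param extra_variant_rate Poisson mean of additional variants beyond the
#'   first in a variant-positive sample (372 variants across 194 positive
#'   samples is about 1.9 per sample).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 399,
                          seed = 1,
                          tumor_type_mix = default_tumor_type_mix(),
                          specimen_mix = default_specimen_mix(),
                          qc_strata = default_qc_strata(),
                          gene_mix = default_gene_mix(),
                          consequence_mix = default_consequence_mix(),
                          clinical_class_mix = default_clinical_class_mix(),
                          vaf_range = c(0.0323, 0.6897),
                          depth_model = list(meanlog = log(2500), sdlog = 0.4),
                          dropout_rate = 0.02,
                          strand_bias_rate = 0.01,
                          fp_rate = 0.02,
                          extra_variant_rate = 0.9) {
  stopifnot(n_samples >= 1, length(seed) == 1)
  check_distribution(tumor_type_mix, "tumor_type_mix")
  check_distribution(specimen_mix, "specimen_mix")
  check_distribution(qc_strata, "qc_strata")
  check_distribution(gene_mix, "gene_mix")
  check_distribution(consequence_mix, "consequence_mix")
  check_distribution(clinical_class_mix, "clinical_class_mix")
  if (length(vaf_range) != 2 || vaf_range[1] >= vaf_range[2] ||
      vaf_range[1] < 0 || vaf_range[2] > 1) {
    abort("vaf_range must be an increasing interval within [0, 1]",
          class = "panelval_config_error")
  }
  rates <- c(dropout_rate, strand_bias_rate, fp_rate)
  if (any(rates < 0) || any(rates > 1)) {
    abort("rates must lie in [0, 1]", class = "panelval_config_error")
  }
  bad_csq <- setdiff(names(consequence_mix), consequence_vocabulary())
  if (length(bad_csq) > 0) {
    abort(sprintf("consequence_mix has unknown classes: %s",
                  paste(bad_csq, collapse = ", ")),
          class = "panelval_config_error")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), seed = as.integer(seed),
      tumor_type_mix = tumor_type_mix, specimen_mix = specimen_mix,
      qc_strata = qc_strata, gene_mix = gene_mix,
      consequence_mix = consequence_mix,
      clinical_class_mix = clinical_class_mix,
      vaf_range = vaf_range, depth_model = depth_model,
      dropout_rate = dropout_rate, strand_bias_rate = strand_bias_rate,
      fp_rate = fp_rate, extra_variant_rate = extra_variant_rate
    ),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_tumor_type_mix <- function() {
  n <- c(
    Gastrointestinal = 115, Hematologic = 73, Lung = 51, Gynecological = 38,
    Breast = 33, Genitourinary = 20, `Head and Neck` = 19, Melanoma = 15,
    `Central Nervous System` = 10, `Other solid tumor` = 25
  )
  n / sum(n)
}

#' @rdname cohort_config
#' @export
default_specimen_mix <- function() {
  n <- c(cytology = 17, resection = 100, endoscopy = 25, biopsy = 257)
  n / sum(n)
}

#' @rdname cohort_config
#' @export
default_qc_strata <- function() {
  n <- c(
    "good:detected" = 159, "good:not_detected" = 59, "good:ngs_fail" = 26,
    "acceptable:detected" = 19, "acceptable:not_detected" = 5,
    "acceptable:ngs_fail" = 27,
    "fail:detected" = 3, "fail:not_detected" = 2, "fail:ngs_fail" = 62,
    "unassessed:detected" = 12, "unassessed:not_detected" = 4,
    "unassessed:ngs_fail" = 21
  )
  n / sum(n)
}

#' @rdname cohort_config
#' @export
default_gene_mix <- function() {
  p <- c(
    TP53 = 0.28, KRAS = 0.16, APC = 0.10, PIK3CA = 0.08, MET = 0.05,
    BRAF = 0.04, SMAD4 = 0.03,
    KIT = 0.02, PTEN = 0.02, NRAS = 0.02, CTNNB1 = 0.02, FBXW7 = 0.02,
    CDH1 = 0.02, ERBB2 = 0.02,
    GNAS = 0.01, MAP2K1 = 0.01, STK11 = 0.01, EGFR = 0.01, PDGFRA = 0.01,
    MSH6 = 0.01, FGFR2 = 0.01, GNAQ = 0.01, SRC = 0.01
  )
  p / sum(p)
}

#' @rdname cohort_config
#' @export
default_consequence_mix <- function() {
  # dominant classes 81/9/7%; the minor classes (in-frame deletion, in-frame
  # insertion, splice region, start lost; reported 2/1/1/1%) are rescaled to
  # fill the residual 3% mass so the distribution is proper
  major <- c("missense" = 0.81, "stop gain" = 0.09, "frameshift" = 0.07)
  minor <- c("inframe deletion" = 2, "inframe insertion" = 1,
             "splice region" = 1, "start lost" = 1)
  c(major, minor / sum(minor) * (1 - sum(major)))
}

#' @rdname cohort_config
#' @export
default_clinical_class_mix <- function() {
  c("pathogenic" = 0.78, "likely pathogenic" = 0.01, "VUS" = 0.19,
    "benign" = 0.01, "likely benign" = 0.01)
}

draw_from <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

# Random allele pair for a consequence class (SNV for point classes, short
# indels for frameshift / in-frame classes).
alleles_for_consequence <- function(consequence) {
  bases <- c("A", "C", "G", "T")
  ref1 <- sample(bases, 1)
  switch(
    consequence,
    "frameshift" = list(ref = paste0(ref1, sample(bases, 1)), alt = ref1),
    "inframe deletion" = list(ref = paste0(ref1, paste(sample(bases, 3, replace = TRUE),
                                                       collapse = "")),
                              alt = ref1),
    "inframe insertion" = list(ref = ref1,
                               alt = paste0(ref1, paste(sample(bases, 3, replace = TRUE),
                                                        collapse = ""))),
    list(ref = ref1, alt = sample(setdiff(bases, ref1), 1))
  )
}

#' Generate a complete synthetic FFPE cohort
#'
#' Draws `n_samples` specimens from the configured joint quality-control
#' strata, builds a sample sheet whose Cq triplicates, override flags and
#' library sizes realise exactly the drawn delta-Cq band and terminal
#' outcome, plants variants (per the gene / consequence / clinical-class
#' mixes and VAF range) into the dual-pool call sets of variant-positive
#' samples, adds defective artifact calls at `fp_rate`, and simulates
#' per-amplicon coverage.  The first planted variant of each positive
#' sample is guaranteed to PASS the dual-pool filter (it is what makes the
#' sample "detected"); additional variants are subject to the dropout and
#' strand-bias knobs.
#'
#' @param config A [cohort_config()].
#' @param panel A [panel_def] (default the bundled panel).
#' @param dir Optional output directory; when given, writes
#'   `sample_sheet.tsv`, `coverage.tsv`, `truth_samples.tsv`,
#'   `truth_variants.tsv` and per-sample pool VCFs under `vcf/`.
#' @return List with tibbles `sample_sheet`, `pool_calls`, `coverage`,
#'   `truth_samples`, `truth_variants`, and the `config`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_samples = 40, seed = 7))
#' head(cohort$sample_sheet)
#' @export
simulate_cohort <- function(config, panel = tst26_panel(), dir = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(panel, "panel_def"))
  set.seed(config$seed)
  n <- config$n_samples
  sid <- sprintf("S%04d", seq_len(n))

  stratum <- draw_from(n, config$qc_strata)
  band <- sub(":.*$", "", stratum)
  outcome <- sub("^.*:", "", stratum)

  tumor_type <- draw_from(n, config$tumor_type_mix)
  specimen_type <- draw_from(n, config$specimen_mix)

  # QC1: the cohort's failures are realised at QC2/QC3, so TCC always stays
  # at or above the 10% floor; a fraction sits in the 10-30 macrodissection
  # band to exercise those paths
  tcc_path <- sample(c("high", "macro", "direct"), n, replace = TRUE,
                     prob = c(0.80, 0.15, 0.05))
  tcc <- ifelse(tcc_path == "high", round(runif(n, 30, 90)),
                round(runif(n, 10, 29)))
  macrodissectable <- tcc_path != "direct"

  # QC2: control triplicates around cycle 27; sample triplicates placed at
  # control mean + target delta with mean-zero replicate noise, so the
  # realised delta-Cq lands exactly in the drawn band
  delta_target <- dplyr::case_when(
    band == "good" ~ runif(n, 1.0, 3.9),
    band == "acceptable" ~ runif(n, 4.05, 5.9),
    band == "fail" ~ runif(n, 6.1, 9.0),
    TRUE ~ NA_real_
  )
  ccq <- matrix(rnorm(3 * n, 27, 0.15), ncol = 3)
  eps <- matrix(rnorm(3 * n, 0, 0.10), ncol = 3)
  eps <- eps - rowMeans(eps)
  scq <- rowMeans(ccq) + delta_target + eps
  scq[is.na(delta_target), ] <- NA_real_
  ccq[is.na(delta_target), ] <- NA_real_

  clinical_override <- band == "fail" & outcome != "ngs_fail"

  # QC3: samples that must fail despite a passing (or skipped) delta-Cq gate
  # do so on library size; everything else sits in the 300-330 band
  fail_at_qc3 <- outcome == "ngs_fail" & band != "fail"
  library_size <- ifelse(fail_at_qc3, round(runif(n, 250, 295)),
                         round(runif(n, 300, 330)))

  sample_sheet <- tibble(
    sample_id = sid, specimen_type = specimen_type, tumor_type = tumor_type,
    tcc_percent = tcc, macrodissectable = macrodissectable,
    sample_cq_1 = scq[, 1], sample_cq_2 = scq[, 2], sample_cq_3 = scq[, 3],
    control_cq_1 = ccq[, 1], control_cq_2 = ccq[, 2], control_cq_3 = ccq[, 3],
    library_size_bp = library_size, clinical_override = clinical_override
  )

  truth_samples <- tibble(
    sample_id = sid, qc_band = band, expected_outcome = outcome,
    expected_terminal = ifelse(outcome == "ngs_fail", "ngs_fail", "sequenced")
  )

  # variants for variant-positive sequenced samples
  variants <- purrr::map(which(outcome == "detected"), function(i) {
    n_var <- 1L + rpois(1, config$extra_variant_rate)
    genes <- draw_from(n_var, config$gene_mix)
    purrr::map(seq_len(n_var), function(k) {
      g <- genes[k]
      regions <- panel$exons[panel$exons$gene_symbol == g, ]
      r <- regions[sample(nrow(regions), 1), ]
      csq <- draw_from(1, config$consequence_mix)
      al <- alleles_for_consequence(csq)
      vaf <- runif(1, config$vaf_range[1], config$vaf_range[2])
      dp <- round(rlnorm(2, config$depth_model$meanlog,
                         config$depth_model$sdlog))
      primary <- k == 1L
      if (primary) dp <- pmax(dp, 501)
      dropped <- if (primary) "none" else if (runif(1) < config$dropout_rate)
        sample(c("A", "B"), 1) else "none"
      sb <- if (primary) FALSE else runif(1) < config$strand_bias_rate
      tibble(
        sample_id = sid[i], gene = g, exon_label = r$exon_label,
        contig = r$contig, pos = as.integer(r$start + sample(50:200, 1)),
        ref = al$ref, alt = al$alt, vaf = vaf,
        depth_a = ifelse(dropped == "A", NA_real_, dp[1]),
        depth_b = ifelse(dropped == "B", NA_real_, dp[2]),
        strand_bias_flagged = sb,
        consequence = csq,
        clinical_class = draw_from(1, config$clinical_class_mix),
        origin = "planted", primary = primary
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  # defective artifact calls on sequenced samples: sub-3% VAF or single-pool
  sequenced <- which(outcome != "ngs_fail")
  artifacts <- purrr::map(sequenced[runif(length(sequenced)) < config$fp_rate],
                          function(i) {
    regions <- panel$exons
    r <- regions[sample(nrow(regions), 1), ]
    defect <- sample(c("low_vaf", "single_pool"), 1)
    dp <- round(rlnorm(2, config$depth_model$meanlog, config$depth_model$sdlog))
    tibble(
      sample_id = sid[i], gene = r$gene_symbol, exon_label = r$exon_label,
      contig = r$contig, pos = as.integer(r$start + sample(50:200, 1)),
      ref = "G", alt = "T",
      vaf = if (defect == "low_vaf") runif(1, 0.005, 0.029)
            else runif(1, 0.031, 0.10),
      depth_a = dp[1],
      depth_b = if (defect == "single_pool") NA_real_ else dp[2],
      strand_bias_flagged = FALSE,
      consequence = "missense", clinical_class = "VUS",
      origin = "artifact", primary = FALSE
    )
  }) |> purrr::list_rbind()

  empty_truth <- tibble(
    sample_id = character(), gene = character(), exon_label = character(),
    contig = character(), pos = integer(), ref = character(),
    alt = character(), vaf = numeric(), depth_a = numeric(),
    depth_b = numeric(), strand_bias_flagged = logical(),
    consequence = character(), clinical_class = character(),
    origin = character(), primary = logical()
  )
  truth_variants <- dplyr::bind_rows(empty_truth, variants, artifacts) |>
    mutate(
      cumulative_depth = dplyr::coalesce(.data$depth_a, 0) +
        dplyr::coalesce(.data$depth_b, 0),
      expected_status = dplyr::case_when(
        .data$vaf < 0.03 ~ "EXCLUDED",
        !is.na(.data$depth_a) & !is.na(.data$depth_b) &
          .data$cumulative_depth >= 1000 &
          !.data$strand_bias_flagged ~ "PASS",
        TRUE ~ "REVIEW"
      )
    )

  pool_calls <- truth_variants |>
    tidyr::pivot_longer(c("depth_a", "depth_b"), names_to = "pool",
                        values_to = "depth") |>
    filter(!is.na(.data$depth)) |>
    mutate(pool = toupper(sub("depth_", "", .data$pool))) |>
    select("sample_id", "pool", "contig", "pos", "ref", "alt", "depth",
           "vaf", "strand_bias_flagged", "consequence", "clinical_class")

  coverage <- simulate_coverage(panel, depth_model = config$depth_model,
                                n_samples = 0, seed = NULL,
                                sample_ids = sid[sequenced])

  out <- list(sample_sheet = sample_sheet, pool_calls = pool_calls,
              coverage = coverage, truth_samples = truth_samples,
              truth_variants = truth_variants, config = config)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' @param cohort List from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$sample_sheet, file.path(dir, "sample_sheet.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$coverage, file.path(dir, "coverage.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth_samples, file.path(dir, "truth_samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth_variants, file.path(dir, "truth_variants.tsv"),
                   progress = FALSE)
  sequenced <- cohort$truth_samples$sample_id[
    cohort$truth_samples$expected_terminal == "sequenced"]
  for (s in sequenced) {
    for (p in c("A", "B")) {
      calls <- cohort$pool_calls |>
        filter(.data$sample_id == s, .data$pool == p)
      write_pool_vcf(calls, file.path(dir, "vcf",
                                      sprintf("%s.pool%s.vcf", s, p)),
                     sample_id = s)
    }
  }
  invisible(dir)
}

#' Per-amplicon coverage simulation with optional planted low regions
#'
#' Draws one mean depth per amplicon (per sample when `sample_ids` are
#' given) from the log-normal depth model, then overrides the amplicon
#' means of any planted region/pool with a fixed low value — the mechanism
#' used to reproduce under-covered exon scenarios.
#'
#' @param panel A [panel_def].
#' @param depth_model `list(meanlog, sdlog)`.
#' @param n_samples Number of samples (ignored when `sample_ids` given).
#' @param plant_low Optional tibble with columns `gene`, `exon_label`,
#'   `pool` (`"A"`, `"B"` or `NA` for both) and `mean_depth`: every amplicon
#'   of that region (and pool) is set to `mean_depth`.
#' @param seed Optional seed (`NULL` to use the current RNG state).
#' @param sample_ids Optional explicit sample ids.
#' @return Coverage tibble: `sample_id`, `amplicon_id`, `pool`,
#'   `mean_depth`.
#' @export
simulate_coverage <- function(panel, depth_model = list(meanlog = log(2500),
                                                        sdlog = 0.4),
                              n_samples = 1, plant_low = NULL, seed = 1,
                              sample_ids = NULL) {
  stopifnot(inherits(panel, "panel_def"))
  if (!is.null(seed)) set.seed(seed)
  sample_ids <- sample_ids %||% sprintf("S%04d", seq_len(n_samples))
  amps <- panel$amplicons
  cov <- tidyr::expand_grid(sample_id = sample_ids,
                            amplicon_id = amps$amplicon_id) |>
    left_join(amps |> select("amplicon_id", "pool", "gene_symbol",
                             "exon_label"),
              by = "amplicon_id") |>
    mutate(mean_depth = round(rlnorm(dplyr::n(), depth_model$meanlog,
                                     depth_model$sdlog)))
  if (!is.null(plant_low)) {
    plant_low <- as_tibble(plant_low)
    check_columns(plant_low, c("gene", "exon_label", "mean_depth"),
                  "plant_low")
    if (!"pool" %in% names(plant_low)) plant_low$pool <- NA_character_
    known <- paste(panel$exons$gene_symbol, panel$exons$exon_label)
    bad <- setdiff(paste(plant_low$gene, plant_low$exon_label), known)
    if (length(bad) > 0) {
      abort(sprintf("planted exon region(s) not in panel: %s",
                    paste(bad, collapse = ", ")),
            class = "panelval_config_error")
    }
    for (i in seq_len(nrow(plant_low))) {
      hit <- cov$gene_symbol == plant_low$gene[i] &
        cov$exon_label == plant_low$exon_label[i] &
        (is.na(plant_low$pool[i]) | cov$pool == plant_low$pool[i])
      cov$mean_depth[hit] <- plant_low$mean_depth[i]
    }
  }
  cov |> select("sample_id", "amplicon_id", "pool", "mean_depth")
}

#' Inter-laboratory validation truth design
#'
#' Builds the 48-sample, 3-center agreement design: `n_mutated` samples each
#' carry one known KRAS/NRAS/BRAF variant per the reference standard, the
#' rest are wild-type; every sample is assessed once per center, giving
#' `n_samples * n_centers` outcomes.  Error-injection knobs flip exactly
#' `n_miss` mutated outcomes to panel-not-detected and `n_fp` wild-type
#' outcomes to panel-detected, so any 2x2 agreement table can be realised.
#'
#' @param seed Integer seed controlling gene assignment and injection
#'   positions.
#' @param n_miss,n_fp Number of missed / spurious panel outcomes to inject.
#' @param n_samples,n_mutated,n_centers Design dimensions (defaults 48 / 29
#'   / 3).
#' @return Truth tibble: `sample_id`, `center_id`, `replicate`, `target`,
#'   `reference_result`, `panel_result`.
#' @examples
#' truth <- simulate_validation_set(seed = 1, n_miss = 7, n_fp = 3)
#' tally_concordance(truth)
#' @export
simulate_validation_set <- function(seed = 1, n_miss = 0, n_fp = 0,
                                    n_samples = 48, n_mutated = 29,
                                    n_centers = 3) {
  stopifnot(n_mutated <= n_samples,
            n_miss <= n_mutated * n_centers,
            n_fp <= (n_samples - n_mutated) * n_centers)
  set.seed(seed)
  genes <- sample(c("KRAS", "NRAS", "BRAF"), n_mutated, replace = TRUE,
                  prob = c(0.65, 0.15, 0.20))
  design <- tidyr::expand_grid(
    sample = seq_len(n_samples),
    center = seq_len(n_centers)
  ) |>
    mutate(
      sample_id = sprintf("V%02d", .data$sample),
      center_id = sprintf("center%d", .data$center),
      replicate = .data$center,
      target = ifelse(.data$sample <= n_mutated, genes[.data$sample],
                      "wild-type"),
      reference_result = ifelse(.data$sample <= n_mutated, "detected",
                                "not_detected"),
      panel_result = .data$reference_result
    )
  mut_rows <- which(design$reference_result == "detected")
  wt_rows <- which(design$reference_result == "not_detected")
  if (n_miss > 0) {
    design$panel_result[sample(mut_rows, n_miss)] <- "not_detected"
  }
  if (n_fp > 0) {
    design$panel_result[sample(wt_rows, n_fp)] <- "detected"
  }
  design |>
    select("sample_id", "center_id", "replicate", "target",
           "reference_result", "panel_result")
}

#' Validation cohort at the variant-call level
#'
#' Generates per-outcome dual-pool call sets for an inter-laboratory design
#' so that the full merge-filter-concordance pipeline can be exercised end
#' to end.  Mutated samples carry one KRAS/NRAS/BRAF variant; with
#' probability `miss_rate` an outcome's call pair is generated with a
#' defect (single pool, sub-3% VAF, sub-1000x cumulative depth, or a
#' strand-bias flag) that the PASS filter must catch, so the target
#' sensitivity is `1 - miss_rate`.  Wild-type outcomes acquire a clean
#' spurious dual-pool call with probability `fp_rate` (target specificity
#' `1 - fp_rate`).
#'
#' @param n_samples,n_centers Design dimensions.
#' @param miss_rate,fp_rate Per-outcome error probabilities.
#' @param seed Integer seed.
#' @param panel A [panel_def].
#' @param mutated_fraction Fraction of samples carrying a variant (default
#'   29/48).
#' @return List with `calls` (per-outcome pool calls keyed by `sample_id`,
#'   `center_id`) and `design` (reference-standard truth per outcome).
#' @export
simulate_validation_calls <- function(n_samples = 48, n_centers = 3,
                                      miss_rate = 0, fp_rate = 0, seed = 1,
                                      panel = tst26_panel(),
                                      mutated_fraction = 29 / 48) {
  set.seed(seed)
  n_mut <- round(n_samples * mutated_fraction)
  genes <- sample(c("KRAS", "NRAS", "BRAF"), n_mut, replace = TRUE,
                  prob = c(0.65, 0.15, 0.20))
  # one locus per mutated sample, fixed across centers
  loci <- purrr::map(genes, function(g) {
    regions <- panel$exons[panel$exons$gene_symbol == g, ]
    r <- regions[sample(nrow(regions), 1), ]
    al <- alleles_for_consequence("missense")
    list(contig = r$contig, pos = as.integer(r$start + sample(50:200, 1)),
         ref = al$ref, alt = al$alt)
  })
  design <- tidyr::expand_grid(sample = seq_len(n_samples),
                               center = seq_len(n_centers)) |>
    mutate(
      sample_id = sprintf("V%03d", .data$sample),
      center_id = sprintf("center%d", .data$center),
      target = ifelse(.data$sample <= n_mut, genes[.data$sample],
                      "wild-type"),
      reference_result = ifelse(.data$sample <= n_mut, "detected",
                                "not_detected"),
      miss = .data$reference_result == "detected" & runif(dplyr::n()) < miss_rate,
      fp = .data$reference_result == "not_detected" & runif(dplyr::n()) < fp_rate,
      defect = ifelse(.data$miss,
                      sample(c("single_pool", "low_vaf", "low_depth",
                               "strand_bias"), dplyr::n(), replace = TRUE),
                      "none")
    )

  make_calls <- function(row) {
    is_mut <- row$reference_result == "detected"
    if (!is_mut && !row$fp) return(NULL)
    if (is_mut) {
      locus <- loci[[row$sample]]
    } else {
      # spurious artifact call at a sample-specific KRAS locus
      regions <- panel$exons[panel$exons$gene_symbol == "KRAS", ]
      r <- regions[sample(nrow(regions), 1), ]
      locus <- list(contig = r$contig,
                    pos = as.integer(r$start + sample(50:200, 1)),
                    ref = "G", alt = "A")
    }
    vaf <- runif(1, 0.05, 0.6)
    dp <- pmax(round(rlnorm(2, log(2500), 0.4)), 501)
    sb <- FALSE
    pools <- c("A", "B")
    if (is_mut && row$defect == "single_pool") pools <- sample(c("A", "B"), 1)
    if (is_mut && row$defect == "low_vaf") vaf <- runif(1, 0.005, 0.029)
    if (is_mut && row$defect == "low_depth") dp <- round(runif(2, 150, 450))
    if (is_mut && row$defect == "strand_bias") sb <- TRUE
    tibble(
      sample_id = row$sample_id, center_id = row$center_id,
      pool = pools,
      contig = locus$contig, pos = locus$pos, ref = locus$ref,
      alt = locus$alt,
      depth = dp[seq_along(pools)], vaf = vaf, strand_bias_flagged = sb,
      consequence = "missense", clinical_class = "pathogenic"
    )
  }
  calls <- design |>
    dplyr::rowwise() |>
    dplyr::group_split() |>
    purrr::map(make_calls) |>
    purrr::list_rbind()

  list(
    calls = calls,
    design = design |>
      select("sample_id", "center_id", "target", "reference_result")
  )
}
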