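# Shared fixtures and independent oracles for the test suite.

# Independent Clopper-Pearson oracle: inverts the two binomial tail sums
# with uniroot, never touching Beta quantiles (the implementation's route).
# lower solves P(X >= x | p) = alpha/2, upper solves P(X <= x | p) = alpha/2.
cp_tail_oracle <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  upper_tail <- function(p) sum(dbinom(x:n, n, p)) - alpha / 2
  lower_tail <- function(p) sum(dbinom(0:x, n, p)) - alpha / 2
  lo <- if (x == 0) 0 else uniroot(upper_tail, c(1e-12, 1 - 1e-12),
                                   tol = 1e-10)$root
  hi <- if (x == n) 1 else uniroot(lower_tail, c(1e-12, 1 - 1e-12),
                                   tol = 1e-10)$root
  c(lower = lo, upper = hi)
}

# 2x2 outcome records with the given cell counts, shuffled deterministically.
make_truth_records <- function(tp, fp, fn, tn, seed = 42) {
  records <- tibble::tibble(
    reference_result = rep(c("detected", "not_detected", "detected",
                             "not_detected"), c(tp, fp, fn, tn)),
    panel_result = rep(c("detected", "detected", "not_detected",
                         "not_detected"), c(tp, fp, fn, tn))
  )
  withr::with_seed(seed, records[sample(nrow(records)), ])
}

# Minimal 1-gene/1-exon/1-amplicon (or dual-pool) manifest written to disk.
write_tiny_manifest <- function(dir, dual_pool = FALSE,
                                amp_start = 90L, amp_end = 310L) {
  bed <- file.path(dir, "tiny.bed")
  tsv <- file.path(dir, "tiny.tsv")
  n_amp <- if (dual_pool) 2L else 1L
  bed_lines <- sprintf("chr1\t%d\t%d\tamp%02d",
                       amp_start + 10L * (seq_len(n_amp) - 1L),
                       amp_end + 10L * (seq_len(n_amp) - 1L),
                       seq_len(n_amp))
  writeLines(bed_lines, bed)
  meta <- c(
    "amplicon_id\tpool\tgene\texon_label\taccession\texons\texon_start\texon_end",
    sprintf("amp%02d\t%s\tGENE1\t1\tNG_000001.1\t1\t100\t300",
            seq_len(n_amp), c("A", "B")[seq_len(n_amp)])
  )
  writeLines(meta, tsv)
  list(bed = bed, tsv = tsv)
}

# Random merged-call table used by the filter property suite.
random_merged_calls <- function(n, seed = 1) {
  withr::with_seed(seed, {
    in_a <- runif(n) < 0.9
    in_b <- runif(n) < 0.9
    in_a[!in_a & !in_b] <- TRUE  # every call exists in at least one pool
    depth_a <- ifelse(in_a, round(runif(n, 0, 1500)), NA_real_)
    depth_b <- ifelse(in_b, round(runif(n, 0, 1500)), NA_real_)
    cum <- dplyr::coalesce(depth_a, 0) + dplyr::coalesce(depth_b, 0)
    vaf_a <- ifelse(in_a, runif(n, 0, 0.8), NA_real_)
    vaf_b <- ifelse(in_b, runif(n, 0, 0.8), NA_real_)
    tibble::tibble(
      contig = "chr1", pos = seq_len(n), ref = "G", alt = "A",
      depth_a = depth_a, vaf_a = vaf_a, depth_b = depth_b, vaf_b = vaf_b,
      in_pool_a = in_a, in_pool_b = in_b,
      cumulative_depth = cum,
      combined_vaf = ifelse(
        cum > 0,
        (dplyr::coalesce(depth_a, 0) * dplyr::coalesce(vaf_a, 0) +
           dplyr::coalesce(depth_b, 0) * dplyr::coalesce(vaf_b, 0)) / cum,
        rowMeans(cbind(vaf_a, vaf_b), na.rm = TRUE)
      ),
      strand_bias_flagged = runif(n) < 0.1
    )
  })
}
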