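pool_call <- function(pos = 100L, ref = "G", alt = "A", depth = 600,
                      vaf = 0.1, sb = FALSE, contig = "chr12") {
  tibble::tibble(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
                 depth = depth, vaf = vaf, strand_bias_flagged = sb)
}

test_that("merging computes cumulative depth and depth-weighted VAF", {
  m <- merge_pools(pool_call(depth = 620, vaf = 0.12),
                   pool_call(depth = 540, vaf = 0.10))
  expect_equal(nrow(m), 1L)
  expect_equal(m$cumulative_depth, 1160)
  expect_equal(m$combined_vaf, (620 * 0.12 + 540 * 0.10) / 1160,
               tolerance = 1e-12)
  expect_true(m$in_pool_a && m$in_pool_b)
  # per-pool provenance is recoverable from the merged record
  expect_equal(c(m$depth_a, m$vaf_a, m$depth_b, m$vaf_b),
               c(620, 0.12, 540, 0.10))
})

test_that("one-sided and empty call sets merge correctly", {
  m <- merge_pools(pool_call(), pool_call(pos = 999L))
  expect_equal(nrow(m), 2L)
  expect_equal(sum(m$in_pool_a & !m$in_pool_b), 1L)
  expect_equal(sum(m$in_pool_b & !m$in_pool_a), 1L)
  empty <- pool_call()[0, ]
  expect_equal(nrow(merge_pools(empty, empty)), 0L)
  expect_equal(nrow(merge_pools(pool_call(), empty)), 1L)
})

test_that("indel representations match after prefix/suffix trimming", {
  # same 1 bp deletion written two ways by the two callers
  a <- pool_call(pos = 100L, ref = "CAGG", alt = "CAG")
  b <- pool_call(pos = 100L, ref = "CAGGT", alt = "CAGT")
  m <- merge_pools(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos, 101L)
  expect_equal(c(m$ref, m$alt), c("AG", "A"))
})

test_that("pool label mismatches are rejected", {
  bad <- pool_call() |> dplyr::mutate(pool = "B")
  expect_error(merge_pools(bad, pool_call()),
               class = "panelval_validation_error")
})

test_that("PASS, REVIEW and EXCLUDED are assigned per the reporting rule", {
  both_ok <- merge_pools(pool_call(depth = 620, vaf = 0.12),
                         pool_call(depth = 540, vaf = 0.10))
  expect_equal(apply_pass_filter(both_ok)$filter_status, "PASS")

  low_vaf <- merge_pools(pool_call(depth = 900, vaf = 0.025),
                         pool_call(depth = 900, vaf = 0.025))
  expect_equal(apply_pass_filter(low_vaf)$filter_status, "EXCLUDED")

  one_pool <- merge_pools(pool_call(depth = 1500, vaf = 0.20), pool_call()[0, ])
  expect_equal(apply_pass_filter(one_pool)$filter_status, "REVIEW")

  biased <- merge_pools(pool_call(depth = 620, vaf = 0.11, sb = TRUE),
                        pool_call(depth = 540, vaf = 0.11))
  expect_equal(apply_pass_filter(biased)$filter_status, "REVIEW")

  shallow <- merge_pools(pool_call(depth = 400, vaf = 0.2),
                         pool_call(depth = 400, vaf = 0.2))
  expect_equal(apply_pass_filter(shallow)$filter_status, "REVIEW")
})

test_that("the strict per-pool depth reading is available as a switch", {
  lopsided <- merge_pools(pool_call(depth = 700, vaf = 0.2),
                          pool_call(depth = 400, vaf = 0.2))
  expect_equal(apply_pass_filter(lopsided)$filter_status, "PASS")
  expect_equal(apply_pass_filter(lopsided, per_pool_min = TRUE)$filter_status,
               "REVIEW")
})

test_that("filter statuses partition randomized calls per the predicates", {
  merged <- random_merged_calls(10000, seed = 99)
  out <- apply_pass_filter(merged)
  expect_equal(nrow(out), nrow(merged))
  expect_true(all(out$filter_status %in% c("PASS", "REVIEW", "EXCLUDED")))

  pass_predicate <- merged$in_pool_a & merged$in_pool_b &
    merged$cumulative_depth >= 1000 & merged$combined_vaf >= 0.03 &
    !merged$strand_bias_flagged
  excluded_predicate <- merged$combined_vaf < 0.03
  expect_equal(out$filter_status == "PASS", pass_predicate)
  expect_equal(out$filter_status == "EXCLUDED", excluded_predicate)
  expect_equal(out$filter_status == "REVIEW",
               !pass_predicate & !excluded_predicate)

  # the two phrasings of the depth rule agree: cumulative >= 1000x across
  # the two pools iff the per-pool average >= 500x
  both <- merged$in_pool_a & merged$in_pool_b
  mean_reading <- (merged$depth_a + merged$depth_b) / 2 >= 500
  cumulative_reading <- merged$cumulative_depth >= 1000
  expect_equal(cumulative_reading[both], mean_reading[both])
})

test_that("consequence terms normalize onto the controlled vocabulary", {
  expect_equal(normalize_consequence("missense_variant"), "missense")
  expect_equal(normalize_consequence("stop_gained"), "stop gain")
  expect_equal(
    normalize_consequence(c("frameshift_variant", "splice_donor_variant",
                            "conservative_inframe_deletion", "Missense")),
    c("frameshift", "splice region", "inframe deletion", "missense")
  )
  expect_error(normalize_consequence("regulatory_region_variant"),
               class = "panelval_vocabulary_error")
  expect_true(all(normalize_consequence(consequence_vocabulary()) ==
                    consequence_vocabulary()))
})

test_that("spectrum summaries report ordered counts and percentages", {
  calls <- tibble::tibble(
    consequence = rep(c("missense", "stop gain", "frameshift", "start lost"),
                      c(81, 9, 7, 3))
  )
  spec <- summarize_spectrum(calls, "consequence")
  expect_equal(spec$value[1:3], c("missense", "stop gain", "frameshift"))
  expect_equal(spec$percent[1:3], c(81, 9, 7))
  expect_equal(sum(spec$percent), 100)
  expect_equal(sum(spec$n), nrow(calls))

  single <- summarize_spectrum(tibble::tibble(gene = "KRAS"), "gene")
  expect_equal(single$percent, 100)
  expect_equal(nrow(summarize_spectrum(calls[0, ], "consequence")), 0L)
})

test_that("pool VCFs round-trip through the reader", {
  calls <- tibble::tibble(
    contig = c("chr12", "chr12", "chr17"),
    pos = c(25398284L, 25380275L, 7578406L),
    ref = c("G", "CAG", "C"), alt = c("A", "C", "T"),
    depth = c(1523, 804, 2210), vaf = c(0.4213, 0.0625, 0.1871),
    strand_bias_flagged = c(FALSE, TRUE, FALSE),
    consequence = c("missense", "inframe deletion", NA),
    clinical_class = c("pathogenic", "VUS", NA)
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_pool_vcf <- getFromNamespace("write_pool_vcf", "panelval")
  write_pool_vcf(calls, path, sample_id = "S1")
  back <- read_pool_vcf(path, "A")
  expect_equal(back$contig, calls$contig)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$depth, calls$depth)
  expect_equal(back$vaf, calls$vaf, tolerance = 1e-6)
  expect_equal(back$strand_bias_flagged, calls$strand_bias_flagged)
  expect_equal(back$consequence, calls$consequence)
  expect_equal(back$pool, rep("A", 3))
})

test_that("merged VCF output carries filter status and provenance INFO", {
  merged <- apply_pass_filter(merge_pools(
    pool_call(depth = 620, vaf = 0.12),
    pool_call(depth = 540, vaf = 0.10)
  )) |>
    dplyr::mutate(consequence = "missense", clinical_class = "pathogenic")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_merged_vcf(merged, path, sample_id = "S1")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE))
  expect_equal(fix$FILTER, "PASS")
  expect_match(fix$INFO, "CDP=1160")
  expect_match(fix$INFO, "POOLS=AB")
  expect_match(fix$INFO, "CSQ=missense")
})
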