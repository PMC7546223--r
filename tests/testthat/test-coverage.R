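test_that("amplicon means aggregate per-position depth correctly", {
  panel <- tst26_panel()
  amp <- panel$amplicons[1, ]  # AKT1 exon 2, single amplicon
  per_pos <- tibble::tibble(
    sample_id = "s1", contig = amp$contig,
    pos = amp$start + 1:3, depth = c(1000, 1200, 1400)
  )
  out <- amplicon_means(per_pos, panel)
  expect_equal(out$mean_depth[out$amplicon_id == amp$amplicon_id], 1200)

  const <- tibble::tibble(sample_id = "s1", contig = amp$contig,
                          pos = amp$start + 1:10, depth = 777)
  expect_equal(amplicon_means(const, panel)$mean_depth[1], 777)
})

test_that("interleaved positions give independent per-amplicon means", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_manifest(dir, dual_pool = TRUE)
  panel <- load_panel(paths$bed, paths$tsv)
  a1 <- panel$amplicons[panel$amplicons$amplicon_id == "amp01", ]
  a2 <- panel$amplicons[panel$amplicons$amplicon_id == "amp02", ]
  # positions exclusive to each amplicon (the two intervals are staggered)
  p1 <- setdiff((a1$start + 1):a1$end, (a2$start + 1):a2$end)
  p2 <- setdiff((a2$start + 1):a2$end, (a1$start + 1):a1$end)
  tbl <- tibble::tibble(
    sample_id = "s1", contig = "chr1",
    pos = c(p1, p2), depth = rep(c(100, 900), c(length(p1), length(p2)))
  )
  out <- amplicon_means(tbl, panel)
  expect_equal(out$mean_depth[out$amplicon_id == "amp01"], 100)
  expect_equal(out$mean_depth[out$amplicon_id == "amp02"], 900)
})

test_that("unknown amplicon ids are rejected", {
  panel <- tst26_panel()
  expect_error(
    amplicon_means(tibble::tibble(amplicon_id = "nope", mean_depth = 10),
                   panel),
    class = "panelval_validation_error"
  )
})

test_that("exon status applies the cross-pool compensation rule", {
  panel <- tst26_panel()
  # STK11 exon 1 has one amplicon per pool: plant the compensable pair
  cov <- simulate_coverage(
    panel, depth_model = list(meanlog = log(5000), sdlog = 0.01),
    plant_low = tibble::tibble(
      gene = "STK11", exon_label = "1", pool = c("A", "B"),
      mean_depth = c(700, 600)
    ), seed = 5
  )
  st <- exon_coverage_status(panel, cov, "STK11", "1")
  expect_equal(st$status, "pass_by_compensation")
  expect_equal(st$cumulative_mean, 1300)

  # single-pool exon (STK11 exon 6 has one pool-A amplicon only): no
  # second pool to compensate with
  cov2 <- simulate_coverage(
    panel, depth_model = list(meanlog = log(5000), sdlog = 0.01),
    plant_low = tibble::tibble(gene = "STK11", exon_label = "6",
                               pool = NA, mean_depth = 800),
    seed = 5
  )
  st2 <- exon_coverage_status(panel, cov2, "STK11", "6")
  expect_equal(st2$status, "fail")
  expect_true(is.na(st2$pool_b_mean))

  # cumulative shortfall fails even with both pools present
  cov3 <- simulate_coverage(
    panel, depth_model = list(meanlog = log(5000), sdlog = 0.01),
    plant_low = tibble::tibble(gene = "STK11", exon_label = "1",
                               pool = c("A", "B"), mean_depth = c(500, 400)),
    seed = 5
  )
  expect_equal(exon_coverage_status(panel, cov3, "STK11", "1")$status, "fail")

  # a single pool reaching the threshold passes outright
  cov4 <- simulate_coverage(
    panel, depth_model = list(meanlog = log(5000), sdlog = 0.01), seed = 5
  )
  expect_equal(exon_coverage_status(panel, cov4, "AKT1", "2")$status, "pass")

  expect_error(exon_coverage_status(panel, cov4[0, ], "AKT1", "2"),
               class = "panelval_missing_data_error")
  expect_error(exon_coverage_status(panel, cov4, "AKT1", "99"),
               class = "panelval_lookup_error")
})

test_that("compensation is commutative in the two pools", {
  panel <- tst26_panel()
  base <- list(meanlog = log(5000), sdlog = 0.01)
  plant_ab <- tibble::tibble(gene = "STK11", exon_label = "1",
                             pool = c("A", "B"), mean_depth = c(700, 600))
  plant_ba <- plant_ab |> dplyr::mutate(mean_depth = c(600, 700))
  st_ab <- exon_coverage_status(
    panel, simulate_coverage(panel, base, plant_low = plant_ab, seed = 5),
    "STK11", "1")
  st_ba <- exon_coverage_status(
    panel, simulate_coverage(panel, base, plant_low = plant_ba, seed = 5),
    "STK11", "1")
  expect_equal(st_ab$status, st_ba$status)
  expect_equal(st_ab$cumulative_mean, st_ba$cumulative_mean)
})

test_that("raising an amplicon's depth never degrades its exon status", {
  panel <- tst26_panel()
  rank <- c(fail = 0, pass_by_compensation = 1, pass = 2)
  base <- list(meanlog = log(5000), sdlog = 0.01)
  for (d in list(c(200, 100), c(700, 600), c(700, 900), c(1100, 100))) {
    lo <- exon_coverage_status(
      panel,
      simulate_coverage(panel, base, seed = 5, plant_low = tibble::tibble(
        gene = "STK11", exon_label = "1", pool = c("A", "B"), mean_depth = d)),
      "STK11", "1")
    hi <- exon_coverage_status(
      panel,
      simulate_coverage(panel, base, seed = 5, plant_low = tibble::tibble(
        gene = "STK11", exon_label = "1", pool = c("A", "B"),
        mean_depth = d + c(400, 0))),
      "STK11", "1")
    expect_gte(rank[hi$status], rank[lo$status])
  }
})

test_that("cohort report covers every exon region exactly once", {
  panel <- tst26_panel()
  cov <- simulate_coverage(panel,
                           depth_model = list(meanlog = log(5000),
                                              sdlog = 0.01),
                           n_samples = 3, seed = 8)
  report <- coverage_report(panel, cov)
  expect_equal(nrow(report), nrow(panel$exons))
  expect_true(all(report$status %in%
                    c("pass", "pass_by_compensation", "fail")))
  expect_equal(sum(report$status == "fail"), 0L)

  # planted low regions are flagged, failures sort first
  cov2 <- simulate_coverage(
    panel, depth_model = list(meanlog = log(5000), sdlog = 0.01),
    plant_low = tibble::tibble(
      gene = c("AKT1", "STK11"), exon_label = c("2", "6"),
      pool = NA, mean_depth = 800
    ), seed = 8
  )
  report2 <- coverage_report(panel, cov2)
  fails <- report2 |> dplyr::filter(.data$status == "fail")
  expect_equal(paste(fails$gene, fails$exon_label),
               c("AKT1 2", "STK11 6"))
  expect_equal(which(report2$status == "fail"), 1:2)
  expect_equal(nrow(report2), nrow(panel$exons))

  # planting a region unknown to the panel is a config error
  expect_error(
    simulate_coverage(panel, plant_low = tibble::tibble(
      gene = "AKT1", exon_label = "99", pool = NA, mean_depth = 10)),
    class = "panelval_config_error"
  )
})

test_that("per-sample mode reports each sample separately", {
  panel <- tst26_panel()
  cov <- simulate_coverage(panel,
                           depth_model = list(meanlog = log(5000),
                                              sdlog = 0.01),
                           n_samples = 2, seed = 9)
  rep_s <- coverage_report(panel, cov, by_sample = TRUE)
  expect_equal(nrow(rep_s), 2L * nrow(panel$exons))
  expect_setequal(unique(rep_s$sample_id), unique(cov$sample_id))
})
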