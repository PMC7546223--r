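test_that("outcome records tally into the 2x2 table", {
  records <- make_truth_records(80, 3, 7, 54)
  tal <- tally_concordance(records)
  expect_equal(tal, tibble::tibble(tp = 80L, fp = 3L, fn = 7L, tn = 54L,
                                   total = 144L))

  concordant <- make_truth_records(6, 0, 0, 4)
  tal2 <- tally_concordance(concordant)
  expect_equal(c(tal2$fp, tal2$fn), c(0L, 0L))

  single <- tibble::tibble(reference_result = "detected",
                           panel_result = "not_detected")
  expect_equal(unlist(tally_concordance(single)),
               c(tp = 0L, fp = 0L, fn = 1L, tn = 0L, total = 1L))

  bad <- tibble::tibble(reference_result = "detected", panel_result = NA)
  expect_error(tally_concordance(bad), class = "panelval_validation_error")
})

test_that("tally is invariant under record permutation", {
  records <- make_truth_records(12, 5, 3, 9, seed = 1)
  for (s in 2:4) {
    shuffled <- withr::with_seed(s, records[sample(nrow(records)), ])
    expect_equal(tally_concordance(shuffled), tally_concordance(records))
  }
})

test_that("metric estimates follow the standard 2x2 definitions", {
  t2 <- tibble::tibble(tp = 80, fp = 3, fn = 7, tn = 54, total = 144)
  sens <- concordance_metric(t2, "sensitivity")
  expect_equal(sens$estimate, 80 / 87)
  expect_equal(c(sens$numerator, sens$denominator), c(80, 87))
  expect_equal(sens$percent, 92)
  expect_equal(concordance_metric(t2, "accuracy")$estimate, 134 / 144)
  expect_equal(concordance_metric(t2, "specificity")$estimate, 54 / 57)
  expect_equal(concordance_metric(t2, "ppv")$estimate, 80 / 83)
  expect_equal(concordance_metric(t2, "npv")$estimate, 54 / 61)

  perfect <- tibble::tibble(tp = 10, fp = 0, fn = 0, tn = 5, total = 15)
  for (m in c("sensitivity", "specificity", "accuracy", "ppv", "npv")) {
    expect_equal(concordance_metric(perfect, m)$estimate, 1)
  }

  degenerate <- tibble::tibble(tp = 0, fp = 0, fn = 0, tn = 10, total = 10)
  expect_error(concordance_metric(degenerate, "sensitivity"),
               class = "panelval_undefined_metric_error")
  inconsistent <- tibble::tibble(tp = 1, fp = 1, fn = 1, tn = 1, total = 5)
  expect_error(concordance_metric(inconsistent, "accuracy"),
               class = "panelval_validation_error")
})

test_that("accuracy decomposes exactly into sensitivity and specificity", {
  withr::with_seed(21, {
    for (i in 1:25) {
      cells <- as.integer(rmultinom(1, sample(20:200, 1), c(4, 1, 1, 3)))
      t <- tibble::tibble(tp = cells[1], fp = cells[2], fn = cells[3],
                          tn = cells[4], total = sum(cells))
      if (t$tp + t$fn == 0 || t$fp + t$tn == 0) next
      acc <- concordance_metric(t, "accuracy")$estimate
      sens <- concordance_metric(t, "sensitivity")$estimate
      spec <- concordance_metric(t, "specificity")$estimate
      expect_equal(acc * t$total,
                   sens * (t$tp + t$fn) + spec * (t$fp + t$tn),
                   tolerance = 1e-9)
    }
  })
})

test_that("Clopper-Pearson interval matches the binomial-tail inversion oracle", {
  # every (x, n) with n <= 12, against an oracle that inverts the two tail
  # sums directly
  for (n in 1:12) {
    for (x in 0:n) {
      ci <- clopper_pearson(x, n)
      oracle <- cp_tail_oracle(x, n)
      expect_equal(ci$lower, unname(oracle["lower"]), tolerance = 1e-6)
      expect_equal(ci$upper, unname(oracle["upper"]), tolerance = 1e-6)
    }
  }
  # second, independent cross-check on the headline interval
  bt <- binom.test(80, 87)$conf.int
  ci <- clopper_pearson(80, 87)
  expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-9)
})

test_that("Clopper-Pearson boundaries and monotonicity hold", {
  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 1)
  ci <- clopper_pearson(0:50, 50)
  expect_true(all(diff(ci$lower) >= 0))
  expect_true(all(diff(ci$upper) >= 0))
  expect_true(all(ci$lower <= (0:50) / 50 & (0:50) / 50 <= ci$upper))
  expect_error(clopper_pearson(5, 4), class = "panelval_validation_error")
  expect_error(clopper_pearson(-1, 4), class = "panelval_validation_error")
  expect_error(clopper_pearson(1, 4, level = 1),
               class = "panelval_validation_error")
})

test_that("Clopper-Pearson achieves nominal coverage on simulated draws", {
  withr::with_seed(2024, {
    for (p in c(0.1, 0.5, 0.9)) {
      x <- rbinom(10000, 50, p)
      ci <- clopper_pearson(x, 50)
      coverage <- mean(ci$lower <= p & p <= ci$upper)
      expect_gte(coverage, 0.95 - 0.01)
    }
  })
})

test_that("detection shortfall reports the missed-variant percentage", {
  expect_equal(round_half_up(detection_shortfall(83, 87)), 5)
  expect_equal(detection_shortfall(87, 87), 0)
  expect_equal(detection_shortfall(0, 87), 100)
  expect_error(detection_shortfall(10, 0), class = "panelval_validation_error")
  expect_error(detection_shortfall(90, 87), class = "panelval_validation_error")
})

test_that("detected fraction reports the per-sample positivity rate", {
  expect_equal(round_half_up(detected_fraction(194, 69)), 74)
  expect_equal(detected_fraction(0, 10), 0)
  expect_equal(detected_fraction(10, 0), 100)
  expect_error(detected_fraction(0, 0), class = "panelval_validation_error")
})

test_that("sample-size planning responds monotonically to power and alpha", {
  base <- required_sample_size(0.10, power = 0.90, alpha = 0.05)
  expect_true(base$n >= 1)
  expect_equal(base$method, "one_sample_normal")

  lower_power <- required_sample_size(0.10, power = 0.50, alpha = 0.05)
  expect_lte(lower_power$n, base$n)
  stricter_alpha <- required_sample_size(0.10, power = 0.90, alpha = 0.01)
  expect_gte(stricter_alpha$n, base$n)
  smaller_diff <- required_sample_size(0.05, power = 0.90, alpha = 0.05)
  expect_gte(smaller_diff$n, base$n)

  two_sample <- required_sample_size(0.10, method = "two_sample_normal")
  expect_true(two_sample$n >= 1)
  expect_error(required_sample_size(1.2), class = "panelval_validation_error")
})

test_that("diagnostic_accuracy objects support tidy, glance and autoplot", {
  fit <- diagnostic_accuracy(make_truth_records(80, 3, 7, 54))
  td <- tidy(fit)
  expect_equal(nrow(td), 5L)
  expect_setequal(td$metric,
                  c("sensitivity", "specificity", "accuracy", "ppv", "npv"))
  expect_true(all(td$ci_low <= td$estimate & td$estimate <= td$ci_high))

  gl <- glance(fit)
  expect_equal(gl$total, 144L)
  expect_equal(gl$accuracy, 134 / 144)

  plt <- autoplot(fit)
  expect_s3_class(plt, "ggplot")
  expect_output(print(fit), "sensitivity")
})
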