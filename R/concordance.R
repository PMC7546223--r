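#' Tally panel outcomes against the reference standard
#'
#' Each record is one outcome of the agreement analysis — one known variant
#' (or the wild-type status of a variant-free sample) assessed by one center
#' in one replicate.  An outcome is a true positive when both the reference
#' standard and the panel detect it, a false negative when only the
#' reference does, a false positive when only the panel does, and a true
#' negative when neither does.
#'
#' @param records Data frame with columns `reference_result` and
#'   `panel_result`, each `"detected"` or `"not_detected"`.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `total`.
#' @examples
#' rec <- tibble::tibble(
#'   reference_result = c("detected", "detected", "not_detected"),
#'   panel_result = c("detected", "not_detected", "not_detected")
#' )
#' tally_concordance(rec)
#' @export
tally_concordance <- function(records) {
  check_columns(records, c("reference_result", "panel_result"), "truth records")
  lv <- c("detected", "not_detected")
  vals <- c(records$reference_result, records$panel_result)
  if (any(is.na(vals)) || !all(vals %in% lv)) {
    abort("reference_result and panel_result must be 'detected' or 'not_detected'",
          class = "panelval_validation_error")
  }
  ref <- records$reference_result == "detected"
  pan <- records$panel_result == "detected"
  tibble(
    tp = sum(ref & pan), fp = sum(!ref & pan),
    fn = sum(ref & !pan), tn = sum(!ref & !pan),
    total = length(ref)
  )
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Central exact interval obtained by inverting the two binomial tail
#' probabilities, computed through the equivalent Beta-distribution
#' quantiles: lower = `qbeta(alpha/2, x, n - x + 1)`, upper =
#' `qbeta(1 - alpha/2, x + 1, n - x)`, with the boundary conventions
#' lower = 0 at x = 0 and upper = 1 at x = n.
#'
#' @param successes,trials Integer vectors (recycled), `0 <= successes <=
#'   trials`, `trials >= 1`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Tibble with columns `lower`, `upper` (fractions).
#' @examples
#' clopper_pearson(80, 87)
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (length(level) != 1 || !is.finite(level) || level <= 0 || level >= 1) {
    abort("level must be a single value in (0, 1)",
          class = "panelval_validation_error")
  }
  n <- max(length(successes), length(trials))
  x <- rep_len(successes, n)
  m <- rep_len(trials, n)
  if (any(is.na(x)) || any(is.na(m)) || any(m < 1) || any(x < 0) || any(x > m)) {
    abort("need 0 <= successes <= trials and trials >= 1",
          class = "panelval_validation_error")
  }
  alpha <- 1 - level
  lower <- ifelse(x == 0, 0, qbeta(alpha / 2, x, m - x + 1))
  upper <- ifelse(x == m, 1, qbeta(1 - alpha / 2, x + 1, m - x))
  tibble(lower = lower, upper = upper)
}

metric_definitions <- function() {
  list(
    sensitivity = function(t) c(t$tp, t$tp + t$fn),
    specificity = function(t) c(t$tn, t$fp + t$tn),
    accuracy    = function(t) c(t$tp + t$tn, t$total),
    ppv         = function(t) c(t$tp, t$tp + t$fp),
    npv         = function(t) c(t$tn, t$fn + t$tn)
  )
}

#' Diagnostic-accuracy metric with exact confidence interval
#'
#' Computes one of the five standard diagnostic metrics from a 2x2 tally —
#' sensitivity TP/(TP+FN), specificity TN/(FP+TN), accuracy (TP+TN)/total,
#' PPV TP/(TP+FP), NPV TN/(FN+TN) — with its exact Clopper-Pearson interval.
#'
#' @param table One-row tally from [tally_concordance()] (columns `tp`,
#'   `fp`, `fn`, `tn`, `total`).
#' @param name Metric name.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `metric`, `numerator`, `denominator`, `estimate`,
#'   `ci_low`, `ci_high`, `level`, and the integer-percent presentation
#'   columns `percent`, `percent_low`, `percent_high` (rounded half-up, the
#'   convention of the printed validation tables).
#' @examples
#' t2 <- tibble::tibble(tp = 80, fp = 3, fn = 7, tn = 54, total = 144)
#' concordance_metric(t2, "sensitivity")
#' @export
concordance_metric <- function(table, name = c("sensitivity", "specificity",
                                               "accuracy", "ppv", "npv"),
                               level = 0.95) {
  name <- arg_match(name)
  check_columns(table, c("tp", "fp", "fn", "tn", "total"), "concordance table")
  stopifnot(nrow(table) == 1)
  if (with(table, tp + fp + fn + tn) != table$total ||
      any(unlist(table) < 0)) {
    abort("tally must be non-negative with tp+fp+fn+tn = total",
          class = "panelval_validation_error")
  }
  nd <- metric_definitions()[[name]](table)
  if (nd[2] == 0) {
    abort(sprintf("metric '%s' is undefined: zero denominator", name),
          class = "panelval_undefined_metric_error")
  }
  ci <- clopper_pearson(nd[1], nd[2], level)
  tibble(
    metric = name,
    numerator = nd[1], denominator = nd[2],
    estimate = nd[1] / nd[2],
    ci_low = ci$lower, ci_high = ci$upper,
    level = level,
    percent = round_half_up(100 * nd[1] / nd[2]),
    percent_low = round_half_up(100 * ci$lower),
    percent_high = round_half_up(100 * ci$upper)
  )
}

#' Full diagnostic-accuracy analysis of a truth set
#'
#' Tallies the outcome records and computes all five metrics with exact
#' Clopper-Pearson intervals.  The returned object supports [tidy()]
#' (metric table), [glance()] (one-row tally + accuracy) and [autoplot()]
#' (estimates with CI bars).
#'
#' @param records Outcome records as for [tally_concordance()], or an
#'   already-tallied one-row table carrying `tp`, `fp`, `fn`, `tn`, `total`.
#' @param level Confidence level (default 0.95).
#' @return An object of class `panel_concordance`.
#' @examples
#' truth <- simulate_validation_set(seed = 1, n_miss = 7, n_fp = 3)
#' fit <- diagnostic_accuracy(truth)
#' tidy(fit)
#' @export
diagnostic_accuracy <- function(records, level = 0.95) {
  table <- if (all(c("tp", "fp", "fn", "tn") %in% names(records))) {
    records <- as_tibble(records)
    if (!"total" %in% names(records)) {
      records$total <- with(records, tp + fp + fn + tn)
    }
    records
  } else {
    tally_concordance(records)
  }
  metrics <- purrr::map(names(metric_definitions()),
                        ~ concordance_metric(table, .x, level)) |>
    purrr::list_rbind()
  structure(list(table = table, metrics = metrics, level = level),
            class = "panel_concordance")
}

#' @export
print.panel_concordance <- function(x, ...) {
  cat(sprintf(
    "<panel_concordance> %d outcomes: TP %d  FP %d  FN %d  TN %d\n",
    x$table$total, x$table$tp, x$table$fp, x$table$fn, x$table$tn
  ))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-11s %3d%% (%d/%d, %d%% CI [%d-%d])\n",
                m$metric[i], m$percent[i], m$numerator[i], m$denominator[i],
                round(100 * m$level[i]), m$percent_low[i], m$percent_high[i]))
  }
  invisible(x)
}

#' @describeIn diagnostic_accuracy Metric table (one row per metric).
#' @param x A `panel_concordance` object.
#' @param ... Unused.
#' @method tidy panel_concordance
#' @export
tidy.panel_concordance <- function(x, ...) x$metrics

#' @describeIn diagnostic_accuracy One-row summary: the 2x2 tally plus the
#'   accuracy estimate.
#' @method glance panel_concordance
#' @export
glance.panel_concordance <- function(x, ...) {
  acc <- x$metrics[x$metrics$metric == "accuracy", ]
  tibble(
    tp = x$table$tp, fp = x$table$fp, fn = x$table$fn, tn = x$table$tn,
    total = x$table$total,
    accuracy = acc$estimate, accuracy_low = acc$ci_low,
    accuracy_high = acc$ci_high
  )
}

#' @describeIn diagnostic_accuracy Point estimates with exact CI bars.
#' @param object A `panel_concordance` object.
#' @method autoplot panel_concordance
#' @export
autoplot.panel_concordance <- function(object, ...) {
  m <- object$metrics |>
    mutate(metric = factor(.data$metric, levels = rev(.data$metric)))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$estimate, y = .data$metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(
      x = sprintf("estimate (exact %d%% CI)", round(100 * object$level)),
      y = NULL,
      title = "Diagnostic accuracy vs. reference standard"
    ) +
    ggplot2::theme_minimal()
}

#' Detection shortfall of the panel against the reference standard
#'
#' Percentage of reference-standard variants the panel failed to identify:
#' `100 * (reference - panel) / reference`.  Use [round_half_up()] for the
#' integer-percent presentation.
#'
#' @param panel_detected,reference_detected Counts of variants identified by
#'   the panel and by the reference standard.
#' @return Numeric percentage (full precision).
#' @examples
#' round_half_up(detection_shortfall(83, 87))  # 5
#' @export
detection_shortfall <- function(panel_detected, reference_detected) {
  if (any(reference_detected <= 0)) {
    abort("reference_detected must be > 0", class = "panelval_validation_error")
  }
  if (any(panel_detected < 0) || any(panel_detected > reference_detected)) {
    abort("need 0 <= panel_detected <= reference_detected",
          class = "panelval_validation_error")
  }
  100 * (reference_detected - panel_detected) / reference_detected
}

#' Minimal sample size to detect a detection-rate difference
#'
#' Plans the validation cohort size for a maximum tolerated difference
#' between the panel's and the reference standard's detection proportions.
#' Two formulas are selectable; the one used is recorded in the output:
#' \describe{
#'   \item{`one_sample_normal`}{closed-form normal approximation for a
#'     one-sample proportion test, `n = p(1-p) (z_{1-alpha/2} + z_power)^2 /
#'     d^2`, at the most conservative `p_baseline = 0.5` by default.}
#'   \item{`two_sample_normal`}{per-group size of a two-sample proportion
#'     comparison (`stats::power.prop.test`) between `p_baseline` and
#'     `p_baseline - max_difference`.}
#' }
#'
#' @param max_difference Largest acceptable difference in detection
#'   proportions (fraction in (0, 1)).
#' @param power Target power (default 0.90).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param method Which formula to use.
#' @param p_baseline Baseline proportion (see above).
#' @return One-row tibble: `n` (smallest integer sample size), `method`,
#'   `max_difference`, `power`, `alpha`, `p_baseline`.
#' @examples
#' required_sample_size(0.10)
#' @export
required_sample_size <- function(max_difference, power = 0.90, alpha = 0.05,
                                 method = c("one_sample_normal",
                                            "two_sample_normal"),
                                 p_baseline = NULL) {
  method <- arg_match(method)
  args <- c(max_difference, power, alpha)
  if (any(!is.finite(args)) || any(args <= 0) || any(args >= 1)) {
    abort("max_difference, power and alpha must lie in (0, 1)",
          class = "panelval_validation_error")
  }
  if (method == "one_sample_normal") {
    p <- p_baseline %||% 0.5
    z <- qnorm(1 - alpha / 2) + qnorm(power)
    n <- ceiling(p * (1 - p) * z^2 / max_difference^2)
  } else {
    p <- p_baseline %||% 0.95
    if (p - max_difference <= 0 || p >= 1) {
      abort("two_sample_normal needs 0 < p_baseline - max_difference and p_baseline < 1",
            class = "panelval_no_solution_error")
    }
    n <- ceiling(stats::power.prop.test(
      p1 = p, p2 = p - max_difference,
      sig.level = alpha, power = power
    )$n)
  }
  tibble(n = as.integer(n), method = method,
         max_difference = max_difference, power = power, alpha = alpha,
         p_baseline = p)
}

#' Fraction of sequenced samples with a detected variant
#'
#' `100 * detected / (detected + not_detected)`; use [round_half_up()] for
#' the integer-percent presentation used in reports.
#'
#' @param n_detected,n_not_detected Sample counts.
#' @return Numeric percentage (full precision).
#' @examples
#' round_half_up(detected_fraction(194, 69))  # 74
#' @export
detected_fraction <- function(n_detected, n_not_detected) {
  if (any(n_detected < 0) || any(n_not_detected < 0) ||
      any(n_detected + n_not_detected == 0)) {
    abort("counts must be non-negative with a positive total",
          class = "panelval_validation_error")
  }
  100 * n_detected / (n_detected + n_not_detected)
}
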