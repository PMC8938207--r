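#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, obtained by inverting
#' the binomial tail probabilities; computationally the bounds are Beta
#' quantiles: lower = Beta(alpha/2; x, n - x + 1) (0 when x = 0) and upper =
#' Beta(1 - alpha/2; x + 1, n - x) (1 when x = n). For x = n the lower bound
#' reduces to the closed form (alpha/2)^(1/n). These intervals are
#' conservative: actual coverage is at least the nominal level.
#'
#' @param numerator Number of events, integer in 0..`denominator`.
#' @param denominator Number of trials, integer > 0.
#' @param confidence Two-sided confidence level, default 0.95.
#' @return A one-row tibble: `numerator, denominator, estimate, ci_low,
#'   ci_high, confidence`, all proportions on the 0-1 scale.
#' @examples
#' clopper_pearson(4, 4)   # lower bound (0.025)^(1/4) = 0.3976
#' clopper_pearson(4, 19)  # 0.0605 - 0.4557
#' @export
clopper_pearson <- function(numerator, denominator, confidence = 0.95) {
  check_counts(numerator, denominator, confidence)
  alpha <- 1 - confidence
  lo <- if (numerator == 0) 0 else qbeta(alpha / 2, numerator,
                                         denominator - numerator + 1)
  hi <- if (numerator == denominator) 1 else qbeta(1 - alpha / 2,
                                                   numerator + 1,
                                                   denominator - numerator)
  tibble::tibble(numerator = as.integer(numerator),
                 denominator = as.integer(denominator),
                 estimate = numerator / denominator,
                 ci_low = lo, ci_high = hi, confidence = confidence)
}

#' Wilson score interval for a binomial proportion
#'
#' Approximate score interval; available as an alternative to the exact
#' default for users who prefer shorter intervals at small n.
#'
#' @inheritParams clopper_pearson
#' @return Same layout as [clopper_pearson()].
#' @export
wilson_interval <- function(numerator, denominator, confidence = 0.95) {
  check_counts(numerator, denominator, confidence)
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- numerator / denominator
  n <- denominator
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  tibble::tibble(numerator = as.integer(numerator),
                 denominator = as.integer(denominator),
                 estimate = p,
                 ci_low = max(0, centre - half),
                 ci_high = min(1, centre + half),
                 confidence = confidence)
}

check_counts <- function(numerator, denominator, confidence) {
  ok <- length(numerator) == 1 && length(denominator) == 1 &&
    !is.na(numerator) && !is.na(denominator) &&
    denominator > 0 && numerator >= 0 && numerator <= denominator &&
    numerator == round(numerator) && denominator == round(denominator)
  if (!ok) {
    abort("need integer counts with 0 <= numerator <= denominator and denominator > 0",
          class = "icptrend_validation_error")
  }
  if (confidence <= 0 || confidence >= 1) {
    abort("confidence must be in (0, 1)", class = "icptrend_config_error")
  }
}

proportion_ci <- function(numerator, denominator, confidence = 0.95,
                          ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  if (denominator == 0) {
    # Undefined, never coerced to 0 or 1: small cohorts routinely empty a
    # stratum and a fabricated value would silently distort the report.
    return(tibble::tibble(numerator = as.integer(numerator), denominator = 0L,
                          estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, confidence = confidence))
  }
  switch(ci_method,
         "clopper-pearson" = clopper_pearson(numerator, denominator, confidence),
         "wilson" = wilson_interval(numerator, denominator, confidence))
}

#' Build the 2x2 trend-by-outcome contingency table
#'
#' Cross-tabulates trend calls at one margin against the six-month outcome.
#' Patients without a call (incomplete monitoring) are excluded; a call whose
#' patient lacks a recorded six-month outcome is an error.
#'
#' @param calls Trend-call tibble from [classify_trend()] or a single margin
#'   of [sweep_margins()]; exactly one call per patient.
#' @param patients Patient tibble with `patient_id` and `outcome_6mo`.
#' @return A 2x2 integer matrix, rows `stable`/`progressive_increase`,
#'   columns `success`/`failure`, with attribute `margin_mmhg`.
#' @export
build_contingency <- function(calls, patients) {
  if (nrow(calls) == 0) {
    abort("no trend calls supplied", class = "icptrend_validation_error")
  }
  if (length(unique(calls$margin_mmhg)) != 1) {
    abort("calls span several margins; filter to one margin first",
          class = "icptrend_validation_error")
  }
  if (anyDuplicated(calls$patient_id)) {
    abort("more than one call per patient at this margin",
          class = "icptrend_validation_error")
  }
  joined <- dplyr::left_join(calls, patients[, c("patient_id", "outcome_6mo")],
                             by = "patient_id")
  no_outcome <- joined$patient_id[is.na(joined$outcome_6mo)]
  if (length(no_outcome) > 0) {
    abort(paste0("missing outcome_6mo for patient(s): ",
                 paste(no_outcome, collapse = ", ")),
          class = "icptrend_validation_error")
  }
  tab <- table(factor(joined$label, levels = .trend_levels),
               factor(joined$outcome_6mo, levels = .outcome_levels))
  out <- matrix(as.integer(tab), nrow = 2,
                dimnames = list(trend = .trend_levels,
                                outcome = .outcome_levels))
  attr(out, "margin_mmhg") <- calls$margin_mmhg[1]
  out
}

#' Construct a contingency table from explicit cell counts
#'
#' Convenience constructor for working directly with published cell counts.
#'
#' @param stable_success,stable_failure,progressive_success,progressive_failure
#'   Non-negative integer cell counts.
#' @param margin_mmhg Optional margin annotation.
#' @return A 2x2 matrix as produced by [build_contingency()].
#' @examples
#' contingency_table(stable_success = 12, stable_failure = 15,
#'                   progressive_success = 0, progressive_failure = 4,
#'                   margin_mmhg = 2)
#' @export
contingency_table <- function(stable_success, stable_failure,
                              progressive_success, progressive_failure,
                              margin_mmhg = NA_real_) {
  cells <- c(stable_success, stable_failure,
             progressive_success, progressive_failure)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers",
          class = "icptrend_validation_error")
  }
  out <- matrix(as.integer(c(stable_success, progressive_success,
                             stable_failure, progressive_failure)),
                nrow = 2,
                dimnames = list(trend = .trend_levels,
                                outcome = .outcome_levels))
  attr(out, "margin_mmhg") <- margin_mmhg
  out
}

#' Diagnostic accuracy of the ICP trend against six-month outcome
#'
#' Treats the trend as a binary test for the outcome in one of two mirrored
#' directions. Under `stable_predicts_success` the condition positive is a
#' successful outcome and the test positive is a stable trend, so
#' sensitivity = P(stable | success), specificity = P(progressive | failure),
#' PPV = P(success | stable) and NPV = P(failure | progressive). Under
#' `progressive_predicts_failure` the roles are swapped, which exchanges
#' sensitivity with specificity and PPV with NPV. Metrics with an empty
#' denominator are reported as `NA` (undefined), never as 0 or 1.
#'
#' @param table 2x2 matrix from [build_contingency()] or
#'   [contingency_table()].
#' @param direction `"stable_predicts_success"` or
#'   `"progressive_predicts_failure"`.
#' @param confidence Confidence level for the per-metric intervals.
#' @param ci_method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @return A tibble with one row per metric (`sensitivity`, `specificity`,
#'   `ppv`, `npv`): `direction, metric, numerator, denominator, estimate,
#'   ci_low, ci_high, confidence`.
#' @examples
#' tab <- contingency_table(12, 15, 0, 4, margin_mmhg = 2)
#' diag_metrics(tab, "stable_predicts_success")
#' @export
diag_metrics <- function(table,
                         direction = c("stable_predicts_success",
                                       "progressive_predicts_failure"),
                         confidence = 0.95,
                         ci_method = c("clopper-pearson", "wilson")) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  check_contingency(table)
  ss <- table["stable", "success"]
  sf <- table["stable", "failure"]
  ps <- table["progressive_increase", "success"]
  pf <- table["progressive_increase", "failure"]
  if (direction == "stable_predicts_success") {
    tp <- ss; fn <- ps; tn <- pf; fp <- sf
  } else {
    tp <- pf; fn <- sf; tn <- ss; fp <- ps
  }
  rows <- list(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    ppv = c(tp, tp + fp),
    npv = c(tn, tn + fn)
  )
  out <- dplyr::bind_rows(lapply(names(rows), function(metric) {
    k <- rows[[metric]]
    ci <- proportion_ci(k[1], k[2], confidence, ci_method)
    dplyr::bind_cols(tibble::tibble(direction = direction, metric = metric), ci)
  }))
  tibble::as_tibble(out)
}

check_contingency <- function(table) {
  ok <- is.matrix(table) && all(dim(table) == c(2, 2)) &&
    !anyNA(table) && all(table >= 0) &&
    identical(rownames(table), .trend_levels) &&
    identical(colnames(table), .outcome_levels)
  if (!ok) {
    abort("expected a 2x2 trend-by-outcome contingency matrix (see contingency_table())",
          class = "icptrend_validation_error")
  }
  if (sum(table) == 0) {
    abort("contingency table is empty", class = "icptrend_validation_error")
  }
  invisible(table)
}

#' Pearson chi-square test on the trend-by-outcome table
#'
#' Uncorrected Pearson statistic sum((O - E)^2 / E) with 1 degree of freedom;
#' the continuity correction is off by default and available by flag.
#'
#' @inheritParams diag_metrics
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A list: `statistic`, `df` (= 1) and `p_value`.
#' @examples
#' pearson_chi_square(contingency_table(11, 11, 1, 8, margin_mmhg = 1))
#' @export
pearson_chi_square <- function(table, correct = FALSE) {
  check_contingency(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("chi-square undefined: zero row or column marginal",
          class = "icptrend_validation_error")
  }
  ht <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Success rate by ICP trend
#'
#' The proportion of successful six-month outcomes within each trend stratum,
#' with a confidence interval per stratum.
#'
#' @inheritParams diag_metrics
#' @return Tibble `trend, numerator, denominator, estimate, ci_low, ci_high,
#'   confidence` with one row per trend.
#' @export
success_rate_by_trend <- function(table, confidence = 0.95,
                                  ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  check_contingency(table)
  out <- dplyr::bind_rows(lapply(.trend_levels, function(tr) {
    ci <- proportion_ci(table[tr, "success"], sum(table[tr, ]),
                        confidence, ci_method)
    dplyr::bind_cols(tibble::tibble(trend = tr), ci)
  }))
  tibble::as_tibble(out)
}

#' Full diagnostic report across a margin sweep
#'
#' For every margin in a sweep, builds the trend-by-outcome table and
#' computes the diagnostic metrics in both prediction directions, the success
#' rate per trend, and the Pearson chi-square when the table has no empty
#' marginal. No multiple-testing adjustment is applied across margins; the
#' report carries a note to that effect.
#'
#' @param sweep Calls tibble from [sweep_margins()].
#' @param patients Patient tibble with six-month outcomes.
#' @param confidence,ci_method Passed to [diag_metrics()].
#' @param correct Passed to [pearson_chi_square()].
#' @return A list of class `icp_diag_report`: `metrics` (per margin x
#'   direction x metric), `success_rates`, `chi_square` (per margin;
#'   `NA` statistic where a marginal is zero), `counts` (per-margin label
#'   counts) and `note`.
#' @export
sweep_report <- function(sweep, patients, confidence = 0.95,
                         ci_method = c("clopper-pearson", "wilson"),
                         correct = FALSE) {
  ci_method <- match.arg(ci_method)
  if (nrow(sweep) == 0) {
    abort("empty sweep", class = "icptrend_validation_error")
  }
  margins <- sort(unique(sweep$margin_mmhg))
  metrics <- list(); rates <- list(); chis <- list()
  for (m in margins) {
    tab <- build_contingency(sweep[sweep$margin_mmhg == m, , drop = FALSE],
                             patients)
    met <- dplyr::bind_rows(
      diag_metrics(tab, "stable_predicts_success", confidence, ci_method),
      diag_metrics(tab, "progressive_predicts_failure", confidence, ci_method)
    )
    metrics[[as.character(m)]] <- dplyr::bind_cols(
      tibble::tibble(margin_mmhg = m), met)
    rates[[as.character(m)]] <- dplyr::bind_cols(
      tibble::tibble(margin_mmhg = m),
      success_rate_by_trend(tab, confidence, ci_method))
    chi <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      list(statistic = NA_real_, df = 1L, p_value = NA_real_)
    } else {
      pearson_chi_square(tab, correct = correct)
    }
    chis[[as.character(m)]] <- tibble::tibble(
      margin_mmhg = m, statistic = chi$statistic, df = chi$df,
      p_value = chi$p_value)
  }
  structure(
    list(metrics = dplyr::bind_rows(metrics),
         success_rates = dplyr::bind_rows(rates),
         chi_square = dplyr::bind_rows(chis),
         counts = sweep_counts(sweep),
         note = paste("Margins are reported without multiple-testing",
                      "adjustment; interpret per-margin p-values accordingly.")),
    class = "icp_diag_report")
}

#' @export
print.icp_diag_report <- function(x, ...) {
  cat("ICP trend diagnostic report\n")
  cat("Margins (mmHg):", paste(x$counts$margin_mmhg, collapse = ", "), "\n\n")
  print(x$counts)
  cat("\nDiagnostic metrics:\n")
  print(x$metrics, n = Inf)
  cat("\nSuccess rates by trend:\n")
  print(x$success_rates, n = Inf)
  cat("\nChi-square (uncorrected Pearson unless stated):\n")
  print(x$chi_square)
  cat("\nNote:", x$note, "\n")
  invisible(x)
}
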