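test_that("exact binomial CI matches the tail-sum bisection oracle and binom.test", {
  cases <- rbind(c(0, 5), c(5, 5), c(4, 4), c(4, 19), c(12, 12), c(12, 27),
                 c(1, 9), c(11, 22), c(7, 31), c(15, 27))
  for (i in seq_len(nrow(cases))) {
    x <- cases[i, 1]; n <- cases[i, 2]
    got <- clopper_pearson(x, n)
    oracle <- cp_bisect(x, n)
    expect_equal(got$ci_low, unname(oracle["lower"]), tolerance = 1e-7)
    expect_equal(got$ci_high, unname(oracle["upper"]), tolerance = 1e-7)
    bt <- binom.test(x, n)$conf.int
    expect_equal(c(got$ci_low, got$ci_high), as.numeric(bt), tolerance = 1e-9)
  }
  # closed forms at the boundaries
  expect_equal(clopper_pearson(0, 10)$ci_low, 0)
  expect_equal(clopper_pearson(10, 10)$ci_high, 1)
  expect_equal(clopper_pearson(4, 4)$ci_low, 0.025^(1 / 4))
  expect_error(clopper_pearson(5, 4), class = "icptrend_validation_error")
  expect_error(clopper_pearson(-1, 4), class = "icptrend_validation_error")
})

test_that("exact intervals achieve at least nominal coverage empirically", {
  withr::with_seed(77, {
    scenarios <- list(c(10, 0.5), c(19, 0.21), c(31, 0.13), c(50, 0.9))
    draws_per <- 500
    covered <- 0; total <- 0
    for (sc in scenarios) {
      n <- sc[1]; p <- sc[2]
      x <- rbinom(draws_per, n, p)
      for (xi in unique(x)) {
        ci <- clopper_pearson(xi, n)
        hits <- sum(x == xi) * (ci$ci_low <= p & p <= ci$ci_high)
        covered <- covered + hits
      }
      total <- total + draws_per
    }
    expect_gte(covered / total, 0.935)
  })
})

test_that("published >2 mmHg table yields the published accuracy metrics", {
  tab <- published_table(2)
  stable_dir <- diag_metrics(tab, "stable_predicts_success")
  est <- setNames(stable_dir$estimate, stable_dir$metric)
  expect_equal(round(100 * est[["sensitivity"]], 2), 100)     # 12/12
  expect_equal(round(100 * est[["specificity"]], 2), 21.05)   # 4/19
  expect_equal(round(100 * est[["ppv"]], 2), 44.44)           # 12/27
  expect_equal(round(100 * est[["npv"]], 2), 100)             # 4/4
  ci <- stable_dir[stable_dir$metric == "specificity", ]
  expect_equal(round(100 * c(ci$ci_low, ci$ci_high), 2), c(6.05, 45.57))

  prog_dir <- diag_metrics(tab, "progressive_predicts_failure")
  est2 <- setNames(prog_dir$estimate, prog_dir$metric)
  expect_equal(round(100 * est2[["sensitivity"]], 2), 21.05)
  expect_equal(round(100 * est2[["specificity"]], 2), 100)
  expect_equal(round(100 * est2[["ppv"]], 2), 100)
  expect_equal(round(100 * est2[["npv"]], 2), 44.44)
  ppv_ci <- prog_dir[prog_dir$metric == "ppv", ]
  expect_equal(round(100 * ppv_ci$ci_low, 2), 39.76)
  expect_equal(ppv_ci$ci_high, 1)
})

test_that("the two prediction directions are mirror images on random tables", {
  withr::with_seed(88, {
    for (rep in 1:1000) {
      tab <- random_table()
      a <- diag_metrics(tab, "stable_predicts_success")
      b <- diag_metrics(tab, "progressive_predicts_failure")
      ea <- setNames(a$estimate, a$metric)
      eb <- setNames(b$estimate, b$metric)
      expect_identical(ea[["sensitivity"]], eb[["specificity"]])
      expect_identical(ea[["specificity"]], eb[["sensitivity"]])
      expect_identical(ea[["ppv"]], eb[["npv"]])
      expect_identical(ea[["npv"]], eb[["ppv"]])
    }
  })
})

test_that("PPV agrees with Bayes' rule from sensitivity, specificity, prevalence", {
  withr::with_seed(99, {
    for (rep in 1:200) {
      tab <- random_table()
      m <- diag_metrics(tab, "stable_predicts_success")
      e <- setNames(m$estimate, m$metric)
      prev <- sum(tab[, "success"]) / sum(tab)
      denom <- e[["sensitivity"]] * prev + (1 - e[["specificity"]]) * (1 - prev)
      if (is.na(denom) || is.na(e[["ppv"]]) || denom == 0) next
      expect_equal(e[["ppv"]],
                   unname(e[["sensitivity"]] * prev / denom),
                   tolerance = 1e-12)
    }
  })
})

test_that("empty denominators yield undefined metrics, not 0 or 1", {
  tab <- contingency_table(stable_success = 10, stable_failure = 5,
                           progressive_success = 0, progressive_failure = 0)
  m <- diag_metrics(tab, "stable_predicts_success")
  expect_true(is.na(m$estimate[m$metric == "npv"]))
  expect_true(is.na(m$ci_low[m$metric == "npv"]))
  expect_false(any(m$estimate[m$metric != "npv"] %in% NA))
})

test_that("uncorrected Pearson chi-square reproduces the published p = 0.044", {
  tab <- published_table(1)  # stable 11/11, increasing 8 failure / 1 success
  res <- pearson_chi_square(tab)
  expect_equal(res$df, 1)
  expect_equal(round(res$p_value, 3), 0.044)
  # the Yates-corrected variant is distinctly different, confirming the
  # uncorrected statistic is the one in use by default
  expect_gt(pearson_chi_square(tab, correct = TRUE)$p_value, 0.09)
})

test_that("chi-square equals the expected-count oracle on random tables", {
  withr::with_seed(111, {
    done <- 0
    while (done < 200) {
      tab <- random_table()
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      res <- pearson_chi_square(tab)
      expect_equal(res$statistic, chisq_oe(tab), tolerance = 1e-12)
      expect_true(res$p_value >= 0 && res$p_value <= 1)
      done <- done + 1
    }
  })
  flat <- contingency_table(3, 3, 3, 3)
  expect_equal(pearson_chi_square(flat)$statistic, 0)
  expect_equal(pearson_chi_square(flat)$p_value, 1)
  degenerate <- contingency_table(4, 6, 0, 0)
  expect_error(pearson_chi_square(degenerate), "marginal",
               class = "icptrend_validation_error")
})

test_that("success rates by trend match the published >1 mmHg contrast", {
  tab <- published_table(1)
  rates <- success_rate_by_trend(tab)
  expect_equal(rates$estimate[rates$trend == "stable"], 11 / 22)
  expect_equal(round(100 * rates$estimate[rates$trend == "progressive_increase"]),
               11)  # 1/9
  all_success <- contingency_table(8, 0, 3, 0)
  expect_equal(success_rate_by_trend(all_success)$estimate, c(1, 1))
})

test_that("contingency construction validates outcomes and margins", {
  calls <- tibble::tibble(patient_id = c("a", "b"), margin_mmhg = 2,
                          label = c("stable", "progressive_increase"),
                          dav_delta_13 = c(0, 3), monotone = c(FALSE, TRUE))
  patients <- tibble::tibble(patient_id = c("a", "b"),
                             outcome_6mo = c("success", NA))
  expect_error(build_contingency(calls, patients), "missing outcome_6mo.*b",
               class = "icptrend_validation_error")
  patients$outcome_6mo <- c("success", "failure")
  tab <- build_contingency(calls, patients)
  expect_equal(tab["stable", "success"], 1L)
  expect_equal(tab["progressive_increase", "failure"], 1L)
  expect_equal(sum(tab), 2L)
  expect_error(build_contingency(calls[0, ], patients),
               class = "icptrend_validation_error")
  mixed <- dplyr::bind_rows(calls, dplyr::mutate(calls, margin_mmhg = 3))
  expect_error(build_contingency(mixed, patients), "several margins",
               class = "icptrend_validation_error")
})

test_that("sweep report reproduces the published sensitivity/specificity columns", {
  cnt <- published_sweep_counts()
  # rebuild per-margin calls/patients that realize the published cell counts
  reports <- lapply(cnt$margin, function(m) {
    tab <- published_table(m)
    list(stable = diag_metrics(tab, "stable_predicts_success"),
         prog = diag_metrics(tab, "progressive_predicts_failure"))
  })
  sens_stable <- sapply(reports, function(r) {
    100 * r$stable$estimate[r$stable$metric == "sensitivity"]
  })
  spec_stable <- sapply(reports, function(r) {
    100 * r$stable$estimate[r$stable$metric == "specificity"]
  })
  expect_equal(round(sens_stable, 1), c(91.7, 100, 100, 100, 100))
  expect_equal(round(spec_stable, 1), c(42.1, 21.1, 15.8, 10.5, 5.3))
  # the increasing-trend rows mirror them
  sens_prog <- sapply(reports, function(r) {
    100 * r$prog$estimate[r$prog$metric == "sensitivity"]
  })
  expect_equal(round(sens_prog, 1), c(42.1, 21.1, 15.8, 10.5, 5.3))
  expect_true(all(diff(cnt$progressive_failure + cnt$progressive_success) < 0))
})

test_that("wilson intervals are valid and narrower than exact at moderate n", {
  w <- wilson_interval(12, 27)
  cp <- clopper_pearson(12, 27)
  expect_true(w$ci_low > cp$ci_low && w$ci_high < cp$ci_high)
  expect_true(w$ci_low <= w$estimate && w$estimate <= w$ci_high)
})
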