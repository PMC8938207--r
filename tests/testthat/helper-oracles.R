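# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: interval bounds come from bisection on binomial
# tail sums, chi-square from direct observed/expected summation, and DAVs
# from an explicit per-day accumulation loop.

# Exact binomial CI by bisection on the tail probabilities: the lower bound
# solves P(X >= x | p) = alpha/2, the upper solves P(X <= x | p) = alpha/2.
cp_bisect <- function(x, n, conf = 0.95, tol = 1e-10) {
  alpha <- 1 - conf
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else {
    bisect(function(p) sum(dbinom(x:n, n, p)) - alpha / 2, 0, 1)
  }
  upper <- if (x == n) 1 else {
    bisect(function(p) alpha / 2 - sum(dbinom(0:x, n, p)), 0, 1)
  }
  c(lower = lower, upper = upper)
}

# Pearson statistic by explicit expected-count summation.
chisq_oe <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# Brute-force daily averages: accumulate sum and count per (patient, day)
# with an explicit loop over rows.
dav_brute <- function(series, min_readings = 24) {
  out <- list()
  for (i in seq_len(nrow(series))) {
    day <- series$hour_index[i] %/% 24 + 1
    if (day > 3) next
    key <- paste(series$patient_id[i], day)
    cur <- out[[key]]
    if (is.null(cur)) cur <- c(sum = 0, n = 0)
    out[[key]] <- c(sum = cur[["sum"]] + series$icp_mmhg[i],
                    n = cur[["n"]] + 1)
  }
  ids <- unique(series$patient_id)
  res <- lapply(ids, function(id) {
    vals <- sapply(1:3, function(d) {
      cur <- out[[paste(id, d)]]
      if (is.null(cur) || cur[["n"]] < min_readings) NA_real_
      else cur[["sum"]] / cur[["n"]]
    })
    ns <- sapply(1:3, function(d) {
      cur <- out[[paste(id, d)]]
      if (is.null(cur)) 0 else cur[["n"]]
    })
    list(patient_id = id, dav = vals, n = ns, complete = !anyNA(vals))
  })
  names(res) <- ids
  res
}

# Random hourly series for property tests: random subset of hours, random
# pressures, optionally several patients.
random_series <- function(n_patients = 1, p_keep = 1, max_pressure = 30) {
  rows <- lapply(seq_len(n_patients), function(i) {
    hours <- 0:71
    hours <- hours[runif(72) <= p_keep]
    if (length(hours) == 0) hours <- 0L
    tibble::tibble(patient_id = sprintf("p%02d", i),
                   hour_index = as.integer(hours),
                   icp_mmhg = round(runif(length(hours), 0, max_pressure), 3))
  })
  dplyr::bind_rows(rows)
}

# Random nonempty 2x2 trend-by-outcome table.
random_table <- function(max_cell = 20) {
  repeat {
    cells <- sample(0:max_cell, 4, replace = TRUE)
    if (sum(cells) > 0) break
  }
  contingency_table(cells[1], cells[2], cells[3], cells[4])
}

# Published margin-sweep cell counts (failure/success by trend at each
# margin), used to exercise the evaluator on the real study's tables.
published_sweep_counts <- function() {
  tibble::tibble(
    margin = 1:5,
    stable_failure = c(11, 15, 16, 17, 18),
    stable_success = c(11, 12, 12, 12, 12),
    progressive_failure = c(8, 4, 3, 2, 1),
    progressive_success = c(1, 0, 0, 0, 0)
  )
}

published_table <- function(margin) {
  cnt <- published_sweep_counts()
  row <- cnt[cnt$margin == margin, ]
  contingency_table(row$stable_success, row$stable_failure,
                    row$progressive_success, row$progressive_failure,
                    margin_mmhg = margin)
}
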