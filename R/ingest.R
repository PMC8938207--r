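#' Read a patient clinical table
#'
#' Parses the `patients.csv` dialect: one row per patient with demographics,
#' etiology, opening pressure (mmHg), outcomes at 1/3/6 months, and an
#' optional Evans ratio. Empty fields are missing. Categorical fields are
#' validated against their closed vocabularies and failures are reported with
#' the offending row number.
#'
#' @param path Path to a UTF-8 comma-separated file with header
#'   `patient_id,age_months,sex,etiology,opening_pressure_mmhg,outcome_1mo,outcome_3mo,outcome_6mo,evans_ratio`.
#' @return A tibble with one validated row per patient, in file order.
#'   `sex`, `etiology` and the outcome columns are character vectors drawn
#'   from their vocabularies (`male|female`, `aqueductal_stenosis|dandy_walker|other`,
#'   `success|failure`).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' cohort <- simulate_cohort(cohort_config(n_patients = 5, seed = 1))
#' paths <- write_cohort(cohort, dir)
#' read_patients(paths$patients)
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("patients file not found: ", path), class = "icptrend_io_error")
  }
  cols <- readr::cols(
    patient_id = readr::col_character(),
    age_months = readr::col_double(),
    sex = readr::col_character(),
    etiology = readr::col_character(),
    opening_pressure_mmhg = readr::col_double(),
    outcome_1mo = readr::col_character(),
    outcome_3mo = readr::col_character(),
    outcome_6mo = readr::col_character(),
    evans_ratio = readr::col_double()
  )
  pats <- readr::read_csv(path, col_types = cols, progress = FALSE)
  missing_cols <- setdiff(names(cols$cols), names(pats))
  if (length(missing_cols) > 0) {
    abort(paste0("patients file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "icptrend_validation_error")
  }
  validate_patients(pats)
  pats
}

validate_patients <- function(pats) {
  row_err <- function(rows, msg) {
    abort(paste0(msg, " (row ", paste(rows, collapse = ", "), ")"),
          class = "icptrend_validation_error")
  }
  if (nrow(pats) == 0) {
    abort("patients table is empty", class = "icptrend_validation_error")
  }
  if (anyNA(pats$patient_id) || any(pats$patient_id == "")) {
    row_err(which(is.na(pats$patient_id) | pats$patient_id == ""),
            "missing patient_id")
  }
  dup <- duplicated(pats$patient_id)
  if (any(dup)) {
    row_err(which(dup), paste0("duplicate patient_id '",
                               pats$patient_id[which(dup)[1]], "'"))
  }
  bad <- which(!is.na(pats$sex) & !pats$sex %in% .sex_levels)
  if (length(bad)) row_err(bad, paste0("unknown sex code '", pats$sex[bad[1]], "'"))
  bad <- which(!is.na(pats$etiology) & !pats$etiology %in% .etiology_levels)
  if (length(bad)) {
    row_err(bad, paste0("unknown etiology code '", pats$etiology[bad[1]], "'"))
  }
  for (oc in c("outcome_1mo", "outcome_3mo", "outcome_6mo")) {
    bad <- which(!is.na(pats[[oc]]) & !pats[[oc]] %in% .outcome_levels)
    if (length(bad)) {
      row_err(bad, paste0("unknown ", oc, " code '", pats[[oc]][bad[1]],
                          "' (accepted: success, failure)"))
    }
  }
  bad <- which(!is.na(pats$age_months) & pats$age_months < 0)
  if (length(bad)) row_err(bad, "negative age_months")
  # Sanity window on opening pressure: out-of-window values usually mean a
  # unit mistake (cmH2O vs mmHg), so fail loudly rather than clip.
  bad <- which(!is.na(pats$opening_pressure_mmhg) &
                 (pats$opening_pressure_mmhg < 0 | pats$opening_pressure_mmhg > 100))
  if (length(bad)) row_err(bad, "opening_pressure_mmhg outside [0, 100] mmHg")
  bad <- which(!is.na(pats$evans_ratio) &
                 (pats$evans_ratio <= 0 | pats$evans_ratio > 1))
  if (length(bad)) row_err(bad, "evans_ratio outside (0, 1]")
  invisible(pats)
}

#' Read an hourly ICP series table
#'
#' Parses the `icp_series.csv` dialect: one row per hourly reading with
#' `patient_id`, `hour_index` (integer hours since the start of monitoring,
#' which begins four hours after skin closure) and `icp_mmhg`. Within each
#' patient, hour indices must be strictly increasing and pressures finite,
#' non-negative and below the 100 mmHg sanity ceiling.
#'
#' @param path Path to the series CSV.
#' @return A tibble `patient_id, hour_index, icp_mmhg` in file order.
#' @export
read_icp_series <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("series file not found: ", path), class = "icptrend_io_error")
  }
  cols <- readr::cols(
    patient_id = readr::col_character(),
    hour_index = readr::col_integer(),
    icp_mmhg = readr::col_double()
  )
  ser <- readr::read_csv(path, col_types = cols, progress = FALSE)
  missing_cols <- setdiff(names(cols$cols), names(ser))
  if (length(missing_cols) > 0) {
    abort(paste0("series file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "icptrend_validation_error")
  }
  validate_series(ser)
  ser
}

validate_series <- function(ser) {
  if (anyNA(ser$hour_index) || any(ser$hour_index < 0)) {
    abort("hour_index must be a non-negative integer for every reading",
          class = "icptrend_validation_error")
  }
  if (anyNA(ser$icp_mmhg) || any(!is.finite(ser$icp_mmhg)) ||
      any(ser$icp_mmhg < 0)) {
    abort("icp_mmhg must be finite and >= 0 for every reading",
          class = "icptrend_validation_error")
  }
  if (any(ser$icp_mmhg > 100)) {
    abort("icp_mmhg above 100 mmHg sanity ceiling (check units: cmH2O vs mmHg?)",
          class = "icptrend_validation_error")
  }
  dup <- ser |>
    dplyr::count(.data$patient_id, .data$hour_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate hour_index for patient ", dup$patient_id[1]),
          class = "icptrend_validation_error")
  }
  invisible(ser)
}

#' Map an hour index to a postoperative monitoring day
#'
#' Hour 0 is the first reading after monitoring starts (four hours after skin
#' closure); days are half-open 24-hour windows, so day 1 covers hours 0-23,
#' day 2 hours 24-47 and day 3 hours 48-71. Indices at 72 or beyond fall past
#' the three-day analysis horizon and map to day 4+.
#'
#' @param hour_index Integer vector of hours since monitoring start, >= 0.
#' @return Integer vector of day indices (1-based).
#' @examples
#' assign_day(c(0, 23, 24, 71, 72))
#' @export
assign_day <- function(hour_index) {
  if (anyNA(hour_index) || any(hour_index < 0)) {
    abort("hour_index must be >= 0", class = "icptrend_validation_error")
  }
  as.integer(hour_index %/% 24L + 1L)
}

#' Compute daily average values (DAV) from hourly ICP readings
#'
#' Averages each patient's hourly pressures within postoperative days 1-3.
#' A day's DAV is reported only when at least `min_readings_per_day` readings
#' exist for that day; the strict default of 24 requires the full set of
#' hourly values, so any interrupted day (e.g. an accidentally pulled drain)
#' marks the patient incomplete and excludes them downstream. Readings past
#' hour 71 are outside the analysis horizon and are dropped with a warning.
#'
#' @param series Tibble of readings as returned by [read_icp_series()]
#'   (columns `patient_id, hour_index, icp_mmhg`), covering one or many
#'   patients.
#' @param min_readings_per_day Minimum hourly readings a day needs before its
#'   average is considered valid; integer in 1..24, default 24.
#' @return A tibble with one row per patient: `dav1, dav2, dav3` (mmHg, `NA`
#'   when the day fails the reading threshold), `n1, n2, n3` reading counts,
#'   and `complete` (`TRUE` iff all three DAVs are present).
#' @examples
#' ser <- tibble::tibble(patient_id = "p1", hour_index = 0:71,
#'                       icp_mmhg = rep(c(5, 6, 7), each = 24))
#' compute_dav(ser)
#' @export
compute_dav <- function(series, min_readings_per_day = 24L) {
  if (!is.numeric(min_readings_per_day) || length(min_readings_per_day) != 1 ||
      is.na(min_readings_per_day) || min_readings_per_day < 1 ||
      min_readings_per_day > 24) {
    abort("min_readings_per_day must be a single integer in 1..24",
          class = "icptrend_config_error")
  }
  validate_series(series)
  if (nrow(series) == 0) {
    abort("series is empty", class = "icptrend_validation_error")
  }
  series <- dplyr::mutate(series, day = assign_day(.data$hour_index))
  beyond <- series$day > 3L
  if (any(beyond)) {
    warn(paste0(sum(beyond), " reading(s) beyond hour 71 ignored ",
                "(three-day analysis horizon)"))
    series <- series[!beyond, , drop = FALSE]
  }
  per_day <- series |>
    dplyr::group_by(.data$patient_id, .data$day) |>
    dplyr::summarise(dav = mean(.data$icp_mmhg), n = dplyr::n(),
                     .groups = "drop")
  grid <- tidyr::expand_grid(patient_id = unique(series$patient_id),
                             day = 1:3)
  per_day <- dplyr::left_join(grid, per_day, by = c("patient_id", "day")) |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
                  dav = ifelse(.data$n >= min_readings_per_day, .data$dav,
                               NA_real_))
  out <- per_day |>
    tidyr::pivot_wider(names_from = "day",
                       values_from = c("dav", "n"), names_sep = "") |>
    dplyr::mutate(complete = !is.na(.data$dav1) & !is.na(.data$dav2) &
                    !is.na(.data$dav3)) |>
    dplyr::select("patient_id", "dav1", "dav2", "dav3",
                  "n1", "n2", "n3", "complete")
  tibble::as_tibble(out)
}

#' Summarize a cohort in the style of a clinical baseline table
#'
#' Produces counts and percentages by age stratum, sex and etiology
#' (percentages on the full cohort denominator) together with mean, SD,
#' median, minimum and maximum of opening pressure and of the three DAVs over
#' complete patients. With a single contributing patient the SD is reported
#' as missing rather than 0.
#'
#' @param patients Patient tibble from [read_patients()].
#' @param davs DAV tibble from [compute_dav()]; only `complete` patients
#'   contribute to the DAV summaries.
#' @return A list with `demographics` (variable, level, n, percent) and
#'   `pressures` (variable, n, mean, sd, median, min, max) tibbles, plus
#'   `n_patients` and `n_complete`.
#' @export
cohort_summary <- function(patients, davs) {
  if (nrow(patients) == 0) {
    abort("empty cohort", class = "icptrend_validation_error")
  }
  n <- nrow(patients)
  age_stratum <- cut(patients$age_months, breaks = c(-Inf, 3, 6, Inf),
                     labels = c("0-3", ">3-6", ">6"))
  n_total <- n
  count_block <- function(var, values, levels) {
    tab <- table(factor(values, levels = levels))
    tibble::tibble(variable = var, level = names(tab),
                   n = as.integer(tab),
                   percent = 100 * as.integer(tab) / n_total)
  }
  demographics <- dplyr::bind_rows(
    count_block("age_months", age_stratum, levels(age_stratum)),
    count_block("sex", patients$sex, .sex_levels),
    count_block("etiology", patients$etiology, .etiology_levels)
  )
  complete <- dplyr::filter(davs, .data$complete)
  num_block <- function(var, x) {
    x <- x[!is.na(x)]
    tibble::tibble(
      variable = var, n = length(x),
      mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) sd(x) else NA_real_,
      median = if (length(x)) median(x) else NA_real_,
      min = if (length(x)) min(x) else NA_real_,
      max = if (length(x)) max(x) else NA_real_
    )
  }
  pressures <- dplyr::bind_rows(
    num_block("opening_pressure_mmhg", patients$opening_pressure_mmhg),
    num_block("dav1", complete$dav1),
    num_block("dav2", complete$dav2),
    num_block("dav3", complete$dav3)
  )
  list(demographics = demographics, pressures = pressures,
       n_patients = n, n_complete = nrow(complete))
}
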