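#' Run the full ICP-trend analysis pipeline
#'
#' Orchestrates ingest (or simulation) -> daily averages -> trend
#' classification across margins -> diagnostic evaluation -> cohort summary,
#' writing every intermediate and final artifact to `out_dir` and logging
#' patient counts at each stage to stderr. All randomness flows from the
#' simulate block's seed, so a fixed configuration reproduces identical
#' artifacts.
#'
#' @param config A run configuration: a named list, or a path to a YAML or
#'   JSON file with the same structure. Exactly one of `input` (list with
#'   `patients` and `series` file paths) or `simulate` (a [cohort_config()]
#'   parameter list, seed included) must be present. Optional fields:
#'   `min_readings_per_day` (default 24), `margins` (default 1:5), `rule`
#'   (`"monotone"`/`"net_only"`), `confidence` (0.95), `ci_method`
#'   (`"clopper-pearson"`/`"wilson"`), `correct` (Yates flag, FALSE),
#'   `out_dir` (default: no files written).
#' @return A list of class `icp_run`: `patients`, `davs`, `calls` (margin
#'   sweep), `report` ([sweep_report()] output), `summary`
#'   ([cohort_summary()] output plus stage counts), `config`, `config_hash`,
#'   and `paths` of written artifacts (empty when `out_dir` is `NULL`).
#' @examples
#' run <- run_pipeline(list(simulate = list(n_patients = 20, seed = 7),
#'                          margins = c(1, 2)))
#' run$summary$n_analyzable
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  log_stage <- function(...) message("[icptrend] ", ...)

  if (!is.null(config$simulate)) {
    log_stage("stage=simulate n_patients=", config$simulate$n_patients,
              " seed=", config$simulate$seed)
    cohort <- simulate_cohort(do.call(cohort_config, config$simulate))
    patients <- cohort$patients
    series <- cohort$series
  } else {
    log_stage("stage=ingest patients=", config$input$patients,
              " series=", config$input$series)
    cohort <- NULL
    patients <- read_patients(config$input$patients)
    series <- read_icp_series(config$input$series)
  }
  validate_patients(patients)
  log_stage("stage=read n_patients=", nrow(patients))

  davs <- compute_dav(series, config$min_readings_per_day)
  davs <- dplyr::left_join(patients["patient_id"], davs, by = "patient_id") |>
    dplyr::mutate(complete = !is.na(.data$complete) & .data$complete)
  n_complete <- sum(davs$complete)
  log_stage("stage=dav n_analyzable=", n_complete,
            " n_excluded=", nrow(patients) - n_complete)
  if (n_complete == 0) {
    abort("no patient has complete three-day monitoring; nothing to classify",
          class = "icptrend_validation_error")
  }

  complete_davs <- dplyr::filter(davs, .data$complete)
  calls <- sweep_margins(complete_davs, config$margins, rule = config$rule)
  counts <- sweep_counts(calls)
  for (i in seq_len(nrow(counts))) {
    log_stage("stage=classify margin=", counts$margin_mmhg[i],
              " stable=", counts$n_stable[i],
              " progressive=", counts$n_progressive[i])
  }

  report <- sweep_report(calls, patients, confidence = config$confidence,
                         ci_method = config$ci_method,
                         correct = config$correct)
  log_stage("stage=evaluate margins=",
            paste(config$margins, collapse = ","))

  summary <- cohort_summary(patients, davs)
  summary$n_analyzable <- n_complete
  summary$n_excluded <- nrow(patients) - n_complete
  summary$label_counts <- counts

  hash <- config_hash(config)
  paths <- list()
  if (!is.null(config$out_dir)) {
    paths <- write_run_artifacts(config$out_dir, patients, series, davs,
                                 calls, report, summary, config, hash)
    log_stage("stage=write out_dir=", config$out_dir)
  }

  structure(list(patients = patients, davs = davs, calls = calls,
                 report = report, summary = summary, cohort = cohort,
                 config = config, config_hash = hash, paths = paths),
            class = "icp_run")
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "icptrend_io_error")
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) {
    abort("config must be a named list or a YAML/JSON file path",
          class = "icptrend_config_error")
  }
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    abort("config must contain exactly one of 'input' or 'simulate'",
          class = "icptrend_config_error")
  }
  if (has_input &&
      (is.null(config$input$patients) || is.null(config$input$series))) {
    abort("config$input needs 'patients' and 'series' file paths",
          class = "icptrend_config_error")
  }
  defaults <- list(min_readings_per_day = 24L, margins = 1:5,
                   rule = "monotone", confidence = 0.95,
                   ci_method = "clopper-pearson", correct = FALSE,
                   out_dir = NULL)
  config <- modifyList(defaults, config)
  margins <- as.numeric(config$margins)
  if (length(margins) == 0 || anyNA(margins) || any(margins <= 0) ||
      is.unsorted(margins, strictly = TRUE)) {
    abort("config 'margins' must be nonempty, strictly increasing and > 0",
          class = "icptrend_config_error")
  }
  config$margins <- margins
  config$rule <- match.arg(config$rule, c("monotone", "net_only"))
  config$ci_method <- match.arg(config$ci_method,
                                c("clopper-pearson", "wilson"))
  config
}

config_hash <- function(config) {
  # hash only settings that affect the analysis, not where results land
  config <- config[setdiff(names(config), "out_dir")]
  canon <- jsonlite::toJSON(config[sort(names(config))], auto_unbox = TRUE,
                            digits = NA, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canon), tmp)
  unname(tools::md5sum(tmp))
}

write_run_artifacts <- function(out_dir, patients, series, davs, calls,
                                report, summary, config, hash) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(name) file.path(out_dir, name)
  paths <- list(davs = p("davs.csv"), calls = p("calls.csv"),
                report = p("report.json"), summary = p("summary.json"))
  readr::write_csv(davs, paths$davs, progress = FALSE)
  readr::write_csv(calls, paths$calls, progress = FALSE)
  jsonlite::write_json(
    list(config_hash = hash,
         metrics = report$metrics, success_rates = report$success_rates,
         chi_square = report$chi_square, counts = report$counts,
         note = report$note),
    paths$report, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  jsonlite::write_json(
    list(config_hash = hash, n_patients = summary$n_patients,
         n_analyzable = summary$n_analyzable,
         n_excluded = summary$n_excluded,
         label_counts = summary$label_counts,
         demographics = summary$demographics,
         pressures = summary$pressures),
    paths$summary, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  paths
}

#' @export
print.icp_run <- function(x, ...) {
  cat("ICP-trend pipeline run (config ", substr(x$config_hash, 1, 8), ")\n",
      sep = "")
  cat("Patients:", x$summary$n_patients,
      "| analyzable:", x$summary$n_analyzable,
      "| excluded:", x$summary$n_excluded, "\n")
  print(x$summary$label_counts)
  invisible(x)
}

#' Render run results as publication-style tables
#'
#' Formats a pipeline run into the four table layouts conventional for this
#' analysis: a pressure-summary table (mean/SD/median/range of opening
#' pressure and DAV1-3), one diagnostic-metric table per prediction
#' direction at a chosen margin (percentages to 2 decimal places with 95%
#' CIs), and the margin-sweep table (per-margin cell counts with percentages
#' and sensitivity/specificity to 1 decimal place). Metrics with an empty
#' denominator render as `"undefined"` with a footnote.
#'
#' @param run An `icp_run` from [run_pipeline()].
#' @param metric_margin Margin (mmHg) at which the two per-direction metric
#'   tables are rendered; default 2.
#' @return A list of character data frames: `pressure_summary`,
#'   `stable_predicts_success`, `progressive_predicts_failure`, `sweep`, and
#'   `footnotes`.
#' @export
render_paper_tables <- function(run, metric_margin = 2) {
  stopifnot(inherits(run, "icp_run"))
  fmt <- function(x, d) ifelse(is.na(x), "undefined",
                               formatC(x, format = "f", digits = d))
  pct <- function(x, d = 2) ifelse(is.na(x), "undefined",
                                   paste0(fmt(100 * x, d), "%"))

  ps <- run$summary$pressures
  pressure_summary <- data.frame(
    measure = c("Opening pressure", "DAV at POD 1", "DAV at POD 2",
                "DAV at POD 3"),
    mean = fmt(ps$mean, 2), sd = fmt(ps$sd, 2), median = fmt(ps$median, 2),
    minimum = fmt(ps$min, 2), maximum = fmt(ps$max, 2),
    check.names = FALSE)

  metric_table <- function(direction) {
    met <- run$report$metrics
    met <- met[met$margin_mmhg == metric_margin &
                 met$direction == direction, , drop = FALSE]
    if (nrow(met) == 0) {
      abort(paste0("margin ", metric_margin, " not present in this run"),
            class = "icptrend_validation_error")
    }
    data.frame(
      test = c("Sensitivity", "Specificity", "Positive predictive value",
               "Negative predictive value")[match(met$metric,
                 c("sensitivity", "specificity", "ppv", "npv"))],
      value = pct(met$estimate),
      `95% CI` = ifelse(is.na(met$estimate), "undefined",
                        paste0(fmt(100 * met$ci_low, 2), "-",
                               fmt(100 * met$ci_high, 2))),
      check.names = FALSE)
  }

  counts_of <- function(m) {
    calls_m <- run$calls[run$calls$margin_mmhg == m, , drop = FALSE]
    build_contingency(calls_m, run$patients)
  }
  margins <- sort(unique(run$calls$margin_mmhg))
  n_total <- run$summary$n_analyzable
  sweep_rows <- lapply(margins, function(m) {
    tab <- counts_of(m)
    met <- run$report$metrics
    sens_stable <- met$estimate[met$margin_mmhg == m &
                                  met$direction == "stable_predicts_success" &
                                  met$metric == "sensitivity"]
    spec_stable <- met$estimate[met$margin_mmhg == m &
                                  met$direction == "stable_predicts_success" &
                                  met$metric == "specificity"]
    cellpct <- function(k) paste0(k, " (", fmt(100 * k / n_total, 1), "%)")
    data.frame(
      margin = paste0(">", m, " mm"),
      trend = c("Stable", "Increasing"),
      failure = cellpct(tab[, "failure"]),
      success = cellpct(tab[, "success"]),
      total = cellpct(rowSums(tab)),
      sensitivity = fmt(100 * c(sens_stable, spec_stable), 1),
      specificity = fmt(100 * c(spec_stable, sens_stable), 1),
      check.names = FALSE)
  })

  list(pressure_summary = pressure_summary,
       stable_predicts_success = metric_table("stable_predicts_success"),
       progressive_predicts_failure =
         metric_table("progressive_predicts_failure"),
       sweep = do.call(rbind, sweep_rows),
       footnotes = c(
         "undefined: metric denominator is empty in this cohort",
         run$report$note))
}
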