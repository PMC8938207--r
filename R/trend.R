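#' Classify a three-day DAV trajectory as stable or progressively increasing
#'
#' A patient shows a *progressive increase* trend at margin `margin_delta`
#' when the daily average value rose continuously across the three monitored
#' days (DAV1 < DAV2 < DAV3, strict) and the day-1 to day-3 increase exceeds
#' the margin (DAV3 - DAV1 > `margin_delta`, strict). Every other complete
#' trajectory — flat, falling, non-monotone, or rising by exactly the margin
#' or less — is *stable*. Comparisons are made on the computed DAVs without
#' rounding. With `rule = "net_only"` the monotonicity clause is dropped and
#' only the net day-1 to day-3 difference is tested.
#'
#' @param davs DAV tibble from [compute_dav()]; every row must be `complete`
#'   (exclude incomplete patients upstream).
#' @param margin_delta Classification margin in mmHg, > 0.
#' @param rule `"monotone"` (default: continuous rise required) or
#'   `"net_only"`.
#' @return A tibble of trend calls: `patient_id, margin_mmhg, label,
#'   dav_delta_13, monotone`.
#' @examples
#' davs <- tibble::tibble(patient_id = c("a", "b"),
#'                        dav1 = c(5, 5), dav2 = c(6, 8), dav3 = c(7.5, 7.5),
#'                        n1 = 24, n2 = 24, n3 = 24, complete = TRUE)
#' classify_trend(davs, margin_delta = 2)
#' @export
classify_trend <- function(davs, margin_delta,
                           rule = c("monotone", "net_only")) {
  rule <- match.arg(rule)
  if (!is.numeric(margin_delta) || length(margin_delta) != 1 ||
      is.na(margin_delta) || margin_delta <= 0) {
    abort("margin_delta must be a single positive number (mmHg)",
          class = "icptrend_config_error")
  }
  if (nrow(davs) == 0) {
    abort("no DAV rows to classify", class = "icptrend_validation_error")
  }
  if (any(!davs$complete)) {
    abort(paste0("incomplete DAV rows for patient(s) ",
                 paste(davs$patient_id[!davs$complete], collapse = ", "),
                 "; exclude incomplete patients before classification"),
          class = "icptrend_validation_error")
  }
  monotone <- davs$dav1 < davs$dav2 & davs$dav2 < davs$dav3
  delta13 <- davs$dav3 - davs$dav1
  rising <- if (rule == "monotone") monotone else rep(TRUE, nrow(davs))
  label <- ifelse(rising & delta13 > margin_delta,
                  "progressive_increase", "stable")
  tibble::tibble(patient_id = davs$patient_id,
                 margin_mmhg = margin_delta,
                 label = label,
                 dav_delta_13 = delta13,
                 monotone = monotone)
}

#' Classify every patient at a grid of margins
#'
#' Applies [classify_trend()] at each margin of an increasing grid and
#' verifies the nesting invariant: the progressive-increase set at a larger
#' margin is always a subset of that at a smaller margin.
#'
#' @param davs Complete DAV tibble (see [classify_trend()]).
#' @param margins Strictly increasing vector of positive margins in mmHg;
#'   default `1:5`, the conventional sweep.
#' @inheritParams classify_trend
#' @return A tibble of calls over all margins (class `icp_margin_sweep`),
#'   with one row per patient per margin.
#' @export
sweep_margins <- function(davs, margins = 1:5,
                          rule = c("monotone", "net_only")) {
  rule <- match.arg(rule)
  if (length(margins) == 0) {
    abort("margins must be nonempty", class = "icptrend_config_error")
  }
  if (any(margins <= 0) || is.unsorted(margins, strictly = TRUE)) {
    abort("margins must be strictly increasing and > 0",
          class = "icptrend_config_error")
  }
  calls <- dplyr::bind_rows(
    lapply(margins, function(m) classify_trend(davs, m, rule = rule))
  )
  # Nesting must hold by construction; a violation indicates corrupted input
  # (e.g. duplicated patient ids) rather than a tuning issue.
  prog_sets <- lapply(margins, function(m) {
    calls$patient_id[calls$margin_mmhg == m &
                       calls$label == "progressive_increase"]
  })
  for (i in seq_along(margins)[-1]) {
    if (!all(prog_sets[[i]] %in% prog_sets[[i - 1]])) {
      abort("nesting invariant violated across margins; check for duplicate patient ids",
            class = "icptrend_internal_error")
    }
  }
  structure(calls, class = c("icp_margin_sweep", class(calls)))
}

#' Per-margin label counts from a margin sweep
#'
#' @param calls Sweep tibble from [sweep_margins()].
#' @return Tibble `margin_mmhg, n_stable, n_progressive, n_total`.
#' @export
sweep_counts <- function(calls) {
  calls |>
    dplyr::group_by(.data$margin_mmhg) |>
    dplyr::summarise(
      n_stable = sum(.data$label == "stable"),
      n_progressive = sum(.data$label == "progressive_increase"),
      n_total = dplyr::n(),
      .groups = "drop"
    )
}
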