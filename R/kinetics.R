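# Plate-reader luminescence quantification: baseline correction, peak,
# trapezoidal area under the curve, and normalization to control conditions.

#' Baseline-correct a plate series
#'
#' Subtracts, per well, the mean luminescence over a baseline window (e.g.
#' the pre-addition read) and clamps at zero.
#'
#' @param series A [plate_series()].
#' @param baseline_window Length-2 numeric, minutes; inclusive time range.
#' @return A corrected [plate_series()].
#' @export
baseline_correct <- function(series, baseline_window) {
  if (length(baseline_window) != 2L || baseline_window[2] < baseline_window[1]) {
    stop("baseline_window must be an increasing length-2 range", call. = FALSE)
  }
  sel <- series$times >= baseline_window[1] & series$times <= baseline_window[2]
  if (!any(sel)) stop("baseline window contains no sampled times", call. = FALSE)
  base <- colMeans(series$values[sel, , drop = FALSE])
  vals <- pmax(sweep(series$values, 2, base), 0)
  plate_series(series$times, vals, series$well_labels, series$condition_map)
}

#' Peak luminescence of one well
#'
#' @param series A [plate_series()].
#' @param well Well label or column index.
#' @return List with `peak` (RLU) and `t_peak` (minutes); ties broken by the
#'   earliest time.
#' @export
peak_luminescence <- function(series, well) {
  v <- series$values[, well]
  i <- which.max(v)  # which.max returns the first (earliest) maximum
  list(peak = v[i], t_peak = series$times[i])
}

#' Trapezoidal area under the luminescence curve
#'
#' @param series A [plate_series()].
#' @param well Well label or column index.
#' @param t_range Length-2 numeric, minutes; must lie within the sampled
#'   times and contain at least two samples. Defaults to the full range.
#' @return AUC in RLU-minutes.
#' @export
auc <- function(series, well, t_range = range(series$times)) {
  if (t_range[1] < min(series$times) || t_range[2] > max(series$times)) {
    stop("t_range lies outside the sampled times", call. = FALSE)
  }
  sel <- series$times >= t_range[1] & series$times <= t_range[2]
  if (sum(sel) < 2L) stop("t_range must span at least two samples", call. = FALSE)
  pracma::trapz(series$times[sel], series$values[sel, well])
}

#' Normalize summary values to a control condition
#'
#' Each value is expressed as a percentage of the control-condition mean, so
#' the control averages 100%.
#'
#' @param values Numeric vector of per-well (or per-animal, per-sample)
#'   summaries.
#' @param conditions Condition label per value.
#' @param control_label The control condition (e.g. vehicle/DMSO).
#' @return Numeric vector of percentages.
#' @export
normalize_to_control <- function(values, conditions, control_label) {
  ctrl <- values[conditions == control_label]
  if (!length(ctrl)) stop("control condition absent", call. = FALSE)
  m <- mean(ctrl)
  if (!is.finite(m) || m == 0) stop("control mean is zero or undefined", call. = FALSE)
  100 * values / m
}

#' Survival (or abundance) as percent of an untreated reference
#'
#' @param treated Measured value(s) under treatment.
#' @param untreated_mean Mean of the untreated reference; must be > 0.
#' @return Percentage value(s).
#' @export
survival_fraction <- function(treated, untreated_mean) {
  if (untreated_mean <= 0) stop("untreated mean must be > 0", call. = FALSE)
  100 * treated / untreated_mean
}

#' Per-well kinetics summary table
#'
#' @param series A [plate_series()].
#' @param baseline_window Optional baseline window passed to
#'   [baseline_correct()].
#' @param t_range AUC integration range (default: full).
#' @param control_label Optional condition label; when given and the series
#'   carries a condition map, peak and AUC are also expressed as percent of
#'   that condition's mean.
#' @return A tibble with one row per well: `well`, `condition`, `baseline`,
#'   `peak`, `t_peak`, `auc`, and (optionally) `peak_pct_control`,
#'   `auc_pct_control`.
#' @export
summarize_kinetics <- function(series, baseline_window = NULL,
                               t_range = NULL, control_label = NULL) {
  base <- rep(0, length(series$well_labels))
  if (!is.null(baseline_window)) {
    sel <- series$times >= baseline_window[1] & series$times <= baseline_window[2]
    base <- colMeans(series$values[sel, , drop = FALSE])
    series <- baseline_correct(series, baseline_window)
  }
  if (is.null(t_range)) t_range <- range(series$times)
  rows <- lapply(seq_along(series$well_labels), function(i) {
    pk <- peak_luminescence(series, i)
    tibble::tibble(
      well = series$well_labels[i],
      condition = if (is.null(series$condition_map)) NA_character_ else
        unname(series$condition_map[series$well_labels[i]]),
      baseline = base[i],
      peak = pk$peak,
      t_peak = pk$t_peak,
      auc = auc(series, i, t_range)
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(control_label) && !is.null(series$condition_map)) {
    out$peak_pct_control <- normalize_to_control(out$peak, out$condition, control_label)
    out$auc_pct_control <- normalize_to_control(out$auc, out$condition, control_label)
  }
  out
}
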