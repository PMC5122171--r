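#' Per-scenario accuracy summary
#'
#' Computes the five accuracy quantities for a collection of primary
#' coefficient estimates and their confidence intervals against the true
#' value: (i) bias `mean(estimate) - true`; (ii) relative bias
#' `bias / true` (undefined and stored as `NA` when `true = 0`);
#' (iii) coverage, the fraction of intervals containing the true value;
#' (iv) mean interval width; (v) mean square error
#' `bias^2 + SD(estimate)^2` with the sample standard deviation
#' (denominator `n - 1`).
#'
#' @param estimates Numeric vector of primary-coefficient estimates.
#' @param lower,upper Interval bounds aligned with `estimates`, or `NULL`
#'   when no intervals were computed (coverage and width become `NA`).
#' @param true_value True coefficient value.
#' @return One-row tibble: `n_used`, `bias`, `relative_bias`, `coverage`,
#'   `mean_ci_width`, `mse`, `sd`.
#' @examples
#' summarize_estimates(c(1.2, 0.8), lower = c(0, -1), upper = c(3, 2),
#'                     true_value = 1)
#' @export
summarize_estimates <- function(estimates, lower = NULL, upper = NULL,
                                true_value) {
  n <- length(estimates)
  if (n < 2) stop("need at least 2 estimates", call. = FALSE)
  if (!is.null(lower) && (length(lower) != n || length(upper) != n)) {
    stop("estimates and intervals must be aligned", call. = FALSE)
  }
  bias <- mean(estimates) - true_value
  sd_est <- stats::sd(estimates)
  tibble::tibble(
    n_used = n,
    bias = bias,
    relative_bias = if (abs(true_value) > 0) bias / true_value else NA_real_,
    coverage = if (is.null(lower)) NA_real_ else
      mean(lower <= true_value & true_value <= upper),
    mean_ci_width = if (is.null(lower)) NA_real_ else mean(upper - lower),
    mse = bias^2 + sd_est^2,
    sd = sd_est
  )
}

#' Aggregate scenario summaries into EPV bands
#'
#' For each band of EPV values, reports the arithmetic mean, maximum and
#' minimum over member scenarios of bias, relative bias, coverage, interval
#' width and MSE, plus the percentage of member scenarios with relative
#' bias above +10% and the percentage with coverage outside the nominal
#' level by more than one percentage point. Relative-bias aggregates skip
#' scenarios with a zero true coefficient (where relative bias is
#' undefined); bias aggregates include them.
#'
#' @param summaries Tibble of per-scenario summaries carrying at least
#'   `epv`, `bias`, `relative_bias`, `coverage`, `mean_ci_width`, `mse`,
#'   and grouping columns such as `estimator`/`policy` if present.
#' @param bands Named list of numeric EPV ranges, e.g.
#'   `list("15 to 30" = c(15, 30))`.
#' @param nominal Nominal coverage level (default 0.90).
#' @return A tibble, one row per band (by any `estimator`/`policy` groups),
#'   with `*_mean`, `*_max`, `*_min` columns, `pct_relbias_gt10` and
#'   `pct_coverage_off`.
#' @export
band_summary <- function(summaries, bands, nominal = 0.90) {
  stopifnot(length(bands) >= 1)
  group_cols <- intersect(c("estimator", "policy", "detector", "conv"),
                          names(summaries))
  purrr::imap_dfr(bands, function(range, label) {
    sub <- dplyr::filter(summaries, .data$epv >= range[1],
                         .data$epv <= range[2])
    if (nrow(sub) == 0) stop("empty EPV band: ", label, call. = FALSE)
    sub |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
      dplyr::summarise(
        band = label,
        n_scenarios = dplyr::n(),
        bias_mean = mean(.data$bias),
        bias_max = max(.data$bias),
        bias_min = min(.data$bias),
        relbias_mean = mean(.data$relative_bias, na.rm = TRUE),
        relbias_max = suppressWarnings(max(.data$relative_bias, na.rm = TRUE)),
        relbias_min = suppressWarnings(min(.data$relative_bias, na.rm = TRUE)),
        pct_relbias_gt10 =
          100 * mean(.data$relative_bias > 0.10, na.rm = TRUE),
        coverage_mean = mean(.data$coverage),
        coverage_max = max(.data$coverage),
        coverage_min = min(.data$coverage),
        pct_coverage_off =
          100 * mean(abs(.data$coverage - nominal) > 0.01),
        width_mean = mean(.data$mean_ci_width),
        mse_mean = mean(.data$mse),
        mse_max = max(.data$mse),
        mse_min = min(.data$mse),
        .groups = "drop"
      ) |>
      dplyr::relocate("band")
  })
}
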