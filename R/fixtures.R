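#' Write the canonical small test datasets
#'
#' Generates the fixed toy datasets used throughout the package's tests and
#' examples and writes them as CSV files in the package's dataset dialect:
#'
#' * `complete_sep`: `x = (-2, -1, 1, 2)`, `y = (0, 0, 1, 1)` — complete
#'   separation, no finite MLE;
#' * `quasi_sep`: `x = (0, 0, 1)`, `y = (0, 1, 1)` — quasi-complete;
#' * `overlap_2x2`: both classes at both levels of a binary covariate;
#' * `cells_6446`: the 2x2 table with cell counts (events at x=1, events at
#'   x=0, non-events at x=1, non-events at x=0) = (6, 4, 4, 6), whose ML
#'   estimate is the closed-form log odds ratio `log(2.25)`;
#' * `balanced_200`: 200 seeded quota-sampled rows, one standard-normal
#'   covariate, `beta1 = log(2)`, 100 events — well overlapped.
#'
#' Regeneration with the same seed is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the one stochastic fixture.
#' @return Named list of the fixture tibbles (invisibly written to `dir`).
#' @export
make_fixtures <- function(dir = ".", seed = 20160101) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- list(
    complete_sep = tibble::tibble(y = c(0L, 0L, 1L, 1L),
                                  x1 = c(-2, -1, 1, 2)),
    quasi_sep = tibble::tibble(y = c(0L, 1L, 1L), x1 = c(0, 0, 1)),
    overlap_2x2 = tibble::tibble(y = c(0L, 0L, 1L, 1L), x1 = c(0, 1, 0, 1)),
    cells_6446 = tibble::tibble(
      y = rep(c(1L, 1L, 0L, 0L), c(6, 4, 4, 6)),
      x1 = rep(c(1, 0, 1, 0), c(6, 4, 4, 6))),
    balanced_200 = sample_quota(
      true_model(log(2), prevalence = 0.5),
      n_total = 200, n_events = 100, seed = seed)
  )
  for (nm in names(fx)) {
    write_dataset(fx[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(fx)
}
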