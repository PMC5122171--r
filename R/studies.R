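study_ids <- c("Ia", "Ib", "Ic", "Id", "IIa", "IIb", "custom")

#' Build the factorial scenario grid for one simulation study
#'
#' The six studies cross events-per-variable (EPV) with one further factor
#' each, holding the rest fixed:
#'
#' * `Ia`: EPV 15 to 150 (step 5) x odds ratio `e^beta1` in
#'   \{1/4, 1/2, 1, 2, 4\}; one standard-normal covariate, prevalence 1/2.
#' * `Ib`: same EPV grid x P in \{2, 3, 4\} x `e^beta` in \{2, 4\} (all
#'   coefficients equal); independent standard normal, prevalence 1/2.
#' * `Ic`: EPV 6 to 30 (step 2) x prevalence in
#'   \{1/2, 1/3, 1/4, 1/5, 1/10\}; P = 2, `e^beta` = 2, uncorrelated.
#' * `Id`: EPV 6 to 30 (step 2) x common covariate correlation `rho` in
#'   \{0.10, 0.15, 0.20, 0.25\}; P = 2, `e^beta` = 2, prevalence 1/4.
#' * `IIa`: EPV 6 to 30 (step 2) x `beta1` in \{log 1, log 2, log 4\}; one
#'   Bernoulli(0.5) covariate, events:non-events 1:1.
#' * `IIb`: the single cell EPV = 4, `beta1` = log 4, one standard-normal
#'   covariate, 1:1 (N = 8).
#'
#' `n_events = EPV x P` and `n_total = n_events / prevalence` (rounded to
#' the nearest integer where the prevalence is not a divisor).
#'
#' @param study One of `"Ia"`, `"Ib"`, `"Ic"`, `"Id"`, `"IIa"`, `"IIb"`.
#' @return A tibble, one row per scenario: `study`, `scenario`, `epv`, `p`,
#'   `prevalence`, `law`, `rho`, `beta1`, `coefficients` (list column),
#'   `n_events`, `n_total`.
#' @examples
#' nrow(build_grid("Ia"))  # 140 scenarios
#' build_grid("IIb")
#' @export
build_grid <- function(study = c("Ia", "Ib", "Ic", "Id", "IIa", "IIb")) {
  study <- match.arg(study)
  epv_hi <- seq(15, 150, by = 5)
  epv_lo <- seq(6, 30, by = 2)
  g <- switch(study,
    Ia = tidyr::expand_grid(epv = epv_hi, or = c(1/4, 1/2, 1, 2, 4)) |>
      dplyr::mutate(p = 1L, prevalence = 1/2, law = "normal", rho = 0),
    Ib = tidyr::expand_grid(epv = epv_hi, p = 2:4, or = c(2, 4)) |>
      dplyr::mutate(prevalence = 1/2, law = "normal", rho = 0),
    Ic = tidyr::expand_grid(epv = epv_lo,
                            prevalence = c(1/2, 1/3, 1/4, 1/5, 1/10)) |>
      dplyr::mutate(or = 2, p = 2L, law = "normal", rho = 0),
    Id = tidyr::expand_grid(epv = epv_lo, rho = c(0.10, 0.15, 0.20, 0.25)) |>
      dplyr::mutate(or = 2, p = 2L, prevalence = 1/4, law = "equicorrelated"),
    IIa = tidyr::expand_grid(epv = epv_lo, or = c(1, 2, 4)) |>
      dplyr::mutate(p = 1L, prevalence = 1/2, law = "bernoulli", rho = 0),
    IIb = tibble::tibble(epv = 4, or = 4, p = 1L, prevalence = 1/2,
                         law = "normal", rho = 0)
  )
  g |>
    dplyr::mutate(
      study = study,
      scenario = dplyr::row_number(),
      beta1 = log(.data$or),
      coefficients = purrr::map2(.data$or, .data$p,
                                 function(or, p) rep(log(or), p)),
      n_events = as.integer(.data$epv * .data$p),
      n_total = as.integer(round(.data$n_events / .data$prevalence))
    ) |>
    dplyr::select("study", "scenario", "epv", "p", "prevalence", "law",
                  "rho", "beta1", "coefficients", "n_events", "n_total")
}

scenario_model <- function(scenario) {
  true_model(scenario$coefficients[[1]],
             law = scenario$law, rho = scenario$rho,
             prevalence = scenario$prevalence)
}

#' Run one simulation scenario
#'
#' For each replicate: quota-sample a dataset, fit the logistic model by
#' maximum likelihood under every convergence specification in
#' `conv_variants` and by Firth's correction, run the requested separation
#' detectors, and compute the 90% Wald (ML) and profile penalized-likelihood
#' (Firth) confidence intervals for the primary coefficient (`x1`). The
#' replicate-level results are then assembled into accuracy summaries per
#' estimator, detector and handling policy:
#'
#' * `remove`: drop replicates flagged by the detector or not converged;
#' * `keep_naive`: keep every replicate's last-iterate output regardless of
#'   convergence or separation status;
#' * `replace_max`: substitute each flagged replicate's primary estimate
#'   (and interval) with those of the replicate holding the largest
#'   non-flagged estimate.
#'
#' For each convergence variant an ML summary with `detector =
#' "nonconvergence"` (drop non-converged only) is always produced; the
#' tracing/threshold detector summaries use the first (default) variant.
#' Firth summaries always use all replicates — its estimates are finite on
#' separated data, so nothing is removed.
#'
#' @param scenario One row of a [build_grid()] tibble (or a tibble with the
#'   same columns).
#' @param n_reps Number of simulated datasets.
#' @param master_seed Integer master seed; each replicate derives its own
#'   RNG stream from (master seed, study, scenario, replicate).
#' @param conv_variants Named list of [conv_spec()]s for the ML fits; the
#'   first is the default used by the detector policies.
#' @param detectors Character subset of `c("tracing", "threshold")` to run
#'   per replicate (non-convergence is always recorded).
#' @param policies Handling policies for flagged datasets under each
#'   detector.
#' @param firth Fit Firth's correction?
#' @param firth_ci Compute profile penalized-likelihood intervals (the
#'   expensive part; disable for bias/MSE-only runs)?
#' @param level Confidence level (0.90 throughout the studies).
#' @param n_refits,trace_cutoff Tracing-detector settings.
#' @param threshold_cutoff Threshold-criterion cut-off (`log(50)`).
#' @param keep_replicates Also return the replicate-level tibble?
#' @return A list with `summaries` (tidy tibble, one row per estimator x
#'   detector x policy x convergence variant) and, if requested,
#'   `replicates`.
#' @export
run_scenario <- function(scenario, n_reps = 10000, master_seed = 1,
                         conv_variants = list(default = conv_spec()),
                         detectors = c("tracing", "threshold"),
                         policies = "remove",
                         firth = TRUE, firth_ci = TRUE, level = 0.90,
                         n_refits = 30L, trace_cutoff = 20,
                         threshold_cutoff = log(50),
                         keep_replicates = FALSE) {
  scenario <- tibble::as_tibble(scenario)
  stopifnot(nrow(scenario) == 1, n_reps >= 2)
  detectors <- match.arg(detectors, c("tracing", "threshold"),
                         several.ok = TRUE)
  if (is.null(names(conv_variants)) || any(names(conv_variants) == "")) {
    stop("conv_variants must be a named list", call. = FALSE)
  }
  model <- scenario_model(scenario)
  nv <- length(conv_variants)
  vnames <- names(conv_variants)
  study_idx <- match(scenario$study, study_ids, nomatch = 7L)

  ml_est <- ml_se <- matrix(NA_real_, n_reps, nv,
                            dimnames = list(NULL, vnames))
  ml_conv <- matrix(NA, n_reps, nv, dimnames = list(NULL, vnames))
  firth_est <- firth_lo <- firth_hi <- rep(NA_real_, n_reps)
  firth_covered <- rep(NA, n_reps)
  flag_tracing <- flag_threshold <- rep(NA, n_reps)

  firth_conv <- conv_spec("default")
  true_b1 <- scenario$beta1
  for (r in seq_len(n_reps)) {
    seed <- mix_seed(master_seed, study_idx, scenario$scenario, r)
    qc <- quota_core(model, scenario$n_total, scenario$n_events, seed = seed)
    X <- cbind(1, qc$x)
    des <- list(X = X, y = as.numeric(qc$y),
                terms = c("(Intercept)", paste0("x", seq_len(ncol(qc$x)))))
    colnames(des$X) <- des$terms
    fit1 <- NULL
    for (v in seq_len(nv)) {
      cv <- conv_variants[[v]]
      fit <- ml_core(des$X, des$y, cv$tolerance, cv$max_iterations)
      ml_est[r, v] <- fit$coefficients[2L]
      ml_se[r, v] <- fit$se[2L]
      ml_conv[r, v] <- fit$converged
      if (v == 1L) fit1 <- fit
    }
    if ("tracing" %in% detectors) {
      tr <- ml_core(des$X, des$y, tolerance = 1e-12,
                    max_iterations = n_refits, exact_iters = n_refits)
      scaled <- sweep(tr$se_path, 2L, tr$se_path[1L, ], "/")
      v_tr <- apply(scaled, 2L, function(col) {
        if (any(!is.finite(col))) Inf else stats::var(col)
      })
      flag_tracing[r] <- any(v_tr > trace_cutoff)
    }
    if ("threshold" %in% detectors) {
      flag_threshold[r] <- any(abs(fit1$coefficients[-1L]) > threshold_cutoff)
    }
    if (firth) {
      ff <- firth_core(des$X, des$y, firth_conv$tolerance,
                       firth_conv$max_iterations)
      firth_est[r] <- ff$coefficients[2L]
      if (firth_ci) {
        names(ff$coefficients) <- names(ff$se) <- des$terms
        fobj <- structure(
          list(method = "firth", coefficients = ff$coefficients, se = ff$se,
               loglik = ff$loglik, converged = ff$converged,
               iterations = ff$iterations, dev_trace = ff$dev_trace,
               conv = firth_conv, X = des$X, y = des$y, terms = des$terms),
          class = "epv_fit")
        # coverage by inversion of the profile penalized-likelihood ratio
        # test: identical to endpoint containment, but defined even when an
        # endpoint lies beyond the root-finding bracket
        firth_covered[r] <-
          2 * (ff$loglik - profile_pl(fobj, 2L, true_b1)) <=
            stats::qchisq(level, df = 1)
        ci <- tryCatch(profile_ci(fobj, "x1", level = level),
                       error = function(e) NULL)
        if (!is.null(ci)) {
          firth_lo[r] <- ci$lower
          firth_hi[r] <- ci$upper
        }
      }
    }
  }

  z <- stats::qnorm((1 + level) / 2)
  scen_cols <- scenario[c("study", "scenario", "epv", "p", "prevalence",
                          "beta1", "n_events", "n_total")]
  rates <- tibble::tibble(
    rate_tracing = if ("tracing" %in% detectors) mean(flag_tracing) else
      NA_real_,
    rate_threshold = if ("threshold" %in% detectors) mean(flag_threshold)
      else NA_real_,
    rate_nonconvergence = mean(!ml_conv[, 1L])
  )

  one_summary <- function(keep, est, lo, hi, estimator, detector, policy,
                          conv_name) {
    s <- summarize_estimates(est[keep], lo[keep], hi[keep], true_b1)
    dplyr::bind_cols(
      scen_cols,
      tibble::tibble(estimator = estimator, detector = detector,
                     policy = policy, conv = conv_name,
                     n_reps = n_reps,
                     pct_removed = 100 * (n_reps - sum(keep)) / n_reps),
      s, rates)
  }

  summaries <- list()

  # ML under each convergence variant, non-convergence as the only filter
  for (v in seq_len(nv)) {
    keep <- ml_conv[, v]
    if (sum(keep) >= 2) {
      summaries[[length(summaries) + 1L]] <- one_summary(
        keep, ml_est[, v], ml_est[, v] - z * ml_se[, v],
        ml_est[, v] + z * ml_se[, v],
        "ml", "nonconvergence", "remove", vnames[v])
    }
  }

  # detector-based policies on the default (first) variant
  est1 <- ml_est[, 1L]
  lo1 <- est1 - z * ml_se[, 1L]
  hi1 <- est1 + z * ml_se[, 1L]
  for (det in detectors) {
    flag <- if (det == "tracing") flag_tracing else flag_threshold
    flag_or_nc <- flag | !ml_conv[, 1L]
    for (pol in policies) {
      if (pol == "remove") {
        keep <- !flag_or_nc
        if (sum(keep) < 2) next
        summaries[[length(summaries) + 1L]] <- one_summary(
          keep, est1, lo1, hi1, "ml", det, "remove", vnames[1L])
      } else if (pol == "keep_naive") {
        summaries[[length(summaries) + 1L]] <- one_summary(
          rep(TRUE, n_reps), est1, lo1, hi1, "ml", det, "keep_naive",
          vnames[1L])
      } else if (pol == "replace_max") {
        if (all(flag_or_nc)) next
        donor <- which.max(ifelse(flag_or_nc, -Inf, est1))
        est2 <- est1; lo2 <- lo1; hi2 <- hi1
        est2[flag_or_nc] <- est1[donor]
        lo2[flag_or_nc] <- lo1[donor]
        hi2[flag_or_nc] <- hi1[donor]
        summaries[[length(summaries) + 1L]] <- one_summary(
          rep(TRUE, n_reps), est2, lo2, hi2, "ml", det, "replace_max",
          vnames[1L])
      }
    }
  }

  if (firth) {
    s <- summarize_estimates(firth_est, NULL, NULL, true_b1)
    if (firth_ci) {
      s$coverage <- mean(firth_covered)
      s$mean_ci_width <- mean(firth_hi - firth_lo, na.rm = TRUE)
    }
    summaries[[length(summaries) + 1L]] <- dplyr::bind_cols(
      scen_cols,
      tibble::tibble(estimator = "firth", detector = NA_character_,
                     policy = "all", conv = "default", n_reps = n_reps,
                     pct_removed = 0,
                     pct_ci_unbounded = if (firth_ci)
                       100 * mean(is.na(firth_lo) | is.na(firth_hi))
                     else NA_real_),
      s, rates)
  }

  out <- list(summaries = dplyr::bind_rows(summaries))
  if (keep_replicates) {
    out$replicates <- tibble::tibble(
      rep = seq_len(n_reps),
      ml_est = est1, ml_se = ml_se[, 1L], ml_converged = ml_conv[, 1L],
      firth_est = firth_est, firth_lower = firth_lo, firth_upper = firth_hi,
      firth_covered = firth_covered,
      tracing = flag_tracing, threshold = flag_threshold)
    if (nv > 1) {
      for (v in 2:nv) {
        out$replicates[[paste0("ml_est_", vnames[v])]] <- ml_est[, v]
        out$replicates[[paste0("ml_converged_", vnames[v])]] <- ml_conv[, v]
      }
    }
  }
  out
}

#' Run a full simulation study
#'
#' Maps [run_scenario()] over the scenario grid of [build_grid()] and binds
#' the per-scenario summaries. For study `"IIb"` the natural call supplies
#' all four convergence presets so the seven-way detector/criterion
#' comparison can be assembled with [iib_table()].
#'
#' @inheritParams run_scenario
#' @param study Study identifier passed to [build_grid()].
#' @param scenarios Optional subset of scenario indices to run.
#' @param ... Passed on to [run_scenario()].
#' @return A tibble of scenario summaries (one row per scenario x estimator
#'   x detector x policy x convergence variant).
#' @export
run_study <- function(study, n_reps = 10000, master_seed = 1,
                      scenarios = NULL, ...) {
  grid <- build_grid(study)
  if (!is.null(scenarios)) grid <- grid[scenarios, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    run_scenario(grid[i, ], n_reps = n_reps, master_seed = master_seed,
                 ...)$summaries
  })
}

#' Assemble the seven-way detection/convergence comparison table
#'
#' Reshapes the summaries of the single-cell convergence study (run with
#' all four convergence presets and the tracing and threshold detectors)
#' into one column per approach — Firth; ML with tracing removal; ML with
#' threshold removal; ML with non-convergence removal under the default,
#' typeI, typeII and typeIII criteria — and one row per reported quantity
#' (percent removed, bias, coverage, mean interval width, MSE).
#'
#' @param summaries Summaries from [run_study()] / [run_scenario()] on the
#'   IIb cell.
#' @return A tibble with a `quantity` column and one column per approach.
#' @export
iib_table <- function(summaries) {
  lab <- function(row) {
    if (row$estimator == "firth") return("firth")
    if (row$detector %in% c("tracing", "threshold")) {
      return(paste0("ml_", row$detector))
    }
    paste0("ml_nonconv_", row$conv)
  }
  cols <- purrr::map_chr(seq_len(nrow(summaries)),
                         function(i) lab(summaries[i, ]))
  wanted <- c("firth", "ml_tracing", "ml_threshold", "ml_nonconv_default",
              "ml_nonconv_typeI", "ml_nonconv_typeII", "ml_nonconv_typeIII")
  out <- tibble::tibble(
    quantity = c("pct_removed", "bias", "coverage", "mean_ci_width", "mse"))
  for (w in intersect(wanted, cols)) {
    row <- summaries[which(cols == w)[1L], ]
    out[[w]] <- c(row$pct_removed, row$bias, row$coverage,
                  row$mean_ci_width, row$mse)
  }
  out
}
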