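#' Specify a true logistic data-generating model
#'
#' The data-generating model is `logit P(Y = 1 | x) = beta0 + beta' x`, with
#' covariates drawn from one of three laws: independent standard normal,
#' equicorrelated multivariate normal (all pairwise correlations equal to
#' `rho`), or independent Bernoulli(0.5).
#'
#' If `intercept` is omitted and `prevalence` is given, the intercept is set
#' by [calibrate_intercept()] so that the marginal event probability
#' `E[expit(beta0 + beta' X)]` equals `prevalence`. Under quota sampling the
#' intercept only affects sampling efficiency, not the conditional law of the
#' retained data, so this choice keeps raw-draw counts minimal.
#'
#' @param coefficients Numeric vector of non-intercept coefficients
#'   (log odds ratios), length `P >= 1`.
#' @param intercept Intercept `beta0` on the logit scale, or `NULL` to
#'   calibrate from `prevalence`.
#' @param law Covariate law: `"normal"` (independent standard normal),
#'   `"equicorrelated"` (multivariate normal, unit variances, common
#'   correlation `rho`), or `"bernoulli"` (independent Bernoulli(0.5)).
#' @param rho Common correlation for `law = "equicorrelated"`; must satisfy
#'   `rho > -1/(P-1)` and `rho < 1` for positive definiteness.
#' @param prevalence Target marginal event probability in (0, 1), used only
#'   when `intercept` is `NULL`.
#' @return An object of class `epv_model`: a list with elements `intercept`,
#'   `coefficients`, `law`, `rho`, `p`.
#' @examples
#' true_model(log(4), prevalence = 0.5)
#' true_model(c(log(2), log(2)), law = "equicorrelated", rho = 0.2,
#'            prevalence = 0.25)
#' @export
true_model <- function(coefficients,
                       intercept = NULL,
                       law = c("normal", "equicorrelated", "bernoulli"),
                       rho = 0,
                       prevalence = NULL) {
  law <- match.arg(law)
  coefficients <- as.numeric(coefficients)
  p <- length(coefficients)
  stopifnot(p >= 1, all(is.finite(coefficients)))
  if (law == "equicorrelated") {
    if (p > 1 && (rho <= -1 / (p - 1) || rho >= 1)) {
      stop("equicorrelated law needs rho in (-1/(P-1), 1) for a positive ",
           "definite correlation matrix", call. = FALSE)
    }
  } else {
    rho <- 0
  }
  if (is.null(intercept)) {
    if (is.null(prevalence)) {
      stop("supply either `intercept` or `prevalence`", call. = FALSE)
    }
    intercept <- calibrate_intercept(coefficients, law = law, rho = rho,
                                     prevalence = prevalence)
  }
  stopifnot(is.finite(intercept))
  structure(
    list(intercept = intercept, coefficients = coefficients,
         law = law, rho = rho, p = p),
    class = "epv_model"
  )
}

#' @export
print.epv_model <- function(x, ...) {
  cat("<epv_model> logit P(Y=1) = ", format(x$intercept, digits = 4))
  for (j in seq_len(x$p)) {
    cat(sprintf(" + %s x%d", format(x$coefficients[j], digits = 4), j))
  }
  cat("\n  covariate law:", x$law)
  if (x$law == "equicorrelated") cat(" (rho =", x$rho, ")")
  cat("\n")
  invisible(x)
}

#' Calibrate the intercept to a target marginal prevalence
#'
#' Solves `E[expit(beta0 + beta' X)] = prevalence` for `beta0`. For the
#' normal laws the linear predictor minus the intercept is
#' `N(0, beta' Sigma beta)`, so the expectation reduces to a one-dimensional
#' integral against the normal density, evaluated with [stats::integrate()].
#' For independent Bernoulli(0.5) covariates the expectation is computed
#' exactly by enumerating all `2^P` covariate patterns. The root is found by
#' [stats::uniroot()] to within `1e-6` on the prevalence scale.
#'
#' @inheritParams true_model
#' @return The calibrated intercept (a length-one numeric).
#' @examples
#' calibrate_intercept(0, prevalence = 0.5)          # logit(1/2) = 0
#' calibrate_intercept(log(2), prevalence = 0.5)     # 0 by symmetry
#' @export
calibrate_intercept <- function(coefficients,
                                law = c("normal", "equicorrelated", "bernoulli"),
                                rho = 0, prevalence) {
  law <- match.arg(law)
  stopifnot(is.numeric(prevalence), length(prevalence) == 1,
            prevalence > 0, prevalence < 1)
  coefficients <- as.numeric(coefficients)
  p <- length(coefficients)

  mean_prob <- if (law == "bernoulli") {
    patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), p)))
    eta_x <- drop(patterns %*% coefficients)
    w <- rep(0.5^p, nrow(patterns))
    function(b0) sum(w * stats::plogis(b0 + eta_x))
  } else {
    sigma2 <- if (law == "equicorrelated" && p > 1) {
      sum(coefficients^2) + rho * (sum(coefficients)^2 - sum(coefficients^2))
    } else {
      sum(coefficients^2)
    }
    if (sigma2 < 1e-12) {
      function(b0) stats::plogis(b0)
    } else {
      s <- sqrt(sigma2)
      function(b0) {
        stats::integrate(function(z) stats::plogis(b0 + s * z) * stats::dnorm(z),
                         -Inf, Inf, rel.tol = 1e-10)$value
      }
    }
  }

  f <- function(b0) mean_prob(b0) - prevalence
  stats::uniroot(f, lower = -50, upper = 50, tol = 1e-6,
                 extendInt = "upX")$root
}

draw_covariates <- function(model, n) {
  p <- model$p
  if (model$law == "bernoulli") {
    matrix(stats::rbinom(n * p, 1, 0.5), nrow = n, ncol = p, byrow = TRUE)
  } else if (model$law == "equicorrelated" && p > 1 && model$rho != 0) {
    # X = sqrt(rho) Z0 + sqrt(1-rho) Z_j gives unit variance, correlation rho
    z0 <- stats::rnorm(n)
    z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p, byrow = TRUE)
    sqrt(model$rho) * z0 + sqrt(1 - model$rho) * z
  } else {
    matrix(stats::rnorm(n * p), nrow = n, ncol = p, byrow = TRUE)
  }
}

#' Quota-sample a dataset with fixed size and event count
#'
#' Draws covariate/outcome pairs i.i.d. from the model — `x` from the
#' covariate law, `y ~ Bernoulli(expit(beta0 + beta' x))` — and retains the
#' first `n_events` pairs with `y = 1` and the first `n_total - n_events`
#' pairs with `y = 0`, discarding surplus draws, until both quotas are
#' filled. Row order is retention (draw) order. The procedure fixes the
#' sample size and the number of events exactly; only the intercept of the
#' data-generating model is affected by this conditioning.
#'
#' @param model An [true_model()] object.
#' @param n_total Total number of rows `N`.
#' @param n_events Number of events (rows with `y = 1`); `0 < n_events <
#'   n_total`.
#' @param seed Optional integer seed; when given, the draw is exactly
#'   reproducible (the RNG state is set with [set.seed()]).
#' @param max_draws Safety cap on raw draws per dataset (default `1e7`);
#'   exceeding it raises an error rather than looping on a degenerate model.
#' @return A tibble with columns `y` (0/1 integer) and `x1 ... xP`, exactly
#'   `n_total` rows of which exactly `n_events` have `y = 1`. The number of
#'   raw draws consumed is attached as attribute `"n_draws"` and the true
#'   model as attribute `"model"`.
#' @examples
#' m <- true_model(log(4), prevalence = 0.5)
#' d <- sample_quota(m, n_total = 8, n_events = 4, seed = 1)
#' sum(d$y)  # exactly 4
#' @export
sample_quota <- function(model, n_total, n_events, seed = NULL,
                         max_draws = 1e7) {
  core <- quota_core(model, n_total, n_events, seed = seed,
                     max_draws = max_draws)
  colnames(core$x) <- paste0("x", seq_len(ncol(core$x)))
  out <- tibble::as_tibble(as.data.frame(core$x))
  out <- tibble::add_column(out, y = core$y, .before = 1)
  attr(out, "n_draws") <- core$n_draws
  attr(out, "model") <- model
  out
}

# vectorized quota sampler used by both sample_quota and the study runner;
# returns the raw covariate matrix and outcome in retention (draw) order
quota_core <- function(model, n_total, n_events, seed = NULL,
                       max_draws = 1e7) {
  stopifnot(inherits(model, "epv_model"),
            n_total > 0, n_events > 0, n_events < n_total)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_non <- n_total - n_events
  p <- model$p

  # fixed chunk size so the retained set is a deterministic function of the
  # RNG stream alone
  chunk <- max(64L, 2L * as.integer(n_total))
  need_e <- as.integer(n_events)
  need_n <- as.integer(n_non)
  drawn <- 0L
  fill_e <- fill_n <- NA_integer_ # global draw index filling each quota
  xs <- list(); ys <- list(); blk <- 0L

  while (need_e > 0L || need_n > 0L) {
    if (drawn >= max_draws) {
      stop("quota sampling exceeded ", max_draws, " raw draws; ",
           "check the model for a degenerate event probability",
           call. = FALSE)
    }
    x <- draw_covariates(model, chunk)
    eta <- model$intercept + drop(x %*% model$coefficients)
    if (any(!is.finite(eta))) {
      stop("non-finite linear predictor; malformed model", call. = FALSE)
    }
    y <- as.integer(stats::runif(chunk) < stats::plogis(eta))
    pos_e <- which(y == 1L)
    pos_n <- which(y == 0L)
    keep_e <- pos_e[seq_len(min(need_e, length(pos_e)))]
    keep_n <- pos_n[seq_len(min(need_n, length(pos_n)))]
    if (need_e > 0L && length(pos_e) >= need_e) {
      fill_e <- drawn + pos_e[need_e]
    }
    if (need_n > 0L && length(pos_n) >= need_n) {
      fill_n <- drawn + pos_n[need_n]
    }
    keep <- sort(c(keep_e, keep_n))
    if (length(keep)) {
      blk <- blk + 1L
      xs[[blk]] <- x[keep, , drop = FALSE]
      ys[[blk]] <- y[keep]
    }
    need_e <- need_e - length(keep_e)
    need_n <- need_n - length(keep_n)
    drawn <- drawn + chunk
  }

  list(x = do.call(rbind, xs), y = do.call(c, ys),
       n_draws = max(fill_e, fill_n))
}

#' Read or write a dataset in the package's CSV dialect
#'
#' Plain CSV with a header row: outcome column `y` coded 0/1 and numeric
#' covariate columns `x1 ... xP`.
#'
#' @param path File path.
#' @return `read_dataset()` returns a tibble with `y` first; `write_dataset()`
#'   returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, check.names = TRUE)
  if (!"y" %in% names(d)) stop("dataset must have a `y` column", call. = FALSE)
  if (!all(d$y %in% c(0, 1))) stop("`y` must be coded 0/1", call. = FALSE)
  d$y <- as.integer(d$y)
  xcols <- setdiff(names(d), "y")
  tibble::as_tibble(d[c("y", xcols)])
}

#' @rdname read_dataset
#' @param data Dataset tibble/data frame (`y` plus covariate columns).
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Deterministic per-dataset seed from (master seed, scenario index, replicate).
# Linear-congruential folding mod 2^31 - 1; products stay below 2^53 so the
# arithmetic is exact in doubles.
mix_seed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (v in c(...)) {
    h <- (h * 48271 + as.numeric(v) + 1) %% m
  }
  as.integer(h)
}
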