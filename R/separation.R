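#' Re-estimation (tracing) separation detector
#'
#' Refits the logistic model by maximum likelihood with the iteration count
#' capped at exactly `k = 1, ..., n_refits` Fisher scoring steps (the
#' tolerance test is disabled so exactly `k` steps always run), and collects
#' the expected-information standard errors of every parameter at each cap.
#' Each parameter's SE path is scaled by its value at `k = 1`, and the
#' dataset is flagged as separated when the variance of any scaled path
#' across the refits (sample variance, denominator `n_refits - 1`) exceeds
#' `cutoff`. On separated data the MLE does not exist and the standard
#' errors diverge along the iterations, so the scaled-path variance
#' explodes; on overlapped data the path stabilizes quickly.
#'
#' Because Fisher scoring from `beta = 0` is deterministic, the `k`-capped
#' fits share their iterates with a single `n_refits`-iteration run, which
#' is what the implementation executes.
#'
#' @param data Dataset (`y` plus covariate columns).
#' @param n_refits Number of capped refits (default 30).
#' @param cutoff Scaled-SE variance cut-off (default 20, chosen by the
#'   original pilot calibration; configurable).
#' @return A list of class `epv_tracing`: `flagged` (logical),
#'   `scaled_variances` (named per-parameter), `flagged_parameters`
#'   (character), `se_paths` (`n_refits` x `P+1` matrix).
#' @examples
#' sep <- tibble::tibble(y = c(0L, 0L, 1L, 1L), x1 = c(-2, -1, 1, 2))
#' detect_tracing(sep)$flagged  # TRUE: SEs diverge under separation
#' @export
detect_tracing <- function(data, n_refits = 30L, cutoff = 20) {
  des <- build_design(data)
  core <- ml_core(des$X, des$y, tolerance = 0, max_iterations = n_refits,
                  exact_iters = n_refits)
  se_paths <- core$se_path
  colnames(se_paths) <- des$terms
  first <- se_paths[1L, ]
  scaled <- sweep(se_paths, 2L, first, "/")
  v <- apply(scaled, 2L, function(col) {
    if (any(!is.finite(col))) Inf else stats::var(col)
  })
  flagged_par <- des$terms[v > cutoff]
  structure(
    list(flagged = any(v > cutoff), scaled_variances = v,
         flagged_parameters = flagged_par, se_paths = se_paths),
    class = "epv_tracing"
  )
}

#' @export
print.epv_tracing <- function(x, ...) {
  cat("<epv_tracing>", if (x$flagged) "SEPARATION flagged" else "no flag", "\n")
  cat("  scaled-SE variances:",
      paste(names(x$scaled_variances),
            format(x$scaled_variances, digits = 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Coefficient-threshold separation criterion
#'
#' Flags a fit when any non-intercept coefficient exceeds `cutoff` in
#' absolute value; the default `log(50)` reproduces the removal rule
#' `|beta_j| > log(50), j != 0` used in earlier events-per-variable studies.
#'
#' @param fit An `epv_fit` from [fit_ml()] (any convergence status).
#' @param cutoff Absolute threshold on the non-intercept coefficients.
#' @return Logical flag.
#' @export
detect_threshold <- function(fit, cutoff = log(50)) {
  stopifnot(inherits(fit, "epv_fit"))
  any(abs(fit$coefficients[-1L]) > cutoff)
}

#' Non-convergence criterion
#'
#' Flags a fit whose deviance tolerance was not met before the iteration cap
#' — the (weak) separation proxy used by several earlier simulation studies.
#'
#' @param fit An `epv_fit`.
#' @return Logical flag (`TRUE` iff the fit did not converge).
#' @export
detect_nonconvergence <- function(fit) {
  stopifnot(inherits(fit, "epv_fit"))
  !fit$converged
}

# Dense primal simplex with Bland's rule for: max c'x, A x <= b, x >= 0,
# with b >= 0 so the slack basis is feasible and no phase 1 is needed.
# Both separation LPs have this form (origin feasible, box-bounded), and
# Bland's rule guarantees termination despite their heavy degeneracy.
lp_box_max <- function(cvec, A, b, max_iter = NULL) {
  m <- nrow(A); nv <- ncol(A)
  stopifnot(all(b >= 0))
  if (is.null(max_iter)) max_iter <- 50L * (m + nv)
  # tableau: [A | I | b] with objective row [-c | 0 | 0]
  Tb <- cbind(A, diag(m), b)
  obj <- c(-cvec, numeric(m), 0)
  basis <- nv + seq_len(m)
  tol <- 1e-11
  for (it in seq_len(max_iter)) {
    enter <- which(obj[seq_len(nv + m)] < -tol)
    if (length(enter) == 0) {
      x <- numeric(nv + m)
      x[basis] <- Tb[, nv + m + 1]
      return(list(value = obj[nv + m + 1], solution = x[seq_len(nv)],
                  solved = TRUE))
    }
    j <- min(enter) # Bland: smallest index enters
    col <- Tb[, j]
    pos <- which(col > tol)
    if (length(pos) == 0) {
      stop("LP unbounded; exact separation verdict unavailable",
           call. = FALSE)
    }
    ratio <- Tb[pos, nv + m + 1] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- cand[which.min(basis[cand])] # Bland: smallest basis index leaves
    piv <- Tb[i, j]
    Tb[i, ] <- Tb[i, ] / piv
    upd <- setdiff(seq_len(m), i)
    Tb[upd, ] <- Tb[upd, ] - outer(Tb[upd, j], Tb[i, ])
    obj <- obj - obj[j] * Tb[i, ]
    basis[i] <- j
  }
  stop("LP solver iteration limit reached; exact separation verdict ",
       "unavailable", call. = FALSE)
}

#' Exact separation classification by linear programming
#'
#' Classifies a dataset as `"none"` (overlap), `"quasi_complete"` or
#' `"complete"` separation using two linear programs over the
#' intercept-augmented design `Z` with signs `s_i = 2 y_i - 1` and the
#' scale-free normalization `||b||_inf <= 1`:
#'
#' * LP-1 maximizes `t` subject to `s_i (Z_i . b) >= t`; an optimum above
#'   `eps` certifies a strictly separating hyperplane (complete).
#' * otherwise LP-2 maximizes `sum(u_i)` subject to
#'   `s_i (Z_i . b) >= u_i`, `0 <= u_i <= 1`; a positive optimum certifies
#'   quasi-complete separation (some points strictly classified, none
#'   misclassified); optimum zero means overlap and a finite MLE exists.
#'
#' @param data Dataset (`y` plus covariate columns).
#' @param eps Strictness threshold guarding against solver round-off.
#' @return One of `"none"`, `"quasi_complete"`, `"complete"`.
#' @examples
#' detect_exact(tibble::tibble(y = c(0L, 1L), x1 = c(-1, 1)))  # "complete"
#' @export
detect_exact <- function(data, eps = 1e-9) {
  des <- build_design(data)
  Z <- des$X
  n <- nrow(Z); p <- ncol(Z)
  S <- Z * (2 * des$y - 1)

  # LP-1: maximize t s.t. s_i (Z_i . b) >= t, ||b||_inf <= 1. Variables
  # (u, v, t) >= 0 with b = u - v; t >= 0 WLOG since (b, t) = 0 is
  # feasible. In <= form: t - S(u - v) <= 0; u, v <= 1.
  A <- rbind(cbind(-S, S, 1),
             cbind(diag(2 * p), 0))
  t_star <- lp_box_max(cvec = c(rep(0, 2 * p), 1),
                       A = A, b = c(rep(0, n), rep(1, 2 * p)))$value
  if (t_star > eps) return("complete")

  # LP-2: maximize sum(w) s.t. s_i (Z_i . b) >= w_i, 0 <= w_i <= 1,
  # ||b||_inf <= 1. In <= form: w - S(u - v) <= 0; u, v, w <= 1.
  A <- rbind(cbind(-S, S, diag(n)),
             diag(2 * p + n))
  opt <- lp_box_max(cvec = c(rep(0, 2 * p), rep(1, n)),
                    A = A, b = c(rep(0, n), rep(1, 2 * p + n)))$value
  if (opt > eps) "quasi_complete" else "none"
}

#' All separation verdicts for one dataset
#'
#' Convenience wrapper running the tracing, threshold and non-convergence
#' detectors (the latter two on a maximum-likelihood fit under `conv`) and,
#' optionally, the exact LP classifier.
#'
#' @inheritParams detect_tracing
#' @param conv [conv_spec()] for the ML fit behind the threshold and
#'   non-convergence criteria.
#' @param exact Run the LP classifier too?
#' @param cutoff_threshold Threshold for [detect_threshold()].
#' @return One-row tibble: `tracing`, `threshold`, `nonconvergence`,
#'   logicals; `exact` (character or `NA`); plus the per-parameter scaled-SE
#'   variances in a list column `scaled_variances`.
#' @export
detect_separation <- function(data, conv = conv_spec(), n_refits = 30L,
                              cutoff = 20, cutoff_threshold = log(50),
                              exact = TRUE) {
  tr <- detect_tracing(data, n_refits = n_refits, cutoff = cutoff)
  fit <- fit_ml(data, conv)
  tibble::tibble(
    tracing = tr$flagged,
    threshold = detect_threshold(fit, cutoff_threshold),
    nonconvergence = detect_nonconvergence(fit),
    exact = if (exact) detect_exact(data) else NA_character_,
    scaled_variances = list(tr$scaled_variances)
  )
}
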