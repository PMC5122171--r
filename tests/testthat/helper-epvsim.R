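# canonical toy datasets (same definitions as make_fixtures())
toy_complete_sep <- function() {
  tibble::tibble(y = c(0L, 0L, 1L, 1L), x1 = c(-2, -1, 1, 2))
}
toy_quasi_sep <- function() {
  tibble::tibble(y = c(0L, 1L, 1L), x1 = c(0, 0, 1))
}
toy_overlap_2x2 <- function() {
  tibble::tibble(y = c(0L, 0L, 1L, 1L), x1 = c(0, 1, 0, 1))
}
# 2x2 table, cell counts (events|x=1, events|x=0, non-events|x=1,
# non-events|x=0) = (6, 4, 4, 6)
toy_cells_6446 <- function() {
  tibble::tibble(y = rep(c(1L, 1L, 0L, 0L), c(6, 4, 4, 6)),
                 x1 = rep(c(1, 0, 1, 0), c(6, 4, 4, 6)))
}
# seeded overlapped continuous dataset
toy_overlap_n <- function(n = 200, beta1 = log(2), seed = 42) {
  sample_quota(true_model(beta1, prevalence = 0.5), n, n %/% 2, seed = seed)
}
random_small_dataset <- function(n, p) {
  # at least one observation per class, covariates standard normal
  y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
  d <- tibble::tibble(y = y)
  for (j in seq_len(p)) d[[paste0("x", j)]] <- rnorm(n)
  d
}

# independent penalized log-likelihood (no scoring machinery shared with
# the implementation beyond base linear algebra)
oracle_pl <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  w <- p * (1 - p)
  # l = sum(y*eta - log(1+exp(eta))), with log(1+e^u) = max(u,0)+log1p(e^-|u|)
  ll <- sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta))))
  as.numeric(ll +
    0.5 * determinant(crossprod(X, X * w), logarithm = TRUE)$modulus)
}

# brute-force Firth estimate: numerical maximization of the penalized
# likelihood, independent of the modified-score iteration
oracle_firth <- function(data) {
  X <- cbind(1, as.matrix(data[setdiff(names(data), "y")]))
  y <- data$y
  f <- function(b) -oracle_pl(X, y, b)
  o <- optim(numeric(ncol(X)), f, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 10000))
  optim(o$par, f, method = "BFGS", control = list(reltol = 1e-14))$par
}

# grid-profile oracle for the penalized-likelihood interval of x1 (single
# covariate): inner 1-D maximization over the intercept at each beta1
oracle_profile_interval <- function(data, level = 0.90, lim = c(-8, 8),
                                    step = 1e-3) {
  X <- cbind(1, as.matrix(data[setdiff(names(data), "y")]))
  y <- data$y
  prof <- function(b1) {
    -optimize(function(b0) -oracle_pl(X, y, c(b0, b1)),
              interval = c(-30, 30), tol = 1e-9)$objective
  }
  b1s <- seq(lim[1], lim[2], by = step)
  pl <- vapply(b1s, prof, numeric(1))
  cut <- max(pl) - qchisq(level, 1) / 2
  inside <- b1s[pl >= cut]
  c(min(inside), max(inside))
}

# central-difference Hessian of the (unpenalized) log-likelihood
oracle_num_hessian <- function(X, y, beta, h = 1e-5) {
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta))))
  }
  p <- length(beta)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ei <- ej <- numeric(p); ei[i] <- h; ej[j] <- h
    H[i, j] <- (ll(beta + ei + ej) - ll(beta + ei - ej) -
                  ll(beta - ei + ej) + ll(beta - ei - ej)) / (4 * h * h)
  }
  H
}
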