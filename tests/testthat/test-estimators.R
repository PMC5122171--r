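test_that("ML fit reproduces 2x2 closed forms", {
  # symmetric table: both coefficients zero
  sym <- tibble::tibble(y = rep(c(1L, 0L), each = 10),
                        x1 = rep(c(1, 0, 1, 0), c(5, 5, 5, 5)))
  f0 <- fit_ml(sym)
  expect_equal(unname(f0$coefficients), c(0, 0), tolerance = 1e-8)

  # cells (6, 4, 4, 6): log odds ratio and its SE in closed form
  f <- fit_ml(toy_cells_6446())
  expect_equal(unname(f$coefficients["x1"]), log((6 * 6) / (4 * 4)),
               tolerance = 1e-7)
  expect_equal(unname(f$se["x1"]), sqrt(1/6 + 1/4 + 1/4 + 1/6),
               tolerance = 1e-7)
  expect_true(f$converged)
})

test_that("ML fit agrees with glm on random overlapped data", {
  set.seed(31)
  for (i in 1:10) {
    d <- sample_quota(true_model(log(2), prevalence = 0.5), 40, 20,
                      seed = 300 + i)
    f <- fit_ml(d)
    g <- glm(y ~ x1, binomial, data = d)
    expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-8)
    expect_equal(unname(f$se), unname(summary(g)$coefficients[, 2]),
                 tolerance = 1e-8)
    expect_equal(f$iterations, g$iter)
    expect_equal(f$converged, g$converged)
  }
})

test_that("ML diverges monotonically on completely separated data", {
  d <- toy_complete_sep()
  ests <- vapply(c(10, 25, 50), function(k) {
    fit_ml(d, conv_spec(tolerance = 1e-300, max_iterations = k))$
      coefficients[["x1"]]
  }, numeric(1))
  expect_gt(ests[1], 5)
  expect_true(all(diff(ests) > 0))
})

test_that("invalid designs are rejected", {
  expect_error(fit_ml(tibble::tibble(y = c(1L, 1L, 1L), x1 = 1:3)),
               "single class")
  expect_error(fit_ml(tibble::tibble(y = c(0L, 1L), x1 = c(1, 1))),
               "rank")
})

test_that("Firth estimates match the add-half closed form and a brute-force
           penalized-likelihood oracle", {
  sym <- tibble::tibble(y = rep(c(1L, 0L), each = 10),
                        x1 = rep(c(1, 0, 1, 0), c(5, 5, 5, 5)))
  expect_equal(unname(fit_firth(sym)$coefficients["x1"]), 0,
               tolerance = 1e-7)

  # single binary covariate: Firth equals the add-1/2-to-each-cell log OR
  f <- fit_firth(toy_cells_6446())
  expect_equal(unname(f$coefficients["x1"]),
               log((6.5 * 6.5) / (4.5 * 4.5)), tolerance = 1e-4)
  expect_equal(unname(f$coefficients["x1"]),
               oracle_firth(toy_cells_6446())[2], tolerance = 1e-3)

  # separated data: finite estimate agreeing with numeric maximization
  fs <- fit_firth(toy_complete_sep())
  expect_true(all(is.finite(fs$coefficients)))
  expect_true(all(fs$se > 0 & is.finite(fs$se)))
  expect_equal(unname(fs$coefficients), unname(oracle_firth(toy_complete_sep())),
               tolerance = 5e-3)
})

test_that("penalized likelihood is non-decreasing over Firth iterations", {
  set.seed(17)
  for (i in 1:5) {
    d <- sample_quota(true_model(log(4), prevalence = 0.5), 10, 5,
                      seed = 800 + i)
    ff <- fit_firth(d)
    pdev <- ff$dev_trace # penalized deviance, should not increase
    expect_true(all(diff(pdev) <= 1e-8))
  }
})

test_that("recoding the outcome flips the sign of every coefficient", {
  set.seed(23)
  for (i in 1:6) {
    d <- sample_quota(true_model(log(2), prevalence = 0.5), 30, 15,
                      seed = 400 + i)
    d_flip <- d
    d_flip$y <- 1L - d$y
    for (method in c("ml", "firth")) {
      a <- fit_logistic(d, method)$coefficients
      b <- fit_logistic(d_flip, method)$coefficients
      expect_equal(unname(a), -unname(b), tolerance = 1e-6)
    }
  }
})

test_that("Firth shrinks the binary-covariate estimate towards zero", {
  set.seed(29)
  for (i in 1:10) {
    d <- sample_quota(true_model(log(4), law = "bernoulli",
                                 prevalence = 0.5), 20, 10, seed = 600 + i)
    fm <- fit_ml(d)
    if (!detect_threshold(fm, log(1e6)) && fm$converged) {
      ff <- fit_firth(d)
      expect_lte(abs(ff$coefficients[["x1"]]),
                 abs(fm$coefficients[["x1"]]) + 1e-8)
    }
  }
})

test_that("ML and Firth agree in large samples", {
  d <- sample_quota(true_model(log(2), prevalence = 0.5), 5000, 2500,
                    seed = 99)
  fm <- fit_ml(d)
  ff <- fit_firth(d)
  expect_lt(max(abs(fm$coefficients - ff$coefficients)), 0.01)
})

test_that("expected-information SEs match a finite-difference Hessian", {
  d <- toy_overlap_n(200, seed = 7)
  f <- fit_ml(d, conv_spec(tolerance = 1e-13, max_iterations = 100))
  X <- cbind(1, as.matrix(d["x1"]))
  H <- oracle_num_hessian(X, d$y, unname(f$coefficients))
  se_obs <- sqrt(diag(solve(-H)))
  expect_lt(max(abs(unname(f$se) - se_obs)), 1e-4)
})

test_that("Wald interval uses the exact normal quantile", {
  f <- fit_ml(toy_cells_6446())
  ci <- wald_ci(f, "x1", level = 0.90)
  est <- log(2.25); se <- sqrt(1/6 + 1/4 + 1/4 + 1/6)
  expect_equal(ci$lower, est - qnorm(0.95) * se, tolerance = 1e-7)
  expect_equal(ci$upper, est + qnorm(0.95) * se, tolerance = 1e-7)
  expect_equal(ci$upper - ci$lower, 2 * 1.645 * se, tolerance = 1e-3)
  ci95 <- wald_ci(f, "x1", level = 0.95)
  expect_equal((ci95$upper - ci95$estimate) / se, 1.959964, tolerance = 1e-5)
})

test_that("profile interval endpoints satisfy the chi-square defining
           equation and match a grid-profile oracle", {
  d <- toy_cells_6446()
  ff <- fit_firth(d)
  ci <- profile_ci(ff, "x1", level = 0.90)
  X <- cbind(1, as.matrix(d["x1"]))
  for (endpoint in c(ci$lower, ci$upper)) {
    prof <- -optimize(function(b0) -oracle_pl(X, d$y, c(b0, endpoint)),
                      c(-30, 30), tol = 1e-10)$objective
    expect_equal(2 * (ff$loglik - prof), qchisq(0.90, 1), tolerance = 1e-4)
  }
  oracle <- oracle_profile_interval(d, level = 0.90)
  expect_equal(ci$lower, oracle[1], tolerance = 5e-3)
  expect_equal(ci$upper, oracle[2], tolerance = 5e-3)
})

test_that("profile and Wald intervals coincide asymptotically", {
  d <- sample_quota(true_model(log(2), prevalence = 0.5), 2000, 1000,
                    seed = 55)
  ff <- fit_firth(d)
  pci <- profile_ci(ff, "x1", level = 0.90)
  z <- qnorm(0.95)
  wald_width <- 2 * z * ff$se[["x1"]]
  expect_lt(abs((pci$upper - pci$lower) - wald_width) / wald_width, 0.02)
})

test_that("tidy and glance return the expected shape", {
  f <- fit_firth(toy_cells_6446())
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "x1"))
  expect_named(td, c("term", "estimate", "std.error"))
  gl <- glance(f)
  expect_equal(gl$nobs, 20L)
  expect_true(gl$converged)
})
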