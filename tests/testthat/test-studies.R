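test_that("scenario grids reproduce the factorial designs", {
  ia <- build_grid("Ia")
  expect_equal(nrow(ia), 140) # 28 EPV values x 5 effect sizes
  expect_equal(range(ia$n_total), c(30, 300))
  expect_true(all(ia$p == 1))

  ib <- build_grid("Ib")
  expect_equal(nrow(ib), 168) # 28 x 3 P x 2 effects
  expect_true(all(vapply(seq_len(nrow(ib)), function(i) {
    length(ib$coefficients[[i]]) == ib$p[i] &&
      all(ib$coefficients[[i]] == ib$beta1[i])
  }, logical(1))))

  ic <- build_grid("Ic")
  expect_equal(nrow(ic), 65) # 13 EPV x 5 prevalences
  expect_equal(range(ic$n_total), c(24, 600))

  id <- build_grid("Id")
  expect_equal(nrow(id), 52) # 13 x 4 correlations
  expect_true(all(id$law == "equicorrelated"))
  expect_true(all(id$prevalence == 1 / 4))

  iia <- build_grid("IIa")
  expect_equal(nrow(iia), 39) # 13 x 3 effects
  expect_true(all(iia$law == "bernoulli"))

  iib <- build_grid("IIb")
  expect_equal(nrow(iib), 1)
  expect_equal(iib$n_events, 4L)
  expect_equal(iib$n_total, 8L)
  expect_equal(iib$beta1, log(4))

  # 465 scenarios in total across the six studies
  expect_equal(140 + 168 + 65 + 52 + 39 + 1, 465)
})

test_that("scenario runs are deterministic given the master seed", {
  g <- build_grid("IIb")
  r1 <- run_scenario(g, n_reps = 60, master_seed = 42, firth_ci = FALSE,
                     keep_replicates = TRUE)
  r2 <- run_scenario(g, n_reps = 60, master_seed = 42, firth_ci = FALSE,
                     keep_replicates = TRUE)
  expect_identical(r1$summaries, r2$summaries)
  expect_identical(r1$replicates, r2$replicates)
  r3 <- run_scenario(g, n_reps = 60, master_seed = 43, firth_ci = FALSE)
  expect_false(identical(r1$summaries$bias, r3$summaries$bias))
})

test_that("removal bookkeeping is exact and policies act as specified", {
  g <- build_grid("IIb")
  res <- run_scenario(g, n_reps = 150, master_seed = 9,
                      policies = c("remove", "keep_naive", "replace_max"),
                      detectors = "tracing", firth = FALSE,
                      keep_replicates = TRUE)
  s <- res$summaries
  rep_tbl <- res$replicates

  rem <- s[s$policy == "remove" & s$detector == "tracing", ]
  flagged <- rep_tbl$tracing | !rep_tbl$ml_converged
  expect_equal(rem$n_used + sum(flagged), rem$n_reps[1])
  expect_equal(rem$pct_removed, 100 * mean(flagged))

  naive <- s[s$policy == "keep_naive", ]
  expect_equal(naive$n_used, 150L)
  expect_equal(naive$bias, mean(rep_tbl$ml_est) - log(4))

  repl <- s[s$policy == "replace_max", ]
  donor <- max(rep_tbl$ml_est[!flagged])
  est2 <- ifelse(flagged, donor, rep_tbl$ml_est)
  expect_equal(repl$bias, mean(est2) - log(4))
})

test_that("without any flagged datasets, remove and keep_naive coincide", {
  # null effect, comfortable EPV: separation essentially impossible
  g <- build_grid("IIa")
  cell <- g[g$epv == 30 & abs(g$beta1) < 1e-12, ]
  res <- run_scenario(cell, n_reps = 80, master_seed = 2,
                      policies = c("remove", "keep_naive"),
                      detectors = "tracing", firth = FALSE)
  s <- res$summaries
  expect_equal(s$rate_tracing[1], 0)
  rem <- s[s$policy == "remove" & s$detector == "tracing", ]
  keep <- s[s$policy == "keep_naive", ]
  expect_equal(rem$bias, keep$bias)
  expect_equal(rem$coverage, keep$coverage)
})

test_that("the seven-way comparison table has the documented shape and a
           clean Firth column", {
  res <- run_scenario(build_grid("IIb"), n_reps = 80, master_seed = 3,
    conv_variants = list(default = conv_spec(), typeI = conv_spec("typeI"),
                         typeII = conv_spec("typeII"),
                         typeIII = conv_spec("typeIII")),
    detectors = c("tracing", "threshold"), policies = "remove",
    firth = TRUE, firth_ci = FALSE)
  tab <- iib_table(res$summaries)
  expect_equal(tab$quantity,
               c("pct_removed", "bias", "coverage", "mean_ci_width", "mse"))
  expect_named(tab, c("quantity", "firth", "ml_tracing", "ml_threshold",
                      "ml_nonconv_default", "ml_nonconv_typeI",
                      "ml_nonconv_typeII", "ml_nonconv_typeIII"))
  expect_equal(tab$firth[tab$quantity == "pct_removed"], 0)
})

test_that("run_study binds per-scenario summaries with scenario identity", {
  out <- run_study("IIa", n_reps = 40, master_seed = 4,
                   scenarios = c(1, 14), detectors = "tracing",
                   policies = "remove", firth = FALSE, firth_ci = FALSE)
  expect_true(all(c("study", "epv", "beta1", "estimator", "bias") %in%
                    names(out)))
  expect_equal(sort(unique(out$scenario)), c(1L, 14L))
  expect_true(all(out$study == "IIa"))
})

test_that("study plots are well-formed ggplot objects", {
  out <- run_study("IIa", n_reps = 40, master_seed = 4,
                   scenarios = c(1, 14), detectors = "tracing",
                   policies = "remove", firth = FALSE, firth_ci = FALSE)
  gg <- plot_study(out, "bias")
  expect_s3_class(gg, "ggplot")
  tr <- detect_tracing(toy_complete_sep())
  expect_s3_class(autoplot(tr), "ggplot")
})
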