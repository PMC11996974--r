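fit_cached <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      cfg <- quick_2p_config(n_subjects = 5, trials = 20)
      d <- simulate_trials(cfg, seed = 17)$data
      d$set_size <- factor(d$set_size)
      fit <<- suppressWarnings(fit_wmm(
        mixture2p("response_error"),
        wmf(kappa ~ 0 + set_size + (1 || subID),
            thetat ~ 0 + set_size + (1 || subID)),
        d, chains = 2, warmup = 250, iter = 250, seed = 41,
        sample_prior = TRUE))
    }
    fit
  }
})

test_that("summarize reports every coefficient once, from the draws", {
  fit <- fit_cached()
  s <- summarize(fit)
  dm <- wmmix:::draws_matrix(fit$draws)
  expect_setequal(c(rownames(s$hyperparameters), rownames(s$coefficients)),
                  grep("^(b|sd|cor)_", colnames(dm), value = TRUE))
  expect_false(anyDuplicated(c(rownames(s$hyperparameters),
                               rownames(s$coefficients))) > 0)
  # mean column equals the arithmetic mean of stored draws
  expect_equal(s$coefficients["b_kappa_set_size1", "Estimate"],
               mean(dm[, "b_kappa_set_size1"]))
  expect_equal(s$hyperparameters["sd_subID_kappa_Intercept", "Estimate"],
               mean(dm[, "sd_subID_kappa_Intercept"]))
  # rows: 2 parameters x 2 set sizes fixed, 2 sd hyperparameters
  expect_equal(nrow(s$coefficients), 4)
  expect_equal(nrow(s$hyperparameters), 2)
  # pure function of draws
  expect_equal(summarize(fit)$coefficients, s$coefficients)
})

test_that("fits without random terms have an empty hyperparameter section", {
  cfg <- quick_2p_config(n_subjects = 3, trials = 10,
                         re_sd = c(kappa = 0, thetat = 0))
  d <- simulate_trials(cfg, seed = 19)$data
  fit <- suppressWarnings(fit_wmm(mixture2p("response_error"),
                                  wmf(kappa ~ 1, thetat ~ 1), d,
                                  chains = 1, warmup = 100, iter = 100, seed = 2))
  s <- summarize(fit)
  expect_equal(nrow(s$hyperparameters), 0)
  expect_equal(nrow(s$coefficients), 2)
})

test_that("to_native applies the documented transformations", {
  expect_equal(round(to_native(2, kind = "theta")[1, ], 2), c(0.88, 0.12))
  expect_equal(to_native(0, kind = "kappa"), 1)
  expect_equal(to_native(c(-1, 0.5), kind = "imm-activation"), exp(c(-1, 0.5)))
  # three-component weight sets match the softmax oracle row-wise
  set.seed(8)
  th <- matrix(rnorm(20), ncol = 2)
  nat <- to_native(th, kind = "theta")
  expect_equal(rowSums(nat), rep(1, 10))
  for (i in 1:10) {
    expect_equal(nat[i, ], softmax_oracle(c(th[i, ], 0)), tolerance = 1e-12)
  }
  # kappa -> circular SD -> degrees chain
  out <- to_native(log(8), kind = "kappa", as_sd = TRUE, degrees = TRUE)
  expect_equal(out$kappa, 8)
  expect_equal(out$sd, rad2deg(k2sd(8)))
  expect_error(to_native(1, kind = "bogus"), "arg")
})

test_that("pp_check produces normalised, seed-stable envelopes", {
  fit <- fit_cached()
  ppc <- pp_check(fit, n_draws = 8, seed = 5)
  gw <- diff(ppc$grid[1:2])
  expect_equal(sum(ppc$observed) * gw, 1, tolerance = 0.02)
  for (i in seq_len(nrow(ppc$yrep))) {
    expect_equal(sum(ppc$yrep[i, ]) * gw, 1, tolerance = 0.02)
  }
  ppc2 <- pp_check(fit, n_draws = 8, seed = 5)
  expect_identical(ppc$yrep, ppc2$yrep)
  expect_error(pp_check(fit, n_draws = 1e6), "exceeds stored")
  # well-specified fit: observed curve inside the replicate envelope at
  # most grid points
  ppc10 <- pp_check(fit, n_draws = 10, seed = 9)
  lo <- apply(ppc10$yrep, 2, min); hi <- apply(ppc10$yrep, 2, max)
  inside <- mean(ppc10$observed >= lo & ppc10$observed <= hi)
  expect_gte(inside, 0.9)
})

test_that("hypothesis computes Savage-Dickey ratios and directional odds", {
  fit <- fit_cached()
  h <- hypothesis(fit, c("b_thetat_set_size1 - b_thetat_set_size2 > 0",
                         "b_thetat_set_size1 - b_thetat_set_size2 = 0"))
  expect_s3_class(h, "wmm_hypothesis")
  # simulated p_mem drops 0.95 -> 0.7: direction should be near-certain
  expect_gt(h$Post.Prob[1], 0.95)
  expect_gt(h$Evid.Ratio[1], 1)
  # the same large difference makes the point-null implausible: BF01 < 1
  expect_lt(h$Evid.Ratio[2], 1)
  expect_equal(h$BF10[2], 1 / h$Evid.Ratio[2])
  # degenerate combination is flagged, not rationalised
  expect_warning(
    hd <- hypothesis(fit, "b_kappa_set_size1 - b_kappa_set_size1 = 0"),
    "degenerate")
  expect_true(is.na(hd$Evid.Ratio[1]))
  expect_error(hypothesis(fit, "b_kappa_set_size1 ~ 0"), "must contain")
  expect_error(hypothesis(fit, "b_nope = 0"), "unknown coefficient")
})

test_that("a parameter untouched by the data keeps its prior (ER ~ 1)", {
  # with every trial at set size 1 the non-target weight never enters the
  # likelihood, so its posterior equals its prior
  cfg <- generative_config(
    mixture3p("response_error", paste0("nt_feature_", 1:2), "setsize"),
    n_subjects = 3, trials_per_cell = 40,
    conditions = data.frame(setsize = 1, kappa = 8, p_mem = 0.8, p_nt = 0),
    max_set_size = 3)
  d <- simulate_trials(cfg, seed = 23)$data
  fit <- suppressWarnings(fit_wmm(
    mixture3p("response_error", paste0("nt_feature_", 1:2), "setsize"),
    wmf(kappa ~ 1, thetat ~ 1, thetant ~ 1), d,
    chains = 2, warmup = 250, iter = 400, seed = 6, sample_prior = TRUE))
  h <- hypothesis(fit, "b_thetant_Intercept = 0")
  expect_gt(h$Evid.Ratio[1], 0.6)
  expect_lt(h$Evid.Ratio[1], 1.7)
})

test_that("hypothesis without prior draws errors only for point statements", {
  cfg <- quick_2p_config(n_subjects = 3, trials = 8)
  d <- simulate_trials(cfg, seed = 29)$data
  fit <- suppressWarnings(fit_wmm(mixture2p("response_error"),
                                  wmf(kappa ~ 1, thetat ~ 1), d,
                                  chains = 1, warmup = 80, iter = 80, seed = 4))
  expect_error(hypothesis(fit, "b_kappa_Intercept = 0"), "sample_prior")
  h <- hypothesis(fit, "b_kappa_Intercept > 0")
  expect_false(is.na(h$Post.Prob[1]))
})

test_that("the Savage-Dickey density estimator is calibrated on normals", {
  # 4000 draws = the default 4 chains x 1000 post-warmup draws
  set.seed(55)
  x <- rnorm(4000, 0.3, 0.2) # point lies 1.5 SDs from the posterior mean
  est <- wmmix:::density_at(x, 0)
  expect_lt(abs(est - dnorm(0, 0.3, 0.2)) / dnorm(0, 0.3, 0.2), 0.15)
  y <- rnorm(4000, 0, 2)
  expect_lt(abs(wmmix:::density_at(y, 0) - dnorm(0, 0, 2)) / dnorm(0, 0, 2), 0.15)
  # the estimator's known limitation: deep-tail points acquire an upward
  # kernel bias, so extreme BF01 values are conservative (closer to 1)
  z <- rnorm(4000, 1, 0.2)
  expect_gt(wmmix:::density_at(z, 0), 0)
})
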