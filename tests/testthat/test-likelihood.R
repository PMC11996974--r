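test_that("softmax_probs matches the worked example and the brute-force oracle", {
  p <- softmax_probs(2)
  expect_equal(round(p, 2), c(0.88, 0.12))
  expect_equal(softmax_probs(c(0, 0)), rep(1 / 3, 3))
  expect_equal(softmax_probs(c(1, 2)), softmax_oracle(c(1, 2, 0)),
               tolerance = 1e-12)
  expect_equal(sum(softmax_probs(c(-3, 7, 0.5))), 1)
  # overflow safety
  expect_equal(softmax_probs(c(1000, 999)),
               softmax_oracle(c(1, 0, -999)), tolerance = 1e-12)
  expect_error(softmax_probs(c(1, Inf)), "finite")
})

test_that("IMM activation mapping produces simplex probabilities", {
  # hand-computed: A = (1.5, 0.5, 0.5), denominator 1 + 2.5 = 3.5
  pr <- imm_component_probs(c = 1, a = 0.5, set_size = 3, version = "abc")
  expect_equal(pr$p_mem, 1.5 / 3.5)
  expect_equal(pr$p_nt, rep(0.5 / 3.5, 2))
  expect_equal(pr$p_guess, 1 / 3.5)
  expect_equal(pr$p_mem + sum(pr$p_nt) + pr$p_guess, 1)

  # a = 0 kills swaps: reduces to the two-parameter structure
  pr0 <- imm_component_probs(c = 2, a = 0, set_size = 4, version = "abc")
  expect_equal(pr0$p_nt, rep(0, 3))

  # s -> infinity removes generalization to lures: full collapses to abc
  D <- c(0.3, 1.2, 2.5)
  prf <- imm_component_probs(c = 1.4, a = 0.6, s = 1e8, distances = D,
                             set_size = 4, version = "full")
  pra <- imm_component_probs(c = 1.4, a = 0.6, set_size = 4, version = "abc")
  expect_equal(prf, pra)
  # s = 0 is full generalization: every item shares the target's activation
  pr_s0 <- imm_component_probs(c = 1.4, a = 0.6, s = 0, distances = D,
                               set_size = 4, version = "full")
  expect_equal(pr_s0$p_nt, rep(pr_s0$p_mem, 3))

  # bsc has no general activation
  prb <- imm_component_probs(c = 2, a = 5, s = 1, distances = D,
                             set_size = 4, version = "bsc")
  expect_equal(prb$p_nt, 2 * exp(-D) / (1 + 2 + sum(2 * exp(-D))))

  expect_error(imm_component_probs(c = -1, set_size = 2, version = "abc"),
               "nonnegative")
  expect_error(imm_component_probs(c = 1, s = 1, set_size = 3, version = "full"),
               "distances")
})

test_that("trial_loglik matches plug-in oracles", {
  m2 <- mixture2p("response_error")
  # 2P with kappa = 4, thetat = 2 at x = 0.3
  ll <- trial_loglik(0.3, list(kappa = log(4), thetat = 2), m2)
  p <- softmax_oracle(c(2, 0))
  oracle <- log(p[1] * exp(vm_logpdf_oracle(0.3, 0, 4)) + p[2] / (2 * pi))
  expect_equal(ll, oracle, tolerance = 1e-8)

  # 3P at set size 1 equals 2P with the same (kappa, thetat)
  m3 <- mixture3p("response_error", paste0("nt", 1:3), "ss")
  ll3 <- trial_loglik(0.3, list(kappa = log(4), thetat = 2, thetant = -5),
                      m3, nt_features = c(NA, NA, NA), set_size = 1)
  expect_equal(ll3, ll, tolerance = 1e-12)

  # 3P full oracle
  mu <- c(0.8, -1.4)
  ll3b <- trial_loglik(0.2, list(kappa = log(6), thetat = 1.5, thetant = 0.3),
                       m3, nt_features = c(mu, NA), set_size = 3)
  p3 <- softmax_oracle(c(1.5, 0.3, 0))
  oracle3 <- log(p3[1] * exp(vm_logpdf_oracle(0.2, 0, 6)) +
                 p3[2] / 2 * sum(exp(vm_logpdf_oracle(0.2, mu, 6))) +
                 p3[3] / (2 * pi))
  expect_equal(ll3b, oracle3, tolerance = 1e-8)

  expect_error(trial_loglik(0.1, list(kappa = 0, thetat = 0, thetant = 0),
                            m3, nt_features = c(0.5, NA, NA), set_size = 3),
               "active non-target slots")
})

test_that("exp(trial_loglik) integrates to 1 for random draws of all models", {
  set.seed(204)
  models <- list(
    mixture2p("response_error"),
    mixture3p("response_error", paste0("nt", 1:3), "ss"),
    imm("response_error", paste0("nt", 1:3), "ss", version = "abc"),
    imm("response_error", paste0("nt", 1:3), "ss", paste0("d", 1:3), "bsc"),
    imm("response_error", paste0("nt", 1:3), "ss", paste0("d", 1:3), "full"))
  for (m in models) {
    for (rep in 1:3) {
      ss <- sample(2:4, 1)
      nt <- wrap_angle(runif(3, -pi, pi)); nt[seq_len(3) > ss - 1] <- NA
      D <- runif(3, 0, pi); D[is.na(nt)] <- NA
      pars <- lapply(m$parameters, function(l) rnorm(1, 0, 1))
      dens <- function(x) vapply(x, function(xi) {
        exp(trial_loglik(xi, pars, m, nt_features = nt, nt_distances = D,
                         set_size = ss))
      }, numeric(1))
      expect_equal(integrate_circle(dens), 1, tolerance = 1e-6)
    }
  }
})

test_that("the stated model nestings hold to numerical precision", {
  set.seed(77)
  m3 <- mixture3p("response_error", paste0("nt", 1:4), "ss")
  m2 <- mixture2p("response_error")
  mabc <- imm("response_error", paste0("nt", 1:4), "ss", version = "abc")
  for (rep in 1:10) {
    ss <- sample(2:5, 1)
    nt <- rep(NA_real_, 4); nt[seq_len(ss - 1)] <- wrap_angle(runif(ss - 1, -pi, pi))
    x <- wrap_angle(runif(1, -pi, pi))
    kappa_link <- rnorm(1, 1.5, 0.7)

    # IMMabc == mixture3p under the activation -> probability mapping
    act <- list(c = exp(rnorm(1)), a = exp(rnorm(1)))
    pr <- imm_component_probs(c = act$c, a = act$a, set_size = ss, version = "abc")
    theta <- c(log(pr$p_mem / pr$p_guess),
               log(sum(pr$p_nt) / pr$p_guess))
    ll_imm <- trial_loglik(x, list(kappa = kappa_link, c = log(act$c),
                                   a = log(act$a)),
                           mabc, nt_features = nt, set_size = ss)
    ll_3p <- trial_loglik(x, list(kappa = kappa_link, thetat = theta[1],
                                  thetant = theta[2]),
                          m3, nt_features = nt, set_size = ss)
    expect_equal(ll_imm, ll_3p, tolerance = 1e-10)

    # mixture2p == mixture3p with the non-target weight pushed to -inf
    th <- rnorm(1, 1, 1)
    ll_2p <- trial_loglik(x, list(kappa = kappa_link, thetat = th), m2)
    ll_3p0 <- trial_loglik(x, list(kappa = kappa_link, thetat = th,
                                   thetant = -745),
                           m3, nt_features = nt, set_size = ss)
    expect_equal(ll_3p0, ll_2p, tolerance = 1e-8)

    # mixture2p == IMMabc with a = 0 (matched p_mem)
    cc <- exp(rnorm(1))
    pr2 <- imm_component_probs(c = cc, a = 0, set_size = ss, version = "abc")
    ll_imm0 <- trial_loglik(x, list(kappa = kappa_link, c = log(cc), a = -745),
                            mabc, nt_features = nt, set_size = ss)
    ll_2pm <- trial_loglik(x, list(kappa = kappa_link,
                                   thetat = log(pr2$p_mem / pr2$p_guess)), m2)
    expect_equal(ll_imm0, ll_2pm, tolerance = 1e-6)
  }
})

test_that("dataset_loglik sums trial likelihoods, order-independently", {
  set.seed(11)
  cfg <- generative_config(
    mixture3p("response_error", paste0("nt_feature_", 1:3), "setsize"),
    n_subjects = 2, trials_per_cell = 25,
    conditions = data.frame(setsize = c(2, 4), kappa = c(8, 5),
                            p_mem = c(0.8, 0.6), p_nt = c(0.1, 0.2)))
  sim <- simulate_trials(cfg, seed = 8)
  d <- sim$data
  m3 <- mixture3p("response_error", paste0("nt_feature_", 1:3), "setsize")
  pars <- c(kappa = log(6), thetat = 1.2, thetant = -0.5)
  total <- dataset_loglik(d, pars, m3)
  # naive loop oracle through the scalar path
  loop <- sum(vapply(seq_len(nrow(d)), function(i) {
    trial_loglik(d$response_error[i], as.list(pars), m3,
                 nt_features = as.numeric(d[i, paste0("nt_feature_", 1:3)]),
                 set_size = d$setsize[i])
  }, numeric(1)))
  expect_equal(as.numeric(total), loop, tolerance = 1e-8)
  expect_length(attr(total, "trial_ll"), nrow(d))
  # single row
  one <- dataset_loglik(d[3, ], pars, m3)
  expect_equal(as.numeric(one), attr(total, "trial_ll")[3], tolerance = 1e-12)
  # permutation invariance
  perm <- sample(nrow(d))
  expect_equal(as.numeric(dataset_loglik(d[perm, ], pars, m3)),
               as.numeric(total), tolerance = 1e-10)
})
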