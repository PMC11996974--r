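test_that("recode_relative subtracts the target and wraps", {
  r <- recode_relative(response = 1.0, target = 0.7,
                       nt_absolute = c(0.5, 0.9, 1.1))
  expect_equal(r$response_error, 0.3)
  expect_equal(r$nt_relative, c(-0.2, 0.2, 0.4))
  expect_equal(recode_relative(0.7, 0.7)$response_error, 0)
  # wrapping across the boundary
  r2 <- recode_relative(response = 3.0, target = 3.0, nt_absolute = -3.0)
  expect_equal(r2$nt_relative, wrap_angle(-6.0))
  expect_equal(r2$nt_relative, -6 + 2 * pi, tolerance = 1e-12) # ~0.2832
  # matrix form with NA padding
  ntm <- rbind(c(0.5, NA), c(1.0, 2.0))
  r3 <- recode_relative(c(0.1, 0.2), c(0, 1), ntm)
  expect_equal(r3$nt_relative[1, ], c(0.5, NA))
  expect_equal(r3$nt_relative[2, ], c(0, 1))
})

test_that("validate_table enforces the schema and normalises padding", {
  d <- toy_mixture_table()
  m3 <- mixture3p("response_error", c("nt1", "nt2"), "setsize")
  v <- validate_table(d, m3)
  expect_true(v$ok)
  # zero in a slot beyond set size - 1 is padding -> NA
  d2 <- d
  d2$nt2[3] <- 0 # row 3 has set size 2: only nt1 active
  v2 <- validate_table(d2, m3)
  expect_true(is.na(v2$data$nt2[3]))
  # non-zero value beyond set size is flagged and dropped
  d3 <- d
  d3$nt2[3] <- 0.4
  v3 <- validate_table(d3, m3)
  expect_false(v3$ok)
  expect_true(is.na(v3$data$nt2[3]))
  # missing required columns are a hard error
  expect_error(validate_table(d[, c("subID", "setsize", "response_error")], m3),
               "requires column")
  # too few active slots for the set size
  d4 <- d; d4$nt2[2] <- NA # row 2 has set size 3
  expect_error(validate_table(d4, m3), "active non-target slots")
  # a degrees-coded table is flagged
  d5 <- d; d5$response_error <- c(-170, 35, 120, 90)
  expect_match(validate_table(d5, m3)$warnings, "degrees", all = FALSE)
  # the two-parameter model needs only the response column
  expect_true(validate_table(data.frame(response_error = c(0.1, -0.2)),
                             mixture2p("response_error"))$ok)
})

test_that("schema presets match the classic set-size experiment layouts", {
  zl <- schema_preset("zhang_luck")
  expect_equal(names(zl), c("subID", "trial", "setsize", "response_error",
                            paste0("col_lure", 1:5)))
  # a populated Zhang & Luck-style row validates against mixture3p
  row <- zl[0, ]; row[1, ] <- c(1, 1, 3, 0.2, 0.5, -0.5, NA, NA, NA)
  m <- mixture3p("response_error", paste0("col_lure", 1:5), "setsize")
  expect_true(validate_table(row, m)$ok)
  expect_equal(names(schema_preset("bays"))[4], "resp_error")
})

test_that("simulate_trials is seed-deterministic with coherent labels", {
  cfg <- quick_2p_config(n_subjects = 3, trials = 10)
  s1 <- simulate_trials(cfg, seed = 5)
  s2 <- simulate_trials(cfg, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1$data$response_error,
                         simulate_trials(cfg, seed = 6)$data$response_error))
  expect_equal(nrow(s1$data), 3 * 2 * 10)
})

test_that("degenerate mixtures generate from the labelled component", {
  # all memory: labels all target, circular SD ~ k2sd(kappa)
  cfg_mem <- generative_config(
    mixture2p("response_error"), n_subjects = 1, trials_per_cell = 1e4,
    conditions = data.frame(set_size = 1, kappa = 8, p_mem = 1))
  sm <- simulate_trials(cfg_mem, seed = 2)
  expect_true(all(sm$labels == "target"))
  expect_lt(abs(circ_sd_sample(sm$data$response_error) - k2sd(8)),
            0.1 * k2sd(8))
  # all guessing: uniform errors
  cfg_g <- generative_config(
    mixture2p("response_error"), n_subjects = 1, trials_per_cell = 1e4,
    conditions = data.frame(set_size = 1, kappa = 8, p_mem = 0))
  sg <- simulate_trials(cfg_g, seed = 2)
  expect_true(all(sg$labels == "guess"))
  # uniformity judged over repeated seeds: a single Rayleigh p-value is
  # itself uniform under H0
  pvals <- vapply(1:8, function(s) {
    rayleigh_p(simulate_trials(cfg_g, seed = s)$data$response_error)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 7 / 8)
  # set size 1 in a 3P world: no lures, no swap labels
  cfg1 <- generative_config(
    mixture3p("response_error", paste0("nt_feature_", 1:2), "setsize"),
    n_subjects = 2, trials_per_cell = 50,
    conditions = data.frame(setsize = 1, kappa = 8, p_mem = 0.8, p_nt = 0),
    max_set_size = 3)
  s1 <- simulate_trials(cfg1, seed = 3)
  expect_true(all(is.na(s1$data$nt_feature_1)))
  expect_false(any(grepl("nontarget", s1$labels)))
})

test_that("component-label frequencies converge to configured probabilities", {
  cfg <- generative_config(
    mixture3p("response_error", paste0("nt_feature_", 1:3), "setsize"),
    n_subjects = 1, trials_per_cell = 1e4,
    conditions = data.frame(setsize = 4, kappa = 8,
                            p_mem = 0.6, p_nt = 0.25))
  s <- simulate_trials(cfg, seed = 10)
  n <- length(s$labels)
  for (case in list(c("target", 0.6), c("guess", 0.15))) {
    p <- as.numeric(case[2])
    freq <- mean(s$labels == case[1])
    expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / n))
  }
  p_nt <- mean(grepl("nontarget", s$labels))
  expect_lt(abs(p_nt - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("absolute-coordinate generation recodes back to the relative table", {
  cfg <- generative_config(
    mixture3p("response_error", paste0("nt_feature_", 1:2), "setsize"),
    n_subjects = 2, trials_per_cell = 20,
    conditions = data.frame(setsize = 3, kappa = 6, p_mem = 0.7, p_nt = 0.2))
  s <- simulate_trials(cfg, seed = 4)
  # rebuild absolute coordinates with random targets, then recode
  set.seed(40)
  target <- wrap_angle(runif(nrow(s$data), -pi, pi))
  resp_abs <- wrap_angle(s$data$response_error + target)
  nt_abs <- wrap_angle(as.matrix(s$data[, paste0("nt_feature_", 1:2)]) + target)
  rec <- recode_relative(resp_abs, target, nt_abs)
  expect_equal(rec$response_error, s$data$response_error, tolerance = 1e-10)
  expect_equal(unname(rec$nt_relative),
               unname(as.matrix(s$data[, paste0("nt_feature_", 1:2)])),
               tolerance = 1e-10)
})

test_that("CSV round trip with column mapping preserves the table", {
  d <- toy_mixture_table()
  path <- tempfile(fileext = ".csv")
  write_trial_table(d, path)
  d2 <- read_trial_table(path)
  expect_equal(d2, d, tolerance = 1e-12)
  d3 <- read_trial_table(path, mapping = list(resp = "response_error"))
  expect_true("resp" %in% names(d3))
  expect_error(read_trial_table(path, mapping = list(a = "nope")),
               "not in file")
  unlink(path)
})

test_that("generative_config rejects inconsistent designs", {
  m3 <- mixture3p("response_error", paste0("nt_feature_", 1:3), "setsize")
  expect_error(generative_config(m3, 2, 10,
                                 data.frame(setsize = 2, kappa = 5, p_mem = 0.9)),
               "p_nt")
  expect_error(generative_config(m3, 2, 10,
                                 data.frame(setsize = 2, kappa = 5,
                                            p_mem = 0.8, p_nt = 0.5)),
               "simplex", fixed = TRUE)
  expect_error(generative_config(m3, 2, 10,
                                 data.frame(setsize = 2, kappa = -1,
                                            p_mem = 0.5, p_nt = 0.1)),
               "kappa")
  expect_error(generative_config(m3, 2, 10,
                                 data.frame(setsize = 2, kappa = 5,
                                            p_mem = 0.5, p_nt = 0.1),
                                 re_sd = c(bogus = 1)),
               "unknown parameter")
})
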