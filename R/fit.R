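#' Fit a working-memory measurement model
#'
#' Hierarchical Bayesian estimation of a [mixture2p()], [mixture3p()], or
#' [imm()] model via Hamiltonian Monte Carlo. Fixed effects, random-effect
#' standard deviations, and standardised random effects (non-centered
#' parameterisation) are sampled on their link scales; prior bounds
#' (e.g. `lb = 0`) are honoured through constrained transforms.
#'
#' @param model A `wmm_model`.
#' @param formula A [wmf()] formula set over the model's parameters.
#' @param data Trial table; validated (and normalised) with
#'   [validate_table()] first.
#' @param priors Optional `wmm_prior` table of user priors; merged into
#'   [default_priors()], most specific match wins.
#' @param contrasts Named list of contrast schemes per factor (see
#'   [build_design()]).
#' @param chains Number of MCMC chains (default 4).
#' @param warmup Warmup iterations per chain (default 1000).
#' @param iter Post-warmup draws per chain (default 1000).
#' @param cores Parallel chains via forked processes (default 1).
#' @param seed Integer seed; chain `c` uses `seed + c - 1`. Identical
#'   seeds give identical draws.
#' @param sample_prior Also sample the prior (likelihood switched off)
#'   with matched dimensions; required for Savage-Dickey evidence ratios
#'   in [hypothesis()].
#' @param control List of sampler controls (`target_accept`, `init_step`,
#'   `traj_length`, `max_leapfrog`, `max_deltaH`).
#' @return A `wmm_fit` object: `draws` (iter x chain x coefficient array
#'   on the link scale), optional `prior_draws`, `diagnostics` (split
#'   R-hat, bulk ESS per coefficient), `divergences` per chain, plus
#'   model, formula, resolved priors, design, data, and seed.
#' @export
fit_wmm <- function(model, formula, data, priors = NULL, contrasts = list(),
                    chains = 4, warmup = 1000, iter = 1000, cores = 1,
                    seed = 1, sample_prior = FALSE, control = list()) {
  stopifnot(inherits(model, "wmm_model"), inherits(formula, "wmm_formula"))
  t0 <- Sys.time()
  val <- validate_table(data, model)
  for (w in val$warnings) warning(w, call. = FALSE)
  data <- val$data
  formula <- check_formula_parameters(formula, model)
  design <- build_design(formula, data, contrasts)
  prior_tab <- resolve_priors(default_priors(model, formula, data, contrasts),
                              priors)
  layout <- build_layout(model, design, prior_tab)
  prep <- prepare_model_data(data, model)
  lp_fun <- make_logpost(model, design, layout, prep, lik_weight = 1)

  run_chains <- function(lp, tag) {
    chain_fun <- function(ch) {
      ch_seed <- as.integer(seed) + ch - 1L
      set.seed(ch_seed)
      res <- NULL
      for (try in 1:10) {
        ini <- init_raw(layout)
        v <- lp(ini)
        if (is.finite(v$lp) && all(is.finite(v$grad))) { res <- ini; break }
      }
      if (is.null(res)) {
        bad <- which(!is.finite(v$trial_ll))[1]
        stop("non-finite ", tag, " at initial values",
             if (length(bad) && !is.na(bad)) paste0(" (first bad trial: row ", bad, ")"))
      }
      run_hmc_chain(lp, res, warmup, iter, seed = ch_seed, control = control)
    }
    if (cores > 1 && .Platform$OS.type == "unix") {
      out <- parallel::mclapply(seq_len(chains), chain_fun,
                                mc.cores = min(cores, chains))
      errs <- vapply(out, inherits, logical(1), "try-error")
      if (any(vapply(out, inherits, logical(1), "condition"))) {
        stop("a parallel chain failed; rerun with cores = 1 for details")
      }
      out
    } else {
      lapply(seq_len(chains), chain_fun)
    }
  }

  post <- run_chains(lp_fun, "log posterior")
  draws <- assemble_draws(post, layout, iter, chains)
  prior_draws <- NULL
  if (sample_prior) {
    lp_prior <- make_logpost(model, design, layout, prep, lik_weight = 0)
    prior_draws <- assemble_draws(run_chains(lp_prior, "log prior"),
                                  layout, iter, chains)
  }
  diagnostics <- draw_diagnostics(draws)
  fit <- structure(list(
    draws = draws, prior_draws = prior_draws, diagnostics = diagnostics,
    divergences = vapply(post, `[[`, integer(1), "divergences"),
    step_sizes = vapply(post, `[[`, numeric(1), "step_size"),
    accept_rates = vapply(post, `[[`, numeric(1), "accept_rate"),
    model = model, formula = formula, contrasts = contrasts,
    priors = prior_tab, design = design, layout = layout, data = data,
    chains = chains, warmup = warmup, iter = iter, seed = as.integer(seed),
    data_fingerprint = data_fingerprint(data),
    time = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "wmm_fit")
  if (sum(fit$divergences) > 0) {
    warning(sum(fit$divergences), " divergent transition(s) after warmup",
            call. = FALSE)
  }
  bad_rhat <- diagnostics$coef[!is.na(diagnostics$rhat) & diagnostics$rhat > 1.05]
  if (length(bad_rhat)) {
    warning("R-hat > 1.05 for: ", paste(utils::head(bad_rhat, 5), collapse = ", "),
            if (length(bad_rhat) > 5) ", ...", call. = FALSE)
  }
  fit
}

assemble_draws <- function(chain_res, layout, iter, chains) {
  npar <- length(layout$stored)
  arr <- array(NA_real_, c(iter, chains, npar),
               dimnames = list(NULL, NULL, layout$stored))
  for (ch in seq_len(chains)) {
    raws <- chain_res[[ch]]$draws
    for (i in seq_len(iter)) {
      arr[i, ch, ] <- constrain_draw(raws[i, ], layout)
    }
  }
  arr
}

data_fingerprint <- function(data) {
  num <- vapply(data, function(col) {
    if (is.numeric(col)) sum(col, na.rm = TRUE) else length(unique(col))
  }, numeric(1))
  sprintf("%dx%d:%s", nrow(data), ncol(data),
          format(sum(num) %% 1e9, digits = 12))
}

#' @export
print.wmm_fit <- function(x, ...) {
  cat("<wmm_fit>", x$model$name, "|", x$chains, "chain(s) x", x$iter,
      "draws (+", x$warmup, "warmup) |", round(x$time, 1), "s\n")
  cat("  divergences:", sum(x$divergences),
      "| max R-hat:", round(max(x$diagnostics$rhat, na.rm = TRUE), 3), "\n")
  print(summarize(x))
  invisible(x)
}

# split R-hat and bulk ESS (Geyer initial positive sequence) ---------------

split_chains <- function(x) {
  # x: iter x chain matrix -> iter/2 x (2*chain)
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

rhat_split <- function(x) {
  x <- split_chains(as.matrix(x))
  m <- ncol(x); n <- nrow(x)
  if (n < 4 || m < 2) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_bulk <- function(x) {
  x <- split_chains(as.matrix(x))
  m <- ncol(x); n <- nrow(x)
  if (n < 4) return(NA_real_)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  means <- colMeans(x)
  B <- n * stats::var(means)
  var_plus <- (n - 1) / n * W + B / n
  # mean autocovariance across chains
  max_lag <- n - 2
  acov <- matrix(0, max_lag + 1, m)
  for (j in seq_len(m)) {
    a <- stats::acf(x[, j], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    acov[, j] <- a
  }
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer: sum consecutive pairs while positive and monotone
  tau <- 1
  t <- 1
  last_pair <- Inf
  while (t + 1 <= length(rho) - 1) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, last_pair)
    last_pair <- pair
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(n * m / tau, 1)
}

draw_diagnostics <- function(draws) {
  coefs <- dimnames(draws)[[3]]
  rhat <- vapply(coefs, function(cf) rhat_split(draws[, , cf]), numeric(1))
  ess <- vapply(coefs, function(cf) ess_bulk(draws[, , cf]), numeric(1))
  data.frame(coef = coefs, rhat = rhat, ess_bulk = ess,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Convergence diagnostics for a fit
#'
#' Per-coefficient split R-hat and bulk effective sample size, plus the
#' run-level divergence count. R-hat values above 1.05 are flagged, the
#' threshold at which sampler warnings indicate convergence problems.
#'
#' @param fit A `wmm_fit`.
#' @return List with `diagnostics` (data frame; `flagged` column marks
#'   R-hat > 1.05), `divergences` (per chain), `ok` (no flags, no
#'   divergences).
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "wmm_fit"))
  d <- fit$diagnostics
  if (fit$chains < 2 && fit$iter < 4) {
    warning("R-hat is unreliable with a single short chain", call. = FALSE)
  }
  if (fit$chains == 1) {
    warning("single-chain fit: R-hat computed from split halves only",
            call. = FALSE)
  }
  low_ess <- !is.na(d$ess_bulk) & d$ess_bulk < 100
  if (any(low_ess)) {
    warning("low effective sample size (< 100) for ",
            sum(low_ess), " coefficient(s)", call. = FALSE)
  }
  d$flagged <- !is.na(d$rhat) & d$rhat > 1.05
  list(diagnostics = d, divergences = fit$divergences,
       ok = !any(d$flagged) && sum(fit$divergences) == 0)
}

# iter x chain x coef -> (iter*chain) x coef matrix
draws_matrix <- function(draws) {
  d <- dim(draws)
  m <- matrix(aperm(draws, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(m) <- dimnames(draws)[[3]]
  m
}
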