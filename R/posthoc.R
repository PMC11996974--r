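#' Summarise a fitted model
#'
#' Two-section summary in the style of regression-model output: multilevel
#' hyperparameters (random-effect SDs and correlations) and regression
#' coefficients, each with posterior mean, posterior SD, 95% interval,
#' split R-hat and bulk ESS. Values are on the link ("parameter") scale —
#' log for `kappa` and the IMM activations, unbounded mixing weights for
#' `thetat`/`thetant`; use [to_native()] to transform.
#'
#' @param fit A `wmm_fit`.
#' @param digits Printing digits.
#' @return A `wmm_summary` object (list of two data frames:
#'   `hyperparameters`, `coefficients`).
#' @export
summarize <- function(fit, digits = 2) {
  stopifnot(inherits(fit, "wmm_fit"))
  m <- draws_matrix(fit$draws)
  coefs <- colnames(m)
  sect <- function(keep) {
    if (!length(keep)) {
      return(data.frame(Estimate = numeric(0), Est.Error = numeric(0),
                        `l-95% CI` = numeric(0), `u-95% CI` = numeric(0),
                        Rhat = numeric(0), Bulk_ESS = numeric(0),
                        check.names = FALSE))
    }
    x <- m[, keep, drop = FALSE]
    di <- fit$diagnostics[match(keep, fit$diagnostics$coef), ]
    data.frame(
      Estimate = colMeans(x),
      Est.Error = apply(x, 2, stats::sd),
      `l-95% CI` = apply(x, 2, stats::quantile, 0.025),
      `u-95% CI` = apply(x, 2, stats::quantile, 0.975),
      Rhat = di$rhat, Bulk_ESS = round(di$ess_bulk),
      row.names = keep, check.names = FALSE)
  }
  out <- list(
    hyperparameters = sect(grep("^(sd|cor)_", coefs, value = TRUE)),
    coefficients = sect(grep("^b_", coefs, value = TRUE)),
    model = fit$model$name, chains = fit$chains, iter = fit$iter,
    digits = digits)
  class(out) <- "wmm_summary"
  out
}

#' @export
print.wmm_summary <- function(x, ...) {
  cat("Model:", x$model, " (", x$chains, "chains x", x$iter, "draws )\n")
  if (nrow(x$hyperparameters)) {
    cat("\nMultilevel hyperparameters:\n")
    print(round(x$hyperparameters, x$digits))
  }
  cat("\nRegression coefficients:\n")
  print(round(x$coefficients, x$digits))
  cat("\nEstimates are on the link (parameter) scale; see to_native().\n")
  invisible(x)
}

#' @export
summary.wmm_fit <- function(object, ...) summarize(object, ...)

#' Transform link-scale draws to the native scale
#'
#' `kappa` and IMM activation draws are exponentiated; mixing-weight draw
#' sets are pushed through the softmax (inverse logit when there are two
#' components). Optionally chains kappa through [k2sd()] and [rad2deg()].
#'
#' @param draws Numeric vector (one coefficient) or matrix (draws x
#'   weight-set columns for `kind = "theta"`).
#' @param kind `"kappa"`, `"theta"`, or `"imm-activation"`.
#' @param as_sd For `kind = "kappa"`: also return the circular SD.
#' @param degrees Report circular SD in degrees.
#' @return Native-scale draws: vector, or for `"theta"` a matrix whose
#'   rows are probability vectors over the components (reference/guessing
#'   component last); for `as_sd = TRUE` a list with `kappa` and `sd`.
#' @examples
#' to_native(2, kind = "theta")     # c(0.88, 0.12)
#' to_native(0, kind = "kappa")     # 1
#' @export
to_native <- function(draws, kind = c("kappa", "theta", "imm-activation"),
                      as_sd = FALSE, degrees = FALSE) {
  kind <- match.arg(kind)
  if (kind == "kappa") {
    kappa <- exp(draws)
    if (!as_sd) return(kappa)
    sd <- k2sd(kappa)
    if (degrees) sd <- rad2deg(sd)
    return(list(kappa = kappa, sd = sd))
  }
  if (kind == "imm-activation") return(exp(draws))
  # mixing weights
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  t(apply(draws, 1, softmax_probs))
}

# per-trial link-scale linear predictors implied by one stored draw
eta_from_draw <- function(fit, draw) {
  design <- fit$design
  P <- length(design$parameters)
  eta <- matrix(0, design$n, P)
  for (p_i in seq_len(P)) {
    pd <- design$parameters[[p_i]]
    b <- draw[pd$coef_names]
    eta[, p_i] <- as.vector(pd$X %*% b)
    for (r in pd$random) {
      U <- matrix(draw[r$z_names], nrow = r$q) # q x n_groups, scaled deviations
      eta[, p_i] <- eta[, p_i] +
        rowSums(r$Z * t(U)[r$group_index, , drop = FALSE])
    }
  }
  colnames(eta) <- names(fit$model$parameters)
  eta
}

# replicate responses given per-trial eta and the observed trial structure
simulate_responses <- function(eta, prep, model) {
  n <- length(prep$x)
  pars <- names(model$parameters)
  version <- if (startsWith(model$name, "imm")) sub("^imm_", "", model$name) else NULL
  out <- numeric(n)
  for (i in seq_len(n)) {
    m <- prep$m[i]
    kappa <- exp(eta[i, "kappa"])
    if (model$name %in% c("mixture2p", "mixture3p")) {
      if (model$name == "mixture2p" || m == 0L) {
        p <- softmax_probs(eta[i, "thetat"])
        probs <- c(p[1], rep(0, m), p[2])
      } else {
        p <- softmax_probs(c(eta[i, "thetat"], eta[i, "thetant"]))
        probs <- c(p[1], rep(p[2] / m, m), p[3])
      }
    } else {
      pr <- imm_component_probs(
        c = exp(eta[i, "c"]),
        a = if ("a" %in% pars) exp(eta[i, "a"]) else 0,
        s = if ("s" %in% pars) exp(eta[i, "s"]) else 0,
        b = model$fixed[["b"]],
        distances = if (version != "abc" && m > 0L) prep$dist[i, seq_len(m)] else NULL,
        set_size = m + 1L, version = version)
      probs <- c(pr$p_mem, pr$p_nt, pr$p_guess)
    }
    comp <- sample.int(m + 2L, 1L, prob = probs)
    out[i] <- if (comp == 1L) rvonmises(1, 0, kappa)
              else if (comp == m + 2L) stats::runif(1, -pi, pi)
              else rvonmises(1, prep$nt[i, comp - 1L], kappa)
  }
  wrap_angle(out)
}

# von Mises kernel density on a circular grid; integrates to 1
circular_density <- function(x, grid, kernel_kappa = 25) {
  dens <- vapply(grid, function(g) {
    mean(dvonmises(g, x, kernel_kappa, log = FALSE))
  }, numeric(1))
  dens
}

#' Posterior predictive check
#'
#' Draws `n_draws` posterior parameter draws, simulates a full replicate
#' dataset for each (same subjects, trial structure, and non-target
#' geometry as the fitted data), and returns von Mises kernel-smoothed
#' response-error densities of the observed and replicated data on a
#' common angular grid. The model fits well when the observed curve lies
#' within the band of replicate curves.
#'
#' @param fit A `wmm_fit`.
#' @param n_draws Number of replicate datasets (default 10).
#' @param seed Integer seed (selection of draws and simulation).
#' @param n_grid Grid resolution over (-pi, pi] (default 101).
#' @param kernel_kappa Concentration of the smoothing kernel (fixed
#'   default 25, roughly a 11-degree kernel SD).
#' @return A `wmm_ppc` object: `grid`, `observed` (density), `yrep`
#'   (n_draws x grid matrix).
#' @export
pp_check <- function(fit, n_draws = 10, seed = 1, n_grid = 101,
                     kernel_kappa = 25) {
  stopifnot(inherits(fit, "wmm_fit"))
  m <- draws_matrix(fit$draws)
  if (n_draws > nrow(m)) {
    stop("n_draws (", n_draws, ") exceeds stored posterior draws (", nrow(m), ")")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  prep <- prepare_model_data(fit$data, fit$model)
  grid <- seq(-pi, pi, length.out = n_grid)
  idx <- sample.int(nrow(m), n_draws)
  yrep <- matrix(NA_real_, n_draws, n_grid)
  for (d in seq_len(n_draws)) {
    eta <- eta_from_draw(fit, m[idx[d], ])
    yrep[d, ] <- circular_density(simulate_responses(eta, prep, fit$model),
                                  grid, kernel_kappa)
  }
  structure(list(grid = grid, observed = circular_density(prep$x, grid, kernel_kappa),
                 yrep = yrep, draw_index = idx),
            class = "wmm_ppc")
}

#' @export
print.wmm_ppc <- function(x, ...) {
  inside <- mean(x$observed >= apply(x$yrep, 2, min) &
                 x$observed <= apply(x$yrep, 2, max))
  cat("<wmm_ppc>", nrow(x$yrep), "replicate densities on",
      length(x$grid), "grid points\n")
  cat("  observed curve inside replicate envelope at",
      sprintf("%.0f%%", 100 * inside), "of grid points\n")
  invisible(x)
}

#' Savage-Dickey hypothesis tests
#'
#' Tests named point (`"expr = 0"`) or directional (`"expr > 0"`,
#' `"expr < 0"`) claims about (combinations of) coefficients. For point
#' hypotheses the evidence ratio is the Savage-Dickey density ratio of
#' prior to posterior at the point — the Bayes factor BF01 in favour of
#' the point hypothesis (its reciprocal BF10 is also reported); it
#' requires a fit run with `sample_prior = TRUE`. For directional
#' hypotheses the posterior probability of the stated direction is
#' computed by draw counting and the evidence ratio is its odds.
#'
#' @param fit A `wmm_fit`.
#' @param statements Character vector of hypotheses over coefficient names
#'   (backtick non-syntactic names); optionally named.
#' @return A `wmm_hypothesis` data frame with `Estimate`, `Est.Error`,
#'   `CI.Lower`, `CI.Upper`, `Evid.Ratio` (BF01 for point hypotheses),
#'   `BF10`, `Post.Prob`.
#' @export
hypothesis <- function(fit, statements) {
  stopifnot(inherits(fit, "wmm_fit"), is.character(statements))
  post <- as.data.frame(draws_matrix(fit$draws), check.names = FALSE)
  prior <- if (!is.null(fit$prior_draws)) {
    as.data.frame(draws_matrix(fit$prior_draws), check.names = FALSE)
  } else NULL
  rows <- lapply(seq_along(statements), function(i) {
    st <- statements[i]
    parsed <- parse_hypothesis(st)
    combo <- eval_combo(parsed$lhs, post) - parsed$rhs
    est <- mean(combo); se <- stats::sd(combo)
    ci <- stats::quantile(combo, c(0.025, 0.975))
    if (parsed$type == "point") {
      if (se == 0) {
        warning("hypothesis '", st, "': derived combination is degenerate at ",
                est + parsed$rhs, "; no density ratio computed", call. = FALSE)
        er <- NA_real_; pp <- NA_real_
      } else {
        if (is.null(prior)) {
          stop("evidence ratios for point hypotheses need prior draws; ",
               "refit with sample_prior = TRUE")
        }
        pcombo <- eval_combo(parsed$lhs, prior) - parsed$rhs
        # Savage-Dickey: BF01 in favour of the point hypothesis is the
        # posterior over the prior density at the point
        er <- density_at(combo, 0) / density_at(pcombo, 0)
        pp <- NA_real_
      }
    } else {
      sign_ok <- if (parsed$type == "greater") combo > 0 else combo < 0
      pp <- mean(sign_ok)
      er <- pp / (1 - pp)
    }
    data.frame(Hypothesis = if (!is.null(names(statements)) && nzchar(names(statements)[i]))
                 names(statements)[i] else st,
               Estimate = est, Est.Error = se,
               CI.Lower = unname(ci[1]), CI.Upper = unname(ci[2]),
               Evid.Ratio = er, BF10 = 1 / er, Post.Prob = pp,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("wmm_hypothesis", "data.frame"))
}

parse_hypothesis <- function(st) {
  if (grepl("=", st, fixed = TRUE) && !grepl("[<>]", st)) {
    parts <- strsplit(st, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed hypothesis: ", st)
    return(list(type = "point", lhs = parts[1], rhs = as.numeric(parts[2])))
  }
  if (grepl(">", st, fixed = TRUE)) {
    parts <- strsplit(st, ">", fixed = TRUE)[[1]]
    return(list(type = "greater", lhs = parts[1], rhs = as.numeric(parts[2])))
  }
  if (grepl("<", st, fixed = TRUE)) {
    parts <- strsplit(st, "<", fixed = TRUE)[[1]]
    return(list(type = "less", lhs = parts[1], rhs = as.numeric(parts[2])))
  }
  stop("hypothesis must contain '=', '>' or '<': ", st)
}

eval_combo <- function(expr_text, draws_df) {
  e <- tryCatch(parse(text = expr_text)[[1]],
                error = function(err) stop("cannot parse '", expr_text, "'"))
  vars <- all.vars(e)
  missing_vars <- setdiff(vars, names(draws_df))
  if (length(missing_vars)) {
    stop("unknown coefficient(s): ", paste(missing_vars, collapse = ", "))
  }
  eval(e, draws_df)
}

# Gaussian kernel density estimate at a point; Sheather-Jones plug-in
# bandwidth with nrd0 fallback
density_at <- function(x, point) {
  bw <- tryCatch(stats::bw.SJ(x), error = function(e) stats::bw.nrd0(x))
  mean(stats::dnorm(point, mean = x, sd = bw))
}
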