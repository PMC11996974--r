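#' Specify a prior
#'
#' Builds one row of a prior table in the style of regression-based
#' Bayesian packages. A prior targets a coefficient class (`"b"` for
#' regression coefficients, `"sd"` for random-effect standard deviations,
#' `"cor"` for random-effect correlations), optionally narrowed to a model
#' parameter, a coefficient name, and/or a grouping variable; the most
#' specific matching row wins when priors are resolved.
#'
#' Supported distributions: `normal(mean, sd)` (optionally truncated via
#' `lb`/`ub`), `student_t(df, mean, sd)`, and `constant(value)`.
#'
#' @param prior Distribution string, e.g. `"normal(0, 1)"`.
#' @param class `"b"`, `"sd"`, or `"cor"`.
#' @param parameter Model parameter name (`"kappa"`, `"thetat"`, ...) or
#'   `""` for all.
#' @param coef Coefficient name or `""` for all coefficients in scope.
#' @param group Grouping variable (for `sd`/`cor`) or `""`.
#' @param lb,ub Optional bounds on the coefficient itself (e.g. `lb = 0`
#'   to force successive-difference coefficients to be non-negative).
#' @return A one-row `data.frame` of class `wmm_prior`.
#' @examples
#' set_prior("normal(0, 1)", class = "b", parameter = "kappa", lb = 0)
#' @export
set_prior <- function(prior, class = "b", parameter = "", coef = "",
                      group = "", lb = NA_real_, ub = NA_real_) {
  stopifnot(is.character(prior), length(prior) == 1L)
  parse_prior_string(prior) # validates
  structure(data.frame(class = class, parameter = parameter, coef = coef,
                       group = group, prior = prior, lb = lb, ub = ub,
                       source = "user", stringsAsFactors = FALSE),
            class = c("wmm_prior", "data.frame"))
}

#' Combine prior rows
#' @param ... `wmm_prior` rows.
#' @return A `wmm_prior` table.
#' @export
prior_table <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  structure(out, class = c("wmm_prior", "data.frame"))
}

parse_prior_string <- function(s) {
  m <- regmatches(s, regexec("^\\s*([a-z_]+)\\s*\\(([^)]*)\\)\\s*$", s))[[1]]
  if (length(m) == 0L) stop("cannot parse prior '", s, "'")
  family <- m[2]
  args <- if (nzchar(trimws(m[3]))) {
    suppressWarnings(as.numeric(strsplit(m[3], ",")[[1]]))
  } else numeric(0)
  if (anyNA(args)) stop("non-numeric arguments in prior '", s, "'")
  n_args <- c(normal = 2L, student_t = 3L, constant = 1L)
  if (!family %in% names(n_args)) {
    stop("unsupported prior family '", family,
         "' (use normal, student_t, or constant)")
  }
  if (length(args) != n_args[[family]]) {
    stop("prior '", s, "' needs ", n_args[[family]], " arguments")
  }
  if (family %in% c("normal", "student_t") && args[length(args)] <= 0) {
    stop("prior scale must be > 0 in '", s, "'")
  }
  list(family = family, args = args)
}

# precompute the parsed form of a prior row (the samplers evaluate priors
# millions of times; string parsing must happen once)
compile_prior <- function(row) {
  p <- parse_prior_string(row$prior)
  list(family = p$family, args = p$args, lb = row$lb, ub = row$ub, row = row)
}

# log density and d/dx of a (possibly truncated) prior at constrained x.
# Truncation only changes the normalising constant, which is parameter-free
# here, so gradients are unaffected. `spec` is a prior row or its
# compile_prior() form.
prior_logpdf <- function(spec, x) {
  p <- if (!is.null(spec$family)) spec else parse_prior_string(spec$prior)
  switch(p$family,
    normal = stats::dnorm(x, p$args[1], p$args[2], log = TRUE),
    student_t = stats::dt((x - p$args[2]) / p$args[3], df = p$args[1], log = TRUE) - log(p$args[3]),
    constant = ifelse(x == p$args[1], 0, -Inf)
  )
}

prior_grad <- function(spec, x) {
  p <- if (!is.null(spec$family)) spec else parse_prior_string(spec$prior)
  switch(p$family,
    normal = -(x - p$args[1]) / p$args[2]^2,
    student_t = {
      z <- (x - p$args[2]) / p$args[3]
      -(p$args[1] + 1) * z / (p$args[1] + z^2) / p$args[3]
    },
    constant = 0 * x
  )
}

prior_mean <- function(spec) {
  p <- if (!is.null(spec$family)) spec else parse_prior_string(spec$prior)
  switch(p$family,
    normal = p$args[1], student_t = p$args[2], constant = p$args[1])
}

#' Default priors for a model and formula
#'
#' Returns the full effective prior table before fitting: the fixed model
#' constants (target and uniform locations at 0, `log(kappa_uniform) =
#' -100`, guessing weight 0, IMM `b = 1`) and weakly informative defaults
#' for every estimable coefficient on its link scale:
#'
#' * `kappa` intercept / cell-mean coefficients: `normal(2, 1)` on log
#'   kappa; difference-type coefficients (interactions, non-intercept
#'   columns of intercepted designs): `normal(0, 1)`;
#' * mixing weights (`thetat`, `thetant`) and IMM log-activations
#'   (`c`, `a`, `s`): `normal(0, 2)`;
#' * random-effect SDs: half-normal, `normal(0, 1)` with `lb = 0`;
#' * random-effect correlations (for `|` terms): uniform partial
#'   correlations.
#'
#' User priors passed to [fit_wmm()] replace matching rows (most specific
#' match wins).
#'
#' @param model A `wmm_model`.
#' @param formula A [wmf()] formula set.
#' @param data Trial table.
#' @param contrasts Contrast assignment as in [build_design()].
#' @return A `wmm_prior` table with a `source` column
#'   (`"default"`/`"constant"`).
#' @export
default_priors <- function(model, formula, data, contrasts = list()) {
  design <- build_design(formula, data, contrasts, model = model)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)

  for (pd in design$parameters) {
    par <- pd$parameter
    has_intercept <- "Intercept" %in% colnames(pd$X)
    for (j in seq_along(pd$coef_names)) {
      cn <- colnames(pd$X)[j]
      if (par == "kappa") {
        is_cellmean <- (cn == "Intercept") ||
          (!has_intercept && !grepl(":", cn, fixed = TRUE))
        pr <- if (is_cellmean) "normal(2, 1)" else "normal(0, 1)"
      } else {
        pr <- "normal(0, 2)"
      }
      add(class = "b", parameter = par, coef = cn, group = "",
          prior = pr, lb = NA_real_, ub = NA_real_, source = "default")
    }
    for (r in pd$random) {
      for (cf in sd_coef_labels(r)) {
        add(class = "sd", parameter = par, coef = cf,
            group = r$group, prior = "normal(0, 1)", lb = 0, ub = NA_real_,
            source = "default")
      }
      if (r$correlated) {
        add(class = "cor", parameter = par, coef = "", group = r$group,
            prior = "uniform_partial_correlations", lb = -1, ub = 1,
            source = "default")
      }
    }
  }
  # fixed constants of the measurement models
  add(class = "constant", parameter = "mu_target", coef = "", group = "",
      prior = "constant(0)", lb = NA_real_, ub = NA_real_, source = "constant")
  add(class = "constant", parameter = "mu_uniform", coef = "", group = "",
      prior = "constant(0)", lb = NA_real_, ub = NA_real_, source = "constant")
  add(class = "constant", parameter = "log_kappa_uniform", coef = "", group = "",
      prior = "constant(-100)", lb = NA_real_, ub = NA_real_, source = "constant")
  add(class = "constant", parameter = "theta_guess", coef = "", group = "",
      prior = "constant(0)", lb = NA_real_, ub = NA_real_, source = "constant")
  if (startsWith(model$name, "imm")) {
    add(class = "constant", parameter = "b", coef = "", group = "",
        prior = "constant(1)", lb = NA_real_, ub = NA_real_, source = "constant")
  }
  structure(do.call(rbind, rows), class = c("wmm_prior", "data.frame"))
}

# most specific user row wins: specificity = filled fields among
# (parameter, coef, group)
resolve_priors <- function(defaults, user) {
  if (is.null(user) || nrow(user) == 0L) return(defaults)
  out <- defaults
  for (i in seq_len(nrow(out))) {
    if (out$class[i] == "constant") next
    cand <- user[user$class == out$class[i] &
                 (user$parameter == "" | user$parameter == out$parameter[i]) &
                 (user$coef == "" | user$coef == out$coef[i]) &
                 (user$group == "" | user$group == out$group[i]), , drop = FALSE]
    if (nrow(cand) == 0L) next
    score <- (cand$parameter != "") + (cand$coef != "") * 2 + (cand$group != "")
    best <- cand[which.max(score), , drop = FALSE]
    out$prior[i] <- best$prior
    if (!is.na(best$lb)) out$lb[i] <- best$lb
    if (!is.na(best$ub)) out$ub[i] <- best$ub
    out$source[i] <- "user"
  }
  out
}

lookup_prior <- function(priors, class, parameter, coef = "", group = "") {
  hit <- priors[priors$class == class & priors$parameter == parameter &
                (priors$coef == coef | priors$coef == "") &
                (priors$group == group | priors$group == ""), , drop = FALSE]
  if (nrow(hit) == 0L) stop("no prior found for ", class, "_", parameter, "_", coef)
  hit[1, , drop = FALSE]
}
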