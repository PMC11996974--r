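#' Save and reload a fit as plain-text files
#'
#' Writes a `wmm_fit` to a directory as tidy CSV and JSON: `draws.csv`
#' (chain, iteration, coefficient, value), optionally `prior_draws.csv`,
#' `diagnostics.json` (per-coefficient R-hat/ESS, divergences, step sizes,
#' seed), `meta.json` (model, formulas, contrasts, dimensions), and
#' `data.csv` (the normalised trial table). `read_wmm_fit()` restores a
#' working `wmm_fit` by re-parsing the formulas and rebuilding the design
#' against the stored data.
#'
#' @param fit A `wmm_fit`.
#' @param dir Output directory (created if missing).
#' @return `write_wmm_fit`: `dir`, invisibly. `read_wmm_fit`: a `wmm_fit`.
#' @export
write_wmm_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "wmm_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_draws_csv(fit$draws, file.path(dir, "draws.csv"))
  if (!is.null(fit$prior_draws)) {
    write_draws_csv(fit$prior_draws, file.path(dir, "prior_draws.csv"))
  }
  jsonlite::write_json(list(
    diagnostics = fit$diagnostics,
    divergences = fit$divergences, step_sizes = fit$step_sizes,
    accept_rates = fit$accept_rates, seed = fit$seed,
    data_fingerprint = fit$data_fingerprint, time_sec = fit$time
  ), file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  v <- fit$model$vars
  jsonlite::write_json(list(
    model = fit$model$name, vars = v[!vapply(v, is.null, logical(1))],
    formulas = formula_strings(fit$formula),
    contrasts = fit$contrasts,
    priors = fit$priors,
    factor_cols = lapply(Filter(is.factor, fit$data), levels),
    chains = fit$chains, warmup = fit$warmup, iter = fit$iter
  ), file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  write_trial_table(fit$data, file.path(dir, "data.csv"))
  invisible(dir)
}

write_draws_csv <- function(draws, path) {
  d <- dim(draws)
  df <- data.frame(
    chain = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
    iteration = rep(seq_len(d[1]), d[2] * d[3]),
    coefficient = rep(dimnames(draws)[[3]], each = d[1] * d[2]),
    value = as.vector(draws))
  utils::write.csv(df, path, row.names = FALSE)
}

read_draws_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  coefs <- unique(df$coefficient)
  chains <- max(df$chain); iters <- max(df$iteration)
  array(df$value, c(iters, chains, length(coefs)),
        dimnames = list(NULL, NULL, coefs))
}

formula_strings <- function(formula) {
  vapply(formula, function(pf) {
    rand <- vapply(pf$random, function(r) {
      bar <- if (r$correlated) "|" else "||"
      grp <- if (is.null(r$by)) r$group else sprintf("gr(%s, by = %s)", r$group, r$by)
      sprintf("(%s %s %s)", deparse_rhs(r$terms, r$intercept), bar, grp)
    }, character(1))
    paste(pf$parameter, "~",
          paste(c(deparse_rhs(pf$fixed_terms, pf$intercept), rand), collapse = " + "))
  }, character(1))
}

model_from_meta <- function(meta) {
  v <- meta$vars
  nt <- unlist(v$nt_features)
  dn <- unlist(v$nt_distances)
  switch(meta$model,
    mixture2p = mixture2p(v$resp_error),
    mixture3p = mixture3p(v$resp_error, nt, v$set_size,
                          regex = isTRUE(v$regex)),
    imm(v$resp_error, nt, v$set_size, nt_distances = dn,
        version = sub("^imm_", "", meta$model), regex = isTRUE(v$regex)))
}

#' @rdname write_wmm_fit
#' @export
read_wmm_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  diag <- jsonlite::read_json(file.path(dir, "diagnostics.json"), simplifyVector = TRUE)
  data <- read_trial_table(file.path(dir, "data.csv"))
  # factors must be restored for the design to rebuild identically
  model <- model_from_meta(meta)
  formula <- wmf(lapply(meta$formulas, stats::as.formula))
  contrasts <- as.list(meta$contrasts)
  for (v in names(meta$factor_cols)) {
    if (v %in% names(data)) {
      data[[v]] <- factor(data[[v]], levels = unlist(meta$factor_cols[[v]]))
    }
  }
  formula <- check_formula_parameters(formula, model)
  design <- build_design(formula, data, contrasts)
  # JSON drops all-NA columns and narrows types; restore the prior schema
  pr <- as.data.frame(meta$priors, stringsAsFactors = FALSE)
  for (cc in c("class", "parameter", "coef", "group", "prior", "source")) {
    if (is.null(pr[[cc]])) pr[[cc]] <- ""
    pr[[cc]] <- as.character(pr[[cc]])
    pr[[cc]][is.na(pr[[cc]])] <- ""
  }
  for (cc in c("lb", "ub")) {
    pr[[cc]] <- if (is.null(pr[[cc]])) NA_real_ else as.numeric(pr[[cc]])
  }
  priors <- structure(pr, class = c("wmm_prior", "data.frame"))
  layout <- build_layout(model, design, priors)
  draws <- read_draws_csv(file.path(dir, "draws.csv"))
  prior_path <- file.path(dir, "prior_draws.csv")
  prior_draws <- if (file.exists(prior_path)) read_draws_csv(prior_path) else NULL
  structure(list(
    draws = draws, prior_draws = prior_draws,
    diagnostics = as.data.frame(diag$diagnostics),
    divergences = diag$divergences, step_sizes = diag$step_sizes,
    accept_rates = diag$accept_rates,
    model = model, formula = formula, contrasts = contrasts,
    priors = priors, design = design, layout = layout, data = data,
    chains = meta$chains, warmup = meta$warmup, iter = meta$iter,
    seed = diag$seed, data_fingerprint = diag$data_fingerprint,
    time = diag$time_sec
  ), class = "wmm_fit")
}
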