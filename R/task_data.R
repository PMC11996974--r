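#' Recode absolute feature values relative to the target
#'
#' The models expect the response as an error relative to the target and
#' the non-target locations relative to the target. Given absolute values,
#' this subtracts the target and wraps to (-pi, pi]: a target of 0.7 with
#' non-targets (0.5, 0.9, 1.1) yields (-0.2, 0.2, 0.4).
#'
#' @param response Absolute response(s) in radians.
#' @param target Absolute target value(s) in radians.
#' @param nt_absolute Vector (single trial) or matrix (one row per trial)
#'   of absolute non-target values; `NA` slots stay `NA`.
#' @return List with `response_error` and `nt_relative` (same shape as
#'   `nt_absolute`).
#' @examples
#' recode_relative(1.0, 0.7, c(0.5, 0.9, 1.1))
#' @export
recode_relative <- function(response, target, nt_absolute = NULL) {
  response_error <- wrap_angle(response - target)
  nt_relative <- NULL
  if (!is.null(nt_absolute)) {
    if (is.matrix(nt_absolute)) {
      nt_relative <- wrap_angle(sweep(nt_absolute, 1, target, "-"))
    } else {
      nt_relative <- wrap_angle(nt_absolute - target)
    }
  }
  list(response_error = response_error, nt_relative = nt_relative)
}

#' Validate a trial table against a model
#'
#' Checks that all columns required by the model are present, that angle
#' columns are wrapped to (-pi, pi], that the number of active non-target
#' slots matches `set_size - 1` per trial, and heuristically flags tables
#' that look degrees-coded (more than 1% of absolute angles above 2*pi).
#' Inactive slots may be coded `NA` or 0; slots beyond `set_size - 1` that
#' are coded 0 are normalised to `NA` in the returned table.
#'
#' @param data Trial table (data frame).
#' @param model A `wmm_model`.
#' @return Invisibly, a list with `data` (normalised table), `ok`,
#'   `warnings` (character). Missing required columns are a hard error.
#' @export
validate_table <- function(data, model) {
  stopifnot(is.data.frame(data), inherits(model, "wmm_model"))
  v <- model$vars
  required <- c(v$resp_error, v$set_size)
  if (!isTRUE(v$regex)) required <- c(required, v$nt_features, v$nt_distances)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("model '", model$name, "' requires column(s) not in data: ",
         paste(missing_cols, collapse = ", "))
  }
  cols <- resolve_model_columns(model, data)
  warnings <- character(0)

  angle_cols <- c(cols$resp_error, cols$nt_features)
  ang <- unlist(data[, angle_cols, drop = FALSE], use.names = FALSE)
  ang <- ang[!is.na(ang)]
  if (length(ang) && mean(abs(ang) > 2 * pi) > 0.01) {
    warnings <- c(warnings, paste0(
      "more than 1% of |angles| exceed 2*pi: the table looks degrees-coded; ",
      "convert with deg2rad() before fitting"))
  }
  out_of_range <- length(ang) && any(ang <= -pi | ang > pi)
  if (out_of_range) {
    warnings <- c(warnings,
                  "angle values outside (-pi, pi]; wrapping with wrap_angle()")
    for (cl in angle_cols) data[[cl]] <- wrap_angle(data[[cl]])
  }

  if (model$name != "mixture2p") {
    ss <- as.integer(as_numeric_set_size(data[[cols$set_size]]))
    if (anyNA(ss) || any(ss < 1)) stop("`", cols$set_size, "` must be integers >= 1")
    M <- length(cols$nt_features)
    if (any(ss - 1L > M)) {
      stop("set size up to ", max(ss), " but only ", M, " non-target slot columns")
    }
    nt <- as.matrix(data[, cols$nt_features, drop = FALSE])
    for (i in seq_len(nrow(data))) {
      m <- ss[i] - 1L
      extra <- setdiff(seq_len(M), seq_len(m))
      # zero-padding of inactive slots is legal; normalise to NA
      zero_pad <- extra[!is.na(nt[i, extra]) & nt[i, extra] == 0]
      nt[i, zero_pad] <- NA_real_
      active <- sum(!is.na(nt[i, seq_len(max(m, 0L))]))
      if (m > 0L && active < m) {
        stop("trial ", i, ": set size ", ss[i], " implies ", m,
             " active non-target slots, found ", active)
      }
      leftover <- extra[!is.na(nt[i, extra])]
      if (length(leftover)) {
        warnings <- c(warnings, paste0(
          "trial ", i, ": non-zero values in slots beyond set size; ",
          "treated as inactive"))
        nt[i, leftover] <- NA_real_
      }
    }
    data[, cols$nt_features] <- nt
    if (model$name %in% c("imm_bsc", "imm_full")) {
      d <- as.matrix(data[, cols$nt_distances, drop = FALSE])
      dn <- d[!is.na(d)]
      if (any(dn < 0)) stop("context distances must be >= 0")
    }
  }
  invisible(list(data = data, ok = length(warnings) == 0L, warnings = warnings))
}

#' Read and write trial tables as long-format CSV
#'
#' Thin CSV wrappers with a column-mapping configuration: `mapping` can
#' rename columns on load (e.g. `list(response_error = "dev_rad")`) and
#' supports regular expressions for slot columns via the model
#' constructors' `regex` option. Missing values are empty fields.
#'
#' @param path File path.
#' @param mapping Named character list: canonical name -> column name in
#'   the file.
#' @param data Trial table to write.
#' @return `read_trial_table`: a data frame.
#' @export
read_trial_table <- function(path, mapping = NULL) {
  data <- utils::read.csv(path, na.strings = c("", "NA"))
  if (!is.null(mapping)) {
    for (canonical in names(mapping)) {
      src <- mapping[[canonical]]
      if (!src %in% names(data)) stop("mapped column '", src, "' not in file")
      names(data)[names(data) == src] <- canonical
    }
  }
  data
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
}

#' Canonical trial-table schemas
#'
#' Zero-row tables with the column layout of the classic set-size
#' experiments: `"zhang_luck"` (subject, trial, set size up to 6,
#' response error, five lure columns `col_lure1..col_lure5`) and
#' `"bays"` (same structure with `resp_error` / `nt1_loc..nt5_loc`
#' naming). Useful as templates when preparing your own data and as the
#' reference schema for [validate_table()].
#'
#' @param name Preset name.
#' @return A zero-row data frame with the preset's columns.
#' @export
schema_preset <- function(name = c("zhang_luck", "bays")) {
  name <- match.arg(name)
  cols <- switch(name,
    zhang_luck = c("subID", "trial", "setsize", "response_error",
                   paste0("col_lure", 1:5)),
    bays = c("subID", "trial", "setsize", "resp_error",
             paste0("nt", 1:5, "_loc")))
  out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  out
}

#' Generative configuration for the trial simulator
#'
#' Describes the world [simulate_trials()] draws from: the design
#' (subjects x condition cells x trials per cell), group-level parameter
#' values per condition on the native scale, and between-subject
#' random-effect standard deviations on the link scale.
#'
#' @param model A `wmm_model`.
#' @param n_subjects Number of subjects.
#' @param trials_per_cell Trials per subject per condition cell.
#' @param conditions Data frame, one row per condition cell. Must contain
#'   the model's set-size column (except `mixture2p`, where a `set_size`
#'   column is optional and defaults to 1) plus native-scale parameter
#'   columns: `kappa` and `p_mem` (all models), `p_nt` (`mixture3p`),
#'   `c`, `a`, `s` as applicable for the IMM.
#' @param re_sd Named numeric: link-scale between-subject SDs per model
#'   parameter (default 0 = no subject variation). Deviations are drawn
#'   per subject and condition cell, matching a `(0 + cell || subject)`
#'   random-effect structure.
#' @param max_set_size Number of non-target slot columns to allocate
#'   (default: max set size in `conditions`).
#' @return A `wmm_generative_config`.
#' @export
generative_config <- function(model, n_subjects, trials_per_cell, conditions,
                              re_sd = NULL, max_set_size = NULL) {
  stopifnot(inherits(model, "wmm_model"), is.data.frame(conditions))
  pars <- names(model$parameters)
  need <- c("kappa",
            switch(model$name,
                   mixture2p = "p_mem",
                   mixture3p = c("p_mem", "p_nt"),
                   imm_abc = c("c", "a"), imm_bsc = c("c", "s"),
                   imm_full = c("c", "a", "s")))
  if (!all(need %in% names(conditions))) {
    stop("`conditions` must contain native-scale parameter column(s): ",
         paste(setdiff(need, names(conditions)), collapse = ", "))
  }
  ss_col <- model$vars$set_size
  if (is.null(ss_col)) ss_col <- "set_size"
  if (!ss_col %in% names(conditions)) {
    if (model$name != "mixture2p") stop("`conditions` must contain '", ss_col, "'")
    conditions[[ss_col]] <- 1L
  }
  ss <- as_numeric_set_size(conditions[[ss_col]])
  if (any(ss < 1)) stop("set sizes must be >= 1")
  if (any(conditions$kappa <= 0)) stop("kappa must be > 0")
  if (model$name == "mixture2p" &&
      any(conditions$p_mem < 0 | conditions$p_mem > 1)) {
    stop("p_mem must lie in [0, 1]")
  }
  if (model$name == "mixture3p") {
    if (any(conditions$p_mem < 0 | conditions$p_nt < 0 |
            conditions$p_mem + conditions$p_nt > 1)) {
      stop("(p_mem, p_nt, p_guess) must lie on the simplex")
    }
  }
  if (startsWith(model$name, "imm")) {
    act <- intersect(c("c", "a", "s"), names(conditions))
    if (any(as.matrix(conditions[, act, drop = FALSE]) < 0)) {
      stop("IMM activations must be >= 0")
    }
  }
  re_sd_full <- stats::setNames(rep(0, length(pars)), pars)
  if (!is.null(re_sd)) {
    bad <- setdiff(names(re_sd), pars)
    if (length(bad)) stop("re_sd for unknown parameter(s): ", paste(bad, collapse = ", "))
    if (any(re_sd < 0)) stop("re_sd must be >= 0")
    re_sd_full[names(re_sd)] <- re_sd
  }
  if (is.null(max_set_size)) max_set_size <- max(ss)
  structure(list(model = model, n_subjects = as.integer(n_subjects),
                 trials_per_cell = as.integer(trials_per_cell),
                 conditions = conditions, set_size_col = ss_col,
                 re_sd = re_sd_full, max_set_size = as.integer(max_set_size)),
            class = "wmm_generative_config")
}

# native-scale condition parameters -> link scale
native_to_link <- function(config, row) {
  model <- config$model
  cond <- config$conditions[row, ]
  out <- numeric(0)
  if (model$name %in% c("mixture2p", "mixture3p")) {
    p_mem <- cond$p_mem
    p_nt <- if (model$name == "mixture3p") cond$p_nt else 0
    p_guess <- 1 - p_mem - p_nt
    # softmax inverse with the guessing weight as reference 0
    eps <- 1e-12
    out <- c(kappa = log(cond$kappa),
             thetat = log(max(p_mem, eps)) - log(max(p_guess, eps)))
    if (model$name == "mixture3p") {
      out["thetant"] <- log(max(p_nt, eps)) - log(max(p_guess, eps))
    }
  } else {
    eps <- 1e-12
    out <- c(kappa = log(cond$kappa), c = log(max(cond$c, eps)))
    if ("a" %in% names(model$parameters)) out["a"] <- log(max(cond$a, eps))
    if ("s" %in% names(model$parameters)) out["s"] <- log(max(cond$s, eps))
  }
  out[names(model$parameters)]
}

#' Simulate trial data from a measurement model
#'
#' The generative counterpart of the mixture likelihood: per subject,
#' link-scale random deviations are drawn for every condition cell and
#' model parameter from centred normals with the configured SDs; per
#' trial, non-target locations are placed uniformly on the circle (context
#' distances drawn uniformly on (0, pi] for the IMM), component
#' probabilities are computed (softmax or IMM mapping), a generating
#' component is drawn, and the response error is drawn from the matching
#' von Mises (uniform for guessing). Identical seeds give identical
#' output.
#'
#' @param config A [generative_config()].
#' @param seed Integer seed.
#' @return List with `data` (trial table: `subID`, `trial`, condition
#'   columns, set size, `response_error`, `nt_feature_*`,
#'   `nt_distance_*`), `true_pars` (link-scale subject-by-cell parameter
#'   values plus the group-level values), and `labels` (generating
#'   component per trial: `"target"`, `"nontarget_<j>"`, or `"guess"`).
#' @export
simulate_trials <- function(config, seed = 1) {
  stopifnot(inherits(config, "wmm_generative_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  model <- config$model
  pars <- names(model$parameters)
  n_cells <- nrow(config$conditions)
  M <- config$max_set_size - 1L
  ss_col <- config$set_size_col
  version <- if (startsWith(model$name, "imm")) sub("^imm_", "", model$name) else NULL

  link_group <- t(vapply(seq_len(n_cells), function(r) native_to_link(config, r),
                         numeric(length(pars))))
  colnames(link_group) <- pars

  # subject-by-cell random deviations on the link scale
  re <- array(stats::rnorm(config$n_subjects * n_cells * length(pars)),
              dim = c(config$n_subjects, n_cells, length(pars)))
  for (p in seq_along(pars)) re[, , p] <- re[, , p] * config$re_sd[pars[p]]

  n_trials <- config$n_subjects * n_cells * config$trials_per_cell
  sub_id <- integer(n_trials)
  trial_id <- integer(n_trials)
  cell_id <- integer(n_trials)
  resp <- numeric(n_trials)
  labels <- character(n_trials)
  nt_mat <- matrix(NA_real_, n_trials, max(M, 0L))
  d_mat <- matrix(NA_real_, n_trials, max(M, 0L))
  true_rows <- vector("list", config$n_subjects * n_cells)
  trial_counter <- integer(config$n_subjects)
  k <- 0L
  for (subj in seq_len(config$n_subjects)) {
    for (cell in seq_len(n_cells)) {
      eta <- link_group[cell, ] + re[subj, cell, ]
      names(eta) <- pars
      set_size <- as.integer(as_numeric_set_size(config$conditions[[ss_col]][cell]))
      m <- set_size - 1L
      kappa <- exp(eta[["kappa"]])
      true_rows[[(subj - 1L) * n_cells + cell]] <-
        data.frame(subID = subj, cell = cell, t(eta))
      for (tr in seq_len(config$trials_per_cell)) {
        nt <- if (m > 0L) wrap_angle(stats::runif(m, -pi, pi)) else numeric(0)
        D <- if (m > 0L) stats::runif(m, 0, pi) else numeric(0)
        if (model$name %in% c("mixture2p", "mixture3p")) {
          if (model$name == "mixture2p" || m == 0L) {
            p <- softmax_probs(eta[["thetat"]])
            probs <- c(p[1], rep(0, m), p[2])
          } else {
            p <- softmax_probs(c(eta[["thetat"]], eta[["thetant"]]))
            probs <- c(p[1], rep(p[2] / m, m), p[3])
          }
        } else {
          pr <- imm_component_probs(
            c = exp(eta[["c"]]),
            a = if ("a" %in% pars) exp(eta[["a"]]) else 0,
            s = if ("s" %in% pars) exp(eta[["s"]]) else 0,
            b = model$fixed[["b"]],
            distances = if (version != "abc") D else NULL,
            set_size = set_size, version = version)
          probs <- c(pr$p_mem, pr$p_nt, pr$p_guess)
        }
        comp <- sample.int(m + 2L, 1L, prob = probs)
        err <- if (comp == 1L) rvonmises(1, 0, kappa)
               else if (comp == m + 2L) stats::runif(1, -pi, pi)
               else rvonmises(1, nt[comp - 1L], kappa)
        trial_counter[subj] <- trial_counter[subj] + 1L
        k <- k + 1L
        sub_id[k] <- subj
        trial_id[k] <- trial_counter[subj]
        cell_id[k] <- cell
        resp[k] <- wrap_angle(err)
        labels[k] <- if (comp == 1L) "target" else if (comp == m + 2L) "guess"
                     else paste0("nontarget_", comp - 1L)
        if (m > 0L) {
          nt_mat[k, seq_len(m)] <- nt
          d_mat[k, seq_len(m)] <- D
        }
      }
    }
  }
  data <- data.frame(subID = sub_id, trial = trial_id)
  cond_cols <- setdiff(names(config$conditions),
                       c("kappa", "p_mem", "p_nt", "c", "a", "s"))
  for (cc in cond_cols) data[[cc]] <- config$conditions[[cc]][cell_id]
  data$response_error <- resp
  if (M > 0L) {
    for (j in seq_len(M)) data[[paste0("nt_feature_", j)]] <- nt_mat[, j]
    for (j in seq_len(M)) data[[paste0("nt_distance_", j)]] <- d_mat[, j]
  }
  true_pars <- do.call(rbind, true_rows)
  list(data = data, true_pars = true_pars,
       group_pars = data.frame(cell = seq_len(n_cells), link_group,
                               config$conditions),
       labels = labels)
}
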