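#' Softmax transform of mixture weights
#'
#' Maps unbounded mixing weights to probabilities on the simplex,
#' `p_i = exp(theta_i) / sum_j exp(theta_j)`. One component's weight is
#' fixed at 0 as the reference (by convention the guessing distribution);
#' pass only the free weights and the reference is appended as the last
#' component. Computed with max-subtraction for overflow safety.
#'
#' @param theta Numeric vector of free mixing weights.
#' @param append_reference Append a reference weight of 0 as the last
#'   component (default `TRUE`). Set to `FALSE` to softmax a complete
#'   weight vector.
#' @return Probability vector summing to 1; with the reference appended,
#'   of length `length(theta) + 1`.
#' @examples
#' softmax_probs(2)        # c(0.88, 0.12): p_mem, p_guess
#' softmax_probs(c(0, 0))  # thirds
#' @export
softmax_probs <- function(theta, append_reference = TRUE) {
  if (!all(is.finite(theta))) stop("`theta` must be finite")
  w <- if (append_reference) c(theta, 0) else theta
  e <- exp(w - max(w))
  e / sum(e)
}

#' IMM activation-to-probability mapping
#'
#' Converts interference-measurement-model activations into the mixture
#' probabilities of recalling the target, swapping to each non-target, or
#' guessing. Each item j carries activation `A_j = a + c * exp(-s * D_j)`
#' with context distance `D_j` (`D = 0` for the target); probabilities are
#' the activations normalised by `b + sum_j A_j` with background noise
#' `b` (fixed to 1 during estimation). Version `"abc"` drops the
#' generalization gradient (lures receive only `a`); `"bsc"` drops the
#' general activation (`a = 0`).
#'
#' @param c Context activation, `>= 0`.
#' @param a General activation, `>= 0` (ignored for `"bsc"`).
#' @param s Generalization-gradient slope, `>= 0` (ignored for `"abc"`).
#' @param b Background noise, `> 0` (default 1).
#' @param distances Non-target context distances `D_j >= 0` (required for
#'   `"bsc"` and `"full"`); its length is `set_size - 1`.
#' @param set_size Number of items held in memory, `>= 1`.
#' @param version `"abc"`, `"bsc"`, or `"full"`.
#' @return List with `p_mem`, `p_nt` (length `set_size - 1`), `p_guess`;
#'   the concatenation lies on the simplex.
#' @examples
#' imm_component_probs(c = 1, a = 0.5, set_size = 3, version = "abc")
#' @export
imm_component_probs <- function(c, a = 0, s = 0, b = 1, distances = NULL,
                                set_size, version = c("full", "bsc", "abc")) {
  version <- match.arg(version)
  if (any(c(c, a, s) < 0) || b <= 0) stop("activations must be nonnegative and b > 0")
  m <- as.integer(set_size) - 1L
  if (m < 0L) stop("`set_size` must be >= 1")
  if (version == "bsc") a <- 0
  if (version != "abc" && m > 0L) {
    if (is.null(distances)) stop("`distances` required for version '", version, "'")
    if (length(distances) != m) stop("need ", m, " distances for set size ", set_size)
    if (any(distances < 0)) stop("`distances` must be >= 0")
  }
  A_t <- a + c
  A_l <- if (m == 0L) numeric(0)
         else if (version == "abc") rep(a, m)
         else a + c * exp(-s * distances)
  Q <- b + A_t + sum(A_l)
  list(p_mem = A_t / Q, p_nt = A_l / Q, p_guess = b / Q)
}

# left-compacted active lure values for one trial
active_slots <- function(values, m) {
  v <- values[!is.na(values)]
  if (length(v) != m) {
    stop("trial has ", length(v), " active non-target slots but set size implies ", m)
  }
  v
}

#' Per-trial mixture log-likelihood
#'
#' Evaluates the log-density of one observed response error under a model
#' variant, given parameter values on the link scale (`kappa`, `c`, `a`,
#' `s` on the log scale; `thetat`, `thetant` on the unbounded weight
#' scale). The target component is `vM(x; 0, kappa)`; each non-target
#' component sits at its relative location with total probability split
#' equally in the three-parameter mixture and per-item in the IMM; the
#' guessing component uses `kappa = exp(-100)`. All sums are combined with
#' log-sum-exp.
#'
#' @param x Response error in radians.
#' @param pars Named list/vector of link-scale parameter values for the
#'   model's estimable parameters.
#' @param model A `wmm_model`.
#' @param nt_features Non-target locations (radians relative to target);
#'   `NA` for inactive slots.
#' @param nt_distances Context distances (IMM `bsc`/`full`).
#' @param set_size Set size of the trial (default: active slots + 1).
#' @return Log-density of `x` (scalar).
#' @export
trial_loglik <- function(x, pars, model, nt_features = NULL,
                         nt_distances = NULL, set_size = NULL) {
  stopifnot(inherits(model, "wmm_model"), length(x) == 1L)
  pars <- as.list(pars)
  need <- names(model$parameters)
  if (!all(need %in% names(pars))) {
    stop("`pars` must contain: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(unlist(pars[need])))) stop("parameter values must be finite")
  if (is.null(set_size)) {
    set_size <- if (is.null(nt_features)) 1L else sum(!is.na(nt_features)) + 1L
  }
  m <- if (model$name == "mixture2p") 0L else as.integer(set_size) - 1L
  kappa <- exp(pars$kappa)
  log_ku <- model$fixed[["log_kappa_uniform"]]
  logf_guess <- dvonmises(x, 0, exp(log_ku))
  logf_t <- dvonmises(x, 0, kappa)

  if (model$name %in% c("mixture2p", "mixture3p")) {
    if (m == 0L) {
      p <- softmax_probs(pars$thetat)
      return(log_sum_exp(c(log(p[1]) + logf_t, log(p[2]) + logf_guess)))
    }
    mu <- active_slots(nt_features, m)
    p <- softmax_probs(c(pars$thetat, pars$thetant))
    terms <- c(log(p[1]) + logf_t,
               log(p[2] / m) + dvonmises(x, mu, kappa),
               log(p[3]) + logf_guess)
    return(log_sum_exp(terms))
  }

  version <- sub("^imm_", "", model$name)
  mu <- if (m > 0L) active_slots(nt_features, m) else numeric(0)
  D <- if (version != "abc" && m > 0L) active_slots(nt_distances, m) else NULL
  pr <- imm_component_probs(c = exp(pars$c),
                            a = if (!is.null(pars$a)) exp(pars$a) else 0,
                            s = if (!is.null(pars$s)) exp(pars$s) else 0,
                            b = model$fixed[["b"]], distances = D,
                            set_size = set_size, version = version)
  terms <- c(log(pr$p_mem) + logf_t,
             if (m > 0L) log(pr$p_nt) + dvonmises(x, mu, kappa),
             log(pr$p_guess) + logf_guess)
  log_sum_exp(terms)
}

log_sum_exp <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(-Inf)
  mx + log(sum(exp(v - mx)))
}

#' Dataset log-likelihood
#'
#' Sums [trial_loglik()] over the rows of a trial table, with parameter
#' values evaluated per trial (e.g. from design matrices). Uses the
#' compiled likelihood core.
#'
#' @param data Trial table (validated against `model`).
#' @param pars Matrix or data frame of link-scale parameter values, one row
#'   per trial, columns named after the model's estimable parameters; a
#'   single named vector is recycled to all trials.
#' @param model A `wmm_model`.
#' @return Total log-likelihood (scalar) with per-trial values in
#'   attribute `"trial_ll"`.
#' @export
dataset_loglik <- function(data, pars, model) {
  stopifnot(inherits(model, "wmm_model"))
  prep <- prepare_model_data(data, model)
  need <- names(model$parameters)
  if (is.null(dim(pars))) pars <- matrix(pars[need], nrow(data), length(need),
                                         byrow = TRUE, dimnames = list(NULL, need))
  pars <- as.matrix(as.data.frame(pars)[, need, drop = FALSE])
  res <- wmm_loglik_cpp(pars, model_code(model), prep$x, prep$nt, prep$dist,
                        prep$m, FALSE)
  structure(res$total, trial_ll = res$trial_ll)
}

model_code <- function(model) {
  match(model$name, c("mixture2p", "mixture3p", "imm_abc", "imm_bsc", "imm_full")) - 1L
}

# compact trial table into the arrays the C++ core expects
prepare_model_data <- function(data, model) {
  cols <- resolve_model_columns(model, data)
  x <- data[[cols$resp_error]]
  n <- length(x)
  if (model$name == "mixture2p") {
    return(list(x = x, nt = matrix(0, n, 0), dist = matrix(0, n, 0),
                m = integer(n)))
  }
  ss <- as.integer(as_numeric_set_size(data[[cols$set_size]]))
  M <- length(cols$nt_features)
  nt_raw <- as.matrix(data[, cols$nt_features, drop = FALSE])
  needs_d <- model$name %in% c("imm_bsc", "imm_full")
  d_raw <- if (needs_d) as.matrix(data[, cols$nt_distances, drop = FALSE]) else NULL
  nt <- matrix(NA_real_, n, M)
  dist <- matrix(NA_real_, n, M)
  m <- pmax(ss - 1L, 0L)
  for (i in seq_len(n)) {
    if (m[i] == 0L) next
    act <- which(!is.na(nt_raw[i, ]))
    if (length(act) < m[i]) {
      stop("trial ", i, ": set size ", ss[i], " implies ", m[i],
           " active non-target slots but only ", length(act), " are non-missing")
    }
    act <- act[seq_len(m[i])]
    nt[i, seq_len(m[i])] <- nt_raw[i, act]
    if (needs_d) {
      dv <- d_raw[i, act]
      if (anyNA(dv)) stop("trial ", i, ": missing context distance for an active slot")
      dist[i, seq_len(m[i])] <- dv
    }
  }
  list(x = x, nt = nt, dist = dist, m = m)
}

as_numeric_set_size <- function(s) {
  if (is.factor(s)) as.numeric(as.character(s)) else as.numeric(s)
}
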