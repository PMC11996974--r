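# Static Hamiltonian Monte Carlo with dual-averaging step-size adaptation
# and diagonal mass-matrix estimation during warmup. This is the sampler
# backend behind fit_wmm(): gradient-based draws, divergence counting,
# seeded determinism.

hmc_control_defaults <- function(control = list()) {
  def <- list(target_accept = 0.8, init_step = 0.1, traj_length = 1.2,
              max_leapfrog = 128L, max_deltaH = 1000, adapt_window = c(0.5, 0.95),
              init_retries = 10L)
  def[names(control)] <- control
  def
}

# One chain. lp_fun(raw) must return list(lp, grad). Returns raw draws
# (post-warmup), divergence count, final step size, mean acceptance.
run_hmc_chain <- function(lp_fun, init, warmup, iter, seed, control = list()) {
  ctl <- hmc_control_defaults(control)
  set.seed(as.integer(seed))
  d <- length(init)
  q <- init
  cur <- lp_fun(q)
  if (!is.finite(cur$lp)) stop("non-finite log posterior at initial values")

  inv_mass <- rep(1, d)
  eps <- find_initial_step(lp_fun, q, cur, inv_mass, ctl$init_step)
  # dual averaging (target delta = target_accept)
  da_mu <- log(10 * eps); da_H <- 0; da_logeps_bar <- log(eps)
  da_gamma <- 0.05; da_t0 <- 10; da_kappa <- 0.75; da_t <- 0

  w_lo <- floor(ctl$adapt_window[1] * warmup)
  w_hi <- floor(ctl$adapt_window[2] * warmup)
  adapt_buf <- matrix(NA_real_, max(w_hi - w_lo, 1L), d)
  buf_n <- 0L

  total <- warmup + iter
  draws <- matrix(NA_real_, iter, d)
  divergences <- 0L
  acc_sum <- 0

  for (it in seq_len(total)) {
    in_warmup <- it <= warmup
    eps_it <- if (in_warmup) eps else exp(da_logeps_bar)
    eps_use <- eps_it * stats::runif(1, 0.9, 1.1)
    L <- max(1L, min(ctl$max_leapfrog, as.integer(round(ctl$traj_length / eps_use))))

    p <- stats::rnorm(d) / sqrt(inv_mass)
    H0 <- -cur$lp + 0.5 * sum(p^2 * inv_mass)
    qp <- q; gp <- cur$grad
    divergent <- FALSE
    p_half <- p + 0.5 * eps_use * gp
    for (l in seq_len(L)) {
      qp <- qp + eps_use * inv_mass * p_half
      prop <- lp_fun(qp)
      if (!is.finite(prop$lp) || any(!is.finite(prop$grad))) {
        divergent <- TRUE; break
      }
      if (l < L) p_half <- p_half + eps_use * prop$grad
    }
    if (!divergent) {
      p_end <- p_half + 0.5 * eps_use * prop$grad
      H1 <- -prop$lp + 0.5 * sum(p_end^2 * inv_mass)
      dH <- H1 - H0
      if (!is.finite(dH) || dH > ctl$max_deltaH) divergent <- TRUE
    }
    alpha <- if (divergent) 0 else min(1, exp(-(H1 - H0)))
    if (!divergent && stats::runif(1) < alpha) {
      q <- qp; cur <- prop
    }
    if (divergent && !in_warmup) divergences <- divergences + 1L

    if (in_warmup) {
      da_t <- da_t + 1
      da_H <- (1 - 1 / (da_t + da_t0)) * da_H +
        (ctl$target_accept - alpha) / (da_t + da_t0)
      logeps <- da_mu - sqrt(da_t) / da_gamma * da_H
      w <- da_t^(-da_kappa)
      da_logeps_bar <- w * logeps + (1 - w) * da_logeps_bar
      eps <- exp(logeps)
      if (it > w_lo && it <= w_hi) {
        buf_n <- buf_n + 1L
        adapt_buf[buf_n, ] <- q
      }
      if (it == w_hi && buf_n > 10L) {
        v <- apply(adapt_buf[seq_len(buf_n), , drop = FALSE], 2, stats::var)
        inv_mass <- (buf_n / (buf_n + 5)) * v + 1e-3 * (5 / (buf_n + 5))
        # restart step-size adaptation around the current step size
        eps <- exp(da_logeps_bar)
        da_mu <- log(10 * eps); da_H <- 0; da_t <- 0
      }
    } else {
      acc_sum <- acc_sum + alpha
      draws[it - warmup, ] <- q
    }
  }
  list(draws = draws, divergences = divergences,
       step_size = exp(da_logeps_bar), accept_rate = acc_sum / max(iter, 1),
       inv_mass = inv_mass)
}

# crude reasonable-step-size heuristic: double/halve until the one-step
# acceptance probability crosses 0.5
find_initial_step <- function(lp_fun, q, cur, inv_mass, eps) {
  p <- stats::rnorm(length(q)) / sqrt(inv_mass)
  H0 <- -cur$lp + 0.5 * sum(p^2 * inv_mass)
  one_step <- function(eps) {
    p1 <- p + 0.5 * eps * cur$grad
    q1 <- q + eps * inv_mass * p1
    prop <- lp_fun(q1)
    if (!is.finite(prop$lp)) return(-Inf)
    p1 <- p1 + 0.5 * eps * prop$grad
    -( -prop$lp + 0.5 * sum(p1^2 * inv_mass) - H0)
  }
  a0 <- one_step(eps)
  dir <- if (is.finite(a0) && a0 > log(0.5)) 1 else -1
  for (i in 1:20) {
    eps_new <- eps * 2^dir
    a <- one_step(eps_new)
    cross <- if (dir > 0) (!is.finite(a) || a < log(0.5)) else (is.finite(a) && a > log(0.5))
    if (cross) break
    eps <- eps_new
  }
  eps
}
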