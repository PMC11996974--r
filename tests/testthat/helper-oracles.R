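# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# modified Bessel function of the first kind by power series
bessel_series <- function(x, nu, terms = 60) {
  k <- 0:(terms - 1)
  sum(exp((2 * k + nu) * log(x / 2) - lgamma(k + 1) - lgamma(k + nu + 1)))
}

# direct von Mises log-density from the series oracle
vm_logpdf_oracle <- function(x, mu, kappa) {
  kappa * cos(x - mu) - log(2 * pi) - log(bessel_series(kappa, 0))
}

# brute-force softmax
softmax_oracle <- function(theta) {
  e <- exp(theta)
  e / sum(e)
}

# numeric integral of a density over (-pi, pi]
integrate_circle <- function(f, rel.tol = 1e-9) {
  stats::integrate(f, -pi, pi, rel.tol = rel.tol, subdivisions = 500L)$value
}

# Rayleigh test p-value for circular uniformity
rayleigh_p <- function(theta) {
  n <- length(theta)
  rbar <- sqrt(sum(cos(theta))^2 + sum(sin(theta))^2) / n
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# circular mean and SD of a sample
circ_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))
circ_sd_sample <- function(theta) {
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  sqrt(-2 * log(rbar))
}

# small 3P-style dataset with slot padding, built by hand
toy_mixture_table <- function() {
  data.frame(
    subID = c(1, 1, 2, 2),
    setsize = c(1, 3, 2, 3),
    response_error = c(0.1, -0.5, 1.2, 3.0),
    nt1 = c(NA, 0.4, -2.0, 1.0),
    nt2 = c(NA, -1.3, NA, -0.7),
    d1 = c(NA, 0.5, 1.1, 0.2),
    d2 = c(NA, 2.0, NA, 1.5)
  )
}

# quick generative config for the two-parameter model
quick_2p_config <- function(n_subjects = 6, trials = 20,
                            p_mem = c(0.95, 0.7), kappa = c(10, 5),
                            re_sd = c(kappa = 0.2, thetat = 0.3)) {
  generative_config(
    mixture2p("response_error"), n_subjects = n_subjects,
    trials_per_cell = trials,
    conditions = data.frame(set_size = seq_along(p_mem), kappa = kappa,
                            p_mem = p_mem),
    re_sd = re_sd)
}

# simple autocorrelation-time ESS for Monte Carlo error bounds in tests
# (independent of the package's diagnostics)
coda_ess <- function(x) {
  n <- length(x)
  rho <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  tau <- 1 + 2 * sum(rho[seq_len(max(which(rho > 0.05), 1))])
  max(n / max(tau, 1), 10)
}
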