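#' Wrap angles to the interval (-pi, pi]
#'
#' All angular quantities in wmmix (response errors, non-target locations)
#' live on the half-open interval (-pi, pi]. Wrapping is idempotent and
#' preserves the angle modulo 2*pi.
#'
#' @param x Numeric vector of angles in radians (unbounded).
#' @return Numeric vector of the same length with every element in
#'   (-pi, pi].
#' @examples
#' wrap_angle(2 * pi)      # 0
#' wrap_angle(6.0)         # 6 - 2*pi
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  bad <- !is.na(x) & !is.finite(x)
  if (any(bad)) stop("`x` contains non-finite values")
  out <- x - 2 * pi * ceiling((x - pi) / (2 * pi))
  # guard against floating point landing exactly on -pi
  out[!is.na(out) & out <= -pi] <- pi
  out
}

#' Convert between degrees and radians
#'
#' Response errors collected in degrees must be converted to radians before
#' modelling; fitted circular standard deviations are often reported back in
#' degrees via `sd_deg = sd_rad / pi * 180`.
#'
#' @param x Numeric vector.
#' @return `deg2rad`: `x * pi / 180`; `rad2deg`: `x / pi * 180`.
#' @examples
#' deg2rad(180)            # pi
#' rad2deg(pi / 4)         # 45
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x / pi * 180

# log I0(kappa), exponentially scaled to stay finite for large kappa;
# besselI() loses accuracy above ~1e5, where the asymptotic expansion is
# exact to machine precision
log_bessel_i0 <- function(kappa) {
  out <- numeric(length(kappa))
  big <- kappa > 1e5
  out[big] <- kappa[big] - 0.5 * log(2 * pi * kappa[big]) +
    log1p(1 / (8 * kappa[big]))
  out[!big] <- log(besselI(kappa[!big], 0, expon.scaled = TRUE)) + kappa[!big]
  out
}

# mean resultant length R = I1(kappa) / I0(kappa)
vm_resultant <- function(kappa) {
  out <- numeric(length(kappa))
  big <- kappa > 1e5
  k <- kappa[big]
  out[big] <- 1 - 1 / (2 * k) - 1 / (8 * k^2) - 1 / (8 * k^3)
  out[!big] <- besselI(kappa[!big], 1, expon.scaled = TRUE) /
    besselI(kappa[!big], 0, expon.scaled = TRUE)
  out
}

#' Von Mises log-density
#'
#' Density `exp(kappa * cos(x - mu)) / (2 * pi * I0(kappa))`. With
#' `kappa = 0` this is the circular uniform `1 / (2 * pi)`; the guessing
#' component of all models uses `kappa = exp(-100)`, which is numerically
#' indistinguishable from uniform.
#'
#' @param x Numeric vector of angles in radians.
#' @param mu Location in radians (recycled).
#' @param kappa Concentration, `>= 0` (recycled).
#' @param log Return log-density (default `TRUE`).
#' @return Numeric vector of (log-)densities.
#' @examples
#' dvonmises(0.3, mu = 0, kappa = 4)
#' dvonmises(1, 0, 0, log = FALSE) # 1 / (2 * pi)
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = TRUE) {
  if (any(kappa < 0)) stop("`kappa` must be >= 0")
  ld <- kappa * cos(x - mu) - base::log(2 * pi) - log_bessel_i0(kappa)
  if (log) ld else exp(ld)
}

#' Sample from the von Mises distribution
#'
#' Best & Fisher (1979) wrapped-Cauchy rejection sampler; falls back to
#' uniform draws when `kappa` is (numerically) zero. Draws are wrapped to
#' (-pi, pi] and are reproducible given the RNG state (use `set.seed()` or
#' the `seed` argument).
#'
#' @param n Number of draws.
#' @param mu Location in radians.
#' @param kappa Concentration, `>= 0`.
#' @param seed Optional integer; when supplied the RNG is seeded locally so
#'   the global RNG state is left untouched.
#' @return Numeric vector of `n` angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1, seed = NULL) {
  stopifnot(length(n) == 1L, n >= 1, kappa >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  if (kappa < 1e-10) return(wrap_angle(stats::runif(n, -pi, pi)))
  # Best-Fisher: envelope is a wrapped Cauchy
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

#' Convert von Mises concentration to circular standard deviation
#'
#' `k2sd` computes the circular SD `sqrt(-2 * log(R))` with mean resultant
#' length `R = I1(kappa) / I0(kappa)`; `sd2k` numerically inverts it. The
#' SD is in radians; use [rad2deg()] for degrees.
#'
#' @param kappa Concentration, `>= 0`.
#' @param sd Circular standard deviation in radians, `> 0`.
#' @return `k2sd`: circular SD in radians (Inf at `kappa = 0`);
#'   `sd2k`: concentration.
#' @examples
#' k2sd(8)
#' sd2k(k2sd(8))           # 8
#' @export
k2sd <- function(kappa) {
  if (any(kappa < 0)) stop("`kappa` must be >= 0")
  out <- numeric(length(kappa))
  zero <- kappa == 0
  out[zero] <- Inf
  out[!zero] <- sqrt(-2 * log(vm_resultant(kappa[!zero])))
  out
}

#' @rdname k2sd
#' @export
sd2k <- function(sd) {
  if (any(sd <= 0)) stop("`sd` must be > 0")
  vapply(sd, function(s) {
    if (s > k2sd(1e-8)) return(0)
    f <- function(k) k2sd(k) - s
    # bracket: k2sd is strictly decreasing
    lo <- 1e-8; hi <- 1
    while (f(hi) > 0) hi <- hi * 2
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}
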