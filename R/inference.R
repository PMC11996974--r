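# Internal machinery mapping the hierarchical model onto an unconstrained
# parameter vector for HMC:
#   fixed effects (beta; lower/upper bounds handled by exp/logit
#   transforms with Jacobian terms), random-effect SDs (log scale),
#   random-effect correlations (canonical partial correlations, tanh
#   transform), and standardised random effects z (non-centered
#   parameterisation: u = diag(sd) L z).

build_layout <- function(model, design, priors) {
  pars <- names(model$parameters)
  blocks <- vector("list", length(design$parameters))
  pos <- 0L
  for (p_i in seq_along(design$parameters)) {
    pd <- design$parameters[[p_i]]
    par <- pd$parameter
    k <- ncol(pd$X)
    beta_priors <- lapply(seq_len(k), function(j) {
      compile_prior(lookup_prior(priors, "b", par, colnames(pd$X)[j]))
    })
    lb <- vapply(beta_priors, function(r) r$lb, numeric(1))
    ub <- vapply(beta_priors, function(r) r$ub, numeric(1))
    beta_idx <- pos + seq_len(k); pos <- pos + k
    rblocks <- vector("list", length(pd$random))
    for (r_i in seq_along(pd$random)) {
      r <- pd$random[[r_i]]
      sd_coefs <- sd_coef_labels(r)
      sd_priors <- lapply(sd_coefs, function(cf) {
        compile_prior(lookup_prior(priors, "sd", par, cf, r$group))
      })
      nsd <- length(sd_coefs)
      sd_idx <- pos + seq_len(nsd); pos <- pos + nsd
      ncor <- if (r$correlated) r$q * (r$q - 1L) / 2L else 0L
      cor_idx <- if (ncor) pos + seq_len(ncor) else integer(0)
      pos <- pos + ncor
      nz <- r$q * r$n_groups
      z_idx <- pos + seq_len(nz); pos <- pos + nz
      rblocks[[r_i]] <- list(r = r, sd_idx = sd_idx, sd_priors = sd_priors,
                             cor_idx = cor_idx, z_idx = z_idx)
    }
    blocks[[p_i]] <- list(par = par, pd = pd, beta_idx = beta_idx,
                          beta_priors = beta_priors, lb = lb, ub = ub,
                          random = rblocks)
  }
  stored <- stored_coef_names(blocks)
  list(blocks = blocks, n_raw = pos, pars = pars, stored = stored)
}

sd_coef_labels <- function(r) {
  if (is.null(r$strata_levels)) {
    r$term_names
  } else {
    as.vector(outer(r$term_names, r$strata_levels,
                    function(t, s) paste0(t, ":", clean_coef_names(s))))
  }
}

stored_coef_names <- function(blocks) {
  nm <- character(0)
  for (bl in blocks) {
    nm <- c(nm, bl$pd$coef_names)
    for (rb in bl$random) {
      nm <- c(nm, rb$r$sd_names, rb$r$cor_names, rb$r$z_names)
    }
  }
  nm
}

# beta transform helpers ----------------------------------------------------

constrain_beta <- function(raw, lb, ub) {
  b <- raw
  logj <- 0
  dconstr <- rep(1, length(raw))   # db/draw
  djac <- rep(0, length(raw))      # d logJ / draw
  for (j in seq_along(raw)) {
    lo <- lb[j]; hi <- ub[j]
    if (!is.na(lo) && is.na(hi)) {
      b[j] <- lo + exp(raw[j]); logj <- logj + raw[j]
      dconstr[j] <- exp(raw[j]); djac[j] <- 1
    } else if (is.na(lo) && !is.na(hi)) {
      b[j] <- hi - exp(raw[j]); logj <- logj + raw[j]
      dconstr[j] <- -exp(raw[j]); djac[j] <- 1
    } else if (!is.na(lo) && !is.na(hi)) {
      p <- stats::plogis(raw[j])
      b[j] <- lo + (hi - lo) * p
      logj <- logj + log(hi - lo) + log(p) + log1p(-p)
      dconstr[j] <- (hi - lo) * p * (1 - p)
      djac[j] <- 1 - 2 * p
    }
  }
  list(b = b, logj = logj, dconstr = dconstr, djac = djac)
}

# canonical-partial-correlation Cholesky ------------------------------------

cpc_chol <- function(y, q) {
  L <- diag(q)
  z_rows <- vector("list", q)
  idx <- 1L
  for (j in 2:q) {
    zj <- tanh(y[idx:(idx + j - 2L)])
    idx <- idx + j - 1L
    z_rows[[j]] <- zj
    rem <- 1
    for (k in seq_len(j - 1L)) {
      L[j, k] <- zj[k] * sqrt(rem)
      rem <- rem - L[j, k]^2
    }
    L[j, j] <- sqrt(max(rem, 0))
  }
  list(L = L, z_rows = z_rows)
}

# backpropagate gradient w.r.t. L entries to the unconstrained y
cpc_chol_grad <- function(chol_obj, dL, q) {
  L <- chol_obj$L
  dy <- numeric(q * (q - 1L) / 2L)
  idx <- 0L
  for (j in 2:q) {
    zj <- chol_obj$z_rows[[j]]
    nj <- j - 1L
    row <- L[j, 1:j]
    for (m in seq_len(nj)) {
      drow <- numeric(j)
      rem <- 1; drem <- 0
      for (k in seq_len(nj)) {
        sq <- sqrt(rem)
        dz_k <- if (k == m) (1 - zj[k]^2) else 0
        drow[k] <- dz_k * sq + if (sq > 0) zj[k] * drem / (2 * sq) else 0
        drem <- drem - 2 * row[k] * drow[k]
        rem <- rem - row[k]^2
      }
      drow[j] <- if (row[j] > 0) drem / (2 * row[j]) else 0
      dy[idx + m] <- sum(drow * dL[j, 1:j])
    }
    idx <- idx + nj
  }
  dy
}

# log posterior and gradient ------------------------------------------------

# Returns a closure raw -> list(lp, grad, trial_ll). `lik_weight` 0 gives
# prior-only sampling (used for sample_prior and prior predictive checks).
make_logpost <- function(model, design, layout, prep, lik_weight = 1) {
  mcode <- model_code(model)
  P <- length(layout$pars)
  n <- design$n

  function(raw, want_grad = TRUE) {
    lp <- 0
    g <- numeric(layout$n_raw)
    eta <- matrix(0, n, P)
    state <- vector("list", length(layout$blocks))

    for (p_i in seq_along(layout$blocks)) {
      bl <- layout$blocks[[p_i]]
      tb <- constrain_beta(raw[bl$beta_idx], bl$lb, bl$ub)
      lp <- lp + tb$logj
      eta[, p_i] <- as.vector(bl$pd$X %*% tb$b)
      rstates <- vector("list", length(bl$random))
      for (r_i in seq_along(bl$random)) {
        rb <- bl$random[[r_i]]
        r <- rb$r
        q <- r$q
        sd_raw <- raw[rb$sd_idx]
        sdv <- exp(sd_raw)
        lp <- lp + sum(sd_raw) # log-Jacobian of the log transform
        sd_mat <- matrix(sdv, q, r$n_strata)
        Zmat <- matrix(raw[rb$z_idx], nrow = q) # q x n_groups, term fastest
        lp <- lp + sum(stats::dnorm(Zmat, log = TRUE))
        chol_obj <- NULL
        if (r$correlated) {
          y <- raw[rb$cor_idx]
          chol_obj <- cpc_chol(y, q)
          # independent uniform partial correlations: density of y
          lp <- lp + sum(log1p(-tanh(y)^2))
          LZ <- chol_obj$L %*% Zmat
        } else {
          LZ <- Zmat
        }
        sd_g <- sd_mat[, r$stratum_of_group, drop = FALSE] # q x n_groups
        U <- sd_g * LZ
        eta[, p_i] <- eta[, p_i] +
          rowSums(r$Z * t(U)[r$group_index, , drop = FALSE])
        rstates[[r_i]] <- list(sdv = sdv, sd_mat = sd_mat, Zmat = Zmat,
                               chol_obj = chol_obj, LZ = LZ, sd_g = sd_g)
      }
      state[[p_i]] <- list(tb = tb, rstates = rstates)
    }

    if (lik_weight > 0) {
      res <- wmm_loglik_cpp(eta, mcode, prep$x, prep$nt, prep$dist, prep$m,
                            want_grad)
      lp <- lp + lik_weight * res$total
      G <- if (want_grad) lik_weight * res$grad else NULL
      trial_ll <- res$trial_ll
    } else {
      G <- if (want_grad) matrix(0, n, P) else NULL
      trial_ll <- NULL
    }
    if (!want_grad) return(list(lp = add_prior_lp(lp, layout, raw, state),
                                grad = NULL, trial_ll = trial_ll))

    for (p_i in seq_along(layout$blocks)) {
      bl <- layout$blocks[[p_i]]
      tb <- state[[p_i]]$tb
      gp <- G[, p_i]
      db <- as.vector(crossprod(bl$pd$X, gp))
      # beta priors on the constrained scale
      pg <- vapply(seq_along(db), function(j) {
        lp <<- lp + prior_logpdf(bl$beta_priors[[j]], tb$b[j])
        prior_grad(bl$beta_priors[[j]], tb$b[j])
      }, numeric(1))
      g[bl$beta_idx] <- (db + pg) * tb$dconstr + tb$djac
      for (r_i in seq_along(bl$random)) {
        rb <- bl$random[[r_i]]
        r <- rb$r
        st <- state[[p_i]]$rstates[[r_i]]
        W <- rowsum(r$Z * gp, r$group_index) # n_groups x q
        # guard: groups absent from rows (cannot happen with factor index)
        Wt <- t(W) # q x n_groups
        if (r$correlated) {
          dz_lik <- crossprod(st$chol_obj$L, st$sd_g * Wt)
          dsd_per_g <- st$LZ * Wt # q x n_groups
          dLmat <- (st$sd_g * Wt) %*% t(st$Zmat)
          dy <- cpc_chol_grad(st$chol_obj, dLmat, r$q)
          g[rb$cor_idx] <- dy - 2 * tanh(raw[rb$cor_idx])
        } else {
          dz_lik <- st$sd_g * Wt
          dsd_per_g <- st$Zmat * Wt
        }
        # z: standard normal prior
        g[rb$z_idx] <- as.vector(dz_lik - st$Zmat)
        # sd: accumulate over groups within stratum, add prior + Jacobian
        dsd <- matrix(0, r$q, r$n_strata)
        for (s in seq_len(r$n_strata)) {
          cols <- which(r$stratum_of_group == s)
          dsd[, s] <- rowSums(dsd_per_g[, cols, drop = FALSE])
        }
        dsd <- as.vector(dsd)
        spg <- vapply(seq_along(dsd), function(j) {
          lp <<- lp + prior_logpdf(rb$sd_priors[[j]], st$sdv[j])
          prior_grad(rb$sd_priors[[j]], st$sdv[j])
        }, numeric(1))
        g[rb$sd_idx] <- (dsd + spg) * st$sdv + 1
      }
    }
    list(lp = lp, grad = g, trial_ll = trial_ll)
  }
}

# prior-only lp (used by the want_grad = FALSE path)
add_prior_lp <- function(lp, layout, raw, state) {
  for (p_i in seq_along(layout$blocks)) {
    bl <- layout$blocks[[p_i]]
    tb <- state[[p_i]]$tb
    for (j in seq_along(tb$b)) {
      lp <- lp + prior_logpdf(bl$beta_priors[[j]], tb$b[j])
    }
    for (r_i in seq_along(bl$random)) {
      rb <- bl$random[[r_i]]
      st <- state[[p_i]]$rstates[[r_i]]
      for (j in seq_along(st$sdv)) {
        lp <- lp + prior_logpdf(rb$sd_priors[[j]], st$sdv[j])
      }
    }
  }
  lp
}

# raw vector -> named constrained draws (b_, sd_, cor_, r_)
constrain_draw <- function(raw, layout) {
  out <- numeric(0)
  for (bl in layout$blocks) {
    tb <- constrain_beta(raw[bl$beta_idx], bl$lb, bl$ub)
    v <- stats::setNames(tb$b, bl$pd$coef_names)
    out <- c(out, v)
    for (rb in bl$random) {
      r <- rb$r
      sdv <- exp(raw[rb$sd_idx])
      out <- c(out, stats::setNames(sdv, r$sd_names))
      Zmat <- matrix(raw[rb$z_idx], nrow = r$q)
      if (r$correlated) {
        chol_obj <- cpc_chol(raw[rb$cor_idx], r$q)
        C <- tcrossprod(chol_obj$L)
        out <- c(out, stats::setNames(C[lower.tri(C)], r$cor_names))
        LZ <- chol_obj$L %*% Zmat
      } else {
        LZ <- Zmat
      }
      sd_mat <- matrix(sdv, r$q, r$n_strata)
      U <- sd_mat[, r$stratum_of_group, drop = FALSE] * LZ
      out <- c(out, stats::setNames(as.vector(U), r$z_names))
    }
  }
  out
}

# initial raw values centred on prior means with jitter
init_raw <- function(layout, jitter = 0.5) {
  raw <- numeric(layout$n_raw)
  for (bl in layout$blocks) {
    for (j in seq_along(bl$beta_idx)) {
      mu <- prior_mean(bl$beta_priors[[j]])
      lo <- bl$lb[j]; hi <- bl$ub[j]
      r0 <- if (!is.na(lo) && is.na(hi)) {
        log(max(mu - lo, 0.25))
      } else if (is.na(lo) && !is.na(hi)) {
        log(max(hi - mu, 0.25))
      } else if (!is.na(lo) && !is.na(hi)) {
        stats::qlogis(min(max((mu - lo) / (hi - lo), 0.05), 0.95))
      } else mu
      raw[bl$beta_idx[j]] <- r0 + stats::runif(1, -jitter, jitter)
    }
    for (rb in bl$random) {
      raw[rb$sd_idx] <- log(0.25) + stats::runif(length(rb$sd_idx), -jitter, jitter)
      if (length(rb$cor_idx)) {
        raw[rb$cor_idx] <- stats::runif(length(rb$cor_idx), -0.1, 0.1)
      }
      raw[rb$z_idx] <- stats::rnorm(length(rb$z_idx), 0, 0.1)
    }
  }
  raw
}
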