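# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive everything from first principles and share
# no code with the package internals.

# Brute-force grid maximizer of the Breslow partial log-likelihood for a
# single binary covariate.
oracle_cox_beta_grid <- function(times, events, x, lo = -5, hi = 5,
                                 step = 1e-4) {
  betas <- seq(lo, hi, by = step)
  ev_times <- sort(unique(times[events == 1]))
  ll <- numeric(length(betas))
  for (t in ev_times) {
    at <- times >= t
    n1 <- sum(at & x == 1)
    n0 <- sum(at & x == 0)
    dead <- times == t & events == 1
    d <- sum(dead)
    d1 <- sum(dead & x == 1)
    ll <- ll + d1 * betas - d * log(n0 + n1 * exp(betas))
  }
  betas[which.max(ll)]
}

# Population limit of the binary-group Cox estimate when the cohort is
# split at the median of a standard-normal hazard modifier h, event times
# are exponential with rate lambda0 * exp(log_hr * h), and censoring is
# independent exponential with rate rho.  Solves the population partial-
# likelihood score equation by quadrature over h (quantile sampling) and
# numerical integration over time.
oracle_true_marginal_beta <- function(log_hr, lambda0, rho, n_h = 400) {
  u <- (seq_len(n_h) - 0.5) / n_h
  lam1 <- lambda0 * exp(log_hr * qnorm(0.5 + 0.5 * u))  # h | h > 0
  lam0 <- lambda0 * exp(log_hr * qnorm(0.5 * u))        # h | h <= 0
  score <- function(beta) {
    integrand <- function(t) {
      vapply(t, function(tt) {
        R1 <- mean(exp(-lam1 * tt))
        R0 <- mean(exp(-lam0 * tt))
        den <- R0 + R1 * exp(beta)
        if (den < 1e-300) return(0)
        q1 <- mean(lam1 * exp(-lam1 * tt))
        q0 <- mean(lam0 * exp(-lam0 * tt))
        (q1 - R1 * exp(beta) / den * (q0 + q1)) * exp(-rho * tt)
      }, numeric(1))
    }
    integrate(integrand, 0, Inf, rel.tol = 1e-8)$value
  }
  uniroot(score, c(0.01, 3), tol = 1e-8)$root
}

# AUC by explicit pair counting (ties count one half).
oracle_auc_pairs <- function(prob, labels) {
  pos <- prob[labels == 1]
  neg <- prob[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg by the literal step-up formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1])
  }
  out <- numeric(m)
  out[o] <- pmin(1, adj_sorted)
  out
}
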