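# Independent oracles used to validate the implementation. These are
# deliberately naive (textbook loops, enumeration, closed forms) and share
# no code with the package internals they check.

# product-limit estimator by direct per-time looping
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, survival = NA_real_)
  for (i in seq_along(ut)) {
    n_at <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_at)
    out$survival[i] <- s
  }
  out
}

# textbook logrank: O - E and hypergeometric variance accumulated in a
# per-event-time loop
oracle_logrank_stat <- function(time, event, in_b) {
  ut <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); nb <- sum(at & in_b)
    d <- sum(time == t & event == 1)
    db <- sum(time == t & event == 1 & in_b)
    o <- o + db
    e <- e + d * nb / n
    if (n > 1) v <- v + d * (nb / n) * (1 - nb / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(0)
  (o - e)^2 / v
}

# Breslow partial log-likelihood for a design matrix X (n x p)
oracle_cox_loglik <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- time == t & event == 1
    risk <- time >= t
    ll <- ll + sum(eta[dead]) - sum(dead) * log(sum(exp(eta[risk])))
  }
  ll
}

# independent Newton-Raphson maximizer of the Breslow partial likelihood
oracle_cox_fit <- function(X, time, event, tol = 1e-10, max_iter = 50) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    grad <- rep(0, p); info <- matrix(0, p, p)
    for (t in sort(unique(time[event == 1]))) {
      dead <- time == t & event == 1
      risk <- time >= t
      s0 <- sum(w[risk])
      s1 <- colSums(X[risk, , drop = FALSE] * w[risk])
      s2 <- t(X[risk, , drop = FALSE]) %*% (X[risk, , drop = FALSE] * w[risk])
      d <- sum(dead)
      grad <- grad + colSums(X[dead, , drop = FALSE]) - d * s1 / s0
      info <- info + d * (s2 / s0 - tcrossprod(s1 / s0))
    }
    step <- solve(info, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, info = info)
}

# Fisher two-sided p by full hypergeometric support enumeration
# ("sum of small p" rule with relative tolerance)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand percentile: linear interpolation over (n - 1) intervals
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# small deterministic survival fixture builder
toy_surv <- function(seed, n = 40, event_p = 0.7, rate = 0.05) {
  set.seed(seed)
  t_event <- rexp(n, rate)
  cens <- rexp(n, rate * (1 - event_p) / event_p)
  list(time = pmin(t_event, cens),
       event = as.integer(t_event <= cens),
       group = sample(c("A", "B"), n, replace = TRUE))
}
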