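test_that("Kaplan-Meier estimate matches hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_equal(km$time, c(1, 2, 4))
  expect_equal(km$survival, c(3 / 4, 1 / 2, 0))
  expect_equal(km$n_risk, c(4, 3, 1))

  # against the naive per-time oracle on random censored data
  s <- toy_surv(101)
  km2 <- km_estimate(s$time, s$event)
  orc <- oracle_km(s$time, s$event)
  expect_equal(km2$time, orc$time)
  expect_equal(km2$survival, orc$survival, tolerance = 1e-12)
})

test_that("KM handles all-censored data and duplication invariance", {
  km <- km_estimate(c(3, 7, 9), c(0, 0, 0))
  expect_equal(nrow(km), 0L)          # survival stays at 1 throughout

  s <- toy_surv(7, n = 25)
  km1 <- km_estimate(s$time, s$event)
  km2 <- km_estimate(rep(s$time, 2), rep(s$event, 2))
  expect_equal(km1$survival, km2$survival, tolerance = 1e-12)
})

test_that("KM with no censoring equals one minus the empirical CDF", {
  set.seed(5)
  t <- rexp(60)
  km <- km_estimate(t, rep(1, 60))
  expect_equal(km$survival, 1 - ecdf(t)(km$time), tolerance = 1e-12)
})

test_that("logrank statistic agrees with survdiff and the naive loop oracle", {
  for (seed in c(1, 2, 3)) {
    s <- toy_surv(seed)
    lt <- logrank_test(s$time, s$event, s$group)
    sd <- survival::survdiff(survival::Surv(s$time, s$event) ~ s$group)
    expect_equal(lt$statistic, sd$chisq, tolerance = 1e-10)
    expect_equal(lt$statistic,
                 oracle_logrank_stat(s$time, s$event, s$group == "B"),
                 tolerance = 1e-10)
  }
})

test_that("logrank degenerate and directional behaviour", {
  # identical groups: duplicated data, statistic 0, p 1
  t <- c(1, 3, 5, 8); e <- c(1, 0, 1, 1)
  lt <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 4))
  expect_equal(lt$statistic, 0)
  expect_equal(lt$p_two_sided, 1)

  # group A all events before any B event: one-sided (adverse A) < two-sided
  time <- c(1, 2, 3, 10, 11, 12); ev <- rep(1, 6)
  grp <- rep(c("A", "B"), each = 3)
  lt2 <- logrank_test(time, ev, grp, adverse = "A")
  expect_lt(lt2$p_one_sided, lt2$p_two_sided)
  expect_equal(lt2$p_one_sided, lt2$p_two_sided / 2)
  # and the anti-directional one-sided p is the complement
  lt3 <- logrank_test(time, ev, grp, adverse = "B")
  expect_equal(lt3$p_one_sided, 1 - lt2$p_two_sided / 2)

  expect_error(logrank_test(time, rep(0, 6), grp), "no events")
  expect_error(logrank_test(time, ev, rep("A", 6)), "two non-empty groups")
})

test_that("exact permutation p-value matches an independent sampling oracle", {
  time  <- c(2, 5, 7, 9, 12, 16, 3, 6, 10, 15, 21, 30)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1, 0, 1)
  grp <- rep(c("A", "B"), each = 6)
  lt <- logrank_test(time, event, grp, method = "permutation")
  set.seed(42)
  B <- 20000
  obs <- logrank_test(time, event, grp)$statistic
  in_b <- grp == "B"
  hits <- 0
  for (i in seq_len(B))
    if (oracle_logrank_stat(time, event, sample(in_b)) >= obs - 1e-12)
      hits <- hits + 1
  p_mc <- hits / B
  expect_lt(abs(lt$p_two_sided - p_mc),
            3 * sqrt(p_mc * (1 - p_mc) / B) + 1e-12)
})

test_that("univariate hazard ratio: identity, symmetry, separation handling", {
  t <- c(1, 3, 5, 8); e <- c(1, 0, 1, 1)
  fit <- univariate_hr(c(t, t), c(e, e), rep(c("A", "B"), each = 4))
  expect_equal(fit$hr, 1, tolerance = 1e-6)

  s <- toy_surv(11)
  f1 <- univariate_hr(s$time, s$event, s$group)
  f2 <- univariate_hr(s$time, s$event, ifelse(s$group == "A", "B", "A"))
  expect_equal(f1$hr, 1 / f2$hr, tolerance = 1e-9)
  expect_true(f1$ci_lower < f1$hr && f1$hr < f1$ci_upper)

  # one group entirely event-free -> monotone likelihood, flagged not crashed
  fit3 <- univariate_hr(c(1, 2, 3, 10, 12, 14), c(1, 1, 1, 0, 0, 0),
                        rep(c("A", "B"), each = 3))
  expect_false(attr(fit3, "estimable"))
  expect_true(is.na(fit3$hr))
  expect_match(attr(fit3, "diagnostic"), "no events")
})

test_that("Cox coefficients match an independent Breslow partial-likelihood maximizer", {
  # 8-case toy, single binary covariate
  time <- c(2, 4, 5, 7, 9, 11, 14, 20)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 1, 1, 0, 1, 0, 0, 0)
  fit <- univariate_hr(time, event, ifelse(x == 1, "B", "A"))
  orc <- oracle_cox_fit(matrix(x, ncol = 1), time, event)
  expect_equal(fit$coef, orc$beta, tolerance = 1e-6)

  # multivariate with ties
  set.seed(31)
  n <- 60
  X <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n))
  tt <- ceiling(rexp(n, exp(0.02 * (0.8 * X[, 1] - 0.5 * X[, 2])) * 0.05))
  ev <- rbinom(n, 1, 0.8)
  fit2 <- cox_ph(as.data.frame(X), tt, ev)
  orc2 <- oracle_cox_fit(X, tt, ev)
  expect_equal(fit2$coef, unname(orc2$beta), tolerance = 1e-6)
})

test_that("cox_ph reduces to univariate_hr and rejects singular designs", {
  s <- toy_surv(13)
  f1 <- univariate_hr(s$time, s$event, s$group)
  f2 <- cox_ph(data.frame(g = as.integer(s$group == "B")), s$time, s$event)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-9)
  expect_equal(f1$hr, f2$hr, tolerance = 1e-9)

  expect_error(cox_ph(data.frame(g = as.integer(s$group == "B"), z = 0),
                      s$time, s$event), "z")
  expect_error(cox_ph(data.frame(a = rnorm(40), b = NA_real_),
                      rexp(40) + 0.1, rbinom(40, 1, .5)), "missing")
})

test_that("cox_ph returns a local maximum of the Breslow partial likelihood", {
  s <- toy_surv(17, n = 50)
  X <- cbind(g = as.integer(s$group == "B"), z = rnorm(50))
  fit <- cox_ph(as.data.frame(X), s$time, s$event)
  ll_hat <- oracle_cox_loglik(fit$coef, X, s$time, s$event)
  set.seed(99)
  for (i in 1:100) {
    ll_pert <- oracle_cox_loglik(fit$coef + rnorm(2, 0, 0.05), X, s$time, s$event)
    expect_lte(ll_pert, ll_hat + 1e-9)
  }
})

test_that("Cox confidence intervals cover simulated true coefficients", {
  # parameter recovery: each true coefficient inside its 95% CI in >= 90%
  # of replicates
  n <- 300; beta <- c(g = 0.7, z = -0.4)
  cover <- c(0, 0)
  reps <- 100
  for (r in seq_len(reps)) {
    set.seed(4000 + r)
    X <- cbind(g = rbinom(n, 1, 0.5), z = rnorm(n))
    tt <- rexp(n, 0.03 * exp(drop(X %*% beta)))
    cc <- pmin(rexp(n, 0.01), 120)
    time <- pmin(tt, cc); ev <- as.integer(tt <= cc)
    fit <- cox_ph(as.data.frame(X), time, ev)
    cover <- cover + (log(fit$ci_lower) <= beta & beta <= log(fit$ci_upper))
  }
  expect_gte(cover[1] / reps, 0.90)
  expect_gte(cover[2] / reps, 0.90)
})

test_that("Fisher exact matches printed clinical-table values and enumeration", {
  expect_equal(fisher_exact_2x2(c(0, 81, 10, 124))$p_two_sided, 0.0146,
               tolerance = 5e-4 / 0.0146)
  expect_equal(fisher_exact_2x2(c(85, 118, 0, 12))$p_two_sided, 0.0039,
               tolerance = 5e-4 / 0.0039)
  expect_equal(fisher_exact_2x2(c(77, 126, 2, 10))$p_two_sided, 0.218,
               tolerance = 5e-3 / 0.218)
  expect_equal(fisher_exact_2x2(c(10, 193, 0, 12))$p_two_sided, 1)
  expect_lt(fisher_exact_2x2(c(49, 32, 36, 98))$p_two_sided, 1e-4)
  expect_equal(fisher_exact_2x2(c(1, 1, 1, 1))$p_two_sided, 1)

  # enumeration oracle on random moderate tables
  set.seed(21)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_two_sided,
                 oracle_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("Fisher p is invariant under transposition and row/column swaps", {
  set.seed(33)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 5), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)$p_two_sided
    expect_equal(fisher_exact_2x2(t(tab))$p_two_sided, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, ])$p_two_sided, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[, 2:1])$p_two_sided, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p_two_sided, p, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "non-negative")
  expect_error(fisher_exact_2x2(c(1.5, 2, 3, 4)), "integer")
})
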