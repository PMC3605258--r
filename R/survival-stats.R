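#' @importFrom survival Surv survfit coxph survdiff
#' @importFrom stats pchisq qnorm quantile rnorm rbinom rexp runif rlnorm median sd setNames
NULL

.check_survival <- function(time, event, what = "survival data") {
  if (length(time) == 0L)
    stop("empty ", what, ": at least one observation is required", call. = FALSE)
  if (length(time) != length(event))
    stop("time and event vectors must have equal length", call. = FALSE)
  if (anyNA(time) || anyNA(event))
    stop("missing values in ", what, call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("follow-up times must be finite and strictly positive", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 (censored) or 1 (event)", call. = FALSE)
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function from right-censored follow-up data.
#' Censored observations leave the risk set without contributing an event.
#'
#' @param time Follow-up time in months, strictly positive.
#' @param event Event indicator, 1 = event observed, 0 = censored.
#' @return An object of class `km_curve`: a data frame with one row per
#'   distinct event time and columns `time`, `n_risk`, `n_event`,
#'   `survival` (the product-limit estimate just after that time).
#' @examples
#' km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
#' @export
km_estimate <- function(time, event) {
  .check_survival(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  curve <- data.frame(
    time     = fit$time[keep],
    n_risk   = fit$n.risk[keep],
    n_event  = fit$n.event[keep],
    survival = fit$surv[keep]
  )
  structure(curve,
            n = length(time), n_events = sum(event),
            class = c("km_curve", "data.frame"))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", attr(x, "n"), " subjects, ",
      attr(x, "n_events"), " events\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Write a Kaplan-Meier curve as TSV
#'
#' Columns `time`, `survival`, `at_risk`, `events`, suitable for plotting.
#'
#' @param curve A `km_curve`.
#' @param path Output file path.
#' @export
write_km_tsv <- function(curve, path) {
  out <- data.frame(time = curve$time, survival = curve$survival,
                    at_risk = curve$n_risk, events = curve$n_event)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Logrank O/E/V per distinct event time, hypergeometric variance at ties.
# Vectorized (tabulate + reverse cumsum) because cross-validated profiling
# calls this ~1e5 times.
.logrank_core <- function(time, event, in_b) {
  lev <- sort(unique(time))
  idx <- match(time, lev)
  K <- length(lev)
  d_all <- tabulate(idx[event == 1], nbins = K)
  d_b   <- tabulate(idx[event == 1 & in_b], nbins = K)
  c_all <- tabulate(idx, nbins = K)
  c_b   <- tabulate(idx[in_b], nbins = K)
  n_at  <- rev(cumsum(rev(c_all)))   # at risk just before each distinct time
  nb_at <- rev(cumsum(rev(c_b)))
  keep <- d_all > 0
  d <- d_all[keep]; db <- d_b[keep]; n <- n_at[keep]; nb <- nb_at[keep]
  e_b <- d * nb / n
  v <- ifelse(n > 1, d * (nb / n) * (1 - nb / n) * (n - d) / (n - 1), 0)
  list(o_b = sum(db), e_b = sum(e_b), v = sum(v), n_events = sum(d))
}

.logrank_stat <- function(time, event, in_b) {
  core <- .logrank_core(time, event, in_b)
  if (core$v <= 0) return(0)
  (core$o_b - core$e_b)^2 / core$v
}

#' Two-group logrank test
#'
#' Standard logrank test with hypergeometric variance at tied event times.
#' The two-sided p-value comes from the chi-square(1) reference
#' distribution. When `adverse` names one of the groups, a one-sided
#' p-value against the prespecified hypothesis "the adverse group does
#' worse" is also reported: half the two-sided p when the adverse group
#' has more observed than expected events, otherwise one minus that half.
#'
#' @param time,event Follow-up times and event indicators (pooled).
#' @param group A two-level factor/vector assigning each subject to a group.
#' @param adverse Optional label of the group hypothesised to have worse
#'   survival (enables the one-sided p-value).
#' @param method `"asymptotic"` (chi-square(1) reference, the default) or
#'   `"permutation"`: the conditional reference distribution obtained by
#'   permuting group labels — complete enumeration when the number of
#'   distinct assignments is at most `max_enumerate`, otherwise
#'   `n_perm` Monte-Carlo draws. Preferable for very small samples where
#'   the chi-square approximation is off by a few percent.
#' @param n_perm,max_enumerate Permutation-method controls.
#' @return An object of class `logrank_test` with elements `statistic`,
#'   `p_two_sided`, `p_one_sided` (NA when `adverse` is missing),
#'   `observed`, `expected` (per group), `n`, `n_events`, `method`.
#' @export
logrank_test <- function(time, event, group, adverse = NULL,
                         method = c("asymptotic", "permutation"),
                         n_perm = 10000L, max_enumerate = 20000L) {
  method <- match.arg(method)
  .check_survival(time, event)
  group <- as.factor(group)
  lev <- levels(droplevels(group))
  if (length(lev) != 2L)
    stop("logrank test requires exactly two non-empty groups", call. = FALSE)
  if (sum(event) == 0)
    stop("logrank test undefined: no events in either group", call. = FALSE)
  in_b <- group == lev[2L]
  core <- .logrank_core(time, event, in_b)
  stat <- if (core$v > 0) (core$o_b - core$e_b)^2 / core$v else 0
  observed <- c(core$n_events - core$o_b, core$o_b)
  expected <- c(core$n_events - core$e_b, core$e_b)
  names(observed) <- names(expected) <- lev
  if (method == "asymptotic") {
    p2 <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    p1 <- NA_real_
    if (!is.null(adverse)) {
      if (!adverse %in% lev)
        stop("adverse group '", adverse, "' is not a level of `group`", call. = FALSE)
      worse <- observed[adverse] > expected[adverse]
      p1 <- if (worse) p2 / 2 else 1 - p2 / 2
    }
  } else {
    perm <- .logrank_permutation(time, event, in_b, n_perm, max_enumerate)
    p2 <- perm$p_two_sided
    p1 <- NA_real_
    if (!is.null(adverse)) {
      if (!adverse %in% lev)
        stop("adverse group '", adverse, "' is not a level of `group`", call. = FALSE)
      p1 <- if (adverse == lev[2L]) perm$p_upper_b else perm$p_lower_b
    }
  }
  structure(list(statistic = stat, p_two_sided = p2, p_one_sided = unname(p1),
                 observed = observed, expected = expected,
                 n = length(time), n_events = core$n_events,
                 adverse = if (is.null(adverse)) NA_character_ else adverse,
                 method = method),
            class = "logrank_test")
}

# conditional permutation reference for the logrank test: enumerate all
# group assignments when feasible, otherwise Monte Carlo. Two-sided p is
# Pr(statistic >= observed); one-sided ps come from the signed score
# z = (O_b - E_b)/sqrt(V).
.logrank_permutation <- function(time, event, in_b, n_perm, max_enumerate) {
  n <- length(time)
  nb <- sum(in_b)
  obs_core <- .logrank_core(time, event, in_b)
  obs_stat <- if (obs_core$v > 0) (obs_core$o_b - obs_core$e_b)^2 / obs_core$v else 0
  obs_z <- if (obs_core$v > 0) (obs_core$o_b - obs_core$e_b) / sqrt(obs_core$v) else 0
  stat_z <- function(sel) {
    co <- .logrank_core(time, event, sel)
    if (co$v > 0) (co$o_b - co$e_b) / sqrt(co$v) else 0
  }
  if (choose(n, nb) <= max_enumerate) {
    combos <- utils::combn(n, nb)
    z <- apply(combos, 2L, function(ix) {
      sel <- logical(n); sel[ix] <- TRUE; stat_z(sel)
    })
  } else {
    z <- vapply(seq_len(n_perm), function(i) stat_z(sample(in_b)), numeric(1))
  }
  tol <- 1e-12
  list(p_two_sided = mean(z^2 >= obs_stat - tol),
       p_upper_b = mean(z >= obs_z - tol),
       p_lower_b = mean(z <= obs_z + tol))
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Logrank test: chi-square = ", signif(x$statistic, 4),
      ", two-sided p = ", signif(x$p_two_sided, 4), "\n", sep = "")
  if (!is.na(x$p_one_sided))
    cat("One-sided p (adverse = ", x$adverse, ") = ",
        signif(x$p_one_sided, 4), "\n", sep = "")
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = signif(x$expected, 4)), row.names = FALSE)
  invisible(x)
}

.cox_fit_frame <- function(fit, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  data.frame(
    term = names(beta),
    coef = unname(beta),
    se = se,
    hr = exp(unname(beta)),
    ci_lower = exp(unname(beta) - z * se),
    ci_upper = exp(unname(beta) + z * se),
    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
    stringsAsFactors = FALSE
  )
}

#' Univariate hazard ratio between two groups
#'
#' Fits a proportional-hazards model with a single binary group indicator
#' (Breslow tie handling) and reports the hazard ratio of the second group
#' relative to the first, with a Wald confidence interval.
#'
#' @inheritParams logrank_test
#' @param conf_level Confidence level for the Wald interval.
#' @return A `cox_fit` (see [cox_ph()]) with one row. If one group has no
#'   events and the fit diverges, the result carries `estimable = FALSE`
#'   and a diagnostic message instead of a crash.
#' @export
univariate_hr <- function(time, event, group, conf_level = 0.95) {
  .check_survival(time, event)
  group <- as.factor(group)
  lev <- levels(droplevels(group))
  if (length(lev) != 2L)
    stop("univariate_hr requires exactly two non-empty groups", call. = FALSE)
  x <- data.frame(group = as.integer(group == lev[2L]))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(survival::Surv(time, event) ~ group,
                                     data = x, ties = "breslow")),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(.non_estimable_cox(paste0(lev[2L], " vs ", lev[1L]), conditionMessage(fit)))
  out <- .cox_fit_frame(fit, conf_level)
  out$term <- paste0(lev[2L], " vs ", lev[1L])
  # divergence: a group without events drives |beta| off to +-Inf
  if (!all(is.finite(out$coef)) || abs(out$coef) > 15 || !all(is.finite(out$se)) ||
      out$se > 100) {
    return(.non_estimable_cox(out$term,
      "monotone likelihood (a group has no events); hazard ratio not estimable"))
  }
  structure(out, estimable = TRUE, class = c("cox_fit", "data.frame"))
}

.non_estimable_cox <- function(term, msg) {
  out <- data.frame(term = term, coef = NA_real_, se = NA_real_, hr = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  structure(out, estimable = FALSE, diagnostic = msg,
            class = c("cox_fit", "data.frame"))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Joint partial-likelihood fit with Breslow tie handling. Reports, per
#' covariate, the coefficient, hazard ratio, Wald 95% confidence interval
#' and Wald p-value.
#'
#' @param covariates A data frame of numeric covariates (no missing values).
#' @param time,event Follow-up times and event indicators aligned with the
#'   rows of `covariates`.
#' @param conf_level Confidence level for Wald intervals.
#' @return A `cox_fit`: a data frame with columns `term`, `coef`, `se`,
#'   `hr`, `ci_lower`, `ci_upper`, `p`.
#' @export
cox_ph <- function(covariates, time, event, conf_level = 0.95) {
  .check_survival(time, event)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(time))
    stop("covariate rows must align with survival data", call. = FALSE)
  if (anyNA(covariates))
    stop("missing covariate values are not allowed (complete cases only)", call. = FALSE)
  if (length(time) <= ncol(covariates))
    stop("need more observations than covariates", call. = FALSE)
  X <- as.matrix(covariates)
  if (!is.numeric(X))
    stop("all covariates must be numeric", call. = FALSE)
  qrX <- qr(scale(X, scale = FALSE))
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("singular information matrix; collinear or constant covariates: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  if (anyNA(stats::coef(fit)))
    stop("singular information matrix; collinear covariates: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  out <- .cox_fit_frame(fit, conf_level)
  out$term <- gsub("`", "", out$term)
  structure(out, estimable = TRUE, loglik = fit$loglik[2],
            class = c("cox_fit", "data.frame"))
}

#' @export
print.cox_fit <- function(x, ...) {
  if (isFALSE(attr(x, "estimable"))) {
    cat("Cox fit non-estimable: ", attr(x, "diagnostic"), "\n", sep = "")
    return(invisible(x))
  }
  show <- data.frame(term = x$term, p = signif(x$p, 4), HR = signif(x$hr, 4),
                     `95% CI` = sprintf("%.2f-%.2f", x$ci_lower, x$ci_upper),
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided p-value by the "sum of small p" convention: the sum of the
#' probabilities of all tables in the hypergeometric support whose
#' probability does not exceed that of the observed table (with a 1e-7
#' relative tolerance), computed stably in log-gamma space.
#'
#' @param x A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled row-wise.
#' @return A list of class `fisher_2x2` with `p_two_sided` and the table.
#' @examples
#' fisher_exact_2x2(matrix(c(0, 81, 10, 124), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(x) {
  if (is.vector(x) && length(x) == 4L) x <- matrix(x, 2, 2, byrow = TRUE)
  if (!is.matrix(x) || !all(dim(x) == c(2L, 2L)))
    stop("expected a 2x2 table", call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(x) == 0)
    stop("table total must be positive", call. = FALSE)
  p <- stats::fisher.test(x)$p.value
  structure(list(p_two_sided = min(p, 1), table = x), class = "fisher_2x2")
}

#' @export
print.fisher_2x2 <- function(x, ...) {
  cat("Fisher's exact test (two-sided): p = ", signif(x$p_two_sided, 4), "\n", sep = "")
  print(x$table)
  invisible(x)
}
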