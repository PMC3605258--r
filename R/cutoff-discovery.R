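# Cross-validated significance profiling over percentile cutoffs, peak
# selection with verification support, maximally selected logrank cutoff
# for skewed markers, and cutoff lockdown.

#' Configuration for cross-validated significance profiling
#'
#' @param percentiles Strictly increasing percentile grid within
#'   \[10, 90\] (default 10, 15, ..., 90 — 17 points).
#' @param n_reps Number of random-split repetitions (default 1000).
#' @param alpha Significance level for the test-half logrank (default 0.05;
#'   a repetition counts as significant when p < alpha, strict).
#' @param split_fraction Train share of each random split (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `profile_config`.
#' @export
profile_config <- function(percentiles = seq(10, 90, by = 5), n_reps = 1000,
                           alpha = 0.05, split_fraction = 0.5, seed = 1) {
  if (length(percentiles) < 1 || any(diff(percentiles) <= 0) ||
      min(percentiles) < 10 || max(percentiles) > 90)
    stop("percentile grid must be strictly increasing within [10, 90]", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(percentiles = percentiles, n_reps = n_reps, alpha = alpha,
                 split_fraction = split_fraction, seed = seed),
            class = "profile_config")
}

#' Cross-validated significance profile over percentile cutoffs
#'
#' For each of `n_reps` repetitions the cohort is randomly split into a
#' train and a test half. At every grid percentile the expression
#' threshold is computed on the train half, the test half is dichotomized
#' at that threshold, and a two-sided logrank test is run on the test
#' half. The profile records, per percentile, the fraction of repetitions
#' with p < alpha. Splits where a test-half group is empty or event-free
#' count as non-significant (they are never redrawn) and are tallied in
#' `n_valid`.
#'
#' The computation is invariant to sample ordering (samples are put into
#' a canonical order before splitting) and bit-reproducible for a fixed
#' seed.
#'
#' @param expr Per-sample gene scores (numeric vector).
#' @param time,event Aligned survival data (months, 0/1 indicator).
#' @param config A [profile_config()].
#' @return An object of class `significance_profile`: data frame with
#'   columns `percentile`, `fraction`, `n_valid`, plus attributes
#'   `n_reps`, `alpha`, `seed`, `n`.
#' @export
cv_significance_profile <- function(expr, time, event, config = profile_config()) {
  n <- length(expr)
  if (n < 20) stop("cohort too small for cross-validated profiling (n < 20)", call. = FALSE)
  if (length(time) != n || length(event) != n)
    stop("expression and survival data must be aligned", call. = FALSE)
  .check_survival(time, event)

  # canonical ordering makes the profile invariant to input permutations
  ord <- order(expr, time, event)
  expr <- expr[ord]; time <- time[ord]; event <- event[ord]

  grid <- config$percentiles
  n_train <- round(n * config$split_fraction)
  if (n_train < 2 || n - n_train < 2)
    stop("split leaves fewer than 2 cases in a half", call. = FALSE)
  n_sig <- integer(length(grid))
  n_valid <- integer(length(grid))
  set.seed(config$seed)
  for (rep in seq_len(config$n_reps)) {
    idx <- sample.int(n, n_train)
    thr <- stats::quantile(expr[idx], grid / 100, type = 7, names = FALSE)
    te <- expr[-idx]; tt <- time[-idx]; tv <- event[-idx]
    for (j in seq_along(grid)) {
      high <- te > thr[j]
      n_high <- sum(high)
      if (n_high == 0L || n_high == length(te)) next
      if (sum(tv[high]) == 0L || sum(tv[!high]) == 0L) next
      n_valid[j] <- n_valid[j] + 1L
      stat <- .logrank_stat(tt, tv, high)
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
      if (p < config$alpha) n_sig[j] <- n_sig[j] + 1L
    }
  }
  structure(data.frame(percentile = grid,
                       fraction = n_sig / config$n_reps,
                       n_valid = n_valid),
            n_reps = config$n_reps, alpha = config$alpha,
            seed = config$seed, n = n,
            class = c("significance_profile", "data.frame"))
}

#' @export
print.significance_profile <- function(x, ...) {
  cat("CV significance profile: ", attr(x, "n_reps"), " repetitions, alpha = ",
      attr(x, "alpha"), ", n = ", attr(x, "n"), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Local maxima of a significance profile
#'
#' An interior grid point is a peak when its fraction is strictly greater
#' than both neighbours; an endpoint qualifies when strictly greater than
#' its single neighbour. Ties produce no peak.
#'
#' @param profile A `significance_profile` (or data frame with
#'   `percentile` and `fraction`).
#' @return Numeric vector of peak percentiles (possibly empty).
#' @export
find_peaks <- function(profile) {
  f <- profile$fraction
  g <- profile$percentile
  k <- length(f)
  if (k == 1L) return(g)
  up <- c(f[1] > f[2], f[-c(1, k)] > f[-c(k - 1, k)] & f[-c(1, k)] > f[-c(1, 2)],
          f[k] > f[k - 1])
  g[up]
}

#' Percentile(s) maximizing a significance profile
#'
#' Returns the median of the grid percentiles attaining the maximum
#' fraction. Ties are common (fractions are multiples of 1/n_reps) and,
#' around a planted threshold, the maximizing set is an interval, so its
#' median is the natural point estimate.
#'
#' @inheritParams find_peaks
#' @return A single percentile.
#' @export
profile_argmax <- function(profile) {
  stats::median(profile$percentile[profile$fraction == max(profile$fraction)])
}

#' Select the training peak supported by the verification cohort
#'
#' Among the training profile's peaks, returns the one with the greatest
#' verification-profile fraction, provided that fraction reaches
#' `min_support`; ties go to the lower percentile. Returns `NULL` when no
#' peak qualifies.
#'
#' @param train,verify `significance_profile`s on the same percentile grid.
#' @param min_support Minimum verification fraction (default 0.20).
#' @return The chosen percentile, or `NULL`.
#' @export
select_supported_peak <- function(train, verify, min_support = 0.20) {
  if (!isTRUE(all.equal(train$percentile, verify$percentile)))
    stop("training and verification profiles must share the same grid", call. = FALSE)
  peaks <- find_peaks(train)
  if (length(peaks) == 0L) return(NULL)
  support <- verify$fraction[match(peaks, verify$percentile)]
  ok <- support >= min_support
  if (!any(ok)) return(NULL)
  peaks <- peaks[ok]; support <- support[ok]
  best <- support == max(support)
  min(peaks[best])
}

#' Maximally selected logrank cutoff
#'
#' Scans candidate thresholds — midpoints between consecutive distinct
#' sorted expression values that leave between `min_high` and floor(n/2)
#' cases in the high group — and returns the threshold maximizing the
#' two-group logrank statistic. Ties are broken toward the larger
#' threshold (smaller high group). Intended for extremely skewed markers
#' (the EVI1 situation) where percentile cross-validation has no power.
#'
#' @param expr Per-sample gene scores.
#' @param time,event Aligned survival data.
#' @param min_high Minimum size of the high group (>= 2).
#' @param gene Gene symbol recorded in the locked cutoff.
#' @param adverse_side Which side of the threshold is adverse
#'   (`"above"` for an overexpression marker).
#' @return A [locked_cutoff()] with method `"maximal-logrank"`, carrying
#'   the maximizing `statistic` and resulting `n_high`.
#' @export
maximal_logrank_cutoff <- function(expr, time, event, min_high = 2,
                                   gene = "gene", adverse_side = "above") {
  .check_survival(time, event)
  n <- length(expr)
  if (length(time) != n) stop("expression and survival data must be aligned", call. = FALSE)
  if (min_high < 2) stop("min_high must be at least 2", call. = FALSE)
  v <- sort(unique(expr))
  if (length(v) < 2) stop("no valid candidate threshold: all scores identical", call. = FALSE)
  mids <- (v[-length(v)] + v[-1]) / 2
  # high group at midpoint between v[i] and v[i+1]: all scores >= v[i+1]
  n_high <- vapply(mids, function(m) sum(expr > m), integer(1))
  ok <- n_high >= min_high & n_high <= floor(n / 2)
  if (!any(ok))
    stop("no candidate threshold leaves between min_high and n/2 high cases",
         call. = FALSE)
  mids <- mids[ok]; n_high <- n_high[ok]
  stats <- vapply(mids, function(m) .logrank_stat(time, event, expr > m), numeric(1))
  best <- which(stats == max(stats))
  pick <- best[which.max(mids[best])]   # ties -> larger threshold
  locked_cutoff(gene = gene, method = "maximal-logrank", threshold = mids[pick],
                adverse_side = adverse_side,
                statistic = stats[pick], n_high = n_high[pick])
}

#' A locked-down decision rule for one gene
#'
#' An immutable record of a discovered cutoff: the expression threshold,
#' how it was obtained (percentile cross-validation or maximal logrank),
#' which side is adverse, and provenance. Cases with score strictly above
#' the threshold classify as `"high"`.
#'
#' @param gene Gene symbol.
#' @param method `"percentile-cv"` or `"maximal-logrank"`.
#' @param threshold Expression threshold (finite).
#' @param percentile Originating percentile (percentile-cv only).
#' @param adverse_side `"above"` or `"below"`.
#' @param provenance Free-form provenance (cohort identifier, seed, ...).
#' @param statistic,n_high Maximal-logrank extras.
#' @return An object of class `locked_cutoff`.
#' @export
locked_cutoff <- function(gene, method = c("percentile-cv", "maximal-logrank"),
                          threshold, percentile = NULL,
                          adverse_side = c("above", "below"),
                          provenance = list(), statistic = NULL, n_high = NULL) {
  method <- match.arg(method)
  adverse_side <- match.arg(adverse_side)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  structure(list(gene = gene, method = method, threshold = threshold,
                 percentile = percentile, adverse_side = adverse_side,
                 provenance = provenance, statistic = statistic,
                 n_high = n_high),
            class = "locked_cutoff")
}

#' Lock a percentile cutoff as an expression threshold
#'
#' Translates a chosen percentile into its expression-level threshold on
#' the discovery cohort's scores and freezes it for external testing.
#'
#' @param expr Per-sample gene scores of the discovery cohort.
#' @param percentile Chosen percentile.
#' @param gene Gene symbol.
#' @param adverse_side Which side of the threshold is adverse.
#' @param provenance Free-form provenance list (cohort identifier, seed).
#' @return A [locked_cutoff()] with method `"percentile-cv"`.
#' @export
lock_cutoff <- function(expr, percentile, gene,
                        adverse_side = c("above", "below"), provenance = list()) {
  adverse_side <- match.arg(adverse_side)
  locked_cutoff(gene = gene, method = "percentile-cv",
                threshold = percentile_cutoff_value(expr, percentile),
                percentile = percentile, adverse_side = adverse_side,
                provenance = provenance)
}

#' @export
print.locked_cutoff <- function(x, ...) {
  cat("Locked cutoff for ", x$gene, ": threshold ", signif(x$threshold, 4),
      " (", x$method,
      if (!is.null(x$percentile)) paste0(", percentile ", x$percentile),
      "), adverse side: ", x$adverse_side, "\n", sep = "")
  invisible(x)
}

#' Serialize / load locked cutoffs and profiles
#'
#' Cutoffs round-trip through JSON with full double precision so that
#' reloading reproduces classification bit-exactly; profiles are written
#' as TSV (`percentile`, `fraction`, `n_valid`).
#'
#' @param cutoff A `locked_cutoff`.
#' @param path File path.
#' @export
write_cutoff <- function(cutoff, path) {
  jsonlite::write_json(unclass(cutoff), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_cutoff
#' @export
read_cutoff <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(obj$provenance) == 0) obj$provenance <- list()
  locked_cutoff(gene = obj$gene, method = obj$method, threshold = obj$threshold,
                percentile = obj$percentile, adverse_side = obj$adverse_side,
                provenance = obj$provenance, statistic = obj$statistic,
                n_high = obj$n_high)
}

#' @rdname write_cutoff
#' @param profile A `significance_profile`.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cutoff
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path)
  structure(df, class = c("significance_profile", "data.frame"))
}
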