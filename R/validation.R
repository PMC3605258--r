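# Application of locked cutoffs to an independent cohort: strict
# classification, one-sided logrank validation of OS/EFS, mutation
# enrichment tables, and multivariate Cox models.

#' Classify cases at a locked cutoff
#'
#' Strict rule: a case is `"high"` exactly when its score exceeds the
#' threshold; scores equal to the threshold classify as `"low"`.
#'
#' @param expr Per-sample scores for the cutoff's gene (numeric vector),
#'   or a gene x sample matrix containing that gene.
#' @param cutoff A [locked_cutoff()] (or a bare numeric threshold).
#' @return Factor with levels `c("low", "high")`, named like the input.
#' @export
classify_cases <- function(expr, cutoff) {
  threshold <- if (inherits(cutoff, "locked_cutoff")) cutoff$threshold else cutoff
  if (is.matrix(expr)) {
    if (!inherits(cutoff, "locked_cutoff") || !cutoff$gene %in% rownames(expr))
      stop("gene '", if (inherits(cutoff, "locked_cutoff")) cutoff$gene else "?",
           "' missing from expression matrix", call. = FALSE)
    expr <- expr[cutoff$gene, ]
  }
  factor(ifelse(expr > threshold, "high", "low"), levels = c("low", "high"))
}

.adverse_label <- function(adverse_side) if (adverse_side == "above") "high" else "low"

#' Validation pass rule
#'
#' A cutoff passes external validation when the one-sided logrank p-value
#' in the prespecified adverse direction is at most 0.05 (inclusive).
#'
#' @param p_one_sided One-sided logrank p-value.
#' @return Logical pass flag (`FALSE` for missing p).
#' @export
validation_pass <- function(p_one_sided) {
  !is.na(p_one_sided) & p_one_sided <= 0.05
}

#' Validate a locked cutoff on an independent cohort
#'
#' One-sided logrank test in the prespecified adverse direction,
#' univariate hazard ratio of the high versus low stratum with its Wald
#' 95% CI, Kaplan-Meier curves of both strata, and the pass flag
#' (p <= 0.05 on the one-sided test). An empty stratum yields a
#' non-estimable report with `pass = FALSE` and a diagnostic.
#'
#' @param labels Factor of `"low"`/`"high"` labels from [classify_cases()].
#' @param time,event Survival endpoint (OS or EFS) aligned with `labels`.
#' @param adverse_side Which side of the cutoff is adverse (`"above"` or
#'   `"below"`), normally taken from the locked cutoff.
#' @param gene,endpoint Labels recorded in the report.
#' @return An object of class `validation_report`.
#' @export
validate_os <- function(labels, time, event, adverse_side = "above",
                        gene = NA_character_, endpoint = "OS") {
  labels <- factor(labels, levels = c("low", "high"))
  n_low <- sum(labels == "low"); n_high <- sum(labels == "high")
  base <- list(gene = gene, endpoint = endpoint,
               n_low = n_low, n_high = n_high,
               adverse = .adverse_label(adverse_side))
  if (n_low == 0L || n_high == 0L) {
    return(structure(c(base, list(
      hr = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
      p_one_sided = NA_real_, p_two_sided = NA_real_, pass = FALSE,
      estimable = FALSE,
      diagnostic = "a stratum is empty; test not estimable",
      km = NULL)), class = "validation_report"))
  }
  lr <- logrank_test(time, event, labels, adverse = base$adverse)
  hr <- univariate_hr(time, event, labels)  # high vs low
  km <- list(low = km_estimate(time[labels == "low"], event[labels == "low"]),
             high = km_estimate(time[labels == "high"], event[labels == "high"]))
  structure(c(base, list(
    hr = hr$hr, ci_lower = hr$ci_lower, ci_upper = hr$ci_upper,
    p_one_sided = lr$p_one_sided, p_two_sided = lr$p_two_sided,
    pass = validation_pass(lr$p_one_sided), estimable = isTRUE(attr(hr, "estimable")),
    diagnostic = attr(hr, "diagnostic"), km = km)),
    class = "validation_report")
}

#' @rdname validate_os
#' @export
validate_efs <- function(labels, time, event, adverse_side = "above",
                         gene = NA_character_) {
  validate_os(labels, time, event, adverse_side, gene = gene, endpoint = "EFS")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation (", x$endpoint, ") for ", x$gene, ": n_low = ", x$n_low,
      ", n_high = ", x$n_high, "\n", sep = "")
  if (!is.null(x$diagnostic)) cat("  note: ", x$diagnostic, "\n", sep = "")
  cat("  HR (high vs low) = ", signif(x$hr, 3),
      " [", signif(x$ci_lower, 3), "-", signif(x$ci_upper, 3), "]",
      ", one-sided logrank p = ", signif(x$p_one_sided, 4),
      " -> ", if (isTRUE(x$pass)) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' Mutation enrichment between expression strata
#'
#' Builds, per mutation, the 2x2 table of stratum by mutant status and
#' tests it with Fisher's exact test (two-sided).
#'
#' @param labels Factor of `"low"`/`"high"` stratum labels.
#' @param mutations Data frame of 0/1 mutation indicators aligned with
#'   `labels`.
#' @return Data frame with one row per mutation: `mutation`, `n_total`,
#'   `n_low_mut`, `n_low`, `n_high_mut`, `n_high`, `p_fisher`.
#' @export
mutation_enrichment <- function(labels, mutations) {
  labels <- factor(labels, levels = c("low", "high"))
  mutations <- as.data.frame(mutations)
  if (nrow(mutations) != length(labels))
    stop("mutation table must align with stratum labels", call. = FALSE)
  rows <- lapply(names(mutations), function(nm) {
    m <- mutations[[nm]]
    if (anyNA(m) || !all(m %in% c(0, 1)))
      stop("mutation column '", nm, "' is not a 0/1 indicator", call. = FALSE)
    a <- sum(m[labels == "low"]); nl <- sum(labels == "low")
    b <- sum(m[labels == "high"]); nh <- sum(labels == "high")
    tab <- matrix(c(a, nl - a, b, nh - b), 2, 2, byrow = TRUE)
    data.frame(mutation = nm, n_total = a + b,
               n_low_mut = a, n_low = nl, n_high_mut = b, n_high = nh,
               p_fisher = fisher_exact_2x2(tab)$p_two_sided,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multivariate Cox model of overall survival
#'
#' Joint proportional-hazards fit of the marker label(s) and clinical
#' covariates, optionally after excluding cases (e.g. refitting in all
#' low-EVI1 cases after removing the EVI1-high stratum).
#'
#' @param covariates Data frame of numeric covariates (marker indicators
#'   coded 0/1, continuous covariates untransformed).
#' @param time,event Survival data aligned with `covariates`.
#' @param exclude Optional logical vector (or predicate function of the
#'   covariate data frame) marking cases to drop before fitting.
#' @return A `cox_fit` (see [cox_ph()]); attribute `n_fit` records the
#'   number of cases actually fitted.
#' @export
multivariate_os <- function(covariates, time, event, exclude = NULL) {
  covariates <- as.data.frame(covariates)
  keep <- rep(TRUE, nrow(covariates))
  if (!is.null(exclude)) {
    drop <- if (is.function(exclude)) exclude(covariates) else exclude
    if (!is.logical(drop) || length(drop) != nrow(covariates))
      stop("`exclude` must give one logical per case", call. = FALSE)
    keep <- !drop
  }
  if (sum(keep) <= ncol(covariates))
    stop("too few cases left after exclusion", call. = FALSE)
  fit <- cox_ph(covariates[keep, , drop = FALSE], time[keep], event[keep])
  attr(fit, "n_fit") <- sum(keep)
  fit
}
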