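# Probe-set -> standardized gene score chain:
#   chip scaling (trimmed-mean) -> geometric mean centering (log2)
#   -> per-probe-set mean/variance normalization -> per-gene averaging.

#' Probe-set map for the four AML marker genes
#'
#' The fixed assignment of array probe sets to marker genes: BAALC and ERG
#' and EVI1 are each the average of two probe sets after mean-variance
#' normalization; MN1 is the value of its single probe set.
#'
#' @return Named list mapping gene symbol to probe-set identifiers.
#' @export
aml_probesets <- function() {
  list(
    BAALC = c("218899_s_at", "222780_s_at"),
    ERG   = c("241926_s_at", "213541_s_at"),
    EVI1  = c("221884_at", "226420_at"),
    MN1   = "205330_at"
  )
}

.check_probeset_matrix <- function(m, positive = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expected a numeric probe-set x sample matrix", call. = FALSE)
  if (is.null(rownames(m)))
    stop("probe-set matrix must carry probe-set identifiers as rownames", call. = FALSE)
  if (anyNA(m))
    stop("probe-set matrix contains missing values", call. = FALSE)
  if (positive && any(m <= 0))
    stop("intensities must be strictly positive before log transformation", call. = FALSE)
  invisible(TRUE)
}

#' Chip normalization by trimmed-mean scaling
#'
#' Rescales every sample (column) so that its trimmed mean equals a common
#' target intensity, the scaling step of MAS5-style chip normalization.
#' Within-sample ordering is preserved exactly.
#'
#' @param m Probe-set x sample matrix of strictly positive intensities.
#' @param target Common target trimmed mean (default 500).
#' @param trim Fraction trimmed from each tail (default 0.02).
#' @return The rescaled matrix.
#' @export
normalize_chips <- function(m, target = 500, trim = 0.02) {
  .check_probeset_matrix(m, positive = TRUE)
  tm <- apply(m, 2L, mean, trim = trim)
  sweep(m, 2L, target / tm, "*")
}

#' Geometric mean centering per probe set
#'
#' Divides each probe-set row by its geometric mean across samples;
#' equivalently, returns log2 intensities minus the per-row mean of log2
#' intensities. Output is on the log2 scale.
#'
#' @param m Probe-set x sample matrix of strictly positive values.
#' @return Log2-scale matrix with each row's arithmetic mean equal to zero.
#' @export
geometric_mean_center <- function(m) {
  .check_probeset_matrix(m, positive = TRUE)
  lg <- log2(m)
  lg - rowMeans(lg)
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-probe-set mean-variance normalization
#'
#' Z-scores every probe-set row to mean 0 and (population) standard
#' deviation 1.
#'
#' @param m Probe-set x sample matrix (any scale).
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`
#'   (divide by n - 1).
#' @return Row-standardized matrix.
#' @export
mean_variance_normalize <- function(m, sd_type = c("population", "sample")) {
  .check_probeset_matrix(m)
  sd_type <- match.arg(sd_type)
  mu <- rowMeans(m)
  ctr <- m - mu
  s <- sqrt(rowMeans(ctr^2))
  if (sd_type == "sample") s <- s * sqrt(ncol(m) / (ncol(m) - 1))
  degenerate <- s < 1e-12
  if (any(degenerate))
    stop("degenerate probe set(s) with zero variance: ",
         paste(rownames(m)[degenerate], collapse = ", "), call. = FALSE)
  ctr / s
}

#' Per-gene standardized scores from normalized probe sets
#'
#' Averages, per gene, the normalized rows of its mapped probe sets;
#' genes mapped to a single probe set pass through unchanged.
#'
#' @param m Normalized probe-set x sample matrix.
#' @param map Named list gene -> probe-set identifiers, see [aml_probesets()].
#' @return Gene x sample matrix of standardized scores.
#' @export
gene_score <- function(m, map = aml_probesets()) {
  .check_probeset_matrix(m)
  missing <- setdiff(unlist(map), rownames(m))
  if (length(missing))
    stop("probe set(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- do.call(rbind, lapply(map, function(ids) colMeans(m[ids, , drop = FALSE])))
  rownames(out) <- names(map)
  colnames(out) <- colnames(m)
  out
}

#' Fit a reference standardization model
#'
#' Freezes the standardization chain on a reference cohort so that single
#' cases can later be scored against the same constants: the chip-scaling
#' target, the per-probe-set log2 centering constant (log2 of the
#' geometric mean), and the per-probe-set scale (population SD of the
#' centered log2 values).
#'
#' @param cohort Probe-set x sample matrix of raw positive intensities,
#'   at least 10 samples.
#' @param map Gene -> probe-set map used downstream.
#' @param target,trim Chip-normalization parameters, see [normalize_chips()].
#' @return An object of class `reference_model`.
#' @export
fit_reference <- function(cohort, map = aml_probesets(), target = 500, trim = 0.02) {
  .check_probeset_matrix(cohort, positive = TRUE)
  if (ncol(cohort) < 10L)
    stop("reference model requires at least 10 samples", call. = FALSE)
  norm <- normalize_chips(cohort, target = target, trim = trim)
  lg <- log2(norm)
  center <- rowMeans(lg)
  scale <- apply(lg - center, 1L, .pop_sd)
  if (any(scale < 1e-12))
    stop("degenerate probe set(s) with zero variance in reference: ",
         paste(rownames(cohort)[scale < 1e-12], collapse = ", "), call. = FALSE)
  structure(list(probeset_ids = rownames(cohort), center = unname(center),
                 scale = unname(scale), target = target, trim = trim,
                 map = map, n_reference = ncol(cohort)),
            class = "reference_model")
}

#' Score one or more cases against a frozen reference model
#'
#' Applies the reference cohort's standardization constants to new raw
#' intensity columns. A sample that was part of the reference cohort
#' reproduces its batch-standardized scores exactly.
#'
#' @param case Probe-set x sample matrix (one or more columns) of raw
#'   positive intensities, or a named vector for a single case.
#' @param ref A `reference_model` from [fit_reference()].
#' @return Gene x sample matrix of standardized scores.
#' @export
apply_reference <- function(case, ref) {
  if (!inherits(ref, "reference_model"))
    stop("`ref` must be a reference_model", call. = FALSE)
  if (is.vector(case) && !is.null(names(case)))
    case <- matrix(case, ncol = 1, dimnames = list(names(case), "case"))
  .check_probeset_matrix(case, positive = TRUE)
  if (!setequal(rownames(case), ref$probeset_ids) ||
      nrow(case) != length(ref$probeset_ids)) {
    unknown <- setdiff(rownames(case), ref$probeset_ids)
    absent <- setdiff(ref$probeset_ids, rownames(case))
    stop("probe-set mismatch with reference model",
         if (length(unknown)) paste0("; unknown: ", paste(unknown, collapse = ", ")),
         if (length(absent)) paste0("; absent: ", paste(absent, collapse = ", ")),
         call. = FALSE)
  }
  case <- case[ref$probeset_ids, , drop = FALSE]
  tm <- apply(case, 2L, mean, trim = ref$trim)
  scaled <- sweep(case, 2L, ref$target / tm, "*")
  z <- (log2(scaled) - ref$center) / ref$scale
  gene_score(z, ref$map)
}

#' Full batch standardization of a probe-set matrix
#'
#' Convenience wrapper running chip normalization, geometric mean
#' centering, mean-variance normalization and gene scoring in one call
#' (the within-cohort equivalent of [fit_reference()] + [apply_reference()]).
#'
#' @inheritParams fit_reference
#' @return Gene x sample matrix of standardized scores.
#' @export
standardize_cohort <- function(cohort, map = aml_probesets(), target = 500, trim = 0.02) {
  norm <- normalize_chips(cohort, target = target, trim = trim)
  gene_score(mean_variance_normalize(geometric_mean_center(norm)), map)
}

#' Expression value at a percentile of a score vector
#'
#' Translates a percentile cutoff into its expression-level threshold
#' using linear interpolation between closest ranks over the n - 1
#' inter-order-statistic intervals (quantile type 7).
#'
#' @param values Numeric vector of per-sample gene scores (>= 2 finite values).
#' @param p Percentile in \[0, 100\].
#' @return The interpolated expression threshold.
#' @examples
#' percentile_cutoff_value(seq(10, 100, by = 10), 30) # 37
#' @export
percentile_cutoff_value <- function(values, p) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 100)
    stop("percentile must be a single value in [0, 100]", call. = FALSE)
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("need at least two finite values", call. = FALSE)
  unname(stats::quantile(values, p / 100, type = 7, names = FALSE))
}

# ---- file formats -----------------------------------------------------------

#' Read / write probe-set matrices as TSV
#'
#' Tab-delimited with a `probeset_id` first column and one column per sample.
#'
#' @param path File path.
#' @return `read_probeset_matrix`: a probe-set x sample numeric matrix.
#' @export
read_probeset_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "probeset_id")
    stop("expected a 'probeset_id' first column in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probeset_id
  m
}

#' @rdname read_probeset_matrix
#' @param m Matrix to write (rownames are identifiers).
#' @param id_column Name of the identifier column (`"probeset_id"` for
#'   probe-set matrices, `"gene"` for gene score tables).
#' @export
write_probeset_matrix <- function(m, path, id_column = "probeset_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample score table written by [write_probeset_matrix()]
#' with `id_column = "gene"`.
#'
#' @param path File path.
#' @return Gene x sample numeric matrix.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Serialize / load a reference model as JSON
#'
#' @param ref A `reference_model`.
#' @param path File path.
#' @export
write_reference <- function(ref, path) {
  jsonlite::write_json(unclass(ref), path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$map <- as.list(obj$map)
  structure(obj, class = "reference_model")
}
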