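#' Score coefficient tables
#'
#' A score-coefficient table maps analyte names to signed weights for the
#' linear score projection, together with the transform provenance (natural
#' log, the +1 rule for zero-containing analytes, per-cohort z-scaling).
#' A synthetic coefficient fixture for the 14-analyte mortality-score panel
#' ships at `system.file("extdata", "score_coefficients_synthetic.tsv",
#' package = "metabocontrast")`; it is *not* the published coefficient set.
#'
#' @param analytes character vector of unique analyte names.
#' @param weights finite numeric weights, one per analyte.
#' @return An object of class `score_coefficients`.
#' @export
score_coefficients <- function(analytes, weights) {
  if (anyDuplicated(analytes)) stop("analyte names must be unique")
  if (length(analytes) != length(weights))
    stop("need one weight per analyte")
  if (!all(is.finite(weights))) stop("weights must be finite")
  structure(list(analytes = as.character(analytes),
                 weights = as.numeric(weights),
                 transform_spec = list(log_base = "natural",
                                       add_one_rule = "per_zero_analyte",
                                       scaling_scope = "per_cohort")),
            class = "score_coefficients")
}

#' @param path TSV with columns `analyte` and `weight`.
#' @rdname score_coefficients
#' @export
read_score_coefficients <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("analyte", "weight") %in% names(df)))
    stop("coefficient table needs columns `analyte` and `weight`")
  score_coefficients(df$analyte, df$weight)
}

#' Log-transform analytes with the +1 rule for zero-containing analytes
#'
#' Applies the natural logarithm per analyte. Any analyte containing at
#' least one observed zero uses `log(x + 1)` for *all* of its values; purely
#' positive analytes use `log(x)`. Missing and below-LOD masks pass through
#' unchanged; a negative observed value is an error.
#'
#' @param matrix a [feature_matrix] of non-negative values.
#' @return A transformed [feature_matrix].
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  v <- matrix$values
  neg <- which(!is.na(v) & v < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop("negative value in analyte ", colnames(v)[neg[1L, 2L]],
         ", sample ", rownames(v)[neg[1L, 1L]])
  has_zero <- apply(v, 2L, function(x) any(!is.na(x) & x == 0))
  out <- v
  out[, has_zero] <- log1p(v[, has_zero, drop = FALSE])
  out[, !has_zero] <- log(v[, !has_zero, drop = FALSE])
  feature_matrix(out, matrix$below_lod, lod = matrix$lod,
                 platform = matrix$platform)
}

#' Z-scale each feature separately within each cohort
#'
#' Within every cohort, each feature's observed values are centred to mean 0
#' and scaled to sample SD 1 (n-1 denominator). Missing cells stay missing.
#' A feature that is constant (or has fewer than two observed values) within
#' a cohort is an error naming the feature and the cohort.
#'
#' @param matrix a [feature_matrix].
#' @param cohort_labels cohort label per sample, aligned with the rows.
#' @return A scaled [feature_matrix].
#' @export
zscale_per_cohort <- function(matrix, cohort_labels) {
  stopifnot(inherits(matrix, "feature_matrix"))
  v <- matrix$values
  if (length(cohort_labels) != nrow(v))
    stop("`cohort_labels` must have one label per sample")
  out <- v
  for (coh in unique(cohort_labels)) {
    rows <- which(cohort_labels == coh)
    for (j in seq_len(ncol(v))) {
      x <- v[rows, j]
      obs <- !is.na(x)
      if (sum(obs) < 2L || length(unique(x[obs])) < 2L)
        stop("feature ", colnames(v)[j], " is constant in cohort ", coh)
      m <- mean(x[obs]); s <- stats::sd(x[obs])
      out[rows, j] <- (x - m) / s
    }
  }
  feature_matrix(out, matrix$below_lod, lod = matrix$lod,
                 platform = matrix$platform)
}

#' Project the linear health score
#'
#' `raw_score(sample) = sum_j weight_j * value_j(sample)` over the
#' coefficient analytes. The matrix must already be log-transformed and
#' z-scaled; a missing value in a scored analyte is an error (no silent
#' imputation).
#'
#' @param matrix a prepared [feature_matrix].
#' @param coeffs a [score_coefficients].
#' @return A `score_vector`: data.frame with columns `sample_id`,
#'   `raw_score` and `age_residual_score` (`NA` until
#'   [residualize_on_age] is applied).
#' @export
project_score <- function(matrix, coeffs) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(coeffs, "score_coefficients"))
  miss_col <- setdiff(coeffs$analytes, colnames(matrix$values))
  if (length(miss_col) > 0L)
    stop("analyte column missing from matrix: ", miss_col[1L])
  sub <- matrix$values[, coeffs$analytes, drop = FALSE]
  nas <- which(is.na(sub), arr.ind = TRUE)
  if (nrow(nas) > 0L)
    stop("missing value in scored analyte ", colnames(sub)[nas[1L, 2L]],
         ", sample ", rownames(sub)[nas[1L, 1L]])
  raw <- drop(sub %*% coeffs$weights)
  structure(data.frame(sample_id = rownames(sub), raw_score = raw,
                       age_residual_score = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("score_vector", "data.frame"))
}

#' Remove the age-associated component of the score
#'
#' Ordinary least squares of the raw score on chronological age; the
#' age-independent score is the residual, which is mean-zero and
#' uncorrelated with age in the fitting population. Idempotent.
#'
#' @param scores a `score_vector` from [project_score] (or one already
#'   residualized; the fit is then re-run on the residual).
#' @param ages numeric ages in years, aligned with `scores` rows.
#' @return The `score_vector` with `age_residual_score` filled in.
#' @export
residualize_on_age <- function(scores, ages) {
  stopifnot(inherits(scores, "score_vector"))
  if (length(ages) != nrow(scores))
    stop("need one age per scored sample")
  if (nrow(scores) < 3L) stop("need at least 3 samples")
  if (stats::sd(ages) == 0) stop("age vector is constant")
  y <- if (all(is.na(scores$age_residual_score))) scores$raw_score
       else scores$age_residual_score
  fit <- stats::lm.fit(cbind(1, ages), y)
  scores$age_residual_score <- unname(fit$residuals)
  scores
}
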