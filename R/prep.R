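#' Differential detectability of left-censored features between groups
#'
#' For each feature, counts detected (observed) versus undetected
#' (below-LOD) samples separately in cases and controls, and tests the 2x2
#' table with a two-sided Fisher exact test; Benjamini-Hochberg adjustment
#' is applied across features.
#'
#' @param matrix a [feature_matrix] carrying a below-LOD mask.
#' @param design a [contrast_design] covering every sample in `matrix`.
#' @return data.frame with one row per feature: `feature`, `case_detected`,
#'   `case_undetected`, `control_detected`, `control_undetected`,
#'   `fisher_p`, `fdr`.
#' @export
detectability_table <- function(matrix, design) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(design, "contrast_design"))
  ids <- rownames(matrix$values)
  known <- c(design$case_ids, design$control_ids)
  if (!all(ids %in% known))
    stop("sample absent from design: ", setdiff(ids, known)[1L])
  und <- matrix$below_lod
  case_rows <- ids %in% design$case_ids
  ctrl_rows <- ids %in% design$control_ids
  cu <- colSums(und[case_rows, , drop = FALSE])
  ku <- colSums(und[ctrl_rows, , drop = FALSE])
  cd <- sum(case_rows) - cu
  kd <- sum(ctrl_rows) - ku
  p <- vapply(seq_along(cu), function(j)
    fisher_exact_2x2(matrix(c(cd[j], cu[j], kd[j], ku[j]), 2, byrow = TRUE)),
    numeric(1))
  data.frame(feature = colnames(und),
             case_detected = unname(cd), case_undetected = unname(cu),
             control_detected = unname(kd), control_undetected = unname(ku),
             fisher_p = p, fdr = bh_fdr(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the point-probability rule: the sum of
#' hypergeometric probabilities of every table with the observed margins
#' whose point probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(table != round(table))) stop("counts must be integers")
  if (sum(table) == 0L) return(1)
  stats::fisher.test(table)$p.value
}

prep_report <- function(excluded = NULL, outliers = NULL, imputed = NULL) {
  structure(list(excluded_features = excluded,
                 outlier_cells = outliers,
                 imputed_cells = imputed),
            class = "prep_report")
}

cells_df <- function(idx, v) {
  if (is.null(idx) || nrow(idx) == 0L)
    return(data.frame(sample_id = character(0), feature = character(0),
                      stringsAsFactors = FALSE))
  data.frame(sample_id = rownames(v)[idx[, 1L]],
             feature = colnames(v)[idx[, 2L]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exclude features undetected in too large a fraction of samples
#'
#' A feature is removed when its below-LOD fraction is *strictly greater*
#' than `max_undetected_frac` (a feature undetected in exactly 65% of the
#' samples is retained under the default).
#'
#' @param matrix a [feature_matrix] with a below-LOD mask.
#' @param max_undetected_frac threshold fraction (default 0.65).
#' @return list `(matrix, report)`: the filtered matrix and a `prep_report`
#'   whose `excluded_features` records each removed feature with its
#'   undetected fraction.
#' @export
filter_undetected <- function(matrix, max_undetected_frac = 0.65) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (max_undetected_frac < 0 || max_undetected_frac > 1)
    stop("`max_undetected_frac` must lie in [0, 1]")
  frac <- colMeans(matrix$below_lod)
  drop <- frac > max_undetected_frac
  rep <- prep_report(excluded = data.frame(
    feature = colnames(matrix$values)[drop],
    reason = rep("undetected_frac", sum(drop)),
    fraction = unname(frac[drop]),
    stringsAsFactors = FALSE))
  list(matrix = fm_subset(matrix,
                          features = colnames(matrix$values)[!drop]),
       report = rep)
}

#' Mask values far from their feature mean as missing
#'
#' Per feature, the mean and sample SD are computed in a single pass over
#' all observed values (outlier candidates included), and entries strictly
#' more than `k_sd` SDs from the mean are set missing. Features with fewer
#' than 3 observed values are skipped with a warning.
#'
#' @param matrix a [feature_matrix].
#' @param k_sd SD multiple (default 5).
#' @return list `(matrix, report)`; `report$outlier_cells` lists the masked
#'   (sample, feature) cells.
#' @export
mask_outliers <- function(matrix, k_sd = 5) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (k_sd <= 0) stop("`k_sd` must be positive")
  v <- matrix$values
  out <- v
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    obs <- !is.na(x)
    if (sum(obs) < 3L) {
      warning("feature ", colnames(v)[j], " has <3 observed values; ",
              "outlier masking skipped", call. = FALSE)
      next
    }
    m <- mean(x[obs]); s <- stats::sd(x[obs])
    out[obs & abs(x - m) > k_sd * s, j] <- NA_real_
  }
  idx <- which(is.na(out) & !is.na(v), arr.ind = TRUE)
  list(matrix = feature_matrix(out, matrix$below_lod, lod = matrix$lod,
                               platform = matrix$platform),
       report = prep_report(outliers = cells_df(idx, v)))
}

#' Exclude features with too many missing values
#'
#' A feature is removed when its missing fraction (unobserved, censored
#' cells not counted) is *strictly greater* than `max_missing_frac`; exactly
#' 5% missing is retained under the default.
#'
#' @param matrix a [feature_matrix].
#' @param max_missing_frac threshold fraction (default 0.05).
#' @param max_missing_count optional absolute-count alternative: when given,
#'   a feature is removed when its missing count strictly exceeds it (the
#'   fraction rule is then ignored).
#' @return list `(matrix, report)` as in [filter_undetected].
#' @export
filter_missing <- function(matrix, max_missing_frac = 0.05,
                           max_missing_count = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stop("`max_missing_frac` must lie in [0, 1]")
  miss <- fm_missing(matrix)
  frac <- colMeans(miss)
  drop <- if (is.null(max_missing_count)) frac > max_missing_frac
          else colSums(miss) > max_missing_count
  rep <- prep_report(excluded = data.frame(
    feature = colnames(matrix$values)[drop],
    reason = rep("missing_frac", sum(drop)),
    fraction = unname(frac[drop]),
    stringsAsFactors = FALSE))
  list(matrix = fm_subset(matrix,
                          features = colnames(matrix$values)[!drop]),
       report = rep)
}

#' Impute missing values by NIPALS principal components
#'
#' Fits `n_components` principal components by nonlinear iterative partial
#' least squares on the feature-mean-centred matrix, restricting every score
#' and loading update to observed cells, then replaces each unobserved cell
#' by its rank-`n_components` reconstruction plus the feature mean. Observed
#' entries are never altered. A component converges when the relative change
#' of its eigenvalue falls below `tol`; the surrounding EM refinement stops
#' when the observed-cell reconstruction error improves by less than `tol`
#' relatively. Hitting `max_iter` first raises a warning, not an error.
#'
#' @param matrix a [feature_matrix]; every feature needs at least one
#'   observed value.
#' @param n_components components to extract; must be smaller than
#'   `min(n_samples, n_features)` (default 5).
#' @param tol relative eigenvalue tolerance (default 1e-6).
#' @param max_iter iteration cap per component (default 500).
#' @return list `(matrix, report)`; `report$imputed_cells` lists the filled
#'   cells.
#' @export
nipals_impute <- function(matrix, n_components = 5, tol = 1e-6,
                          max_iter = 500) {
  stopifnot(inherits(matrix, "feature_matrix"))
  v <- matrix$values
  n <- nrow(v); p <- ncol(v)
  if (n_components >= min(n, p))
    stop("`n_components` must be smaller than min(n_samples, n_features)")
  obs <- !is.na(v)
  if (any(colSums(obs) == 0L))
    stop("all-missing feature: ",
         colnames(v)[which(colSums(obs) == 0L)[1L]])
  if (all(obs))
    return(list(matrix = matrix, report = prep_report(
      imputed = cells_df(NULL, v))))

  # EM-style completion: fill unobserved cells with feature means, then
  # alternate (i) NIPALS components of the completed matrix and (ii)
  # re-imputation from the rank-k reconstruction, to a fixed point. At the
  # fixed point the completed matrix is self-consistent with its own
  # principal subspace (the alternating-least-squares solution), which makes
  # exactly-low-rank matrices recoverable to numerical precision.
  mu0 <- colMeans(v, na.rm = TRUE)
  filled <- v
  filled[!obs] <- matrix(mu0, n, p, byrow = TRUE)[!obs]
  converged <- FALSE
  sse_old <- Inf
  for (outer in seq_len(max_iter)) {
    mu <- colMeans(filled)
    E <- sweep(filled, 2L, mu)
    recon <- matrix(0, n, p)
    for (h in seq_len(n_components)) {
      t_vec <- E[, which.max(colSums(E^2))]
      if (all(t_vec == 0)) break
      ev_old <- 0
      for (it in seq_len(max_iter)) {
        p_vec <- as.vector(crossprod(E, t_vec)) / sum(t_vec^2)
        p_vec <- p_vec / sqrt(sum(p_vec^2))
        t_vec <- as.vector(E %*% p_vec)
        ev <- sum(t_vec^2)
        if (abs(ev - ev_old) <= tol * max(ev, 1e-300)) break
        ev_old <- ev
      }
      recon <- recon + tcrossprod(t_vec, p_vec)
      E <- E - tcrossprod(t_vec, p_vec)
    }
    filled[!obs] <- sweep(recon, 2L, mu, "+")[!obs]
    # EM monotonically improves the observed-cell reconstruction error;
    # stop once its relative improvement falls below tol (near-degenerate
    # trailing eigenvalues make the fill itself rotate forever, so the
    # objective, not the fill, is the quantity to monitor)
    sse <- sum((sweep(v, 2L, mu) - recon)[obs]^2)
    if (is.finite(sse_old) && sse_old - sse <= tol * max(sse_old, 1e-300)) {
      converged <- TRUE
      break
    }
    sse_old <- sse
  }
  if (!converged)
    warning("NIPALS imputation did not converge in ", max_iter,
            " iterations", call. = FALSE)
  idx <- which(!obs, arr.ind = TRUE)
  # imputation clears both masks: the cells now hold values
  below <- matrix$below_lod; below[!obs] <- FALSE
  list(matrix = feature_matrix(filled, below, lod = matrix$lod,
                               platform = matrix$platform),
       report = prep_report(imputed = cells_df(idx, v)))
}

#' Final log + per-cohort z transform of a prepared panel
#'
#' Delegates to [log_transform] then [zscale_per_cohort]; the contracts of
#' those two operations apply unchanged.
#'
#' @inheritParams zscale_per_cohort
#' @return A transformed [feature_matrix].
#' @export
prep_transform <- function(matrix, cohort_labels) {
  zscale_per_cohort(log_transform(matrix), cohort_labels)
}

#' Standard preprocessing chains for cytokine and proteomics panels
#'
#' `prep_cytokines()`: detectability table, undetected-fraction filter,
#' outlier masking, log + per-cohort z. `prep_proteomics()`: missingness
#' filter, outlier masking, NIPALS imputation, log + per-cohort z.
#'
#' @param matrix the platform [feature_matrix] restricted to the analyzed
#'   samples.
#' @param design the [contrast_design] (cytokines; used for the
#'   detectability table).
#' @param cohort_labels per-sample cohort labels for the z-scaling step.
#' @param max_undetected_frac,k_sd,max_missing_frac,n_components thresholds,
#'   see the individual operations.
#' @return list with the transformed `matrix`, the `detectability` table
#'   (cytokines only) and the per-step reports.
#' @export
prep_cytokines <- function(matrix, design, cohort_labels,
                           max_undetected_frac = 0.65, k_sd = 5) {
  det <- detectability_table(matrix, design)
  f1 <- filter_undetected(matrix, max_undetected_frac)
  f2 <- mask_outliers(f1$matrix, k_sd)
  out <- prep_transform(f2$matrix, cohort_labels)
  list(matrix = out, detectability = det,
       reports = list(undetected = f1$report, outliers = f2$report))
}

#' @param nipals_tol convergence tolerance handed to [nipals_impute]
#'   (default 1e-4 here: imputed-cell precision far below measurement noise
#'   is enough for downstream scans and keeps the EM iteration short).
#' @rdname prep_cytokines
#' @export
prep_proteomics <- function(matrix, cohort_labels, max_missing_frac = 0.05,
                            k_sd = 5, n_components = 5, nipals_tol = 1e-4) {
  f1 <- filter_missing(matrix, max_missing_frac)
  f2 <- mask_outliers(f1$matrix, k_sd)
  f3 <- nipals_impute(f2$matrix, n_components = n_components,
                      tol = nipals_tol)
  # intensities are positive; a low-rank reconstruction can stray below
  # zero, so imputed cells are floored at half the feature's smallest
  # observed intensity before the log transform
  fm <- f3$matrix
  if (nrow(f3$report$imputed_cells) > 0L) {
    was_obs <- !is.na(f2$matrix$values)
    for (j in seq_len(ncol(fm$values))) {
      xo <- f2$matrix$values[was_obs[, j], j]
      floor_j <- min(xo[xo > 0]) / 2
      bad <- !was_obs[, j] & fm$values[, j] <= 0
      fm$values[bad, j] <- floor_j
    }
  }
  out <- prep_transform(fm, cohort_labels)
  list(matrix = out,
       reports = list(missing = f1$report, outliers = f2$report,
                      imputed = f3$report))
}
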