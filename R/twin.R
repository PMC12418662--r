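#' Twin-pair correlations of a score by zygosity
#'
#' Pearson correlation over double-entered complete pairs: each pair
#' contributes both member orderings, which makes the estimate symmetric to
#' within-pair labelling (an intraclass-style estimator). The 95% confidence
#' interval uses the Fisher z transform with effective n equal to the number
#' of *pairs* (not twice that), which avoids the anticonservatism of
#' double entry.
#'
#' @param scores a `score_vector` (`value` picks the column, default the raw
#'   score; set `value = "age_residual_score"` to pre-residualize), or any
#'   named numeric vector of per-sample trait values.
#' @param covars sample table with `sample_id`, `family_id`, `zygosity`.
#' @param value score column used when `scores` is a `score_vector`.
#' @return list of class `twin_correlations`: `r_mz`, `r_dz`, `ci_mz`,
#'   `ci_dz`, `n_mz_pairs`, `n_dz_pairs`.
#' @export
twin_correlations <- function(scores, covars, value = "raw_score") {
  s <- if (inherits(scores, "score_vector"))
    stats::setNames(scores[[value]], scores$sample_id)
  else if (is.numeric(scores) && !is.null(names(scores))) scores
  else stop("`scores` must be a score_vector or a named numeric vector")
  one_zyg <- function(zyg) {
    sub <- covars[!is.na(covars$zygosity) & covars$zygosity == zyg, ,
                  drop = FALSE]
    fams <- split(sub$sample_id, sub$family_id)
    pairs <- Filter(function(m) length(m) == 2L &&
                      all(m %in% names(s)) && !anyNA(s[m]), fams)
    if (length(pairs) < 3L)
      stop("fewer than 3 complete ", zyg, " pairs")
    m1 <- vapply(pairs, function(m) s[[sort(m)[1L]]], 1)
    m2 <- vapply(pairs, function(m) s[[sort(m)[2L]]], 1)
    r <- stats::cor(c(m1, m2), c(m2, m1))   # double entry
    npair <- length(pairs)
    z <- atanh(r)
    half <- stats::qnorm(0.975) / sqrt(npair - 3)
    list(r = r, ci = tanh(c(z - half, z + half)), n = npair)
  }
  mz <- one_zyg("MZ"); dz <- one_zyg("DZ")
  structure(list(r_mz = mz$r, r_dz = dz$r, ci_mz = mz$ci, ci_dz = dz$ci,
                 n_mz_pairs = mz$n, n_dz_pairs = dz$n),
            class = "twin_correlations")
}

#' @export
print.twin_correlations <- function(x, ...) {
  cat(sprintf("rMZ = %.3f (95%% CI %.3f-%.3f, %d pairs)\n",
              x$r_mz, x$ci_mz[1], x$ci_mz[2], x$n_mz_pairs))
  cat(sprintf("rDZ = %.3f (95%% CI %.3f-%.3f, %d pairs)\n",
              x$r_dz, x$ci_dz[1], x$ci_dz[2], x$n_dz_pairs))
  cat(sprintf("Falconer h2 = %.3f\n", falconer_h2(x$r_mz, x$r_dz)))
  invisible(x)
}

#' Falconer moment estimator of narrow-sense heritability
#'
#' `h2 = 2 * (r_mz - r_dz)`. Sampling error can push the estimate outside
#' `[0, 1]`; that raises a warning, not an error.
#'
#' @param r_mz,r_dz twin correlations in `[-1, 1]`.
#' @return The heritability estimate, exactly `2 * (r_mz - r_dz)`.
#' @export
falconer_h2 <- function(r_mz, r_dz) {
  if (!is.finite(r_mz) || !is.finite(r_dz))
    stop("twin correlations must be finite")
  if (abs(r_mz) > 1 || abs(r_dz) > 1)
    stop("twin correlations must lie in [-1, 1]")
  h2 <- 2 * (r_mz - r_dz)
  if (h2 < 0 || h2 > 1)
    warning("Falconer estimate ", signif(h2, 3),
            " outside [0, 1] (sampling error)", call. = FALSE)
  h2
}

#' Twin correlations, CIs and Falconer heritability in one object
#'
#' @inheritParams twin_correlations
#' @return list of class `heritability_result` with the fields of
#'   [twin_correlations] plus `h2 = 2 * (r_mz - r_dz)`.
#' @export
estimate_heritability <- function(scores, covars, value = "raw_score") {
  tc <- twin_correlations(scores, covars, value = value)
  structure(c(unclass(tc), list(h2 = falconer_h2(tc$r_mz, tc$r_dz))),
            class = "heritability_result")
}

#' Within-pair linear mixed model (random pair intercept) fitted by REML
#'
#' Fits `y = X beta + b_pair + eps`, `b ~ N(0, sigma_b^2)`,
#' `eps ~ N(0, sigma_e^2)` on complete pairs. Each pair is rotated into its
#' sum and difference contrasts, which diagonalizes the covariance; the
#' restricted likelihood is profiled over the variance ratio
#' `lambda = sigma_b^2 / sigma_e^2` (floored at 0) and maximized by bounded
#' scalar optimization. The reported estimate is the exposure (`status`)
#' coefficient with its Wald standard error; the two-sided p uses a t
#' reference with conservative pair-count degrees of freedom
#' `n_pairs - rank(between-pair design) - 1`.
#'
#' @param y numeric response.
#' @param status exposure (0/1 within-pair case status, or continuous).
#' @param pair_ids pair/family identifier per observation; every pair must
#'   appear exactly twice with complete data.
#' @param covars optional covariate data.frame (columns as in
#'   [fit_linear_assoc]).
#' @param feature,covariate_set labels carried into the result.
#' @return One-row data.frame in the [fit_linear_assoc] schema, with extra
#'   columns `sigma_b2` and `sigma_e2`.
#' @export
fit_within_pair_lmm <- function(y, status, pair_ids, covars = NULL,
                                feature = "feature",
                                covariate_set = "unadjusted") {
  X <- cbind(`(Intercept)` = 1, status = as.numeric(status))
  if (!is.null(covars)) X <- add_covar_columns(X, as.data.frame(covars))
  ok <- stats::complete.cases(cbind(y, X)) & !is.na(pair_ids)
  tab <- table(pair_ids[ok])
  bad <- names(tab)[tab != 2L]
  bad <- union(bad, setdiff(unique(pair_ids), names(tab)))
  if (length(bad) > 0L)
    stop("incomplete pair(s): ", paste(sort(bad), collapse = ", "))
  ord <- order(as.character(pair_ids))
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  m <- length(y) / 2L
  i1 <- seq(1L, 2L * m, by = 2L); i2 <- i1 + 1L

  # sum/diff rotation: Var(sum row) = sigma_e^2 (1 + 2 lambda), Var(diff) = sigma_e^2
  ys <- (y[i1] + y[i2]) / sqrt(2); yd <- (y[i1] - y[i2]) / sqrt(2)
  Xs <- (X[i1, , drop = FALSE] + X[i2, , drop = FALSE]) / sqrt(2)
  Xd <- (X[i1, , drop = FALSE] - X[i2, , drop = FALSE]) / sqrt(2)
  yt <- c(ys, yd); Xt <- rbind(Xs, Xd)
  is_sum <- rep(c(TRUE, FALSE), each = m)
  n <- 2L * m; pcol <- ncol(Xt)
  if (n <= pcol + 1L) stop("too few pairs for the design")

  crit <- function(lambda) {
    w <- ifelse(is_sum, 1 / (1 + 2 * lambda), 1)
    sw <- sqrt(w)
    Xw <- Xt * sw; yw <- yt * sw
    qx <- qr(Xw)
    if (qx$rank < pcol) return(list(obj = Inf))
    beta <- qr.coef(qx, yw)
    rss <- sum((yw - drop(Xw %*% beta))^2)
    XtX <- crossprod(Xw)
    obj <- (n - pcol) * log(rss) + m * log(1 + 2 * lambda) +
      determinant(XtX, logarithm = TRUE)$modulus
    list(obj = as.numeric(obj), beta = beta, rss = rss, XtX = XtX)
  }
  f <- function(s) crit(exp(s))$obj
  opt <- stats::optimize(f, c(-25, 25), tol = 1e-10)
  cand <- c(0, exp(opt$minimum))
  objs <- vapply(cand, function(l) crit(l)$obj, 1)
  lambda <- cand[which.min(objs)]
  fit <- crit(lambda)
  if (!is.finite(fit$obj)) stop("rank-deficient within-pair design")
  sigma_e2 <- fit$rss / (n - pcol)
  if (sigma_e2 <= .Machine$double.eps * max(stats::var(yt), 1))
    stop("degenerate fit: residual variance is (numerically) zero")
  sigma_b2 <- lambda * sigma_e2
  covb <- sigma_e2 * chol2inv(chol(fit$XtX))
  dimnames(covb) <- list(colnames(Xt), colnames(Xt))
  est <- fit$beta[["status"]]
  se <- sqrt(covb["status", "status"])

  Xb <- (X[i1, , drop = FALSE] + X[i2, , drop = FALSE]) / 2
  df <- m - qr(Xb)$rank - 1L
  if (df < 1L) stop("non-positive degrees of freedom (too few pairs)")
  tval <- est / se
  p <- max(2 * stats::pt(abs(tval), df, lower.tail = FALSE),
           .Machine$double.xmin)
  tcrit <- stats::qt(0.975, df)
  data.frame(feature = feature, estimate = est, se = se,
             ci_low = est - tcrit * se, ci_high = est + tcrit * se,
             p = p, fdr = NA_real_, n = n, covariate_set = covariate_set,
             sigma_b2 = sigma_b2, sigma_e2 = sigma_e2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Within-pair mixed-model scan over a feature panel
#'
#' Runs [fit_within_pair_lmm] per feature for a twin-mode design (status 1
#' for the higher-scoring co-twin) and applies Benjamini-Hochberg adjustment
#' per covariate set.
#'
#' @param matrix prepared [feature_matrix] over the paired samples.
#' @param design a twin-mode [contrast_design].
#' @param covars sample table (needs `sample_id`, `family_id` plus covariate
#'   columns).
#' @param covariate_sets named list of covariate column vectors.
#' @return data.frame of stacked results with `fdr` filled per set.
#' @export
run_twin_scan <- function(matrix, design, covars = NULL,
                          covariate_sets = list(unadjusted = character(0))) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(design, "contrast_design"))
  if (design$mode != "twin") stop("need a twin-mode design")
  pm <- design$pair_map
  ids <- c(pm$high_id, pm$low_id)
  status <- stats::setNames(rep(c(1, 0), each = nrow(pm)), ids)
  pair <- stats::setNames(rep(pm$pair_id, 2L), ids)
  V <- matrix$values[ids, , drop = FALSE]
  if (!is.null(covars)) {
    rownames(covars) <- covars$sample_id
    covars <- covars[ids, , drop = FALSE]
  }
  out <- list()
  for (set_name in names(covariate_sets)) {
    cols <- covariate_sets[[set_name]]
    cv <- if (length(cols) == 0L) NULL else covars[, cols, drop = FALSE]
    if (!is.null(cv)) {
      const <- vapply(cv, function(x) length(unique(x)) < 2L, TRUE)
      if (any(const)) {
        warning("covariate(s) constant over the selected pairs dropped: ",
                paste(names(cv)[const], collapse = ", "), call. = FALSE)
        cv <- cv[, !const, drop = FALSE]
        if (ncol(cv) == 0L) cv <- NULL
      }
    }
    res <- do.call(rbind, lapply(colnames(V), function(f)
      fit_within_pair_lmm(V[, f], status, pair, cv, feature = f,
                          covariate_set = set_name)))
    res$fdr <- bh_fdr(res$p)
    out[[set_name]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
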