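#' Covariate-adjusted linear association of one feature with case status
#'
#' Ordinary least squares of `y` on an intercept, the exposure (typically
#' the 0/1 case status; a continuous exposure is equally valid) and any
#' covariates. The reported estimate is the exposure coefficient, with its
#' standard error from the unbiased residual-variance estimator, a two-sided
#' t p-value on `n - p - 1` degrees of freedom (p = exposure + covariates)
#' and a 95% t confidence interval. Rows with a missing value in `y`, the
#' exposure or a covariate are dropped (complete-case); the n actually used
#' is reported.
#'
#' @param y numeric response (one feature).
#' @param status exposure: 0/1 case status or a continuous variable.
#' @param covars optional data.frame/matrix of covariate columns, or `NULL`.
#' @param feature feature name carried into the result.
#' @param covariate_set label of the adjustment set carried into the result.
#' @return One-row data.frame: `feature`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`, `fdr` (`NA` here; filled by the scan), `n`,
#'   `covariate_set`.
#' @export
fit_linear_assoc <- function(y, status, covars = NULL, feature = "feature",
                             covariate_set = "unadjusted") {
  X <- cbind(`(Intercept)` = 1, status = status)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    for (nm in names(covars)) {
      col <- covars[[nm]]
      if (is.character(col) || is.factor(col)) {
        lev <- sort(unique(stats::na.omit(as.character(col))))
        if (length(lev) > 2L)
          for (l in lev[-1L]) X <- cbind(X, as.numeric(col == l))
        else X <- cbind(X, as.numeric(col == lev[length(lev)]))
        colnames(X)[ncol(X)] <- nm
      } else {
        X <- cbind(X, as.numeric(col))
        colnames(X)[ncol(X)] <- nm
      }
    }
  }
  keep <- stats::complete.cases(cbind(y, X))
  yk <- y[keep]; Xk <- X[keep, , drop = FALSE]
  n <- length(yk); pcol <- ncol(Xk)
  if (n <= pcol + 1L)
    stop("too few complete observations (", n, ") for ", pcol - 1L,
         " regressors")
  qx <- qr(Xk)
  if (qx$rank < pcol) {
    bad <- colnames(Xk)[qx$pivot[(qx$rank + 1L):pcol]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, yk)
  res <- yk - drop(Xk %*% beta)
  df <- n - pcol
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(Xk)))
  dimnames(XtXinv) <- list(colnames(Xk), colnames(Xk))
  se <- sqrt(sigma2 * XtXinv["status", "status"])
  est <- beta[["status"]]
  if (sigma2 <= .Machine$double.eps * stats::var(yk) ||
      !is.finite(se) || se == 0) {
    # perfect fit: p reported at the machine floor rather than 0
    se <- 0; p <- .Machine$double.xmin
    ci <- c(est, est)
  } else {
    tval <- est / se
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    p <- max(p, .Machine$double.xmin)
    tcrit <- stats::qt(0.975, df)
    ci <- est + c(-1, 1) * tcrit * se
  }
  data.frame(feature = feature, estimate = est, se = se,
             ci_low = ci[1L], ci_high = ci[2L], p = p, fdr = NA_real_,
             n = n, covariate_set = covariate_set,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Association scan of every feature against case status
#'
#' Runs [fit_linear_assoc] for each feature and each named covariate set,
#' then applies Benjamini-Hochberg adjustment within each covariate set
#' (the scan is per platform, so a covariate set is one multiple-testing
#' family). Features without missing values share a single QR factorization
#' for speed; features with missing cells fall back to a per-feature
#' complete-case fit.
#'
#' @param matrix prepared [feature_matrix].
#' @param design a population-mode [contrast_design], or a named 0/1 (or
#'   continuous) exposure vector.
#' @param covars sample table with `sample_id` plus covariate columns.
#' @param covariate_sets named list of character vectors of covariate column
#'   names; default a single unadjusted scan.
#' @return data.frame of stacked [fit_linear_assoc] rows with `fdr` filled.
#' @export
run_association_scan <- function(matrix, design, covars = NULL,
                                 covariate_sets = list(unadjusted =
                                                         character(0))) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (ncol(matrix$values) == 0L) stop("empty feature set")
  status <- if (inherits(design, "contrast_design")) design_status(design)
            else design
  ids <- intersect(rownames(matrix$values), names(status))
  if (length(ids) == 0L) stop("no overlap between matrix and design samples")
  V <- matrix$values[ids, , drop = FALSE]
  st <- status[ids]
  if (!is.null(covars)) {
    rownames(covars) <- covars$sample_id
    covars <- covars[ids, , drop = FALSE]
  }
  out <- list()
  for (set_name in names(covariate_sets)) {
    cols <- covariate_sets[[set_name]]
    cv <- if (length(cols) == 0L) NULL else covars[, cols, drop = FALSE]
    res <- scan_one_set(V, st, cv, set_name)
    res$fdr <- bh_fdr(res$p)
    out[[set_name]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

scan_one_set <- function(V, status, cv, set_name) {
  covar_ok <- is.null(cv) || all(stats::complete.cases(cv))
  no_miss <- !anyNA(V)
  if (covar_ok && no_miss) {
    # shared design matrix: one QR for the whole panel
    X <- cbind(`(Intercept)` = 1, status = status)
    if (!is.null(cv)) X <- add_covar_columns(X, cv)
    qx <- qr(X)
    if (qx$rank < ncol(X))
      stop("rank-deficient design; collinear column(s): ",
           paste(colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]],
                 collapse = ", "))
    B <- qr.coef(qx, V)
    R <- V - X %*% B
    df <- nrow(X) - ncol(X)
    sigma2 <- colSums(R^2) / df
    XtXinv <- chol2inv(chol(crossprod(X)))
    css <- XtXinv[2L, 2L]
    est <- B[2L, ]
    se <- sqrt(sigma2 * css)
    tval <- est / se
    p <- pmax(2 * stats::pt(abs(tval), df, lower.tail = FALSE),
              .Machine$double.xmin)
    tcrit <- stats::qt(0.975, df)
    data.frame(feature = colnames(V), estimate = unname(est),
               se = unname(se), ci_low = unname(est - tcrit * se),
               ci_high = unname(est + tcrit * se), p = unname(p),
               fdr = NA_real_, n = nrow(X), covariate_set = set_name,
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    do.call(rbind, lapply(colnames(V), function(f)
      fit_linear_assoc(V[, f], status, cv, feature = f,
                       covariate_set = set_name)))
  }
}

add_covar_columns <- function(X, cv) {
  for (nm in names(cv)) {
    col <- cv[[nm]]
    if (is.character(col) || is.factor(col)) {
      lev <- sort(unique(as.character(col)))
      X <- cbind(X, as.numeric(col == lev[length(lev)]))
    } else X <- cbind(X, as.numeric(col))
    colnames(X)[ncol(X)] <- nm
  }
  X
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values `min_{j >= rank(i)} p_(j) * m / j`, capped at
#' 1; order-preserving. Inputs outside (0, 1] are an error.
#'
#' @param pvals p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Random-effects meta-analysis by restricted maximum likelihood
#'
#' Pools per-study estimates under the random-effects model
#' `y_i ~ N(mu, v_i + tau^2)`. The between-study variance tau^2 maximizes
#' the restricted log-likelihood (profiled over mu) by bounded scalar
#' optimization, floored at 0; the pooled estimate is the inverse-variance
#' weighted mean with weights `1 / (v_i + tau^2)` and
#' `pooled_se = (sum w_i)^(-1/2)`. With a single study the pooled result is
#' that study and tau^2 = 0.
#'
#' @param estimates per-study effect estimates.
#' @param ses per-study standard errors, all positive.
#' @param feature optional feature name carried into the result.
#' @return list of class `meta_result`: `feature`, `pooled_estimate`,
#'   `pooled_se`, `tau2`, `ci_low`, `ci_high`, `p` (normal approximation),
#'   `per_study`.
#' @export
reml_meta <- function(estimates, ses, feature = NA_character_) {
  k <- length(estimates)
  if (k == 0L) stop("need at least one study")
  if (length(ses) != k) stop("`estimates` and `ses` lengths differ")
  if (any(!is.finite(estimates)) || any(!is.finite(ses)) || any(ses <= 0))
    stop("standard errors must be positive and finite")
  v <- ses^2
  if (k == 1L) {
    tau2 <- 0
  } else {
    nll <- function(tau2) -reml_loglik(estimates, v, tau2)
    upper <- max(10 * stats::var(estimates), max(v), 1e-6)
    opt <- stats::optimize(nll, c(0, upper), tol = 1e-10)
    tau2 <- if (nll(0) <= opt$objective + 1e-12) 0 else opt$minimum
  }
  w <- 1 / (v + tau2)
  mu <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- mu / se
  structure(list(feature = feature, pooled_estimate = mu, pooled_se = se,
                 tau2 = tau2,
                 ci_low = mu - stats::qnorm(0.975) * se,
                 ci_high = mu + stats::qnorm(0.975) * se,
                 p = max(2 * stats::pnorm(abs(z), lower.tail = FALSE),
                         .Machine$double.xmin),
                 per_study = data.frame(estimate = estimates, se = ses)),
            class = "meta_result")
}

# Restricted log-likelihood of the random-effects model, mu profiled out.
reml_loglik <- function(y, v, tau2) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

#' Meta-analyze per-cohort association scans feature by feature
#'
#' @param scans list of association-scan data.frames (one per cohort) from
#'   [run_association_scan], restricted to a single covariate set each.
#' @return data.frame with one row per feature present in every scan:
#'   pooled estimate, SE, tau2, CI, p and `fdr` (BH across features).
#' @export
run_meta_scan <- function(scans) {
  if (length(scans) == 0L) stop("need at least one scan")
  feats <- Reduce(intersect, lapply(scans, function(s) s$feature))
  if (length(feats) == 0L) stop("no shared features across scans")
  rows <- lapply(feats, function(f) {
    est <- vapply(scans, function(s) s$estimate[s$feature == f][1L], 1)
    se <- vapply(scans, function(s) s$se[s$feature == f][1L], 1)
    m <- reml_meta(est, se, feature = f)
    data.frame(feature = f, pooled_estimate = m$pooled_estimate,
               pooled_se = m$pooled_se, tau2 = m$tau2, ci_low = m$ci_low,
               ci_high = m$ci_high, p = m$p, fdr = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Concordance of two association scans (beta-beta comparison)
#'
#' For the features shared by two result tables, counts those significant in
#' both at the FDR threshold, split by sign agreement, and returns the
#' paired estimates for plotting.
#'
#' @param res_a,res_b association result data.frames with columns `feature`,
#'   `estimate` and `fdr` (for meta results, `pooled_estimate` is accepted).
#' @param alpha FDR significance threshold (default 0.05).
#' @return list: `counts` (`shared_significant`, `both_positive`,
#'   `both_negative`, `sign_discordant`) and `pairs` (per-feature estimates
#'   and significance flags).
#' @export
beta_beta_concordance <- function(res_a, res_b, alpha = 0.05) {
  getcol <- function(d, nm, alt) if (nm %in% names(d)) d[[nm]] else d[[alt]]
  a <- data.frame(feature = res_a$feature,
                  estimate_a = getcol(res_a, "estimate", "pooled_estimate"),
                  fdr_a = res_a$fdr, stringsAsFactors = FALSE)
  b <- data.frame(feature = res_b$feature,
                  estimate_b = getcol(res_b, "estimate", "pooled_estimate"),
                  fdr_b = res_b$fdr, stringsAsFactors = FALSE)
  m <- merge(a, b, by = "feature")
  if (nrow(m) == 0L) stop("the two result tables share no features")
  m$sig_both <- m$fdr_a <= alpha & m$fdr_b <= alpha
  m$sign_agree <- sign(m$estimate_a) == sign(m$estimate_b)
  counts <- c(shared_significant = sum(m$sig_both),
              both_positive = sum(m$sig_both & m$sign_agree &
                                    m$estimate_a > 0),
              both_negative = sum(m$sig_both & m$sign_agree &
                                    m$estimate_a < 0),
              sign_discordant = sum(m$sig_both & !m$sign_agree))
  list(counts = counts, pairs = m)
}

#' Pairwise Pearson correlations between two feature panels
#'
#' Pearson r on pairwise-complete observations for every (feature of A,
#' feature of B) pair, with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))`. Pairs with fewer than 3 complete
#' observations are skipped with a warning.
#'
#' @param mat_a,mat_b [feature_matrix] objects sharing samples.
#' @return data.frame: `feature_a`, `feature_b`, `r`, `n`, `p`.
#' @export
correlate_features <- function(mat_a, mat_b) {
  stopifnot(inherits(mat_a, "feature_matrix"),
            inherits(mat_b, "feature_matrix"))
  ids <- intersect(rownames(mat_a$values), rownames(mat_b$values))
  if (length(ids) == 0L) stop("no shared samples")
  A <- mat_a$values[ids, , drop = FALSE]
  B <- mat_b$values[ids, , drop = FALSE]
  rows <- list()
  for (fa in colnames(A)) for (fb in colnames(B)) {
    ok <- !is.na(A[, fa]) & !is.na(B[, fb])
    n <- sum(ok)
    if (n < 3L) {
      warning("pair (", fa, ", ", fb, ") has fewer than 3 complete ",
              "observations; skipped", call. = FALSE)
      next
    }
    r <- stats::cor(A[ok, fa], B[ok, fb])
    p <- if (abs(r) >= 1) .Machine$double.xmin else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      max(2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE),
          .Machine$double.xmin)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature_a = fa, feature_b = fb, r = r, n = n, p = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
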