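# Small simulated worlds shared across tests.

small_config <- function(seed = 1L, ...) {
  sim_config(n_per_cohort = c(LLS = 300, RS = 300),
             n_mz_pairs = 60, n_dz_pairs = 40, seed = seed, ...)
}

# tiny feature matrix from a plain matrix, naming rows/cols if absent
fm <- function(values, ...) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  feature_matrix(values, ...)
}

# score_vector built directly from named values (bypasses projection)
sv_from <- function(ids, raw, resid = raw - mean(raw)) {
  structure(data.frame(sample_id = ids, raw_score = raw,
                       age_residual_score = resid,
                       stringsAsFactors = FALSE),
            class = c("score_vector", "data.frame"))
}

# independent OLS oracle: solve the normal equations directly
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

# independent two-sided Fisher oracle: exhaustive hypergeometric
# enumeration with the point-probability rule
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 + r2 == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(k, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}
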