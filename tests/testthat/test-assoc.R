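test_that("linear association matches the normal-equations oracle", {
  set.seed(44)
  n <- 40
  status <- rep(0:1, each = n / 2)
  covars <- data.frame(age = runif(n, 50, 70), bmi = rnorm(n, 25, 3))
  y <- 0.8 * status + 0.02 * covars$age - 0.05 * covars$bmi + rnorm(n)
  res <- fit_linear_assoc(y, status, covars)
  X <- cbind(1, status, covars$age, covars$bmi)
  beta <- ols_oracle(X, y)
  expect_equal(res$estimate, beta[2], tolerance = 1e-8)
  sigma2 <- sum((y - X %*% beta)^2) / (n - 4)
  se <- sqrt(sigma2 * solve(crossprod(X))[2, 2])
  expect_equal(res$se, se, tolerance = 1e-8)
  # and agrees with lm() + confint()
  lmfit <- lm(y ~ status + age + bmi, data = cbind(covars, status, y))
  expect_equal(res$p, summary(lmfit)$coefficients["status", 4],
               tolerance = 1e-10)
  expect_equal(c(res$ci_low, res$ci_high),
               unname(confint(lmfit)["status", ]), tolerance = 1e-8)
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
})

test_that("unadjusted estimate is the case-control mean difference", {
  set.seed(45)
  y <- rnorm(30)
  status <- rep(c(1, 0), 15)
  res <- fit_linear_assoc(y, status)
  expect_equal(res$estimate, mean(y[status == 1]) - mean(y[status == 0]),
               tolerance = 1e-12)
  # perfect fit reports the machine-floor p rather than zero
  perf <- fit_linear_assoc(as.numeric(status), status)
  expect_equal(perf$estimate, 1)
  expect_identical(perf$p, .Machine$double.xmin)
  # rank-deficient design names the collinear column
  covars <- data.frame(dup = status)
  expect_error(fit_linear_assoc(y, status, covars), "collinear.*dup")
})

test_that("null p-values are uniform under permutation", {
  set.seed(46)
  n <- 60
  y <- rnorm(n)
  p <- replicate(2000, fit_linear_assoc(y, sample(rep(0:1, n / 2)))$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("scan batch path equals per-feature fits and fills FDR per set", {
  set.seed(47)
  n <- 50; pfeat <- 8
  ids <- sprintf("s%02d", 1:n)
  V <- matrix(rnorm(n * pfeat), n, pfeat,
              dimnames = list(ids, sprintf("f%d", 1:pfeat)))
  status <- setNames(rep(c(1, 0), n / 2), ids)
  covars <- data.frame(sample_id = ids, age = runif(n, 40, 70),
                       sex = sample(c("F", "M"), n, TRUE))
  m <- feature_matrix(V)
  scan <- run_association_scan(m, status, covars,
                               list(age_sex = c("age", "sex")))
  for (f in c("f1", "f5")) {
    single <- fit_linear_assoc(V[, f], status,
                               covars[, c("age", "sex")], feature = f)
    row <- scan[scan$feature == f, ]
    expect_equal(row$estimate, single$estimate, tolerance = 1e-10)
    expect_equal(row$se, single$se, tolerance = 1e-10)
    expect_equal(row$p, single$p, tolerance = 1e-10)
  }
  expect_equal(scan$fdr, bh_fdr(scan$p))
  # missing values fall back to complete-case per feature
  V2 <- V; V2[1:3, 2] <- NA
  scan2 <- run_association_scan(feature_matrix(V2), status, covars,
                                list(age_sex = c("age", "sex")))
  expect_equal(scan2$n[scan2$feature == "f2"], n - 3)
  # single feature: fdr equals p
  scan1 <- run_association_scan(fm_subset(m, features = "f1"), status,
                                covars, list(u = character(0)))
  expect_equal(scan1$fdr, scan1$p)
  # estimates on z-scaled features are invariant to raw affine rescaling
  Vr <- sweep(sweep(V, 2, c(1:8), "*"), 2, c(8:1), "+")
  zs <- function(M) scale(M)[, , drop = FALSE]
  s_orig <- run_association_scan(fm(zs(V)), status, NULL)
  s_resc <- run_association_scan(fm(zs(Vr)), status, NULL)
  expect_equal(s_orig$estimate, s_resc$estimate, tolerance = 1e-10)
})

test_that("BH adjustment matches the hand step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  p <- c(0.005, 0.009, 0.05, 0.5, 1)
  m <- length(p)
  # independent oracle: min over j >= rank of p_(j) m / j, capped at 1
  o <- order(p)
  adj <- rev(cummin(rev(pmin(p[o] * m / seq_len(m), 1))))[order(o)]
  expect_equal(bh_fdr(p), adj)
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("REML meta-analysis behaves at its exact special cases", {
  m <- reml_meta(c(0.7, 0.7, 0.7), c(0.2, 0.2, 0.2))
  expect_equal(m$pooled_estimate, 0.7)
  expect_equal(m$tau2, 0)
  sym <- reml_meta(c(0, 2), c(1, 1))
  expect_equal(sym$pooled_estimate, 1)
  one <- reml_meta(1.3, 0.4, feature = "x")
  expect_equal(one$pooled_estimate, 1.3)
  expect_equal(one$pooled_se, 0.4)
  expect_equal(one$tau2, 0)
  expect_error(reml_meta(c(1, 2), c(0.1, -0.2)), "positive")
})

test_that("REML tau2 matches a brute-force restricted-likelihood grid", {
  # independent oracle: grid search of the restricted log-likelihood
  grid_tau2 <- function(y, v, upper = 10, step = 1e-4) {
    taus <- seq(0, upper, by = step)
    ll <- vapply(taus, function(t2) {
      w <- 1 / (v + t2); mu <- sum(w * y) / sum(w)
      -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (y - mu)^2))
    }, 1)
    taus[which.max(ll)]
  }
  cases <- list(list(y = c(0.2, 1.1, 2.3), se = c(0.3, 0.25, 0.4)),
                list(y = c(-0.5, 0.1, 0.4, 1.9), se = c(0.5, 0.3, 0.4, 0.6)),
                list(y = c(1.0, 1.05, 0.95), se = c(0.1, 0.12, 0.11)))
  for (cs in cases) {
    got <- reml_meta(cs$y, cs$se)$tau2
    want <- grid_tau2(cs$y, cs$se^2)
    expect_lt(abs(got - want), 1e-4)
  }
})

test_that("REML reduces to fixed-effect pooling when tau2 is zero", {
  y <- c(1.0, 1.05, 0.95); se <- c(0.3, 0.35, 0.32)
  m <- reml_meta(y, se)
  expect_equal(m$tau2, 0)
  w <- 1 / se^2
  expect_equal(m$pooled_estimate, sum(w * y) / sum(w), tolerance = 1e-8)
  expect_equal(m$pooled_se, 1 / sqrt(sum(w)), tolerance = 1e-8)
})

test_that("meta-analysis of homogeneous cohorts matches the pooled scan", {
  set.seed(48)
  cfg <- small_config(seed = 48)
  co <- read_score_coefficients(
    system.file("extdata", "score_coefficients_synthetic.tsv",
                package = "metabocontrast"))
  scans <- list(); pooled_v <- list(); pooled_status <- list()
  for (cl in c("LLS", "RS")) {
    sim <- simulate_population(cfg, cl)
    sv <- compute_score(sim$metabolites, co, sim$samples)
    cases <- select_extreme_cases(sv, 25)
    d <- select_matched_controls(sv, cases, sim$samples,
                                 age_tolerance = 2.5)
    sel <- c(d$case_ids, d$control_ids)
    z <- prep_transform(fm_subset(sim$proteins, samples = sel),
                        rep(cl, 50))
    scans[[cl]] <- run_association_scan(z, d)
    pooled_v[[cl]] <- z$values
    pooled_status[[cl]] <- design_status(d)
  }
  meta <- run_meta_scan(scans)
  V <- rbind(pooled_v$LLS, pooled_v$RS)
  status <- c(pooled_status$LLS, pooled_status$RS)
  pooled <- run_association_scan(feature_matrix(V), status)
  cmp <- merge(meta, pooled, by = "feature")
  # no heterogeneity simulated: pooled REML estimates sit within
  # Monte-Carlo error of the single pooled-cohort scan
  expect_lt(max(abs(cmp$pooled_estimate - cmp$estimate)),
            3 * max(cmp$pooled_se))
  expect_gt(cor(cmp$pooled_estimate, cmp$estimate), 0.98)
})

test_that("beta-beta concordance counts match a manual tally", {
  mk <- function(est, fdr) data.frame(feature = sprintf("f%d",
                                                        seq_along(est)),
                                      estimate = est, fdr = fdr,
                                      stringsAsFactors = FALSE)
  a <- mk(c(1, -1, 2, -2, 0.5, -0.5), c(0.01, 0.01, 0.2, 0.01, 0.01, 0.5))
  b <- mk(c(2, -2, 1, 2, -1, -1), c(0.04, 0.02, 0.01, 0.01, 0.04, 0.01))
  out <- beta_beta_concordance(a, b, alpha = 0.05)
  # significant in both: f1 (+/+), f2 (-/-), f4 (-/+), f5 (+/-)
  expect_equal(unname(out$counts["shared_significant"]), 4)
  expect_equal(unname(out$counts["both_positive"]), 1)
  expect_equal(unname(out$counts["both_negative"]), 1)
  expect_equal(unname(out$counts["sign_discordant"]), 2)
  ident <- beta_beta_concordance(a, a, alpha = 0.05)
  expect_equal(unname(ident$counts["sign_discordant"]), 0)
  mirr <- beta_beta_concordance(a, transform(a, estimate = -estimate),
                                alpha = 0.05)
  expect_equal(unname(mirr$counts["both_positive"] +
                        mirr$counts["both_negative"]), 0)
  expect_error(beta_beta_concordance(a, mk(1, 0.5)[0, ]), "share no")
})

test_that("feature correlations match hand arithmetic", {
  a <- fm(matrix(c(1, 2, 3), 3, 1))
  b <- fm(matrix(c(2, 4, 7), 3, 1))
  out <- correlate_features(a, b)
  x <- c(1, 2, 3); y <- c(2, 4, 7)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-10)
  expect_equal(out$p, cor.test(x, y)$p.value, tolerance = 1e-8)
  self <- correlate_features(a, a)
  expect_equal(self$r, 1)
  orth <- correlate_features(fm(matrix(c(1, -1, 1, -1), 4, 1)),
                             fm(matrix(c(1, 1, -1, -1), 4, 1)))
  expect_equal(orth$r, 0)
  short <- fm(matrix(c(1, NA, NA, 4), 4, 1))
  expect_warning(out2 <- correlate_features(short, b2 <- fm(matrix(1:4, 4, 1) + 0)),
                 "fewer than 3")
})
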