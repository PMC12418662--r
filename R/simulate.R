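#' Configuration for the synthetic multi-cohort generator
#'
#' Describes the stated world the generator emulates: two population cohorts
#' and a twin registry measured on three omics layers, all driven by a latent
#' "metabolic health" trait of unit variance. The trait decomposes as
#' L = a*A + c*C + e*E with a^2 = `h2_true`, c^2 = `c2_true`,
#' e^2 = 1 - h2_true - c2_true, so `h2_true` is directly the narrow-sense
#' heritability the Falconer estimator should recover. Metabolites load
#' linearly onto L on the log scale (values are exponentiated so the
#' downstream log transform is defined); cytokines are log-normal with an
#' additive trait effect and a recorded lower detection limit; proteins carry
#' planted effects of class `"null"` (no association), `"environmental"`
#' (association through L only, preserved within twin pairs) or
#' `"pleiotropic"` (an extra path through the genetic component A, which
#' cancels within monozygotic pairs).
#'
#' @param n_per_cohort named integer vector: samples per population cohort.
#'   Defaults mimic the source cohorts (~2300 and ~3000).
#' @param n_mz_pairs,n_dz_pairs complete monozygotic / dizygotic twin pairs
#'   in the registry (defaults 726 and 450).
#' @param h2_true,c2_true additive-genetic and shared-environment fractions
#'   of the latent trait variance; `h2_true + c2_true <= 1`. Default
#'   `h2_true = 0.4` (a moderately heritable score), `c2_true = 0`.
#' @param n_metabolites number of score analytes (default 14).
#' @param metabolite_loadings signed loadings of each analyte onto L (log
#'   scale), length `n_metabolites`.
#' @param metabolite_noise_sd residual SD of each log analyte (default 0.5).
#' @param cytokine_panel data.frame with columns `name`, `log_mean`,
#'   `log_sd`, `trait_effect`, `lod` (LOD on the measurement scale). The
#'   default 15-cytokine panel gives 6 cytokines detection limits near their
#'   75th percentile (mostly undetectable) and the rest limits near their
#'   5th percentile.
#' @param protein_panel data.frame with columns `name`,
#'   `class` (`"null"|"environmental"|"pleiotropic"`), `effect` (slope of the
#'   log intensity on L), `genetic_effect` (extra slope on A, pleiotropic
#'   class only), `noise_sd`.
#' @param age_range named list of `c(min, max)` years per cohort label
#'   (uniform draw). Defaults reflect the age contrast between a middle-aged
#'   cohort (~56y), an older cohort (~67y) and a young twin registry (~36y).
#' @param sex_fraction fraction of female participants (default 0.52).
#' @param age_effect,sex_effect additive effects of standardized age and of
#'   female sex on L in the population cohorts (the registry trait is pure
#'   ACE, so co-twin shared age/sex cannot masquerade as common environment).
#' @param covariate_effects named list of slopes of covariates on L:
#'   `lymphocyte` (% per trait SD, default -3), `monocyte`, `bmi`, and
#'   log-odds slopes `lipid_med`, `bp_med`.
#' @param seed integer; fixes all randomness of the generator.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_cohort = c(LLS = 2300, RS = 3000),
                       n_mz_pairs = 726, n_dz_pairs = 450,
                       h2_true = 0.4, c2_true = 0,
                       n_metabolites = 14,
                       metabolite_loadings = NULL,
                       metabolite_noise_sd = 0.5,
                       cytokine_panel = default_cytokine_panel(),
                       protein_panel = default_protein_panel(),
                       age_range = list(LLS = c(45, 68), RS = c(56, 78),
                                        NTR = c(25, 47)),
                       sex_fraction = 0.52,
                       age_effect = 0.3, sex_effect = 0.1,
                       covariate_effects = list(lymphocyte = -3,
                                                monocyte = -0.5,
                                                bmi = 0.8,
                                                lipid_med = 0.4,
                                                bp_med = 0.4),
                       seed = 1L) {
  if (is.null(metabolite_loadings))
    metabolite_loadings <- default_metabolite_loadings(n_metabolites)
  if (any(n_per_cohort <= 0) || n_mz_pairs <= 0 || n_dz_pairs <= 0)
    stop("cohort and pair counts must be positive")
  if (is.null(names(n_per_cohort)))
    stop("`n_per_cohort` must be named by cohort label")
  if (h2_true < 0 || h2_true > 1 || c2_true < 0 || c2_true > 1)
    stop("`h2_true` and `c2_true` must lie in [0, 1]")
  if (h2_true + c2_true > 1)
    stop("`h2_true` + `c2_true` must not exceed 1")
  if (length(metabolite_loadings) != n_metabolites)
    stop("`metabolite_loadings` must have length `n_metabolites` (",
         n_metabolites, "), got ", length(metabolite_loadings))
  if (!all(is.finite(metabolite_loadings)))
    stop("metabolite loadings must be finite")
  stopifnot(is.data.frame(cytokine_panel),
            all(c("name", "log_mean", "log_sd", "trait_effect", "lod") %in%
                  names(cytokine_panel)))
  stopifnot(is.data.frame(protein_panel),
            all(c("name", "class", "effect", "genetic_effect", "noise_sd") %in%
                  names(protein_panel)))
  if (!all(protein_panel$class %in% c("null", "environmental", "pleiotropic")))
    stop("protein classes must be null/environmental/pleiotropic")
  if (!all(is.finite(protein_panel$effect)) ||
      !all(is.finite(protein_panel$genetic_effect)))
    stop("protein effects must be finite")
  if (sex_fraction < 0 || sex_fraction > 1)
    stop("`sex_fraction` must lie in [0, 1]")
  names(metabolite_loadings) <- default_analyte_names(n_metabolites)
  structure(list(n_per_cohort = n_per_cohort,
                 n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 h2_true = h2_true, c2_true = c2_true,
                 n_metabolites = as.integer(n_metabolites),
                 metabolite_loadings = metabolite_loadings,
                 metabolite_noise_sd = metabolite_noise_sd,
                 cytokine_panel = cytokine_panel,
                 protein_panel = protein_panel,
                 age_range = age_range,
                 sex_fraction = sex_fraction,
                 age_effect = age_effect, sex_effect = sex_effect,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Analyte names follow the published 14-analyte mortality-score panel
# (lipoprotein lipids, branched-chain amino acids, glycolysis markers,
# albumin, glycoprotein acetyls); loadings are synthetic.
default_analyte_names <- function(n = 14) {
  base <- c("XXL_VLDL_L", "S_HDL_L", "VLDL_D", "PUFA_FA_pct", "Glucose",
            "Lactate", "Histidine", "Isoleucine", "Leucine", "Valine",
            "Phenylalanine", "Acetoacetate", "Albumin", "GlycA")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("analyte_%02d", seq_len(n - length(base))))
}

default_metabolite_loadings <- function(n = 14) {
  base <- c(0.45, -0.40, 0.30, -0.35, 0.30, 0.25, -0.30, 0.25, -0.25, -0.30,
            0.35, 0.25, -0.40, 0.50)
  out <- rep_len(base, n)
  names(out) <- default_analyte_names(n)
  out
}

#' Default synthetic omics panels
#'
#' `default_cytokine_panel()`: 15 cytokines on the log scale; six (IL2,
#' TRAIL, GRO1a, IFNg, IL1b, PAI1) get a detection limit at their 75th
#' percentile so they are mostly undetectable, the other nine at their 5th
#' percentile. `default_protein_panel()`: 30 proteins, 10 per planted class.
#' Real assay detection limits are proprietary to the platform; these values
#' are free parameters of the stated world.
#' @return data.frame describing the panel (see [sim_config]).
#' @export
default_cytokine_panel <- function() {
  name <- c("IL6", "GDF15", "MIG", "Eotaxin", "MCP1", "IP10", "RANTES",
            "IL8", "TNFa", "IL2", "TRAIL", "GRO1a", "IFNg", "IL1b", "PAI1")
  high_lod <- name %in% c("IL2", "TRAIL", "GRO1a", "IFNg", "IL1b", "PAI1")
  log_mean <- rep(1.0, 15)
  log_sd <- rep(0.8, 15)
  trait_effect <- ifelse(name %in% c("IL6", "GDF15", "MIG"), 0.35,
                         ifelse(high_lod, 0.1, 0.15))
  s_tot <- sqrt(log_sd^2 + trait_effect^2)
  log_lod <- ifelse(high_lod, log_mean + stats::qnorm(0.75) * s_tot,
                    log_mean + stats::qnorm(0.05) * s_tot)
  data.frame(name = name, log_mean = log_mean, log_sd = log_sd,
             trait_effect = trait_effect, lod = exp(log_lod))
}

#' @rdname default_cytokine_panel
#' @export
default_protein_panel <- function() {
  cls <- rep(c("null", "environmental", "pleiotropic"), each = 10)
  name <- sprintf("PROT_%s_%02d", toupper(substr(cls, 1, 3)),
                  rep(1:10, times = 3))
  sgn <- rep_len(c(1, -1), 30)
  effect <- ifelse(cls == "null", 0,
                   ifelse(cls == "environmental", sgn * 0.45, sgn * 0.20))
  genetic_effect <- ifelse(cls == "pleiotropic", sgn * 0.45, 0)
  data.frame(name = name, class = cls, effect = effect,
             genetic_effect = genetic_effect, noise_sd = 0.6)
}

# Deterministic 31-bit substream seed from a base seed and a stage label.
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

# Shared machinery: given latent trait L and genetic factor A, draw the
# three omics layers and the covariate table.
simulate_omics <- function(config, L, A, ids) {
  n <- length(L)
  lam <- config$metabolite_loadings
  met <- exp(outer(L, lam) +
               matrix(stats::rnorm(n * length(lam),
                                   sd = config$metabolite_noise_sd),
                      n, length(lam)))
  dimnames(met) <- list(ids, names(lam))

  cp <- config$cytokine_panel
  cyt <- exp(matrix(cp$log_mean, n, nrow(cp), byrow = TRUE) +
               outer(L, cp$trait_effect) +
               matrix(stats::rnorm(n * nrow(cp)), n, nrow(cp)) *
                 matrix(cp$log_sd, n, nrow(cp), byrow = TRUE))
  dimnames(cyt) <- list(ids, cp$name)
  lods <- stats::setNames(cp$lod, cp$name)

  pp <- config$protein_panel
  prot <- exp(outer(L, pp$effect) + outer(A, pp$genetic_effect) +
                matrix(stats::rnorm(n * nrow(pp)), n, nrow(pp)) *
                  matrix(pp$noise_sd, n, nrow(pp), byrow = TRUE))
  dimnames(prot) <- list(ids, pp$name)

  list(metabolites = feature_matrix(met, platform = "metabolomics"),
       cytokines = feature_matrix(cyt, lod = lods, platform = "cytokine"),
       proteins = feature_matrix(prot, platform = "proteomics"))
}

simulate_covariates <- function(config, L, age, sex, ids) {
  ce <- config$covariate_effects
  n <- length(L)
  data.frame(
    sample_id = ids,
    age = age,
    sex = sex,
    bmi = 25.5 + ce$bmi * L + stats::rnorm(n, sd = 3),
    lymphocyte_pct = 32 + ce$lymphocyte * L + stats::rnorm(n, sd = 5),
    monocyte_pct = 8 + ce$monocyte * L + stats::rnorm(n, sd = 2),
    lipid_med = stats::rbinom(n, 1, stats::plogis(-1.5 + ce$lipid_med * L)),
    bp_med = stats::rbinom(n, 1, stats::plogis(-1.5 + ce$bp_med * L)),
    stringsAsFactors = FALSE)
}

#' Simulate one population cohort of unrelated individuals
#'
#' Draws a latent health trait `L = a*A + c*C + e*E` plus age and sex effects
#' for `n_per_cohort[cohort_label]` unrelated participants, then generates
#' metabolite, cytokine and protein layers and a covariate table from it.
#' Cytokine detection limits are recorded in the returned matrix but values
#' are *not* censored here (see [apply_detection_limit]).
#'
#' @param config a [sim_config].
#' @param cohort_label one of the cohort names in `config$n_per_cohort`.
#' @return A list with elements `samples` (covariate data.frame with cohort,
#'   family id and zygosity columns), `metabolites`, `cytokines`, `proteins`
#'   (each a [feature_matrix]) and `truth` (a `truth_record`: per-sample
#'   `latent_trait` and `genetic_component`, `protein_classes` and the
#'   planted per-feature effects).
#' @export
simulate_population <- function(config, cohort_label) {
  stopifnot(inherits(config, "sim_config"))
  if (!cohort_label %in% names(config$n_per_cohort))
    stop("cohort label ", cohort_label, " not present in `n_per_cohort`")
  n <- as.integer(config$n_per_cohort[[cohort_label]])
  if (n <= 0) stop("non-positive cohort size")
  set.seed(derive_seed(config$seed, paste0("population_", cohort_label)))

  rng <- config$age_range[[cohort_label]]
  if (is.null(rng)) rng <- c(40, 70)
  age <- stats::runif(n, rng[1], rng[2])
  sex <- ifelse(stats::rbinom(n, 1, config$sex_fraction) == 1, "F", "M")

  a <- sqrt(config$h2_true); cc <- sqrt(config$c2_true)
  e <- sqrt(max(0, 1 - config$h2_true - config$c2_true))
  A <- stats::rnorm(n); C <- stats::rnorm(n); E <- stats::rnorm(n)
  z_age <- (age - mean(rng)) / (diff(rng) / sqrt(12))
  L <- a * A + cc * C + e * E +
    config$age_effect * z_age + config$sex_effect * (sex == "F")

  ids <- sprintf("%s_%04d", cohort_label, seq_len(n))
  om <- simulate_omics(config, L, A, ids)
  cov <- simulate_covariates(config, L, age, sex, ids)
  samples <- data.frame(sample_id = ids, cohort = cohort_label,
                        family_id = NA_character_, zygosity = NA_character_,
                        cov[, -1L], stringsAsFactors = FALSE)
  truth <- truth_record(config, L, A, ids)
  c(list(samples = samples), om, list(truth = truth))
}

#' Simulate a twin registry of complete MZ and DZ pairs
#'
#' The latent trait is the pure ACE decomposition `L = a*A + c*C + e*E`:
#' the additive-genetic factor A is identical within monozygotic pairs and
#' correlated 0.5 within dizygotic pairs (no assortative mating, no
#' dominance), the common environment C is shared within every pair, E is
#' individual. Co-twins share age; monozygotic co-twins share sex. Omics
#' layers and covariates are generated exactly as in [simulate_population].
#'
#' @param config a [sim_config] with `n_mz_pairs`, `n_dz_pairs >= 2`.
#' @return As [simulate_population]; `samples$family_id` and
#'   `samples$zygosity` (`"MZ"`/`"DZ"`) identify the pairs.
#' @export
simulate_twin_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_mz_pairs < 2 || config$n_dz_pairs < 2)
    stop("need at least 2 MZ and 2 DZ pairs")
  if (config$h2_true + config$c2_true > 1)
    stop("`h2_true` + `c2_true` must not exceed 1")
  set.seed(derive_seed(config$seed, "twin_registry"))

  nmz <- config$n_mz_pairs; ndz <- config$n_dz_pairs
  npairs <- nmz + ndz
  zyg <- rep(c("MZ", "DZ"), c(nmz, ndz))
  fam <- sprintf("NTR_F%04d", seq_len(npairs))

  a <- sqrt(config$h2_true); cc <- sqrt(config$c2_true)
  e <- sqrt(max(0, 1 - config$h2_true - config$c2_true))

  A1 <- stats::rnorm(npairs)
  A2 <- ifelse(zyg == "MZ", A1,
               0.5 * A1 + sqrt(0.75) * stats::rnorm(npairs))
  Cf <- stats::rnorm(npairs)
  E1 <- stats::rnorm(npairs); E2 <- stats::rnorm(npairs)
  L1 <- a * A1 + cc * Cf + e * E1
  L2 <- a * A2 + cc * Cf + e * E2

  rng <- config$age_range[["NTR"]]
  if (is.null(rng)) rng <- c(25, 47)
  age_f <- stats::runif(npairs, rng[1], rng[2])
  sex1 <- ifelse(stats::rbinom(npairs, 1, config$sex_fraction) == 1, "F", "M")
  sex2 <- ifelse(zyg == "MZ", sex1,
                 ifelse(stats::rbinom(npairs, 1, config$sex_fraction) == 1,
                        "F", "M"))

  # interleave members so pair rows sit together
  ids <- as.vector(rbind(paste0(fam, "_T1"), paste0(fam, "_T2")))
  L <- as.vector(rbind(L1, L2))
  A <- as.vector(rbind(A1, A2))
  age <- rep(age_f, each = 2)
  sex <- as.vector(rbind(sex1, sex2))
  fam_id <- rep(fam, each = 2)
  zygosity <- rep(zyg, each = 2)

  om <- simulate_omics(config, L, A, ids)
  cov <- simulate_covariates(config, L, age, sex, ids)
  samples <- data.frame(sample_id = ids, cohort = "NTR",
                        family_id = fam_id, zygosity = zygosity,
                        cov[, -1L], stringsAsFactors = FALSE)
  truth <- truth_record(config, L, A, ids)
  c(list(samples = samples), om, list(truth = truth))
}

truth_record <- function(config, L, A, ids) {
  pp <- config$protein_panel
  structure(list(
    latent_trait = stats::setNames(L, ids),
    genetic_component = stats::setNames(A, ids),
    protein_classes = stats::setNames(pp$class, pp$name),
    planted_effects = list(
      metabolites = config$metabolite_loadings,
      cytokines = stats::setNames(config$cytokine_panel$trait_effect,
                                  config$cytokine_panel$name),
      proteins = stats::setNames(pp$effect, pp$name),
      proteins_genetic = stats::setNames(pp$genetic_effect, pp$name))),
    class = "truth_record")
}

#' Censor a feature matrix at per-feature lower detection limits
#'
#' Values strictly below their feature's limit are removed and flagged in the
#' below-LOD mask; values at or above the limit are untouched. The input is
#' not modified.
#'
#' @param matrix a [feature_matrix].
#' @param lods per-feature detection limits: a named numeric vector covering
#'   every feature, or `NULL` to use the limits recorded in `matrix$lod`.
#' @return A new censored [feature_matrix].
#' @export
apply_detection_limit <- function(matrix, lods = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (is.null(lods)) lods <- matrix$lod
  if (is.null(lods)) stop("no detection limits supplied or recorded")
  feats <- colnames(matrix$values)
  if (is.null(names(lods))) {
    if (length(lods) != length(feats))
      stop("`lods` length ", length(lods), " does not match ",
           length(feats), " features")
    names(lods) <- feats
  }
  if (!all(feats %in% names(lods)))
    stop("missing detection limit for feature: ",
         setdiff(feats, names(lods))[1L])
  lods <- lods[feats]
  if (!all(is.finite(lods))) stop("detection limits must be finite")
  vals <- matrix$values
  below <- matrix$below_lod
  hit <- !is.na(vals) & sweep(vals, 2L, lods, "<")
  vals[hit] <- NA_real_
  below <- below | hit
  feature_matrix(vals, below, lod = lods, platform = matrix$platform)
}

#' Inject completely-at-random missingness into a feature matrix
#'
#' Each cell is independently set missing with its feature's rate;
#' deterministic under `seed`. Cells already censored stay censored.
#'
#' @param matrix a [feature_matrix].
#' @param rate missingness rate(s) in `[0, 1]`: scalar or one per feature.
#' @param seed integer seed.
#' @return A new [feature_matrix].
#' @export
inject_missingness <- function(matrix, rate, seed = 1L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  p <- ncol(matrix$values)
  rate <- rep_len(rate, p)
  if (any(rate < 0 | rate > 1)) stop("missingness rate must lie in [0, 1]")
  set.seed(derive_seed(seed, "inject_missingness"))
  n <- nrow(matrix$values)
  hit <- matrix(stats::runif(n * p), n, p) <
    matrix(rate, n, p, byrow = TRUE)
  vals <- matrix$values
  vals[hit & !matrix$below_lod] <- NA_real_
  feature_matrix(vals, matrix$below_lod, lod = matrix$lod,
                 platform = matrix$platform)
}
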