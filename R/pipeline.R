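#' Score a metabolite panel end to end
#'
#' Convenience composition of the scoring pipeline: [log_transform],
#' [zscale_per_cohort], [project_score], then [residualize_on_age] fitted
#' separately within each cohort (selection happens within cohorts).
#'
#' @param metabolites a raw metabolite [feature_matrix].
#' @param coeffs a [score_coefficients].
#' @param samples sample table with `sample_id`, `cohort`, `age`.
#' @return A residualized `score_vector`.
#' @export
compute_score <- function(metabolites, coeffs, samples) {
  rownames(samples) <- samples$sample_id
  samples <- samples[rownames(metabolites$values), , drop = FALSE]
  prepped <- zscale_per_cohort(log_transform(metabolites), samples$cohort)
  sv <- project_score(prepped, coeffs)
  out <- sv
  for (coh in unique(samples$cohort)) {
    rows <- which(samples$cohort == coh)
    part <- sv[rows, , drop = FALSE]
    class(part) <- class(sv)
    part <- residualize_on_age(part, samples$age[rows])
    out$age_residual_score[rows] <- part$age_residual_score
  }
  out
}

#' Default pipeline configuration
#'
#' Bundles the generator configuration with the selection, preprocessing and
#' association settings of the full demo pipeline. The default simulated
#' world keeps the twin registry at its stated scale (726 MZ + 450 DZ
#' pairs) but downscales the population cohorts to 400 participants each so
#' the bundled demo runs in seconds; full-scale runs only change `sim`.
#'
#' @param sim a [sim_config].
#' @param n_cases extreme cases per cohort (default 25).
#' @param age_tolerance matching tolerance in years (default 2.5).
#' @param n_pairs discordant MZ pairs to select (default 25).
#' @param max_undetected_frac,k_sd,max_missing_frac,n_components,nipals_tol
#'   preprocessing thresholds (see [prep_cytokines], [prep_proteomics]).
#' @param covariate_sets named list of covariate column sets for the scans.
#' @param alpha FDR significance threshold for summary counts.
#' @param seed integer master seed; each stage derives a named substream.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(n_per_cohort = c(LLS = 400,
                                                              RS = 400)),
                            n_cases = 25, age_tolerance = 2.5, n_pairs = 25,
                            max_undetected_frac = 0.65, k_sd = 5,
                            max_missing_frac = 0.05, n_components = 5,
                            nipals_tol = 1e-4,
                            covariate_sets = list(
                              age_sex = c("age", "sex"),
                              age_sex_bmi = c("age", "sex", "bmi")),
                            alpha = 0.05, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]")
  structure(list(sim = sim, n_cases = n_cases,
                 age_tolerance = age_tolerance, n_pairs = n_pairs,
                 max_undetected_frac = max_undetected_frac, k_sd = k_sd,
                 max_missing_frac = max_missing_frac,
                 n_components = n_components, nipals_tol = nipals_tol,
                 covariate_sets = covariate_sets,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full contrast pipeline on simulated cohorts
#'
#' Simulates the configured cohorts, projects and residualizes the score,
#' selects extremes with matched controls (population cohorts) and the most
#' discordant MZ pairs (registry), censors and preprocesses the cytokine
#' panel, imputes and preprocesses the proteomics panel, then runs the
#' per-cohort association scans, the cross-cohort REML meta-analysis, the
#' twin heritability estimate, the within-pair mixed-model scan and the
#' population-vs-twin concordance summary. All stage outputs are written as
#' TSV/JSON under `out_dir` together with `summary.json` and a `MANIFEST`
#' of md5 content hashes; re-running with the same config and seed
#' reproduces every hash.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if absent).
#' @param seed optional override of `config$seed`.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$sim$seed <- config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(stage, ...) message("[", stage, "] ", ...)
  written <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (inherits(obj, "feature_matrix")) write_matrix(obj, path)
    else if (is.data.frame(obj))
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, force = TRUE)
    written <<- c(written, path)
    path
  }

  coeffs <- read_score_coefficients(
    system.file("extdata", "score_coefficients_synthetic.tsv",
                package = "metabocontrast"))

  logf("simulate", "generating population cohorts and twin registry")
  cohorts <- names(config$sim$n_per_cohort)
  pops <- lapply(cohorts, function(cl) simulate_population(config$sim, cl))
  names(pops) <- cohorts
  twins <- simulate_twin_registry(config$sim)

  summary <- list(seed = config$seed, cohorts = cohorts,
                  alpha = config$alpha)
  pop_scans <- list()
  designs <- list()
  for (cl in cohorts) {
    pop <- pops[[cl]]
    logf("score", cl)
    sv <- compute_score(pop$metabolites, coeffs, pop$samples)
    emit(sv, paste0("scores_", cl, ".tsv"))

    logf("select", cl)
    cases <- select_extreme_cases(sv, config$n_cases)
    design <- select_matched_controls(sv, cases, pop$samples,
                                      n_controls = config$n_cases,
                                      age_tolerance = config$age_tolerance)
    designs[[cl]] <- design
    sel <- c(design$case_ids, design$control_ids)
    emit(data.frame(sample_id = sel,
                    role = rep(c("case", "control"), each = config$n_cases)),
         paste0("design_", cl, ".tsv"))
    emit(design$matching_map, paste0("matching_map_", cl, ".json"))

    logf("prep", cl, ": cytokines")
    cyt <- apply_detection_limit(fm_subset(pop$cytokines, samples = sel))
    cohort_lab <- rep(cl, length(sel))
    pc <- prep_cytokines(cyt, design, cohort_lab,
                         max_undetected_frac = config$max_undetected_frac,
                         k_sd = config$k_sd)
    emit(pc$detectability, paste0("detectability_", cl, ".tsv"))
    emit(pc$matrix, paste0("cytokines_prepped_", cl, ".tsv"))

    logf("prep", cl, ": proteomics")
    prot <- inject_missingness(fm_subset(pop$proteins, samples = sel),
                               rate = 0.02,
                               seed = derive_seed(config$seed,
                                                  paste0("missing_", cl)))
    pp <- prep_proteomics(prot, cohort_lab,
                          max_missing_frac = config$max_missing_frac,
                          k_sd = config$k_sd,
                          n_components = config$n_components,
                          nipals_tol = config$nipals_tol)
    emit(pp$matrix, paste0("proteomics_prepped_", cl, ".tsv"))

    logf("associate", cl)
    covars <- pop$samples
    scan_c <- run_association_scan(pc$matrix, design, covars,
                                   config$covariate_sets)
    scan_p <- run_association_scan(pp$matrix, design, covars,
                                   config$covariate_sets)
    scan_c$platform <- "cytokine"; scan_p$platform <- "proteomics"
    emit(rbind(scan_c, scan_p), paste0("assoc_", cl, ".tsv"))
    pop_scans[[cl]] <- list(cytokine = scan_c, proteomics = scan_p)

    summary[[paste0("cohort_", cl)]] <- list(
      n = nrow(pop$samples), n_cases = length(design$case_ids),
      cytokines_retained = ncol(pc$matrix$values),
      cytokines_excluded = nrow(pc$reports$undetected$excluded_features),
      proteins_retained = ncol(pp$matrix$values),
      proteins_excluded = nrow(pp$reports$missing$excluded_features),
      protein_outliers = nrow(pp$reports$outliers$outlier_cells),
      protein_imputed = nrow(pp$reports$imputed$imputed_cells),
      significant = count_sig(rbind(scan_c, scan_p), config$alpha))
  }

  logf("meta", "REML meta-analysis across population cohorts")
  first_set <- names(config$covariate_sets)[1L]
  meta_p <- run_meta_scan(lapply(pop_scans, function(s)
    s$proteomics[s$proteomics$covariate_set == first_set, ]))
  emit(meta_p, "meta_proteomics.tsv")
  summary$meta <- list(covariate_set = first_set,
                       n_features = nrow(meta_p),
                       significant = sum(meta_p$fdr <= config$alpha),
                       median_tau2 = stats::median(meta_p$tau2))

  logf("twin", "heritability and within-pair scan")
  sv_t <- compute_score(twins$metabolites, coeffs, twins$samples)
  emit(sv_t, "scores_NTR.tsv")
  her <- estimate_heritability(sv_t, twins$samples)
  emit(unclass(her), "heritability.json")
  tdesign <- select_discordant_pairs(sv_t, twins$samples, config$n_pairs)
  emit(tdesign$pair_map, "design_NTR.tsv")

  sel_t <- c(tdesign$case_ids, tdesign$control_ids)
  cyt_t <- apply_detection_limit(fm_subset(twins$cytokines,
                                           samples = sel_t))
  pc_t <- prep_cytokines(cyt_t, tdesign, rep("NTR", length(sel_t)),
                         max_undetected_frac = config$max_undetected_frac,
                         k_sd = config$k_sd)
  prot_t <- fm_subset(twins$proteins, samples = sel_t)
  pp_t <- prep_proteomics(prot_t, rep("NTR", length(sel_t)),
                          max_missing_frac = config$max_missing_frac,
                          k_sd = config$k_sd,
                          n_components = config$n_components,
                          nipals_tol = config$nipals_tol)
  twin_scan <- run_twin_scan(pp_t$matrix, tdesign, twins$samples,
                             config$covariate_sets[1L])
  twin_scan$platform <- "proteomics"
  emit(twin_scan, "assoc_NTR.tsv")

  logf("concordance", "population meta vs within-pair scan")
  conc <- beta_beta_concordance(meta_p, twin_scan, alpha = config$alpha)
  emit(conc$pairs, "beta_beta_pairs.tsv")

  summary$twin <- list(
    r_mz = her$r_mz, r_dz = her$r_dz, h2 = her$h2,
    n_mz_pairs = her$n_mz_pairs, n_dz_pairs = her$n_dz_pairs,
    n_discordant_pairs = nrow(tdesign$pair_map),
    mean_pair_score_diff = mean(tdesign$pair_map$score_diff),
    significant_within_pair = sum(twin_scan$fdr <= config$alpha))
  summary$concordance <- as.list(conc$counts)

  emit(summary, "summary.json")
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  utils::write.table(manifest, file.path(out_dir, "MANIFEST"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logf("done", length(written), " files written to ", out_dir)
  invisible(summary)
}

count_sig <- function(scan, alpha) {
  parts <- split(scan, list(scan$platform, scan$covariate_set), drop = TRUE)
  out <- lapply(parts, function(s)
    list(total = nrow(s), significant = sum(s$fdr <= alpha),
         positive = sum(s$fdr <= alpha & s$estimate > 0),
         negative = sum(s$fdr <= alpha & s$estimate < 0)))
  out
}
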