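#' Contrast designs: extreme cases vs matched controls, or discordant pairs
#'
#' A `contrast_design` records who is compared with whom. In `population`
#' mode it holds equally sized, disjoint case and control id sets plus a
#' matching map (case id -> admissible matched controls). In `twin` mode it
#' holds the selected pairs (`pair_map`: pair id, higher-scoring member =
#' case, lower-scoring member = control, absolute score difference).
#' @name contrast_design
NULL

new_contrast_design <- function(mode, case_ids, control_ids,
                                matching_map = NULL, pair_map = NULL) {
  if (length(intersect(case_ids, control_ids)) > 0L)
    stop("case and control sets must be disjoint")
  structure(list(mode = mode, case_ids = case_ids, control_ids = control_ids,
                 matching_map = matching_map, pair_map = pair_map),
            class = "contrast_design")
}

#' @export
print.contrast_design <- function(x, ...) {
  cat(sprintf("contrast_design [%s]: %d cases, %d controls\n",
              x$mode, length(x$case_ids), length(x$control_ids)))
  invisible(x)
}

# ids sorted by value desc (or asc), ties broken lexicographically by id
order_by_score <- function(ids, values, decreasing = TRUE) {
  o <- order(if (decreasing) -values else values, ids, method = "radix")
  ids[o]
}

#' Select the samples with the most extreme age-independent scores
#'
#' Returns the `n_cases` sample ids with the largest `age_residual_score`
#' (ties broken lexicographically by sample id, for reproducibility).
#'
#' @param scores a `score_vector` with `age_residual_score` filled in.
#' @param n_cases number of cases, `1 <= n_cases <=` population size.
#' @return Character vector of case ids.
#' @export
select_extreme_cases <- function(scores, n_cases) {
  stopifnot(inherits(scores, "score_vector"))
  if (n_cases <= 0) stop("`n_cases` must be positive")
  s <- scores$age_residual_score
  if (all(is.na(s))) stop("scores must be residualized first")
  if (n_cases > nrow(scores)) stop("`n_cases` exceeds population size")
  order_by_score(scores$sample_id, s)[seq_len(n_cases)]
}

#' Select low-score controls matched to the cases on age and sex
#'
#' Walks the non-case candidates in ascending age-independent score and
#' admits a candidate if and only if at least one case has identical sex and
#' an absolute age difference within `age_tolerance`; stops once
#' `n_controls` controls are admitted (greedy, not optimal bipartite
#' matching). The matching map records, per case, every admitted control
#' that qualifies against it.
#'
#' @param scores a residualized `score_vector` covering cases and candidates.
#' @param cases case ids from [select_extreme_cases].
#' @param covars sample table with columns `sample_id`, `age`, `sex`.
#' @param n_controls controls to admit (default: one per case).
#' @param age_tolerance maximum |age difference| in years (default 2.5; the
#'   matching criterion itself is a design choice, see the vignette).
#' @return A `population`-mode [contrast_design].
#' @export
select_matched_controls <- function(scores, cases, covars,
                                    n_controls = length(cases),
                                    age_tolerance = 2.5) {
  stopifnot(inherits(scores, "score_vector"))
  if (age_tolerance < 0) stop("`age_tolerance` must be non-negative")
  if (!all(cases %in% scores$sample_id))
    stop("unknown case id: ", setdiff(cases, scores$sample_id)[1L])
  rownames(covars) <- covars$sample_id
  if (!all(scores$sample_id %in% covars$sample_id))
    stop("covariate table missing sample: ",
         setdiff(scores$sample_id, covars$sample_id)[1L])

  cand <- scores[!scores$sample_id %in% cases, , drop = FALSE]
  cand_ids <- order_by_score(cand$sample_id, cand$age_residual_score,
                             decreasing = FALSE)
  case_age <- covars[cases, "age"]
  case_sex <- covars[cases, "sex"]

  controls <- character(0)
  map <- stats::setNames(vector("list", length(cases)), cases)
  for (id in cand_ids) {
    if (length(controls) >= n_controls) break
    ok <- case_sex == covars[id, "sex"] &
      abs(case_age - covars[id, "age"]) <= age_tolerance
    if (any(ok)) {
      controls <- c(controls, id)
      for (cs in cases[ok]) map[[cs]] <- c(map[[cs]], id)
    }
  }
  if (length(controls) < n_controls) {
    unmatched <- cases[vapply(map, length, 1L) == 0L]
    stop("only ", length(controls), " of ", n_controls,
         " admissible controls found; cases with no qualifying candidate: ",
         if (length(unmatched)) paste(unmatched, collapse = ", ")
         else "(none)")
  }
  new_contrast_design("population", cases, controls, matching_map = map)
}

#' Select the most score-discordant complete monozygotic twin pairs
#'
#' Complete MZ pairs (two members sharing a family id, both scored) are
#' ranked by absolute within-pair score difference, descending, ties broken
#' by family id; the top `n_pairs` are taken and within each the
#' higher-scoring member is labelled the case. Incomplete pairs (one member
#' lacking a score) are dropped with a warning.
#'
#' @param scores a residualized `score_vector`. Co-twins share their age, so
#'   within-pair differences are identical on the raw and the
#'   age-residualized scale.
#' @param covars sample table with `sample_id`, `family_id`, `zygosity`.
#' @param n_pairs number of pairs to select.
#' @return A `twin`-mode [contrast_design]; `pair_map` is a data.frame with
#'   columns `pair_id`, `high_id`, `low_id`, `score_diff`.
#' @export
select_discordant_pairs <- function(scores, covars, n_pairs) {
  stopifnot(inherits(scores, "score_vector"))
  if (n_pairs <= 0) stop("`n_pairs` must be positive")
  s <- stats::setNames(scores$age_residual_score, scores$sample_id)
  if (all(is.na(s))) s <- stats::setNames(scores$raw_score, scores$sample_id)
  mz <- covars[!is.na(covars$zygosity) & covars$zygosity == "MZ", ,
               drop = FALSE]
  fams <- split(mz$sample_id, mz$family_id)
  rows <- lapply(names(fams), function(f) {
    members <- sort(fams[[f]])
    scored <- members[members %in% names(s) & !is.na(s[members])]
    if (length(scored) != 2L) {
      warning("incomplete MZ pair ", f, " excluded (",
              length(scored), " scored member(s))", call. = FALSE)
      return(NULL)
    }
    hi <- if (s[scored[1L]] >= s[scored[2L]]) scored[1L] else scored[2L]
    lo <- setdiff(scored, hi)
    data.frame(pair_id = f, high_id = hi, low_id = lo,
               score_diff = abs(s[scored[1L]] - s[scored[2L]]),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) < n_pairs)
    stop("`n_pairs` (", n_pairs, ") exceeds the ",
         if (is.null(pairs)) 0L else nrow(pairs), " available complete MZ pairs")
  o <- order(-pairs$score_diff, pairs$pair_id, method = "radix")
  sel <- pairs[o[seq_len(n_pairs)], , drop = FALSE]
  rownames(sel) <- NULL
  new_contrast_design("twin", sel$high_id, sel$low_id, pair_map = sel)
}

#' Case/control status vector of a contrast design
#'
#' @param design a [contrast_design].
#' @return Named integer vector (1 = case, 0 = control) over the design's
#'   samples, cases first.
#' @export
design_status <- function(design) {
  stopifnot(inherits(design, "contrast_design"))
  stats::setNames(rep(c(1L, 0L), c(length(design$case_ids),
                                   length(design$control_ids))),
                  c(design$case_ids, design$control_ids))
}
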