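#' Sample-by-feature matrix with missing and below-LOD masks
#'
#' The central container of the package: a numeric matrix (samples as rows,
#' features as columns) together with a logical below-LOD mask of the same
#' shape and optional per-feature lower detection limits. Unobserved cells
#' hold `NA` in `values`; a cell is *below-LOD* when its mask entry is `TRUE`
#' (the value has been removed by censoring) and *missing* when it is `NA`
#' without the censoring flag.
#'
#' @param values numeric matrix with unique row names (sample ids) and unique
#'   column names (feature names). `NA` marks unobserved cells.
#' @param below_lod optional logical matrix of the same dimension; `TRUE`
#'   where a value was removed because it fell below the detection limit.
#' @param lod optional named numeric vector of per-feature lower detection
#'   limits (on the measurement scale).
#' @param platform optional platform label (e.g. `"metabolomics"`,
#'   `"cytokine"`, `"proteomics"`), carried as metadata.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, below_lod = NULL, lod = NULL,
                           platform = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("`values` must have sample ids as rownames")
  if (ncol(values) > 0L && is.null(colnames(values)))
    stop("`values` must have feature names as colnames")
  if (is.null(dimnames(values)))
    dimnames(values) <- list(character(0), character(0))
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature name: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (is.null(below_lod)) {
    below_lod <- matrix(FALSE, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  }
  if (!identical(dim(below_lod), dim(values)))
    stop("`below_lod` must have the same dimension as `values`")
  dimnames(below_lod) <- dimnames(values)
  if (any(below_lod & !is.na(values)))
    stop("below-LOD cells must have their value removed (NA)")
  if (!is.null(lod)) {
    if (is.null(names(lod)) || !all(colnames(values) %in% names(lod)))
      stop("`lod` must be named and cover every feature")
    lod <- lod[colnames(values)]
  }
  structure(list(values = values, below_lod = below_lod, lod = lod,
                 platform = platform),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("feature_matrix: %d samples x %d features%s\n",
              nrow(v), ncol(v),
              if (is.null(x$platform)) "" else paste0(" [", x$platform, "]")))
  cat(sprintf("  missing: %d cells, below-LOD: %d cells\n",
              sum(is.na(v) & !x$below_lod), sum(x$below_lod)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Sample ids and feature names of a feature matrix
#' @param x a [feature_matrix]
#' @return character vector.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
feature_names <- function(x) colnames(x$values)

#' Subset a feature matrix by sample ids and/or feature names
#' @param x a [feature_matrix]
#' @param samples,features character vectors of row/column names (or indices);
#'   `NULL` keeps all.
#' @return A new [feature_matrix].
#' @export
fm_subset <- function(x, samples = NULL, features = NULL) {
  if (is.null(samples)) samples <- rownames(x$values)
  if (is.null(features)) features <- colnames(x$values)
  if (is.character(samples) && !all(samples %in% rownames(x$values)))
    stop("unknown sample id: ", setdiff(samples, rownames(x$values))[1L])
  if (is.character(features) && !all(features %in% colnames(x$values)))
    stop("unknown feature: ", setdiff(features, colnames(x$values))[1L])
  feature_matrix(x$values[samples, features, drop = FALSE],
                 x$below_lod[samples, features, drop = FALSE],
                 lod = if (is.null(x$lod)) NULL else x$lod[features],
                 platform = x$platform)
}

#' Logical masks of a feature matrix
#'
#' `fm_missing()` is `TRUE` where a cell is missing (unobserved but not
#' censored); `fm_observed()` where a value is present.
#' @param x a [feature_matrix]
#' @return logical matrix with the dimensions of `x`.
#' @export
fm_missing <- function(x) is.na(x$values) & !x$below_lod

#' @rdname fm_missing
#' @export
fm_observed <- function(x) !is.na(x$values)

#' Read and write feature matrices as TSV
#'
#' The TSV dialect has a header of feature names, a first column `sample_id`,
#' empty cells for unobserved values, UTF-8 and Unix newlines. Censoring is
#' carried in a companion mask TSV of the same shape whose cells are either
#' empty or the token `"<LOD"`. Round-tripping write then read is lossless
#' for values (15 significant digits), masks and ordering.
#'
#' @param path path of the value TSV.
#' @param mask_path optional path of the companion below-LOD mask TSV. For
#'   `write_matrix` the mask file is only written when the matrix contains
#'   censored cells (default path: value path with `_mask.tsv` suffix).
#' @param platform optional platform label attached on read.
#' @return `read_matrix` returns a [feature_matrix]; `write_matrix` returns
#'   `path` invisibly.
#' @export
read_matrix <- function(path, mask_path = NULL, platform = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = "")
  if (names(df)[1L] != "sample_id")
    stop("first column of ", path, " must be `sample_id`")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample id in ", path, ": ", ids[duplicated(ids)][1L])
  raw <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(vals <- matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(vals) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric cell in ", path, ": sample ", ids[bad[1L, 1L]],
         ", feature ", colnames(raw)[bad[1L, 2L]],
         " = \"", raw[bad[1L, , drop = FALSE]], "\"")
  dimnames(vals) <- list(ids, colnames(raw))
  below <- NULL
  if (!is.null(mask_path) && file.exists(mask_path)) {
    mdf <- utils::read.delim(mask_path, check.names = FALSE,
                             colClasses = "character", na.strings = "")
    if (!identical(names(mdf)[1L], "sample_id"))
      stop("first column of ", mask_path, " must be `sample_id`")
    if (!all(names(mdf)[-1L] %in% colnames(vals)))
      stop("mask file references unknown feature: ",
           setdiff(names(mdf)[-1L], colnames(vals))[1L])
    if (!all(mdf$sample_id %in% ids))
      stop("mask file references unknown sample: ",
           setdiff(mdf$sample_id, ids)[1L])
    mraw <- as.matrix(mdf[, -1L, drop = FALSE])
    rownames(mraw) <- mdf$sample_id
    below <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
    below[mdf$sample_id, colnames(mraw)] <- !is.na(mraw) & mraw == "<LOD"
    vals[below] <- NA_real_
  }
  feature_matrix(vals, below, platform = platform)
}

#' @param matrix a [feature_matrix] to write.
#' @rdname read_matrix
#' @export
write_matrix <- function(matrix, path, mask_path = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  v <- matrix$values
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.15g", x))
  body <- apply(v, 2L, fmt)
  if (nrow(v) == 1L) body <- t(body)  # apply drops to vector
  df <- data.frame(sample_id = rownames(v), body, check.names = FALSE)
  names(df) <- c("sample_id", colnames(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  if (any(matrix$below_lod)) {
    if (is.null(mask_path))
      mask_path <- sub("\\.tsv$", "", path)
    if (!grepl("_mask\\.tsv$", mask_path))
      mask_path <- paste0(mask_path, "_mask.tsv")
    mk <- ifelse(matrix$below_lod, "<LOD", "")
    mdf <- data.frame(sample_id = rownames(v), mk, check.names = FALSE)
    names(mdf) <- c("sample_id", colnames(v))
    utils::write.table(mdf, mask_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}
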