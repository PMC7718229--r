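## sample labels look like CT{tt}_r{k}; parse to (time, replicate)
parse_sample_labels <- function(labels) {
  m <- regmatches(labels, regexec("^CT([0-9]+(?:\\.[0-9]+)?)_r([0-9]+)$", labels))
  bad <- labels[vapply(m, length, integer(1)) == 0L]
  if (length(bad) > 0) {
    stop("sample label(s) not of the form CT{tt}_r{k}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(
    label = labels,
    time_h = vapply(m, function(x) as.numeric(x[2]), numeric(1)),
    replicate = vapply(m, function(x) as.integer(x[3]), integer(1)),
    stringsAsFactors = FALSE
  )
}

## check labels cover every grid timepoint with a constant replicate count
validate_labels_against_grid <- function(parsed, grid) {
  t_grid <- grid_times(grid)
  off <- parsed$label[!parsed$time_h %in% t_grid]
  if (length(off) > 0) {
    stop("sample label(s) at times not on the grid: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  counts <- table(parsed$time_h)
  missing <- t_grid[!t_grid %in% as.numeric(names(counts))]
  if (length(missing) > 0) {
    stop("grid timepoint(s) missing from the matrix: CT",
         paste(missing, collapse = ", CT"), call. = FALSE)
  }
  if (length(unique(counts)) != 1L) {
    stop("unequal replicate counts across timepoints", call. = FALSE)
  }
  invisible(parsed)
}

#' Read an expression matrix from TSV
#'
#' Expects a header of sample labels of the form `CT{tt}_r{k}`, a leading
#' `gene_id` column, and a numeric body. The labels are validated against the
#' sampling grid: every grid timepoint must be present with the same
#' replicate count, and no label may fall off the grid. Row order is
#' preserved; duplicate gene ids, ragged rows and negative values are
#' rejected with messages naming the offender.
#'
#' @param path Path to a TSV written as by [write_expression_tsv()].
#' @param grid A [sampling_grid()].
#' @return Numeric matrix (genes x samples) with gene ids as row names and
#'   sample labels as column names.
#' @export
read_expression_matrix <- function(path, grid) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "gene_id") {
    stop("expected a `gene_id` first column in ", path, call. = FALSE)
  }
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    stop("non-numeric values in the matrix body of ", path, call. = FALSE)
  }
  if (anyNA(mat)) {
    bad <- ids[apply(is.na(mat), 1, any)]
    stop("missing values in row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(mat < 0)) {
    bad <- ids[apply(mat < 0, 1, any)]
    stop("negative values in row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  rownames(mat) <- ids
  parsed <- parse_sample_labels(colnames(mat))
  validate_labels_against_grid(parsed, grid)
  mat
}

#' Remove genes with any zero expression
#'
#' Retains exactly the genes whose value is strictly positive in every sample
#' (every replicate and timepoint); order is preserved. Genes with zeros
#' cannot enter the geometric-mean reference of the size-factor estimator and
#' are excluded from the oscillation analysis.
#'
#' @param mat Numeric matrix, genes x samples.
#' @return The filtered matrix (possibly with zero rows).
#' @export
filter_zero_genes <- function(mat) {
  stopifnot(is.matrix(mat))
  keep <- apply(mat > 0, 1, all)
  mat[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample `j`, the size factor is the median over genes of
#' `value[g, j] / geomean(g)`, where `geomean(g)` is the geometric mean of
#' gene `g` across samples, computed over the genes positive in every sample.
#' This is the standard count-normalization estimator for sequencing
#' libraries; the median of an even number of ratios is the mean of the two
#' central values. The factors are standardized to unit geometric mean, which
#' leaves all between-sample ratios untouched and makes the estimator
#' idempotent: the size factors of an already-normalized matrix are exactly 1.
#'
#' @param mat Numeric non-negative matrix, genes x samples, with at least one
#'   all-positive gene row.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 1)
  pos <- apply(mat > 0, 1, all)
  if (!any(pos)) {
    stop("no gene is positive in every sample; run filter_zero_genes() first",
         call. = FALSE)
  }
  m <- mat[pos, , drop = FALSE]
  log_geomean <- rowMeans(log(m))
  log_sf <- apply(m, 2, function(col) stats::median(log(col) - log_geomean))
  sf <- exp(log_sf - mean(log_sf))   # unit geometric mean
  stats::setNames(sf, colnames(mat))
}

#' Normalize samples by size factors
#'
#' Divides each column by its size factor.
#'
#' @param mat Numeric matrix, genes x samples.
#' @param factors Positive numeric vector of length `ncol(mat)`.
#' @return Normalized matrix of the same shape.
#' @export
normalize_matrix <- function(mat, factors) {
  stopifnot(is.matrix(mat), length(factors) == ncol(mat))
  if (any(factors <= 0) || any(!is.finite(factors))) {
    stop("size factors must be positive and finite", call. = FALSE)
  }
  sweep(mat, 2, factors, "/")
}

#' Average replicates at each timepoint
#'
#' Returns, per gene, the arithmetic mean across replicates at each grid
#' timepoint, with columns ordered by time. Sample labels must parse as
#' `CT{tt}_r{k}` and cover the grid with a constant replicate count.
#'
#' @param mat Numeric matrix, genes x samples, with `CT{tt}_r{k}` column
#'   names.
#' @param grid A [sampling_grid()].
#' @return Numeric matrix, genes x `grid$n_points`, columns named `CT{tt}`.
#' @export
average_replicates <- function(mat, grid) {
  stopifnot(is.matrix(mat))
  parsed <- parse_sample_labels(colnames(mat))
  validate_labels_against_grid(parsed, grid)
  t_grid <- grid_times(grid)
  out <- matrix(0, nrow = nrow(mat), ncol = length(t_grid),
                dimnames = list(rownames(mat), sprintf("CT%g", t_grid)))
  for (i in seq_along(t_grid)) {
    cols <- parsed$label[parsed$time_h == t_grid[i]]
    out[, i] <- rowMeans(mat[, cols, drop = FALSE])
  }
  out
}
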