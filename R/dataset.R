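#' Construct a transposable dataset
#'
#' A transposable dataset holds N independent subject-level r x c matrices
#' sharing the same row labels (e.g. genes) and column labels (e.g. tissues).
#' Values are stored as an r x c x N array; every subject's matrix uses the
#' identical row/column label order.
#'
#' @param values numeric array of dimension r x c x N (or an r x c matrix for
#'   N = 1). All entries must be finite.
#' @param row_ids,col_ids,subject_ids character vectors of unique labels; when
#'   \code{NULL} they are taken from \code{dimnames(values)} or auto-generated.
#' @return An object of class \code{"transposable_dataset"}: a list with
#'   elements \code{values} (labelled r x c x N array), \code{row_ids},
#'   \code{col_ids} and \code{subject_ids}.
#' @examples
#' x <- array(rnorm(24), dim = c(4, 3, 2))
#' ds <- transposable_dataset(x)
#' dim(ds)
#' @export
transposable_dataset <- function(values, row_ids = NULL, col_ids = NULL,
                                 subject_ids = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be an r x c x N array (or an r x c matrix)")
  storage.mode(values) <- "double"
  d <- dim(values)
  if (any(d < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(values)))
    stop("all values must be finite (no NA/NaN/Inf)")
  dn <- dimnames(values)
  pick <- function(given, stored, n, prefix) {
    ids <- if (!is.null(given)) as.character(given)
           else if (!is.null(stored)) as.character(stored)
           else sprintf("%s%0*d", prefix, nchar(n), seq_len(n))
    if (length(ids) != n)
      stop(sprintf("expected %d %s ids, got %d", n, prefix, length(ids)))
    if (anyDuplicated(ids))
      stop(sprintf("duplicate %s id: '%s'", prefix, ids[duplicated(ids)][1L]))
    if (any(!nzchar(ids))) stop(sprintf("empty %s id not allowed", prefix))
    ids
  }
  row_ids <- pick(row_ids, dn[[1L]], d[1L], "g")
  col_ids <- pick(col_ids, dn[[2L]], d[2L], "t")
  subject_ids <- pick(subject_ids, dn[[3L]], d[3L], "s")
  dimnames(values) <- list(row_ids, col_ids, subject_ids)
  structure(list(values = values, row_ids = row_ids, col_ids = col_ids,
                 subject_ids = subject_ids),
            class = "transposable_dataset")
}

#' @export
dim.transposable_dataset <- function(x) dim(x$values)

#' Number of subjects, rows and columns
#' @param ds a \code{transposable_dataset}.
#' @return integer count.
#' @export
n_subjects <- function(ds) dim(ds$values)[3L]

#' @rdname n_subjects
#' @export
n_rows <- function(ds) dim(ds$values)[1L]

#' @rdname n_subjects
#' @export
n_cols <- function(ds) dim(ds$values)[2L]

#' @export
print.transposable_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("transposable_dataset: %d rows x %d columns x %d subjects\n",
              d[1L], d[2L], d[3L]))
  cat("  rows:     ", paste(utils::head(x$row_ids, 4L), collapse = ", "),
      if (d[1L] > 4L) ", ..." else "", "\n", sep = "")
  cat("  columns:  ", paste(utils::head(x$col_ids, 6L), collapse = ", "),
      if (d[2L] > 6L) ", ..." else "", "\n", sep = "")
  cat("  subjects: ", paste(utils::head(x$subject_ids, 6L), collapse = ", "),
      if (d[3L] > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Subset a transposable dataset by row and/or column labels
#'
#' Selection is label-driven and order-preserving: the result's rows and
#' columns appear in exactly the requested order. Subjects are unchanged.
#'
#' @param x a \code{transposable_dataset}.
#' @param rows optional character vector of row ids to keep (in this order).
#' @param cols optional character vector of column ids to keep (in this order).
#' @param ... ignored.
#' @return A \code{transposable_dataset} restricted to the requested labels.
#' @export
subset.transposable_dataset <- function(x, rows = NULL, cols = NULL, ...) {
  sel <- function(ids, want, what) {
    if (is.null(want)) return(ids)
    want <- as.character(want)
    if (length(want) == 0L) stop(sprintf("empty %s selection", what))
    miss <- setdiff(want, ids)
    if (length(miss))
      stop(sprintf("unknown %s id(s): %s", what,
                   paste(utils::head(miss, 5L), collapse = ", ")))
    if (anyDuplicated(want))
      stop(sprintf("duplicated %s id in selection", what))
    want
  }
  r <- sel(x$row_ids, rows, "row")
  co <- sel(x$col_ids, cols, "column")
  transposable_dataset(x$values[r, co, , drop = FALSE],
                       row_ids = r, col_ids = co,
                       subject_ids = x$subject_ids)
}

#' Drop low-expression rows by their total across columns
#'
#' Mirrors the usual expression filter in multi-tissue RNAseq work: a gene is
#' removed when the sum of its values across the tissues falls below a
#' threshold. With several subjects the rule needs a reduction:
#' \code{"mean_over_subjects"} (default) drops row a iff the subject-averaged
#' row total is below the threshold; \code{"per_subject_any"} drops row a iff
#' any single subject's row total is below it.
#'
#' @param ds a \code{transposable_dataset}.
#' @param threshold nonnegative cutoff on the row total (e.g. 0.1 on RPKM).
#' @param reduction how subjects are combined; see Details.
#' @return A list with elements \code{dataset} (the filtered
#'   \code{transposable_dataset}, surviving rows in their original order) and
#'   \code{dropped_rows} (character vector of removed row ids).
#' @examples
#' ds <- transposable_dataset(array(c(0.01, 1, 0.04, 1), c(2, 2, 1)))
#' filter_rows_by_total(ds, threshold = 0.1)$dropped_rows
#' @export
filter_rows_by_total <- function(ds, threshold = 0.1,
                                 reduction = c("mean_over_subjects",
                                               "per_subject_any")) {
  stopifnot(inherits(ds, "transposable_dataset"))
  reduction <- match.arg(reduction)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("'threshold' must be a single nonnegative number")
  d <- dim(ds$values)
  ## row totals per subject: r x N
  tot <- apply(ds$values, c(1L, 3L), sum)
  tot <- matrix(tot, nrow = d[1L])
  drop <- switch(reduction,
    mean_over_subjects = rowMeans(tot) < threshold,
    per_subject_any = apply(tot < threshold, 1L, any))
  if (all(drop)) stop("filter would drop every row; lower the threshold")
  keep <- ds$row_ids[!drop]
  list(dataset = subset(ds, rows = keep),
       dropped_rows = ds$row_ids[drop])
}

#' Mean-free pair difference of two subjects
#'
#' D = (X_i - X_j) / sqrt(2) has mean zero and the same Kronecker covariance
#' as a single subject matrix, which makes it the basic building block of the
#' U-statistic estimators in this package.
#'
#' @param ds a \code{transposable_dataset}.
#' @param i,j distinct subject indices (1-based) or subject ids.
#' @return r x c numeric matrix.
#' @export
pair_difference <- function(ds, i, j) {
  stopifnot(inherits(ds, "transposable_dataset"))
  res <- function(k) {
    if (is.character(k)) k <- match(k, ds$subject_ids)
    k <- as.integer(k)
    if (is.na(k) || k < 1L || k > n_subjects(ds))
      stop("unknown subject index/id")
    k
  }
  i <- res(i); j <- res(j)
  if (i == j) stop("subject indices must be distinct (i != j)")
  d <- dim(ds$values)
  matrix((ds$values[, , i] - ds$values[, , j]) / sqrt(2), d[1L], d[2L],
         dimnames = list(ds$row_ids, ds$col_ids))
}
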