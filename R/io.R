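## File I/O for transposable datasets.
##
## Long format (canonical interchange): one delimited file with header
##   subject_id <delim> row_id <delim> col_id <delim> value
## and exactly one line per (subject, row, column) triple.
##
## Wide format: one delimited matrix file per subject (header = column ids,
## first column = row ids) bound together by a two-column manifest
## (subject_id <delim> file path, relative paths resolved against the
## manifest's directory).

#' Load a transposable dataset from a long-format table
#'
#' @param path path to a delimited text file with header columns
#'   \code{subject_id}, \code{row_id}, \code{col_id}, \code{value}.
#' @param delimiter field separator (default tab).
#' @return A \code{\link{transposable_dataset}}. Subject, row and column
#'   orders follow first appearance in the file.
#' @export
load_long_table <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = c(NA, NA, NA, NA),
                           stringsAsFactors = FALSE, check.names = TRUE,
                           comment.char = "", quote = "\"")
  need <- c("subject_id", "row_id", "col_id", "value")
  if (!all(need %in% names(tab)))
    stop("long table must have header columns: ",
         paste(need, collapse = ", "))
  val <- tab$value
  if (is.character(val)) {
    val <- suppressWarnings(as.numeric(val))
  }
  if (!is.numeric(val) || anyNA(val))
    stop("non-numeric 'value' entries in long table")
  subj <- as.character(tab$subject_id)
  rid <- as.character(tab$row_id)
  cid <- as.character(tab$col_id)
  subjects <- unique(subj); rows <- unique(rid); cols <- unique(cid)
  N <- length(subjects); r <- length(rows); cc <- length(cols)
  ri <- match(rid, rows); ci <- match(cid, cols); si <- match(subj, subjects)
  pos <- ri + (ci - 1L) * r + (si - 1L) * r * cc
  if (anyDuplicated(pos)) {
    k <- pos[duplicated(pos)][1L]
    w <- which(pos == k)[1L]
    stop(sprintf("duplicate triple (%s, %s, %s) in long table",
                 subj[w], rid[w], cid[w]))
  }
  if (length(pos) != N * r * cc) {
    all_pos <- seq_len(N * r * cc)
    k <- setdiff(all_pos, pos)[1L]
    s0 <- (k - 1L) %/% (r * cc) + 1L
    rest <- (k - 1L) %% (r * cc)
    c0 <- rest %/% r + 1L
    r0 <- rest %% r + 1L
    stop(sprintf("incomplete cube: missing triple (%s, %s, %s)",
                 subjects[s0], rows[r0], cols[c0]))
  }
  cube <- array(NA_real_, dim = c(r, cc, N))
  cube[pos] <- val
  transposable_dataset(cube, row_ids = rows, col_ids = cols,
                       subject_ids = subjects)
}

#' Load a transposable dataset from per-subject wide matrices
#'
#' @param manifest path to a two-column delimited file (no header required;
#'   a header line \code{subject_id} / \code{path} is tolerated) mapping each
#'   subject id to its matrix file. Relative paths are resolved against the
#'   manifest's directory.
#' @param delimiter field separator used in the manifest and matrix files.
#' @return A \code{\link{transposable_dataset}}. Row/column order follows the
#'   first subject's file; later files may list labels in any order but must
#'   carry the identical label sets.
#' @export
load_wide_matrices <- function(manifest, delimiter = "\t") {
  man <- utils::read.table(manifest, header = FALSE, sep = delimiter,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (ncol(man) < 2L) stop("manifest must have two columns: subject_id, path")
  if (identical(tolower(man[1L, 1L]), "subject_id")) man <- man[-1L, , drop = FALSE]
  subjects <- as.character(man[[1L]])
  paths <- as.character(man[[2L]])
  if (anyDuplicated(subjects))
    stop("duplicate subject_id in manifest: ",
         subjects[duplicated(subjects)][1L])
  base <- dirname(manifest)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", paths), paths,
                  file.path(base, paths))
  mats <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    m <- utils::read.table(paths[k], header = TRUE, sep = delimiter,
                           row.names = 1L, check.names = FALSE,
                           comment.char = "", quote = "\"")
    m <- as.matrix(m)
    if (!is.numeric(m))
      stop(sprintf("non-numeric entries in matrix file for subject '%s'",
                   subjects[k]))
    if (k == 1L) {
      rows <- rownames(m); cols <- colnames(m)
    } else {
      if (!setequal(rownames(m), rows) || !setequal(colnames(m), cols))
        stop(sprintf("label-set mismatch for subject '%s'", subjects[k]))
      m <- m[rows, cols, drop = FALSE]
    }
    mats[[k]] <- m
  }
  cube <- array(unlist(mats, use.names = FALSE),
                dim = c(length(rows), length(cols), length(subjects)))
  transposable_dataset(cube, row_ids = rows, col_ids = cols,
                       subject_ids = subjects)
}

#' Write a transposable dataset to disk
#'
#' @param ds a \code{\link{transposable_dataset}}.
#' @param path for \code{format = "long"}, the output file; for
#'   \code{format = "wide"}, an output directory (created if missing) that
#'   will receive one matrix file per subject plus \code{manifest.tsv}.
#' @param format \code{"long"} or \code{"wide"}.
#' @param delimiter field separator.
#' @return Invisibly, the path(s) written. Values are formatted with 17
#'   significant digits so that a write/load round trip reproduces the cube
#'   to floating-point precision.
#' @export
write_dataset <- function(ds, path, format = c("long", "wide"),
                          delimiter = "\t") {
  stopifnot(inherits(ds, "transposable_dataset"))
  format <- match.arg(format)
  fmt <- function(x) sprintf("%.17g", x)
  if (format == "long") {
    d <- dim(ds$values)
    grid <- expand.grid(row_id = ds$row_ids, col_id = ds$col_ids,
                        subject_id = ds$subject_ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(subject_id = grid$subject_id, row_id = grid$row_id,
                      col_id = grid$col_id,
                      value = fmt(as.vector(ds$values)),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    return(invisible(path))
  }
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create output directory: ", path)
  files <- file.path(path, paste0(ds$subject_ids, ".tsv"))
  for (k in seq_along(ds$subject_ids)) {
    m <- ds$values[, , k, drop = FALSE]
    dim(m) <- dim(ds$values)[1:2]
    out <- cbind(row_id = ds$row_ids,
                 matrix(fmt(m), nrow = nrow(m),
                        dimnames = list(NULL, ds$col_ids)))
    utils::write.table(out, files[k], sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  manifest <- file.path(path, "manifest.tsv")
  utils::write.table(data.frame(subject_id = ds$subject_ids,
                                path = basename(files)),
                     manifest, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(manifest, files))
}
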