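## Sample and Stein-type shrinkage estimators of the row (gene) and column
## (tissue) covariance matrices. The shrinkage estimator mixes the sample
## covariance S with a structured target T,
##
##   Sigma_hat = (1 - lambda) S + lambda T,   lambda in [0, 1],
##
## with a data-driven intensity computed from the trace functionals
## (plug-in minimization of the expected Frobenius loss). With lambda > 0
## and a positive-definite target the estimate is positive definite, hence
## invertible, for any number of rows/columns. Column-side estimates carry
## the identifiability convention tr(SigmaC) = c.

.new_cov_estimate <- function(side, matrix, target, intensity, ids,
                              normalization) {
  dimnames(matrix) <- list(ids, ids)
  structure(list(side = side, matrix = matrix, target = target,
                 intensity = intensity, normalization = normalization,
                 ids = ids),
            class = "covariance_estimate")
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf("covariance estimate (%s side, %d x %d)\n",
              x$side, nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  target: %s, intensity lambda = %.4f\n", x$target,
              x$intensity))
  if (nzchar(x$normalization))
    cat("  normalization: ", x$normalization, "\n", sep = "")
  invisible(x)
}

#' Sample covariance of the rows or columns
#'
#' Rows: S_R = sum_i (X_i - Xbar)(X_i - Xbar)' / ((N - 1) c), unbiased for
#' SigmaR under the convention tr(SigmaC) = c. Columns: the raw scatter
#' sum_i (X_i - Xbar)'(X_i - Xbar) / (N - 1) rescaled to trace c.
#'
#' @param ds a \code{\link{transposable_dataset}} with N >= 2.
#' @param side \code{"rows"} or \code{"columns"}.
#' @return A \code{"covariance_estimate"} with \code{target = "none"} and
#'   \code{intensity = 0}.
#' @export
sample_covariance <- function(ds, side = c("rows", "columns")) {
  stopifnot(inherits(ds, "transposable_dataset"))
  side <- match.arg(side)
  d <- dim(ds$values)
  r <- d[1L]; cc <- d[2L]; N <- d[3L]
  if (N < 2L) stop("sample covariance needs N >= 2 subjects")
  Xstack <- ds$values; dim(Xstack) <- c(r, cc * N)
  Xbar <- matrix(rowSums(matrix(as.vector(ds$values), r * cc, N)), r, cc) / N
  Cstack <- Xstack - Xbar[, rep(seq_len(cc), times = N), drop = FALSE]
  if (side == "rows") {
    S <- tcrossprod(Cstack) / ((N - 1) * cc)
    return(.new_cov_estimate("rows", S, "none", 0, ds$row_ids, ""))
  }
  Sc <- matrix(0, cc, cc)
  for (i in seq_len(N)) {
    Ci <- Cstack[, ((i - 1L) * cc + 1L):(i * cc), drop = FALSE]
    Sc <- Sc + crossprod(Ci)
  }
  Sc <- Sc / (N - 1)
  tr <- sum(diag(Sc))
  if (tr <= 0) stop("zero total variance: column covariance is undefined")
  .new_cov_estimate("columns", Sc * (cc / tr), "none", 0, ds$col_ids,
                    "tr(SigmaC) = c")
}

## Shrinkage intensity from trace functionals; exposed internally so the
## population plug-in algebra (lambda = 1 on-target) can be checked directly.
.shrinkage_intensity <- function(target, t1, t2, t3, t4, N, p) {
  num_den <- switch(target,
    spherical = c(t3 + t2, N * t2 + ((p - N + 1) / p) * t3),
    identity  = c(t3 + t2, N * (t2 - 2 * t1 + p) + t2 + t3),
    diagonal  = c(t3 + t2 - 2 * t4, N * (t2 - t4) + t2 + t3 - 2 * t4),
    stop("unknown target: ", target))
  if (!all(is.finite(num_den)) || num_den[2L] <= 0) {
    warning("degenerate (near-target) data: shrinkage intensity set to 1")
    return(1)
  }
  min(1, max(0, num_den[1L] / num_den[2L]))
}

#' Stein-type shrinkage estimator of the row or column covariance matrix
#'
#' Shrinks the sample covariance toward \code{"spherical"} ((t1/p) I),
#' \code{"identity"} (I) or \code{"diagonal"} (diag(S)) with intensity
#' estimated from the trace functionals and truncated to [0, 1]. The
#' intensity approaches 1 when the truth lies in the target family and
#' decays as O(1/N) otherwise; for the spherical and identity targets any
#' positive intensity yields a positive-definite (invertible) estimate even
#' when p greatly exceeds N.
#'
#' @param ds a \code{\link{transposable_dataset}} with N >= 4.
#' @param side \code{"rows"} or \code{"columns"}.
#' @param target \code{"spherical"}, \code{"identity"} or \code{"diagonal"}.
#' @return A \code{"covariance_estimate"}; column-side output is
#'   renormalized to trace c after mixing.
#' @export
shrink_covariance <- function(ds, side = c("rows", "columns"),
                              target = c("spherical", "identity",
                                         "diagonal")) {
  side <- match.arg(side)
  target <- match.arg(target)
  d <- dim(ds$values)
  N <- d[3L]
  if (N < 4L) stop("shrinkage intensities need N >= 4 subjects")
  est <- sample_covariance(ds, side)
  tf <- trace_functionals(ds, side)
  p <- tf$p
  lam <- .shrinkage_intensity(target, tf$t1, tf$t2, tf$t3, tf$t4, N, p)
  Tm <- switch(target,
    spherical = diag(tf$t1 / p, p),
    identity = diag(p),
    diagonal = diag(diag(est$matrix), nrow = p))
  S <- (1 - lam) * est$matrix + lam * Tm
  norm <- ""
  if (side == "columns") {
    S <- S * (p / sum(diag(S)))
    norm <- "tr(SigmaC) = c"
  }
  .new_cov_estimate(side, S, target, lam,
                    if (side == "rows") ds$row_ids else ds$col_ids, norm)
}

#' Standard deviations and correlation matrix from a covariance estimate
#'
#' @param est a \code{"covariance_estimate"} (or a plain symmetric matrix)
#'   with strictly positive diagonal.
#' @return A list with \code{sd} (named vector of diagonal square roots) and
#'   \code{correlation} (matrix with unit diagonal).
#' @export
correlation_from_covariance <- function(est) {
  m <- if (inherits(est, "covariance_estimate")) est$matrix else as.matrix(est)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  dg <- diag(m)
  bad <- which(dg <= 0)
  if (length(bad))
    stop("nonpositive variance for: ", paste(ids[bad], collapse = ", "))
  s <- sqrt(dg)
  corr <- m / tcrossprod(s)
  diag(corr) <- 1
  dimnames(corr) <- list(ids, ids)
  list(sd = stats::setNames(s, ids), correlation = corr)
}
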