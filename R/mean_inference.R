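## Mean-matrix estimation and high-dimensional tests of mean conservation
## across column groups.
##
## The conservation hypothesis "M is constant within each column group" is
## encoded by a centering projection P (block diagonal, I_k - J_k/k per
## group): H0 holds iff M P = 0. The test statistic
##
##   T = (1 / (N(N-1))) sum_{i != j} tr(X_i P X_j')
##
## is unbiased for tr(M P M') >= 0 (zero exactly under H0) without requiring
## any estimate of SigmaR, so it remains valid when r >> N. Its null variance
## (2 / (N(N-1))) tr((P SigmaC)^2) tr(SigmaR^2) is estimated unbiasedly by a
## quadruple U-statistic over pair differences, computed via the same
## inclusion-exclusion identity as the trace functionals (O(N^2) cost). The
## reference distribution is standard normal, one-sided.

#' Estimate the mean matrix
#'
#' @param ds a \code{\link{transposable_dataset}}.
#' @return An object of class \code{"mean_matrix"}: list with the r x c
#'   \code{matrix} Xbar = (1/N) sum_i X_i, \code{row_ids} and \code{col_ids}.
#' @export
estimate_mean <- function(ds) {
  stopifnot(inherits(ds, "transposable_dataset"))
  d <- dim(ds$values)
  m <- matrix(rowSums(matrix(as.vector(ds$values), d[1L] * d[2L], d[3L])),
              d[1L], d[2L]) / d[3L]
  dimnames(m) <- list(ds$row_ids, ds$col_ids)
  structure(list(matrix = m, row_ids = ds$row_ids, col_ids = ds$col_ids),
            class = "mean_matrix")
}

#' @export
print.mean_matrix <- function(x, ...) {
  cat(sprintf("mean matrix (%d rows x %d columns)\n", nrow(x$matrix),
              ncol(x$matrix)))
  print(utils::head(x$matrix, 6L))
  invisible(x)
}

.check_grouping <- function(groups) {
  if (!is.list(groups) || length(groups) == 0L)
    stop("'groups' must be a nonempty list of column-id vectors")
  groups <- lapply(groups, as.character)
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group not allowed")
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("groups must be disjoint; duplicated id: ",
         all_ids[duplicated(all_ids)][1L])
  groups
}

#' Group-centering projection matrix
#'
#' For an ordered partition of the selected columns into groups, builds the
#' block-diagonal projection P with block I_k - J_k / k for a group of size
#' k. P is symmetric and idempotent with rank (#columns - #groups), and the
#' hypothesis "mean constant within each group" is exactly M P = 0.
#'
#' @param groups list of character vectors: disjoint column-id groups.
#' @return Symmetric idempotent matrix with rows/columns labelled by the
#'   concatenated group ids.
#' @examples
#' make_projection(list(c("t1", "t2")))
#' @export
make_projection <- function(groups) {
  groups <- .check_grouping(groups)
  ids <- unlist(groups, use.names = FALSE)
  cp <- length(ids)
  P <- matrix(0, cp, cp, dimnames = list(ids, ids))
  at <- 0L
  for (g in groups) {
    k <- length(g)
    idx <- at + seq_len(k)
    P[idx, idx] <- diag(k) - matrix(1 / k, k, k)
    at <- at + k
  }
  P
}

.new_test_result <- function(statistic, z, p_value, hypothesis, method,
                             details = list()) {
  structure(list(statistic = statistic, z = z, p.value = p_value,
                 hypothesis = hypothesis, method = method,
                 details = details),
            class = "kronstat_test")
}

#' @export
print.kronstat_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  H0: ", x$hypothesis, "\n", sep = "")
  cat(sprintf("  statistic = %.6g, z = %.4f, p-value = %.4g\n",
              x$statistic, x$z, x$p.value))
  invisible(x)
}

## Plug-in estimate of the null skewness of T,
##   skew(T) = 2 sqrt(2) (N-2) / sqrt(N(N-1)) * tr((A S)^3) / tr((A S)^2)^{3/2}
## with A S = (P SigmaC) (x) SigmaR (exact Gaussian third moment of the
## pair U-statistic; only subject triangles i-j-k contribute). SigmaR and
## SigmaC are replaced by their spherical-target shrinkage estimates; the
## row-side cube trace is computed from the rank-structured form
## alpha I + beta C C' via the (N c) x (N c) Gram, so no r x r matrix is
## formed. Drives the third-moment-matched chi-square reference below.
.mean_test_skewness <- function(ds, P) {
  d <- dim(ds$values)
  r <- d[1L]; cc <- d[2L]; N <- d[3L]
  tf <- trace_functionals(ds, "rows")
  lam <- .shrinkage_intensity("spherical", tf$t1, tf$t2, tf$t3, tf$t4, N, r)
  alpha <- lam * tf$t1 / r
  beta <- (1 - lam) / ((N - 1) * cc)
  Xstack <- ds$values; dim(Xstack) <- c(r, cc * N)
  Xbar <- matrix(rowSums(matrix(as.vector(ds$values), r * cc, N)), r, cc) / N
  Cstack <- Xstack - Xbar[, rep(seq_len(cc), times = N), drop = FALSE]
  Gc <- crossprod(Cstack)
  m1 <- sum(diag(Gc)); m2 <- sum(Gc * Gc); m3 <- sum(Gc * (Gc %*% Gc))
  trR2 <- alpha^2 * r + 2 * alpha * beta * m1 + beta^2 * m2
  trR3 <- alpha^3 * r + 3 * alpha^2 * beta * m1 + 3 * alpha * beta^2 * m2 +
    beta^3 * m3
  SC <- shrink_covariance(ds, "columns", "spherical")$matrix
  PC <- P %*% SC
  trC2 <- sum(diag(PC %*% PC)); trC3 <- sum(diag(PC %*% PC %*% PC))
  tr2 <- trC2 * trR2; tr3 <- trC3 * trR3
  if (!is.finite(tr2) || tr2 <= 0 || !is.finite(tr3) || tr3 <= 0)
    return(0)
  2 * sqrt(2) * (N - 2) / sqrt(N * (N - 1)) * tr3 / tr2^1.5
}

## theta_hat = avg over all-distinct quadruples (i,j,k,l) of
## tr(D_ij P D_kl')^2, unbiased for tr((P SigmaC)^2) tr(SigmaR^2).
.theta_hat <- function(values, P) {
  d <- dim(values)
  r <- d[1L]; cc <- d[2L]; N <- d[3L]
  Xstack <- values; dim(Xstack) <- c(r, cc * N)
  G <- crossprod(Xstack)
  Harr <- aperm(array(G, c(cc, N, cc, N)), c(2L, 4L, 1L, 3L))
  pr <- .tf_pairs(N)
  I <- pr$I; J <- pr$J; Pn <- length(I)
  Gv <- matrix(0, Pn, Pn)
  for (b in seq_len(cc)) for (bp in seq_len(cc)) {
    w <- P[b, bp]
    if (w == 0) next
    H <- Harr[, , b, bp]
    Gv <- Gv + w * (H[I, I, drop = FALSE] - H[I, J, drop = FALSE] -
                      H[J, I, drop = FALSE] + H[J, J, drop = FALSE]) / 2
  }
  Zmat <- matrix(0, N, Pn)
  Zmat[cbind(I, seq_len(Pn))] <- 1
  Zmat[cbind(J, seq_len(Pn))] <- 1
  ovl <- crossprod(Zmat)                       # |p intersect q|
  G2 <- Gv * Gv
  S4 <- 4 * sum(G2) - 4 * sum(ovl * G2) + 4 * sum(diag(G2))
  S4 / (N * (N - 1) * (N - 2) * (N - 3))
}

#' Test of mean conservation across column groups
#'
#' Tests H0: the mean matrix is constant within each column group (M P = 0
#' for the group-centering projection P) against the one-sided alternative
#' tr(M P M') > 0. Valid in the r >> N regime; requires N >= 4 for the
#' variance U-statistic.
#'
#' @param ds a \code{\link{transposable_dataset}}.
#' @param groups list of character vectors partitioning the columns of
#'   interest into disjoint groups; columns not mentioned are ignored. At
#'   least one group must have two or more columns (all-singleton groupings
#'   make the hypothesis vacuous).
#' @return A \code{"kronstat_test"} with elements \code{statistic} (T,
#'   unbiased for tr(M P M')), \code{p.value} (one-sided; standardized score
#'   referred to a third-moment-matched chi-square reference that tends to
#'   the standard normal as the null skewness vanishes), \code{z} (the
#'   normal-quantile equivalent of the p-value), \code{hypothesis} and
#'   \code{details} (variance estimate, raw standardized score, plug-in
#'   skewness, N, grouping).
#' @export
mean_conservation_test <- function(ds, groups) {
  stopifnot(inherits(ds, "transposable_dataset"))
  groups <- .check_grouping(groups)
  N <- n_subjects(ds)
  if (N < 4L) stop("mean conservation test needs N >= 4 subjects")
  if (all(vapply(groups, length, 1L) == 1L))
    stop("vacuous hypothesis: all groups are singletons (projection is zero)")
  ids <- unlist(groups, use.names = FALSE)
  sub <- subset(ds, cols = ids)
  P <- make_projection(groups)
  d <- dim(sub$values)
  r <- d[1L]; cc <- d[2L]
  ## T = [tr(Sx P Sx') - sum_i tr(X_i P X_i')] / (N(N-1))
  Sx <- matrix(rowSums(matrix(as.vector(sub$values), r * cc, N)), r, cc)
  SxP <- Sx %*% P
  total <- sum(SxP * Sx)
  diag_term <- 0
  for (i in seq_len(N)) {
    Xi <- matrix(sub$values[, , i], r, cc)
    diag_term <- diag_term + sum((Xi %*% P) * Xi)
  }
  Tstat <- (total - diag_term) / (N * (N - 1))
  theta <- .theta_hat(sub$values, P)
  vhat <- 2 * theta / (N * (N - 1))
  if (!is.finite(vhat) || vhat <= 0)
    stop("degenerate data: null variance estimate is not positive")
  score <- Tstat / sqrt(vhat)
  ## third-moment-matched chi-square reference: f = 8 / skew^2 degrees of
  ## freedom, matching the U-statistic's null mean, variance and skewness;
  ## tends to the standard normal as the skewness vanishes (large N or
  ## large effective row dimension)
  skew <- .mean_test_skewness(sub, P)
  if (is.finite(skew) && skew > 1e-8) {
    f <- 8 / skew^2
    pv <- stats::pchisq(f + score * sqrt(2 * f), df = f, lower.tail = FALSE)
  } else {
    pv <- stats::pnorm(score, lower.tail = FALSE)
  }
  z <- stats::qnorm(pv, lower.tail = FALSE)
  hyp <- paste0("mean constant within group(s): ",
                paste(vapply(groups, paste, "", collapse = ","),
                      collapse = " | "))
  .new_test_result(Tstat, z, pv, hyp,
                   "Mean conservation test (projection U-statistic)",
                   details = list(variance = vhat, score = score,
                                  skewness = skew, n_subjects = N,
                                  groups = groups, rank = cc - length(groups)))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order (monotone step-up
#'   adjustment; adjusted >= raw, capped at 1).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || length(pvals) == 0L)
    stop("'pvals' must be a nonempty numeric vector")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Pairwise mean-conservation tests against a reference column
#'
#' For a row subset (e.g. a tissue-specific gene list), tests conservation of
#' the mean between the reference column and each other column separately
#' (single group {reference, other}), with Benjamini-Hochberg adjustment
#' across the family.
#'
#' @param ds a \code{\link{transposable_dataset}}.
#' @param row_subset character vector of row ids to test on.
#' @param reference_col the reference column id.
#' @param other_cols column ids to compare against (default: all others).
#' @return A data frame with one row per comparison: \code{reference},
#'   \code{other}, \code{statistic}, \code{z}, \code{p.value},
#'   \code{p.adjusted}.
#' @export
pairwise_conservation_tests <- function(ds, row_subset, reference_col,
                                        other_cols = NULL) {
  stopifnot(inherits(ds, "transposable_dataset"))
  if (is.null(other_cols)) other_cols <- setdiff(ds$col_ids, reference_col)
  if (reference_col %in% other_cols)
    stop("'reference_col' must not appear in 'other_cols'")
  if (length(row_subset) == 0L) stop("'row_subset' must be nonempty")
  sub <- subset(ds, rows = row_subset)
  res <- lapply(other_cols, function(f) {
    tst <- mean_conservation_test(sub, list(c(reference_col, f)))
    data.frame(reference = reference_col, other = f,
               statistic = tst$statistic, z = tst$z, p.value = tst$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p.adjusted <- bh_adjust(out$p.value)
  rownames(out) <- NULL
  out
}
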