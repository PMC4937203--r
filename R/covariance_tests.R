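## Sphericity and identity tests for the row or column covariance matrix.
##
## Both statistics are functions of the trace functionals, so they stay well
## defined when the dimension exceeds the number of subjects (no likelihood
## ratio, no inverse). Sphericity: U = p t2 / t1^2 - 1, a scale-free measure
## that is 0 iff Sigma is proportional to the identity and positive
## otherwise. Identity: V = (t2 - 2 t1 + p) / p = ||Sigma - I||_F^2 / p at
## the population.
##
## Null calibration. In transposable data the side NOT under test supplies
## effective replication: under H0 the quadruple U-statistic behind U is
## degenerate (its first-order Hajek projection vanishes) and its limit is a
## second-order Gaussian chaos, giving
##
##   X = q + p sqrt(N(N-1)) U / (2 kappa)  ->  chi-square(q),
##   q = p(p+1)/2 - 1,  kappa = tr(Sigma_other^2) / tr^2(Sigma_other),
##
## a John-type statistic in which 1/kappa acts as the effective number of
## replicates contributed per subject by the other side. For the identity
## test the overall scale is not projected out and q = p(p+1)/2. When the
## other side is one-dimensional (kappa = 1) and p is large this reduces to
## the familiar z = n U / 2 ~ N(0,1) normalization for vector-valued data.
## kappa is estimated by the scale-free ratio t2/t3 of the opposite side's
## trace functionals. The reported z is the standard-normal quantile
## equivalent of the chi-square p-value.

.kappa_other <- function(ds, side) {
  if (side == "columns") {
    tt <- .tf_row_t2t3(ds$values)             # lean: no diagonal work
    k <- tt$t2 / tt$t3
  } else {
    tf <- trace_functionals(ds, "columns")
    k <- tf$t2 / tf$t3
  }
  if (!is.finite(k) || k <= 0)
    stop("degenerate data: cannot estimate the opposite side's trace shape")
  k
}

.cov_test_core <- function(ds, side, subset_ids, kind, pvalue, reps, seed,
                           kappa = NULL) {
  stopifnot(inherits(ds, "transposable_dataset"))
  full_ds <- ds
  if (!is.null(subset_ids)) {
    ds <- if (side == "columns") subset(ds, cols = subset_ids)
          else subset(ds, rows = subset_ids)
  }
  N <- n_subjects(ds)
  if (N < 4L) stop("covariance tests need N >= 4 subjects")
  tf <- trace_functionals(ds, side)
  p <- tf$p
  if (p < 2L) stop("covariance tests need dimension p >= 2")
  stat <- switch(kind,
    sphericity = p * tf$t2 / tf$t1^2 - 1,
    identity = (tf$t2 - 2 * tf$t1 + p) / p)
  if (is.null(kappa)) kappa <- .kappa_other(ds, side)
  q <- if (kind == "sphericity") p * (p + 1) / 2 - 1 else p * (p + 1) / 2
  X <- q + p * sqrt(N * (N - 1)) * stat / (2 * kappa)
  pv <- stats::pchisq(X, df = q, lower.tail = FALSE)
  z <- stats::qnorm(pv, lower.tail = FALSE)
  method <- sprintf("%s test (%s side, trace-functional U-statistic)",
                    if (kind == "sphericity") "Sphericity" else "Identity",
                    side)
  hyp <- if (kind == "sphericity")
    sprintf("Sigma_%s proportional to identity (equal variances, zero correlation)",
            side)
  else
    sprintf("Sigma_%s equal to identity [under tr(SigmaC) = c]", side)
  details <- list(p = p, n_subjects = N, t1 = tf$t1, t2 = tf$t2,
                  kappa_other = kappa, chisq = X, df = q,
                  pvalue_mode = pvalue)
  if (pvalue == "mc") {
    pv <- .cov_test_mc_pvalue(ds, side, kind, stat, tf, reps, seed)
    details$mc_reps <- reps
  }
  .new_test_result(stat, z, pv, hyp, method, details)
}

## Monte-Carlo p-value: simulate the Gaussian null with the tested side set
## to its null value ((t1/p) I for sphericity, I for identity) and the other
## side set to its spherical-target shrinkage estimate.
.cov_test_mc_pvalue <- function(ds, side, kind, stat, tf, reps, seed) {
  if (reps < 1L) stop("Monte-Carlo p-value needs reps >= 1")
  p <- tf$p
  null_S <- if (kind == "sphericity") diag(tf$t1 / p, p) else diag(p)
  other <- shrink_covariance(ds, if (side == "rows") "columns" else "rows",
                             "spherical")$matrix
  if (side == "rows") { SR <- null_S; SC <- other } else { SR <- other; SC <- null_S }
  N <- n_subjects(ds)
  exceed <- 0L
  for (b in seq_len(reps)) {
    cfg <- simulation_config(M = 0, SigmaR = SR, SigmaC = SC, N = N,
                             family = "gaussian", seed = seed + (b - 1L) * N)
    dsb <- sample_dataset(cfg)
    tfb <- trace_functionals(dsb, side)
    sb <- switch(kind,
      sphericity = p * tfb$t2 / tfb$t1^2 - 1,
      identity = (tfb$t2 - 2 * tfb$t1 + p) / p)
    if (sb >= stat) exceed <- exceed + 1L
  }
  (1 + exceed) / (reps + 1)
}

#' Sphericity test for the row or column covariance matrix
#'
#' Tests H0: Sigma_side = sigma^2 I (proportionality to the identity; for a
#' tissue pair this means equal variances and zero correlation) using the
#' scale-invariant statistic U = p t2 / t1^2 - 1 built from the trace
#' functionals. The null reference is a John-type chi-square law with
#' p(p+1)/2 - 1 degrees of freedom in which the opposite side's trace shape
#' tr(Sigma^2)/tr^2(Sigma) sets the effective replication (see the package
#' vignette); a Monte-Carlo p-value mode is available as a fallback.
#'
#' @param ds a \code{\link{transposable_dataset}} with N >= 4.
#' @param side \code{"columns"} (default) or \code{"rows"}.
#' @param subset optional vector of ids (of the tested side) to restrict to,
#'   e.g. a tissue pair.
#' @param pvalue \code{"normal"} (chi-square analytic reference, default) or
#'   \code{"mc"}.
#' @param reps,seed Monte-Carlo replications and seed (pvalue = "mc" only).
#' @return A \code{"kronstat_test"} with \code{statistic} = U, \code{z} (the
#'   normal-quantile equivalent of the p-value) and \code{p.value};
#'   \code{details} carries the chi-square statistic, its degrees of freedom
#'   and the estimated opposite-side shape.
#' @export
sphericity_test <- function(ds, side = c("columns", "rows"), subset = NULL,
                            pvalue = c("normal", "mc"), reps = 200L,
                            seed = 1L) {
  side <- match.arg(side)
  pvalue <- match.arg(pvalue)
  .cov_test_core(ds, side, subset, "sphericity", pvalue, as.integer(reps),
                 as.integer(seed))
}

#' Identity test for the row or column covariance matrix
#'
#' Tests H0: Sigma_side = I using V = (t2 - 2 t1 + p) / p (population value
#' ||Sigma - I||_F^2 / p), with the chi-square null reference described in
#' \code{\link{sphericity_test}} (q = p(p+1)/2: the scale is part of the
#' hypothesis). The column side is tested under the tr(SigmaC) = c
#' normalization, where the identity and sphericity hypotheses coincide
#' (recorded in the result metadata).
#'
#' @inheritParams sphericity_test
#' @return A \code{"kronstat_test"}.
#' @export
identity_test <- function(ds, side = c("columns", "rows"), subset = NULL,
                          pvalue = c("normal", "mc"), reps = 200L,
                          seed = 1L) {
  side <- match.arg(side)
  pvalue <- match.arg(pvalue)
  .cov_test_core(ds, side, subset, "identity", pvalue, as.integer(reps),
                 as.integer(seed))
}

#' Sphericity scan over all column pairs with FDR control
#'
#' Runs \code{\link{sphericity_test}} on every unordered pair of columns and
#' applies a Benjamini-Hochberg adjustment across the choose(c, 2) p-values.
#' Rejection of a pair's sphericity indicates unequal variances and/or
#' nonzero correlation for that pair. The opposite-side (row) trace shape is
#' estimated once from the full dataset and shared across pairs.
#'
#' @param ds a \code{\link{transposable_dataset}} with c >= 2 columns.
#' @param side tested side (default \code{"columns"}).
#' @param level FDR level used for the \code{reject} flag.
#' @return A data frame with one row per pair: \code{col_1}, \code{col_2},
#'   \code{statistic}, \code{z}, \code{p.value}, \code{p.adjusted},
#'   \code{reject}.
#' @export
all_pairs_sphericity <- function(ds, side = "columns", level = 0.05) {
  stopifnot(inherits(ds, "transposable_dataset"))
  ids <- if (side == "columns") ds$col_ids else ds$row_ids
  if (length(ids) < 2L) stop("need at least two labels for a pair scan")
  kappa <- .kappa_other(ds, side)
  prs <- utils::combn(ids, 2L)
  res <- lapply(seq_len(ncol(prs)), function(k) {
    tst <- .cov_test_core(ds, side, prs[, k], "sphericity", "normal", 0L, 1L,
                          kappa = kappa)
    data.frame(col_1 = prs[1L, k], col_2 = prs[2L, k],
               statistic = tst$statistic, z = tst$z, p.value = tst$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p.adjusted <- bh_adjust(out$p.value)
  out$reject <- out$p.adjusted <= level
  rownames(out) <- NULL
  out
}
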