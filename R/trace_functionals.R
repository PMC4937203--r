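## U-statistic estimators of the trace functionals tr(Sigma), tr(Sigma^2),
## tr^2(Sigma) and sum_j Sigma_jj^2 of the row or column covariance matrix.
##
## All estimators are built from mean-free pair differences
## D_ij = (X_i - X_j)/sqrt(2) and average over index tuples with ALL subjects
## distinct, which removes the mean and makes them unbiased without
## distributional assumptions. The quadruple averages are never enumerated:
## for any bilinear functional h of two pair matrices, the sum over ordered
## all-distinct quadruples (i,j,k,l) of h(T_ij, T_kl) equals
##
##   4 h(W, W) - 4 sum_v h(B_v, B_v) + 4 sum_{i<j} h(T_ij, T_ij),
##
## where W = sum_{i<j} T_ij and B_v = sum_{a != v} T_va (inclusion-exclusion
## over coincident subjects). Every aggregate reduces to algebra on the
## (N c) x (N c) Gram matrix of the stacked subject matrices, so the cost is
## O(r (N c)^2 + N^2 c^2) regardless of how large r is. Correctness is
## pinned by the literal O(N^4) oracle below, not by the derivation.
##
## Identifiability: SigmaC (x) SigmaR is invariant to (a SigmaC, SigmaR / a);
## the package-wide convention is tr(SigmaC) = c, under which the row-side
## functionals are directly estimable and the column-side t1 and t3 are the
## constants c and c^2. Column-side t2 and t4 are scale-free ratio estimators
## (consistent, not exactly unbiased).

.tf_pairs <- function(N) {
  idx <- which(upper.tri(matrix(TRUE, N, N)), arr.ind = TRUE)
  list(I = idx[, 1L], J = idx[, 2L])
}

## Shared geometry: the subject-block Gram Harr[i,j,a,b] = (X_i' X_j)[a,b]
## and the pair-level c x c blocks M_p = D_p' D_p.
.tf_core <- function(values) {
  d <- dim(values)
  r <- d[1L]; cc <- d[2L]; N <- d[3L]
  Xstack <- values; dim(Xstack) <- c(r, cc * N)
  G <- crossprod(Xstack)
  Harr <- aperm(array(G, c(cc, N, cc, N)), c(2L, 4L, 1L, 3L))
  pr <- .tf_pairs(N)
  I <- pr$I; J <- pr$J; P <- length(I)
  Mmat <- matrix(0, P, cc * cc)               # row p = vec(D_p' D_p)
  II <- cbind(I, I); IJ <- cbind(I, J); JI <- cbind(J, I); JJ <- cbind(J, J)
  for (b in seq_len(cc)) for (a in seq_len(cc)) {
    H <- Harr[, , a, b]
    Mmat[, (b - 1L) * cc + a] <- (H[II] - H[IJ] - H[JI] + H[JJ]) / 2
  }
  dpos <- (seq_len(cc) - 1L) * cc + seq_len(cc)
  list(r = r, cc = cc, N = N, Xstack = Xstack, Harr = Harr,
       I = I, J = J, P = P, Mmat = Mmat, dpos = dpos)
}

## Row-side quadruple aggregates, entirely on the block Gram:
## B_v = (1/2)(N X_v X_v' - X_v S' - S X_v' + Q) with S = sum_a X_a and
## Q = sum_a X_a X_a'; every trace in tr(B_v^2) contracts to c x c blocks.
## The diagonal (t4) aggregates need row-level detail and are skipped unless
## requested.
.tf_row_aggregates <- function(values, core, need_diag = TRUE) {
  r <- core$r; cc <- core$cc; N <- core$N
  Harr <- core$Harr
  M1 <- colMeans(Harr)                        # [j,a,b] = (S' X_j)[a,b] / N
  SS <- apply(M1, c(2L, 3L), sum)             # S'S / N, c x c
  m12 <- SS / N                               # (S'S)[a,b] / N^2
  ## centered Gram for tr(W), tr(W^2): Hc[i,j,,] = Harr - M1[j] - M2[i] + m12
  trW <- 0; trW2 <- 0
  for (b in seq_len(cc)) for (a in seq_len(cc)) {
    Hab <- Harr[, , a, b]
    ## M2[i,a,b] = (X_i' S)[a,b] / N = M1[i,b,a]
    Hcab <- Hab - rep(M1[, a, b], each = N) - M1[, b, a] + m12[a, b]
    trW2 <- trW2 + sum(Hcab * Hcab)
    if (a == b) trW <- trW + sum(diag(Hcab))
  }
  h2 <- rowSums(matrix(Harr * Harr, nrow = N))    # trAQ_v = sum_a ||X_v'X_a||^2
  trQ2 <- sum(h2)
  Kmat <- matrix(M1, N, cc * cc) * N          # row a = vec(S' X_a)
  trQ <- 0
  for (v in seq_len(N)) trQ <- trQ + sum(diag(matrix(Harr[v, v, , ], cc, cc)))
  sumBv_tr2 <- 0; sumBv_frob2 <- 0
  for (v in seq_len(N)) {
    Gvv <- matrix(Harr[v, v, , ], cc, cc)
    Kv <- matrix(Kmat[v, ], cc, cc)           # S' X_v
    trA2 <- sum(Gvv * Gvv)
    trBB <- sum(Kv * t(Kv))
    trBBt <- sum(Gvv * SS) * N                # tr(Xv'Xv S'S), SS = S'S/N
    trAB <- sum(Kv * Gvv)
    trAQ <- h2[v]
    Hv <- matrix(Harr[v, , , ], N, cc * cc)   # row a = vec(X_v' X_a)
    trBQ <- sum(Kmat * Hv)
    trK2 <- N^2 * trA2 + 2 * trBB + trQ2 + 2 * trBBt -
      4 * N * trAB + 2 * N * trAQ - 4 * trBQ
    sumBv_frob2 <- sumBv_frob2 + trK2 / 4
    trBv <- (N * sum(diag(Gvv)) - 2 * sum(diag(Kv)) + trQ) / 2
    sumBv_tr2 <- sumBv_tr2 + trBv^2
  }
  out <- list(W_tr2 = trW^2, W_frob2 = trW2,
              Bv_tr2 = sumBv_tr2, Bv_frob2 = sumBv_frob2,
              W_diag2 = NA_real_, Bv_diag2 = NA_real_, A_diag2 = NA_real_)
  if (!need_diag) return(out)
  ## diagonal (t4) aggregates: need the r-level data
  Xstack <- core$Xstack
  Ssum <- matrix(rowSums(matrix(as.vector(values), r * cc, N)), r, cc)
  Cstack <- Xstack - (Ssum / N)[, rep(seq_len(cc), times = N), drop = FALSE]
  out$W_diag2 <- sum(rowSums(Cstack * Cstack)^2)
  qdiag <- rowSums(Xstack * Xstack)
  sumBv_diag2 <- 0
  for (v in seq_len(N)) {
    Xv <- values[, , v, drop = FALSE]; dim(Xv) <- c(r, cc)
    dBv <- (N * rowSums(Xv * Xv) - 2 * rowSums(Xv * Ssum) + qdiag) / 2
    sumBv_diag2 <- sumBv_diag2 + sum(dBv^2)
  }
  out$Bv_diag2 <- sumBv_diag2
  ## sum over pairs p of sum_a (D_p D_p')_aa^2, one row of the cube at a time
  I <- core$I; J <- core$J
  II <- cbind(I, I); IJ <- cbind(I, J); JJ <- cbind(J, J)
  Xperm <- aperm(values, c(2L, 3L, 1L))       # c x N x r, contiguous slices
  sumA_diag2 <- 0
  for (a in seq_len(r)) {
    Wa <- crossprod(matrix(Xperm[, , a], cc, N))
    da <- (Wa[II] + Wa[JJ] - 2 * Wa[IJ]) / 2
    sumA_diag2 <- sumA_diag2 + sum(da^2)
  }
  out$A_diag2 <- sumA_diag2
  out
}

## Lean row-side t2/t3 (shape ratio kappa = t2/t3) used by the covariance
## tests; skips all diagonal work.
.tf_row_t2t3 <- function(values) {
  d <- dim(values); N <- d[3L]; cc <- d[2L]
  core <- .tf_core(values)
  ag <- .tf_row_aggregates(values, core, need_diag = FALSE)
  denom <- N * (N - 1) * (N - 2) * (N - 3)
  trA <- rowSums(core$Mmat[, core$dpos, drop = FALSE])
  Zsum <- as.vector(rowsum(c(trA, trA), c(core$I, core$J)))
  S4_trtr <- 4 * sum(trA)^2 - 4 * sum(Zsum^2) + 4 * sum(trA^2)
  sumA_frob2 <- sum(core$Mmat * core$Mmat)
  S4_tr <- N^2 * ag$W_frob2 - 4 * ag$Bv_frob2 + 4 * sumA_frob2
  list(t2 = (S4_tr / denom) / cc^2, t3 = (S4_trtr / denom) / cc^2)
}

#' Unbiased trace-functional estimates for one side of a transposable dataset
#'
#' Estimates t1 = tr(Sigma), t2 = tr(Sigma^2), t3 = tr^2(Sigma) and
#' t4 = sum_j Sigma_jj^2 for the row covariance matrix (\code{side = "rows"})
#' or the column covariance matrix (\code{side = "columns"}), under the
#' identifiability convention tr(SigmaC) = c. These power the shrinkage
#' intensities and the covariance-test statistics. t3 uses a genuinely
#' unbiased quadruple U-statistic rather than t1^2, avoiding its
#' O(tr Sigma^2 / N) bias.
#'
#' Row-side estimates are unbiased; column-side t2 and t4 are consistent
#' ratio estimators (scale-free), and column-side t1 and t3 equal c and c^2
#' exactly by the normalization convention.
#'
#' @param ds a \code{\link{transposable_dataset}} with at least 4 subjects
#'   (the quadruple U-statistics need four distinct subjects).
#' @param side \code{"rows"} or \code{"columns"}.
#' @return An object of class \code{"trace_functionals"}: list with elements
#'   \code{side}, \code{p} (dimension of the estimated covariance),
#'   \code{t1}, \code{t2}, \code{t3}, \code{t4} and \code{n_subjects}.
#' @seealso \code{\link{trace_functionals_oracle}} for the literal O(N^4)
#'   enumeration of the same quantities.
#' @export
trace_functionals <- function(ds, side = c("rows", "columns")) {
  stopifnot(inherits(ds, "transposable_dataset"))
  side <- match.arg(side)
  d <- dim(ds$values)
  N <- d[3L]
  if (N < 4L)
    stop("insufficient subjects for quadruple U-statistics (need N >= 4)")
  if (!all(is.finite(ds$values))) stop("non-finite values in dataset")
  core <- .tf_core(ds$values)
  cc <- core$cc
  denom <- N * (N - 1) * (N - 2) * (N - 3)
  Mmat <- core$Mmat; dpos <- core$dpos
  trA <- rowSums(Mmat[, dpos, drop = FALSE])  # tr(D_p' D_p), both sides
  t1_raw <- mean(trA)

  ## shared tr x tr aggregate (identical for both sides)
  Zmat <- matrix(0, N, core$P)
  Zmat[cbind(core$I, seq_len(core$P))] <- 1
  Zmat[cbind(core$J, seq_len(core$P))] <- 1
  trBv <- as.vector(Zmat %*% trA)
  S4_trtr <- 4 * sum(trA)^2 - 4 * sum(trBv^2) + 4 * sum(trA^2)
  Q_trtr <- S4_trtr / denom

  if (side == "rows") {
    ag <- .tf_row_aggregates(ds$values, core, need_diag = TRUE)
    sumA_frob2 <- sum(Mmat * Mmat)            # tr((D_p' D_p)^2) summed
    S4_tr <- N^2 * ag$W_frob2 - 4 * ag$Bv_frob2 + 4 * sumA_frob2
    S4_dg <- N^2 * ag$W_diag2 - 4 * ag$Bv_diag2 + 4 * ag$A_diag2
    out <- list(side = side, p = core$r,
                t1 = t1_raw / cc,
                t2 = (S4_tr / denom) / cc^2,
                t3 = Q_trtr / cc^2,
                t4 = (S4_dg / denom) / cc^2,
                n_subjects = N)
  } else {
    tsum <- colSums(Mmat)                     # vec of sum_p D_p' D_p
    Btil <- Zmat %*% Mmat                     # row v = vec(B_v), c x c
    S4_tr <- 4 * sum(tsum^2) - 4 * sum(Btil * Btil) + 4 * sum(Mmat * Mmat)
    dg <- Mmat[, dpos, drop = FALSE]
    tsd <- tsum[dpos]
    S4_dg <- 4 * sum(tsd^2) - 4 * sum(Btil[, dpos, drop = FALSE]^2) +
      4 * sum(dg * dg)
    Q2 <- S4_tr / denom; Q4 <- S4_dg / denom
    if (Q_trtr <= 0) {
      warning("degenerate data: column-side ratio functionals are undefined")
      t2 <- NaN; t4 <- NaN
    } else {
      t2 <- cc^2 * Q2 / Q_trtr
      t4 <- cc^2 * Q4 / Q_trtr
    }
    out <- list(side = side, p = cc, t1 = cc, t2 = t2, t3 = cc^2, t4 = t4,
                n_subjects = N)
  }
  class(out) <- "trace_functionals"
  out
}

#' @export
print.trace_functionals <- function(x, ...) {
  cat(sprintf("trace functionals (%s side, p = %d, N = %d)\n",
              x$side, x$p, x$n_subjects))
  cat(sprintf("  t1 = tr(Sigma)        %.6g\n", x$t1))
  cat(sprintf("  t2 = tr(Sigma^2)      %.6g\n", x$t2))
  cat(sprintf("  t3 = tr^2(Sigma)      %.6g\n", x$t3))
  cat(sprintf("  t4 = sum_j Sigma_jj^2 %.6g\n", x$t4))
  invisible(x)
}

#' Literal enumeration oracle for the trace functionals
#'
#' Computes exactly the same estimands as \code{\link{trace_functionals}} by
#' looping over every ordered tuple of distinct subjects (O(N^4) pair-matrix
#' products). Intended as an independent correctness check on small N; the
#' efficient implementation must agree to relative 1e-10.
#'
#' @param ds a \code{\link{transposable_dataset}} with 4 <= N <= 12.
#' @param side \code{"rows"} or \code{"columns"}.
#' @return A \code{"trace_functionals"} object.
#' @export
trace_functionals_oracle <- function(ds, side = c("rows", "columns")) {
  stopifnot(inherits(ds, "transposable_dataset"))
  side <- match.arg(side)
  d <- dim(ds$values)
  N <- d[3L]
  if (N < 4L)
    stop("insufficient subjects for quadruple U-statistics (need N >= 4)")
  if (N > 12L) stop("oracle enumeration is limited to N <= 12")
  r <- d[1L]; cc <- d[2L]
  pr <- .tf_pairs(N)
  key <- function(i, j) paste(min(i, j), max(i, j))
  Ac <- list(); Adg <- list(); Dm <- list()
  for (p in seq_along(pr$I)) {
    D <- matrix((ds$values[, , pr$I[p]] - ds$values[, , pr$J[p]]) / sqrt(2),
                r, cc)
    k <- key(pr$I[p], pr$J[p])
    Ac[[k]] <- crossprod(D)            # c x c
    Adg[[k]] <- rowSums(D * D)         # diag of D D'
    Dm[[k]] <- D
  }
  s_tr <- 0; s_trtr <- 0; s_dg_row <- 0; s_tr_col <- 0; s_dg_col <- 0
  n_quad <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (j == i) next
    for (k in seq_len(N)) {
      if (k == i || k == j) next
      for (l in seq_len(N)) {
        if (l == i || l == j || l == k) next
        n_quad <- n_quad + 1
        A1 <- Ac[[key(i, j)]]; A2 <- Ac[[key(k, l)]]
        s_tr <- s_tr + sum(crossprod(Dm[[key(i, j)]], Dm[[key(k, l)]])^2)
        s_trtr <- s_trtr + sum(diag(A1)) * sum(diag(A2))
        s_dg_row <- s_dg_row + sum(Adg[[key(i, j)]] * Adg[[key(k, l)]])
        s_tr_col <- s_tr_col + sum(A1 * A2)
        s_dg_col <- s_dg_col + sum(diag(A1) * diag(A2))
      }
    }
  }
  t1_raw <- mean(vapply(Ac, function(a) sum(diag(a)), numeric(1)))
  Q_tr_row <- s_tr / n_quad; Q_trtr <- s_trtr / n_quad
  Q_dg_row <- s_dg_row / n_quad
  Q_tr_col <- s_tr_col / n_quad; Q_dg_col <- s_dg_col / n_quad
  if (side == "rows") {
    out <- list(side = side, p = r, t1 = t1_raw / cc, t2 = Q_tr_row / cc^2,
                t3 = Q_trtr / cc^2, t4 = Q_dg_row / cc^2, n_subjects = N)
  } else {
    out <- list(side = side, p = cc, t1 = cc,
                t2 = if (Q_trtr > 0) cc^2 * Q_tr_col / Q_trtr else NaN,
                t3 = cc^2,
                t4 = if (Q_trtr > 0) cc^2 * Q_dg_col / Q_trtr else NaN,
                n_subjects = N)
  }
  class(out) <- "trace_functionals"
  out
}
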