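# Collective-variable selection: Nystrom reconstruction of the time-lagged
# correlation matrix from a column subset, with greedy spectral-oASIS
# selection of the columns that preserve the slowest implied timescales.

#' Instantaneous and time-lagged covariance of mean-free CVs
#'
#' Estimates the instantaneous covariance `C0` and the symmetrized
#' time-lagged covariance `Ctau` of the mean-free collective variables over
#' all valid (t, t + lag) pairs. Multiple trajectories contribute pairs
#' independently; pairs never cross trajectory boundaries.
#'
#' @param series a [CVSeries-class] or list of them.
#' @param lag lag in frames (>= 1).
#' @return list with `C0`, `Ctau` (K x K matrices), `tau` (ps), `nSamples`.
#' @export
estimateCorrelations <- function(series, lag) {
  if (is(series, "CVSeries")) series <- list(series)
  stopifnot(length(series) >= 1, lag >= 1)
  mats <- lapply(series, cvMatrix)
  if (any(vapply(mats, nrow, integer(1)) <= lag))
    stop("lag (", lag, " frames) must be shorter than every trajectory")
  mu <- colMeans(do.call(rbind, mats))
  K <- length(mu)
  C0 <- matrix(0, K, K); Ct <- matrix(0, K, K); n0 <- 0; nt <- 0
  for (m in mats) {
    x <- sweep(m, 2, mu)
    C0 <- C0 + crossprod(x); n0 <- n0 + nrow(x)
    a <- x[seq_len(nrow(x) - lag), , drop = FALSE]
    b <- x[(lag + 1):nrow(x), , drop = FALSE]
    Ct <- Ct + crossprod(a, b); nt <- nt + nrow(a)
  }
  C0 <- C0 / n0
  Ct <- Ct / nt
  list(C0 = C0, Ctau = (Ct + t(Ct)) / 2,
       tau = lag * series[[1]]@stride, nSamples = nt)
}

#' Nystrom reconstruction of a symmetric matrix from a column subset
#'
#' `Chat = C[, cols] %*% pinv(C[cols, cols]) %*% C[cols, ]`. Exact whenever
#' the selected columns span the column space of `C` (in particular when
#' `rank(C) <= length(cols)` with well-chosen columns). Singular sub-blocks
#' are handled by the pseudo-inverse (tolerance 1e-10).
#'
#' @param C K x K symmetric matrix.
#' @param cols non-empty vector of unique column indices.
#' @return K x K reconstructed matrix.
#' @export
nystromReconstruct <- function(C, cols) {
  stopifnot(length(cols) >= 1, !anyDuplicated(cols))
  W <- C[cols, cols, drop = FALSE]
  Cc <- C[, cols, drop = FALSE]
  Cc %*% pracma::pinv(W, tol = 1e-10) %*% t(Cc)
}

# generalized symmetric eigenproblem Ctau v = lambda C0 v with diagonal
# regularization of C0; returns eigenvalues (descending) and vectors
generalizedEigen <- function(Ctau, C0) {
  K <- nrow(C0)
  C0r <- C0 + diag(1e-10 * sum(diag(C0)) / K + 1e-300, K)
  L <- tryCatch(chol(C0r), error = function(e)
    stop("C0 is not positive definite after regularization: ",
         conditionMessage(e)))
  Li <- backsolve(L, diag(K), transpose = TRUE)
  M <- Li %*% Ctau %*% t(Li)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = t(Li) %*% e$vectors)
}

# implied timescales from generalized eigenvalues at lag tau. The CVs are
# mean-free, so the trivial constant eigenfunction (eigenvalue 1) is absent
# and the slowest mode is the top eigenvalue. Non-positive eigenvalues
# yield timescale 0 with a warning; eigenvalues >= 1 are clipped.
timescalesFromEigen <- function(lambda, tau, m) {
  lam <- lambda[seq_len(min(m, length(lambda)))]
  if (any(lam <= 0))
    warning("non-positive eigenvalue(s) encountered; timescale set to 0")
  lam <- pmin(lam, 1 - 1e-12)
  ifelse(lam <= 0, 0, -tau / log(lam))
}

#' Greedy spectral-oASIS selection of a CV subset
#'
#' Starting from the empty set, repeatedly adds the column whose inclusion
#' best reduces the spectral reconstruction error — the summed absolute
#' deviation of the top-`m` generalized eigenvalues of the
#' Nystrom-reconstructed time-lagged matrix `(Ctau_hat, C0)` from those of
#' the full pair `(Ctau, C0)`. Ties are broken toward the lower column
#' index. After
#' each addition the top-`m` implied timescales of the problem restricted to
#' the selected columns are recorded, along with the Frobenius
#' reconstruction error of `Ctau`.
#'
#' @param series a [CVSeries-class] or list of them.
#' @param lag lag in frames for the time-lagged covariance.
#' @param nSelect number of CVs to select.
#' @param m number of slow eigenpairs to preserve.
#' @return list with `selected` (ordered indices), `names`,
#'   `timescaleCurves` (list: per subset size, top-m implied timescales in
#'   ps), `reconstructionError` (Frobenius norm per size), and
#'   `fullTimescales`.
#' @export
spectralOasisSelect <- function(series, lag, nSelect, m = 3) {
  corr <- estimateCorrelations(series, lag)
  K <- nrow(corr$C0)
  stopifnot(nSelect <= K, m <= max(nSelect, 1))
  full <- generalizedEigen(corr$Ctau, corr$C0)
  lamFull <- full$values[seq_len(m)]
  specErr <- function(cols) {
    Cth <- nystromReconstruct(corr$Ctau, cols)
    lam <- generalizedEigen(Cth, corr$C0)$values[seq_len(m)]
    sum(abs(lam - lamFull))
  }
  selected <- integer()
  tsCurves <- list()
  frob <- numeric()
  for (step in seq_len(nSelect)) {
    cand <- setdiff(seq_len(K), selected)
    errs <- vapply(cand, function(c) specErr(c(selected, c)), numeric(1))
    selected <- c(selected, cand[which.min(errs)])  # which.min: lowest index
    sub <- selected
    eSub <- generalizedEigen(corr$Ctau[sub, sub, drop = FALSE],
                             corr$C0[sub, sub, drop = FALSE])
    tsCurves[[step]] <- timescalesFromEigen(eSub$values, corr$tau,
                                            min(m, length(sub)))
    frob[step] <- norm(corr$Ctau - nystromReconstruct(corr$Ctau, sub), "F")
  }
  nm <- colnames(if (is(series, "CVSeries")) cvMatrix(series) else
    cvMatrix(series[[1]]))
  list(selected = selected, names = nm[selected],
       timescaleCurves = tsCurves, reconstructionError = frob,
       fullTimescales = timescalesFromEigen(full$values, corr$tau, m))
}
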