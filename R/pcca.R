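# PCCA+ metastable lumping: inner-simplex vertex search on the dominant
# right eigenvectors of a reversible transition matrix, followed by a
# feasibility projection onto the membership simplex.

# pi-orthonormal right eigenvectors of a reversible T (first = constant 1)
dominantEigenvectors <- function(T, pi, m) {
  S <- diag(sqrt(pi)) %*% T %*% diag(1 / sqrt(pi))
  asym <- max(abs(S - t(S)))
  if (asym > 1e-6)
    stop("transition matrix is not reversible with respect to pi ",
         sprintf("(asymmetry %.2g); PCCA+ requires detailed balance", asym))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- e$values[seq_len(m)]
  if (m < length(e$values) && abs(vals[m] - e$values[m + 1]) < 1e-12)
    warning("degenerate eigenvalue at the cluster cut; ordering by index")
  psi <- diag(1 / sqrt(pi)) %*% e$vectors[, seq_len(m), drop = FALSE]
  # fix signs and normalize the trivial eigenvector to +1
  psi[, 1] <- psi[, 1] / psi[1, 1]
  list(vectors = psi, values = vals)
}

# inner-simplex vertex search: indices of m rows of X spanning the simplex
innerSimplexVertices <- function(X) {
  m <- ncol(X)
  idx <- integer(m)
  ortho <- X
  idx[1] <- which.max(rowSums(ortho^2))
  ortho <- sweep(ortho, 2, ortho[idx[1], ])
  for (k in seq_len(m - 1)) {
    v <- ortho[idx[k], ]
    nv <- sqrt(sum(v^2))
    if (nv > 1e-14) {
      v <- v / nv
      ortho <- ortho - (ortho %*% v) %*% t(v)
    }
    idx[k + 1] <- which.max(rowSums(ortho^2))
  }
  idx
}

#' PCCA+ lumping of microstates into metastable macro-states
#'
#' Robust Perron cluster analysis on the top-`nMacro` right eigenvectors of
#' a reversible transition matrix: the inner-simplex algorithm picks
#' `nMacro` spread-maximizing vertex microstates, the linear transform
#' mapping their eigenvector rows to the unit vectors defines fuzzy
#' memberships, and the result is projected onto the probability simplex
#' (negative entries clipped, rows renormalized). The crisp assignment is
#' the row-wise argmax, ties to the lower macro index.
#'
#' @param T row-stochastic transition matrix (reversible w.r.t. `pi`).
#' @param pi stationary distribution of `T`.
#' @param nMacro number of macro-states.
#' @return a [MacroModel-class].
#' @export
pccaPlus <- function(T, pi, nMacro) {
  n <- nrow(T)
  stopifnot(nMacro >= 1, nMacro <= n)
  if (nMacro == n) {
    return(new("MacroModel", membership = diag(n),
               crisp = seq_len(n), macroT = T, macroPi = pi))
  }
  ev <- dominantEigenvectors(T, pi, nMacro)
  X <- ev$vectors
  vert <- innerSimplexVertices(X)
  A <- solve(X[vert, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  rs <- rowSums(chi)
  rs[rs == 0] <- 1
  chi <- chi / rs
  crisp <- max.col(chi, ties.method = "first")
  cg <- coarseGrain(T, pi, crisp, nMacro)
  new("MacroModel", membership = chi, crisp = as.integer(crisp),
      macroT = cg$macroT, macroPi = cg$macroPi)
}

#' Coarse-grain a transition matrix by a crisp lumping
#'
#' `macroPi_A = sum_{i in A} pi_i` and
#' `macroT_AB = sum_{i in A, j in B} pi_i T_ij / macroPi_A`.
#'
#' @param T microstate transition matrix.
#' @param pi stationary distribution.
#' @param crisp integer micro -> macro assignment.
#' @param nMacro number of macro-states (defaults to `max(crisp)`).
#' @return list with `macroT` and `macroPi`.
#' @export
coarseGrain <- function(T, pi, crisp, nMacro = max(crisp)) {
  M <- outer(crisp, seq_len(nMacro), `==`) * 1   # n x nMacro indicator
  flowFull <- t(M) %*% (pi * T) %*% M            # pi_i T_ij aggregated
  macroPi <- as.numeric(t(M) %*% pi)
  macroT <- flowFull / macroPi
  list(macroT = macroT, macroPi = macroPi)
}
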