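# Microstate Markov state model estimation and validation: k-centers
# discretization, transition counting, reversible maximum-likelihood
# transition matrices, implied timescales, Chapman-Kolmogorov test and GMRQ
# cross-validation.

# run expr with a local RNG seeded by `seed`, restoring global RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# standardization stats over concatenated CV matrices (zero-sd columns -> 1)
cvScaling <- function(mats) {
  all <- do.call(rbind, mats)
  mu <- colMeans(all)
  sd <- apply(all, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(center = mu, scale = sd)
}

#' Greedy k-centers clustering of CV space
#'
#' CVs are standardized (zero mean, unit variance) before clustering. The
#' first center is a seeded random frame; each subsequent center is the
#' frame farthest (Euclidean) from the existing centers, which carries the
#' classical 2-approximation covering-radius guarantee. Frames are assigned
#' to their nearest center.
#'
#' @param series a [CVSeries-class] or list of them.
#' @param nStates number of cluster centers.
#' @param seed integer seed for the first-center draw.
#' @return list with `centers` (nStates x K, original CV units), `dtrajs`
#'   (list of 1-based integer state sequences), `radius` (covering radius in
#'   standardized units), and the standardization (`center`, `scale`).
#' @export
kcentersCluster <- function(series, nStates, seed = 1) {
  if (is(series, "CVSeries")) series <- list(series)
  mats <- lapply(series, cvMatrix)
  lens <- vapply(mats, nrow, integer(1))
  X <- do.call(rbind, mats)
  if (nStates > nrow(X))
    stop("nStates (", nStates, ") exceeds total frames (", nrow(X), ")")
  sc <- cvScaling(mats)
  Z <- sweep(sweep(X, 2, sc$center), 2, sc$scale, `/`)
  n <- nrow(Z)
  centerIdx <- integer(nStates)
  centerIdx[1] <- withSeed(seed, sample.int(n, 1))
  d2 <- rowSums(sweep(Z, 2, Z[centerIdx[1], ])^2)
  assign <- rep(1L, n)
  if (nStates > 1) for (k in 2:nStates) {
    centerIdx[k] <- which.max(d2)
    dk <- rowSums(sweep(Z, 2, Z[centerIdx[k], ])^2)
    upd <- dk < d2
    d2[upd] <- dk[upd]
    assign[upd] <- k
  }
  dt <- split(assign, rep(seq_along(lens), lens))
  names(dt) <- NULL
  list(centers = X[centerIdx, , drop = FALSE],
       dtrajs = lapply(dt, as.integer),
       radius = sqrt(max(d2)), center = sc$center, scale = sc$scale)
}

#' Assign frames to existing k-centers
#'
#' Projects new CV data onto a previously learned discretization (used to
#' project elevated-temperature data onto the reference-temperature states).
#'
#' @param series a [CVSeries-class] or list of them.
#' @param clustering result of [kcentersCluster()].
#' @return list of integer state sequences.
#' @export
assignToCenters <- function(series, clustering) {
  if (is(series, "CVSeries")) series <- list(series)
  Cz <- sweep(sweep(clustering$centers, 2, clustering$center), 2,
              clustering$scale, `/`)
  lapply(series, function(s) {
    Z <- sweep(sweep(cvMatrix(s), 2, clustering$center), 2,
               clustering$scale, `/`)
    # nearest center via |z|^2 - 2 z.c + |c|^2
    cross <- Z %*% t(Cz)
    d2 <- outer(rowSums(Z^2), rowSums(Cz^2), `+`) - 2 * cross
    as.integer(max.col(-d2, ties.method = "first"))
  })
}

#' Count state-to-state transitions at a lag
#'
#' Sliding mode counts every (t, t + lag) pair within each trajectory;
#' strided mode counts only pairs starting at t = 1, 1 + lag, 1 + 2 lag, ...
#' Pairs never cross trajectory boundaries.
#'
#' @param dtrajs list of integer state sequences (1-based).
#' @param lag lag in frames (>= 1).
#' @param nStates total number of states (defaults to the maximum observed).
#' @param mode `"sliding"` (default) or `"strided"`.
#' @return nStates x nStates integer-valued count matrix.
#' @export
countTransitions <- function(dtrajs, lag, nStates = max(unlist(dtrajs)),
                             mode = c("sliding", "strided")) {
  mode <- match.arg(mode)
  stopifnot(lag >= 1)
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  C <- matrix(0, nStates, nStates)
  for (d in dtrajs) {
    if (length(d) <= lag) next
    from <- d[seq_len(length(d) - lag)]
    to <- d[(lag + 1):length(d)]
    if (mode == "strided") {
      keep <- seq(1, length(from), by = lag)
      from <- from[keep]; to <- to[keep]
    }
    tab <- table(factor(from, seq_len(nStates)), factor(to, seq_len(nStates)))
    C <- C + unclass(tab)
  }
  dimnames(C) <- NULL
  C
}

# largest strongly connected component of the count graph, by state count;
# ties broken toward the component containing the smallest state index
largestSCC <- function(counts) {
  g <- igraph::graph_from_adjacency_matrix(
    (counts > 0) * 1, mode = "directed", diag = TRUE)
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    mins <- vapply(best, function(b) min(which(comp$membership == b)),
                   integer(1))
    best <- best[which.min(mins)]
  }
  sort(which(comp$membership == best))
}

#' Estimate a transition matrix from counts
#'
#' Restricts the counts to the largest strongly connected set of states
#' (ergodic trimming), then estimates the row-stochastic transition matrix.
#' Non-reversible: simple row normalization. Reversible (default): maximum
#' likelihood under detailed balance via the self-consistent fixed-point
#' update of the symmetric edge weights, iterated until the stationary
#' distribution changes by less than 1e-10 (cap 1e6 sweeps; non-convergence
#' is an error, never a silent fallback).
#'
#' @param counts square count matrix.
#' @param reversible enforce detailed balance (default `TRUE`).
#' @return list with `transition`, `stationary`, `active` (indices of the
#'   retained states in the original numbering).
#' @export
estimateTransitionMatrix <- function(counts, reversible = TRUE) {
  active <- largestSCC(counts)
  if (!length(active)) stop("empty connected component: no transitions")
  C <- counts[active, active, drop = FALSE]
  if (any(rowSums(C) == 0)) stop("state without outgoing counts after trim")
  n <- nrow(C)
  if (!reversible) {
    T <- C / rowSums(C)
    pi <- stationaryVector(T)
    return(list(transition = T, stationary = pi, active = active))
  }
  Csym <- C + t(C)
  X <- Csym / sum(C)                       # symmetric initial edge weights
  ci <- rowSums(C)
  piOld <- rowSums(X) / sum(X)
  for (it in seq_len(1e6)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, `+`)
    X <- Csym / denom
    X <- X * (Csym > 0)
    pi <- rowSums(X) / sum(X)
    if (max(abs(pi - piOld)) < 1e-10) {
      T <- X / rowSums(X)
      return(list(transition = T, stationary = pi, active = active))
    }
    piOld <- pi
  }
  stop("reversible MLE did not converge within 1e6 sweeps")
}

# stationary distribution of a row-stochastic matrix (left Perron vector)
stationaryVector <- function(T) {
  e <- eigen(t(T))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v <- abs(v)
  v / sum(v)
}

#' Build a microstate Markov state model
#'
#' Convenience wrapper: k-centers discretization, transition counting at the
#' requested lag, ergodic trimming and transition-matrix estimation.
#'
#' @param series a [CVSeries-class] or list of them.
#' @param nStates number of microstates.
#' @param lag lag in frames.
#' @param reversible enforce detailed balance (default `TRUE`).
#' @param seed seed for the k-centers initialization.
#' @return a [MicrostateModel-class].
#' @export
buildMSM <- function(series, nStates, lag, reversible = TRUE, seed = 1) {
  if (is(series, "CVSeries")) series <- list(series)
  cl <- kcentersCluster(series, nStates, seed = seed)
  msmFromDtrajs(cl$dtrajs, lag, nStates = nStates, reversible = reversible,
                centers = cl$centers, stride = series[[1]]@stride)
}

#' Build a microstate model from precomputed discrete trajectories
#'
#' @param dtrajs list of integer state sequences.
#' @param lag lag in frames.
#' @param nStates total state count.
#' @param reversible enforce detailed balance.
#' @param centers optional state centers (for provenance).
#' @param stride physical time per frame, ps.
#' @return a [MicrostateModel-class].
#' @export
msmFromDtrajs <- function(dtrajs, lag, nStates = max(unlist(dtrajs)),
                          reversible = TRUE, centers = NULL, stride = 1) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  counts <- countTransitions(dtrajs, lag, nStates)
  est <- estimateTransitionMatrix(counts, reversible = reversible)
  if (is.null(centers)) centers <- matrix(seq_len(nStates), ncol = 1)
  new("MicrostateModel", centers = centers,
      dtrajs = lapply(dtrajs, as.integer), lag = as.integer(lag),
      lagTime = lag * stride, counts = counts, transition = est$transition,
      stationary = est$stationary, active = as.integer(est$active),
      reversible = reversible)
}

#' Implied timescale curves
#'
#' `t_i(tau) = -tau / log(lambda_i(tau))` for the top-`m` nontrivial
#' eigenvalues of the transition matrix re-estimated at each lag.
#' Non-positive eigenvalues yield `NA` (undefined), never a negative
#' timescale.
#'
#' @param dtrajs list of integer state sequences.
#' @param lags vector of lags in frames.
#' @param m number of nontrivial timescales.
#' @param reversible estimator flag.
#' @param stride physical time per frame (ps); timescales are returned in
#'   the same units times frames.
#' @return data.frame with columns `lag`, `index`, `timescale`.
#' @export
impliedTimescales <- function(dtrajs, lags, m = 3, reversible = TRUE,
                              stride = 1) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  out <- lapply(lags, function(lag) {
    est <- estimateTransitionMatrix(
      countTransitions(dtrajs, lag, max(unlist(dtrajs))),
      reversible = reversible)
    ev <- sort(Re(eigen(est$transition, only.values = TRUE)$values),
               decreasing = TRUE)
    lam <- ev[seq(2, min(m + 1, length(ev)))]
    ts <- ifelse(lam <= 0, NA_real_,
                 -lag * stride / log(pmin(lam, 1 - 1e-15)))
    data.frame(lag = lag, index = seq_along(ts), timescale = ts)
  })
  do.call(rbind, out)
}

# set residence probability curves from a transition matrix power
setResidence <- function(T, pi, members, k) {
  Tk <- matPow(T, k)
  p <- pi[members] / sum(pi[members])
  sum(p * rowSums(Tk[members, members, drop = FALSE]))
}

matPow <- function(T, k) {
  R <- diag(nrow(T))
  P <- T
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% P
    P <- P %*% P
    k <- k %/% 2
  }
  R
}

#' Chapman-Kolmogorov test
#'
#' For each state grouping, compares the model prediction `T(tau)^k` of the
#' residence probability with the estimate from a model re-estimated at lag
#' `k * tau`, for k = 1..kMax. Uncertainty bands on the empirical curve come
#' from bootstrap resampling of trajectories (trajectories are split into
#' segments first when only one is available).
#'
#' @param dtrajs list of integer state sequences.
#' @param lag base lag in frames.
#' @param sets list of integer vectors of state indices (groupings).
#' @param kMax maximum lag multiple.
#' @param nBoot bootstrap replicates (default 50).
#' @param reversible estimator flag.
#' @param seed bootstrap seed.
#' @return data.frame with columns `set`, `k`, `model`, `estimated`,
#'   `lower`, `upper`.
#' @export
ckTest <- function(dtrajs, lag, sets, kMax = 5, nBoot = 50,
                   reversible = TRUE, seed = 1) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (length(dtrajs) == 1L) {   # split the single trajectory into segments
    d <- dtrajs[[1]]
    nSeg <- 10L
    cuts <- floor(seq(0, length(d), length.out = nSeg + 1))
    dtrajs <- lapply(seq_len(nSeg), function(s) d[(cuts[s] + 1):cuts[s + 1]])
  }
  nStates <- max(unlist(dtrajs))
  base <- estimateTransitionMatrix(countTransitions(dtrajs, lag, nStates),
                                   reversible = reversible)
  mapIn <- function(set) match(intersect(set, base$active), base$active)
  resid <- function(dt, k) {
    est <- estimateTransitionMatrix(
      countTransitions(dt, lag * k, nStates), reversible = reversible)
    vapply(sets, function(s) {
      mem <- match(intersect(s, est$active), est$active)
      if (!length(mem)) return(NA_real_)
      setResidence(est$transition, est$stationary, mem, 1)
    }, numeric(1))
  }
  boot <- withSeed(seed, {
    replicate(nBoot, {
      idx <- sample.int(length(dtrajs), replace = TRUE)
      vapply(seq_len(kMax), function(k)
        tryCatch(resid(dtrajs[idx], k), error = function(e)
          rep(NA_real_, length(sets))),
        numeric(length(sets)))
    })
  })  # dims: set x k x boot (or k x boot when one set)
  boot <- array(boot, c(length(sets), kMax, nBoot))
  out <- list()
  for (si in seq_along(sets)) {
    mem <- mapIn(sets[[si]])
    for (k in seq_len(kMax)) {
      model <- if (length(mem))
        setResidence(base$transition, base$stationary, mem, k) else NA_real_
      estv <- resid(dtrajs, k)[si]
      bs <- boot[si, k, ]
      out[[length(out) + 1L]] <- data.frame(
        set = si, k = k, model = model, estimated = estv,
        lower = stats::quantile(bs, 0.025, na.rm = TRUE),
        upper = stats::quantile(bs, 0.975, na.rm = TRUE))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# correlation matrices of state indicator functions over dtrajs at a lag
indicatorCorrelations <- function(dtrajs, lag, nStates) {
  C <- countTransitions(dtrajs, lag, nStates)
  Csym <- (C + t(C)) / 2
  n <- sum(C)
  C00 <- diag((rowSums(Csym) + colSums(Csym)) / (2 * n))
  list(C00 = C00, C0t = Csym / n)
}

#' Generalized matrix Rayleigh quotient of model eigenfunctions on data
#'
#' Scores the top-`m` estimated eigenvectors `V` (columns, over all states)
#' on held-out discrete trajectories: the sum of generalized Rayleigh
#' quotients `trace((V' C00 V)^{-1} (V' C0t V))` with the indicator
#' correlation matrices of the test data. Higher is better; the stationary
#' eigenvector alone scores 1.
#'
#' @param V nStates x m matrix of eigenvectors (right eigenvectors of a
#'   reversible transition matrix, extended with zeros outside the active
#'   set).
#' @param dtrajs held-out discrete trajectories.
#' @param lag lag in frames.
#' @param nStates total state count.
#' @return scalar GMRQ score.
#' @export
gmrqScore <- function(V, dtrajs, lag, nStates) {
  cc <- indicatorCorrelations(dtrajs, lag, nStates)
  A <- t(V) %*% cc$C00 %*% V
  B <- t(V) %*% cc$C0t %*% V
  sum(diag(solve(A + diag(1e-12, ncol(A)), B)))
}

# top-m right eigenvectors of a reversible transition matrix, pi-orthonormal,
# embedded into the full state space (zeros outside active set)
msmEigenvectors <- function(est, m, nStates) {
  T <- est$transition; pi <- est$stationary
  S <- diag(sqrt(pi)) %*% T %*% diag(1 / sqrt(pi))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  psi <- diag(1 / sqrt(pi)) %*% e$vectors[, seq_len(m), drop = FALSE]
  V <- matrix(0, nStates, m)
  V[est$active, ] <- psi
  V
}

#' Cross-validated GMRQ score for a state-count choice
#'
#' Splits trajectories into folds, learns the discretization and the model
#' on the training folds, assigns test frames to the training centers, and
#' evaluates the train eigenvectors on the test data with [gmrqScore()].
#' Used to choose the number of microstates.
#'
#' @param series list of [CVSeries-class] (>= 2 for by-trajectory folds; a
#'   single series is split into contiguous segments).
#' @param nStates number of microstates to score.
#' @param lag lag in frames.
#' @param m number of eigenpairs in the score.
#' @param nFolds number of folds (>= 2).
#' @param seed seed for fold assignment and clustering.
#' @return list with `mean` and `folds` (per-fold test scores).
#' @export
gmrqCV <- function(series, nStates, lag, m = 2, nFolds = 2, seed = 1) {
  stopifnot(nFolds >= 2)
  if (is(series, "CVSeries")) {
    x <- cvMatrix(series)
    nSeg <- max(nFolds, 4L)
    cuts <- floor(seq(0, nrow(x), length.out = nSeg + 1))
    series <- lapply(seq_len(nSeg), function(s)
      CVSeries(x[(cuts[s] + 1):cuts[s + 1], , drop = FALSE],
               stride = series@stride))
  }
  if (length(series) < nFolds)
    stop("need at least nFolds trajectories (or one splittable series)")
  folds <- withSeed(seed, sample(rep_len(seq_len(nFolds), length(series))))
  scores <- vapply(seq_len(nFolds), function(f) {
    train <- series[folds != f]; test <- series[folds == f]
    cl <- kcentersCluster(train, nStates, seed = seed)
    est <- estimateTransitionMatrix(
      countTransitions(cl$dtrajs, lag, nStates), reversible = TRUE)
    V <- msmEigenvectors(est, m, nStates)
    gmrqScore(V, assignToCenters(test, cl), lag, nStates)
  }, numeric(1))
  list(mean = mean(scores), folds = scores)
}
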