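# Transition path theory on discrete Markov chains: committors, reactive
# flux, bottleneck pathway decomposition, transition-state identification,
# mean first passage times, Markov chain Monte Carlo trajectory synthesis,
# and nucleation-rate arithmetic.

#' Forward and backward committors
#'
#' The forward committor solves the discrete boundary-value problem
#' `q(i) = sum_j T_ij q(j)` for states outside `A` and `B`, with `q = 0` on
#' the source `A` and `q = 1` on the sink `B` (direct linear solve). The
#' backward committor is the forward committor of the time-reversed chain
#' with the roles of `A` and `B` swapped; for a reversible chain
#' `qMinus = 1 - qPlus`.
#'
#' @param T row-stochastic transition matrix.
#' @param A,B disjoint non-empty integer state sets.
#' @param pi stationary distribution (computed from `T` when omitted).
#' @return list with `qPlus` and `qMinus`.
#' @export
committors <- function(T, A, B, pi = NULL) {
  n <- nrow(T)
  A <- as.integer(A); B <- as.integer(B)
  stopifnot(length(A) >= 1, length(B) >= 1, !length(intersect(A, B)))
  if (is.null(pi)) pi <- stationaryVector(T)
  forward <- function(Tm, src, snk) {
    q <- numeric(n)
    q[snk] <- 1
    U <- setdiff(seq_len(n), c(src, snk))
    if (length(U)) {
      M <- diag(length(U)) - Tm[U, U, drop = FALSE]
      rhs <- rowSums(Tm[U, snk, drop = FALSE])
      sol <- tryCatch(solve(M, rhs), error = function(e)
        stop("singular committor system (absorbing intermediate state(s) ",
             paste(U[rowSums(Tm[U, , drop = FALSE] > 0) <= 1],
                   collapse = ", "), "): ", conditionMessage(e)))
      q[U] <- sol
    }
    q
  }
  qPlus <- forward(T, A, B)
  Trev <- t(T * pi) / pi                 # reversed chain: pi_j T_ji / pi_i
  qMinus <- forward(Trev, B, A)
  list(qPlus = pmin(1, pmax(0, qPlus)), qMinus = pmin(1, pmax(0, qMinus)))
}

#' Reactive flux matrices
#'
#' Gross reactive flux `f_ij = pi_i qMinus_i T_ij qPlus_j` (zero diagonal),
#' net flux `max(0, f_ij - f_ji)`, and total reactive flux
#' `sum_{i in A, j notin A} f_ij`, all per lag time.
#'
#' @param T transition matrix.
#' @param pi stationary distribution.
#' @param qPlus,qMinus committors from [committors()].
#' @param A source set (for the total-flux sum).
#' @return list with `flux`, `netFlux`, `totalFlux`.
#' @export
reactiveFlux <- function(T, pi, qPlus, qMinus, A) {
  f <- (pi * qMinus) * T * rep(qPlus, each = nrow(T))
  diag(f) <- 0
  net <- pmax(f - t(f), 0)
  total <- sum(f[A, setdiff(seq_len(ncol(T)), A), drop = FALSE])
  list(flux = f, netFlux = net, totalFlux = total)
}

# widest (max-bottleneck) path from set A to set B in a capacity matrix;
# returns list(path, bottleneck) or NULL when disconnected
widestPath <- function(cap, A, B) {
  n <- nrow(cap)
  width <- rep(-Inf, n)
  width[A] <- Inf
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  repeat {
    u <- which(!done & width > -Inf)
    if (!length(u)) break
    u <- u[which.max(width[u])]
    done[u] <- TRUE
    if (u %in% B) break
    nz <- which(cap[u, ] > 0 & !done)
    for (v in nz) {
      w <- min(width[u], cap[u, v])
      if (w > width[v]) { width[v] <- w; prev[v] <- u }
    }
  }
  end <- B[which.max(width[B])]
  if (!is.finite(width[end]) || width[end] <= 0) return(NULL)
  path <- end
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  list(path = path, bottleneck = width[end])
}

#' Iterative bottleneck decomposition of the net flux into pathways
#'
#' Repeatedly finds the A -> B path with the largest bottleneck capacity in
#' the net-flux network, records it with its bottleneck flux, and subtracts
#' that flux along the path. Stops when the remaining flux fraction drops
#' below `minFraction` or the network disconnects. Pathways are returned
#' sorted by flux, descending.
#'
#' @param netFlux net reactive flux matrix.
#' @param A,B source and sink sets.
#' @param minFraction stop threshold on the remaining flux fraction
#'   (default 0: full decomposition).
#' @return list of `list(path, flux)`.
#' @export
decomposePathways <- function(netFlux, A, B, minFraction = 0) {
  cap <- netFlux
  total <- sum(netFlux[A, setdiff(seq_len(ncol(netFlux)), A), drop = FALSE])
  if (total <= 0) {
    warning("no A -> B net flux; returning empty pathway list")
    return(list())
  }
  out <- list()
  remaining <- total
  repeat {
    if (remaining / total < minFraction && length(out)) break
    wp <- widestPath(cap, A, B)
    if (is.null(wp)) {
      if (!length(out)) warning("no A -> B path in the net flux network")
      break
    }
    for (s in seq_len(length(wp$path) - 1))
      cap[wp$path[s], wp$path[s + 1]] <-
        cap[wp$path[s], wp$path[s + 1]] - wp$bottleneck
    out[[length(out) + 1L]] <- list(path = wp$path, flux = wp$bottleneck)
    remaining <- remaining - wp$bottleneck
    if (remaining <= total * 1e-14) break
  }
  out[order(vapply(out, `[[`, numeric(1), "flux"), decreasing = TRUE)]
}

#' Aggregate a microstate net flux into macro-states
#'
#' `F_AB = sum_{i in A, j in B} netFlux_ij`, then the macro-level net part
#' `max(0, F_AB - F_BA)` with zero diagonal.
#'
#' @param netFlux microstate net flux matrix.
#' @param crisp integer micro -> macro assignment.
#' @param nMacro number of macro-states.
#' @return nMacro x nMacro macro net flux matrix.
#' @export
macroFlux <- function(netFlux, crisp, nMacro = max(crisp)) {
  M <- outer(crisp, seq_len(nMacro), `==`) * 1
  F <- t(M) %*% netFlux %*% M
  Fn <- pmax(F - t(F), 0)
  diag(Fn) <- 0
  Fn
}

#' Transition-state microstates from the committor
#'
#' States whose forward committor lies inside the window (default
#' `[0.45, 0.55]`), the discrete analogue of the free-energy saddle point.
#'
#' @param qPlus forward committor.
#' @param window numeric(2) committor window.
#' @return integer vector of state indices (warns when empty).
#' @export
transitionStateMicrostates <- function(qPlus, window = c(0.45, 0.55)) {
  idx <- which(qPlus >= window[1] & qPlus <= window[2])
  if (!length(idx))
    warning("no microstates with committor in [", window[1], ", ",
            window[2], "]")
  idx
}

#' Mean first passage times to a target set
#'
#' Solves `m = lagTime + T m` on the non-target states with `m = 0` on the
#' targets (direct linear solve).
#'
#' @param T transition matrix.
#' @param targets integer target state set.
#' @param lagTime physical time per lag (default 1, i.e. MFPT in lags).
#' @return numeric vector of per-state MFPTs.
#' @export
mfpt <- function(T, targets, lagTime = 1) {
  n <- nrow(T)
  targets <- as.integer(targets)
  stopifnot(length(targets) >= 1)
  m <- numeric(n)
  Q <- setdiff(seq_len(n), targets)
  if (length(Q)) {
    M <- diag(length(Q)) - T[Q, Q, drop = FALSE]
    m[Q] <- solve(M, rep(lagTime, length(Q)))
  }
  m
}

#' Sample trajectories from a transition matrix
#'
#' Markov chain Monte Carlo synthesis: categorical sampling per step from
#' the rows of `T`, reproducible under a fixed seed. Mirrors the protocol
#' of generating independent long trajectories from a microstate model to
#' recover pathways and estimate MFPTs.
#'
#' @param T transition matrix.
#' @param nSteps steps per trajectory.
#' @param nTraj number of independent trajectories.
#' @param seed integer seed.
#' @param start either a single starting state, a vector of per-trajectory
#'   starting states, or `NULL` to draw starts from the stationary
#'   distribution.
#' @return list of integer state sequences of length `nSteps + 1`.
#' @export
sampleChain <- function(T, nSteps, nTraj = 1, seed = 1, start = NULL) {
  n <- nrow(T)
  cum <- t(apply(T, 1, cumsum))
  cum[, n] <- 1 + 1e-12
  withSeed(seed, {
    starts <- if (is.null(start)) {
      pi <- stationaryVector(T)
      sample.int(n, nTraj, replace = TRUE, prob = pi)
    } else rep_len(as.integer(start), nTraj)
    lapply(seq_len(nTraj), function(tr) {
      out <- integer(nSteps + 1)
      out[1] <- starts[tr]
      u <- stats::runif(nSteps)
      s <- out[1]
      for (t in seq_len(nSteps)) {
        s <- findInterval(u[t], cum[s, ]) + 1L
        out[t + 1] <- s
      }
      out
    })
  })
}

#' Heterogeneous nucleation rate from a mean first passage time
#'
#' `J = 1 / (MFPT x V)` in events per second per cubic metre.
#'
#' @param mfptSeconds mean first passage time, s.
#' @param volumeM3 simulation volume, m^3.
#' @return rate, s^-1 m^-3.
#' @export
nucleationRate <- function(mfptSeconds, volumeM3) {
  if (!is.finite(mfptSeconds) || mfptSeconds <= 0)
    stop("mfptSeconds must be positive")
  if (!is.finite(volumeM3) || volumeM3 <= 0)
    stop("volumeM3 must be positive")
  1 / (mfptSeconds * volumeM3)
}

#' Full transition path theory analysis
#'
#' Committors, reactive flux and bottleneck pathway decomposition between a
#' source and a sink set, bundled into a [TPTResult-class].
#'
#' @param T transition matrix.
#' @param A,B source and sink sets.
#' @param pi stationary distribution (computed when omitted).
#' @param minFraction pathway decomposition stop threshold.
#' @return a [TPTResult-class].
#' @export
tptAnalysis <- function(T, A, B, pi = NULL, minFraction = 0) {
  if (is.null(pi)) pi <- stationaryVector(T)
  q <- committors(T, A, B, pi)
  fl <- reactiveFlux(T, pi, q$qPlus, q$qMinus, A)
  pw <- decomposePathways(fl$netFlux, A, B, minFraction)
  new("TPTResult", A = as.integer(A), B = as.integer(B),
      qPlus = q$qPlus, qMinus = q$qMinus, flux = fl$flux,
      netFlux = fl$netFlux, totalFlux = fl$totalFlux, pathways = pw)
}
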