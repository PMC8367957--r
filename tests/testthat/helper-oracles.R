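# Independent oracles, deliberately coded with explicit closed-form tables
# and plain nested loops, sharing no code path with the package internals.

# closed-form associated Legendre functions (Condon-Shortley), l = 4 and 6
.oraP <- list(
  "4" = list(
    function(x) (35 * x^4 - 30 * x^2 + 3) / 8,
    function(x) -(5 / 2) * (7 * x^3 - 3 * x) * sqrt(1 - x^2),
    function(x) (15 / 2) * (7 * x^2 - 1) * (1 - x^2),
    function(x) -105 * x * (1 - x^2)^1.5,
    function(x) 105 * (1 - x^2)^2),
  "6" = list(
    function(x) (231 * x^6 - 315 * x^4 + 105 * x^2 - 5) / 16,
    function(x) -(21 / 8) * x * (33 * x^4 - 30 * x^2 + 5) * sqrt(1 - x^2),
    function(x) (105 / 8) * (33 * x^4 - 18 * x^2 + 1) * (1 - x^2),
    function(x) -(315 / 2) * x * (11 * x^2 - 3) * (1 - x^2)^1.5,
    function(x) (945 / 2) * (11 * x^2 - 1) * (1 - x^2)^2,
    function(x) -10395 * x * (1 - x^2)^2.5,
    function(x) 10395 * (1 - x^2)^3)
)

# closed-form complex Y_lm for a single unit vector
oracleYlm <- function(l, m, v) {
  ct <- max(-1, min(1, v[3]))
  phi <- atan2(v[2], v[1])
  am <- abs(m)
  P <- .oraP[[as.character(l)]][[am + 1]](ct)
  nf <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - am) / factorial(l + am))
  Yp <- nf * P * exp(1i * am * phi)
  if (m >= 0) Yp else (-1)^am * Conj(Yp)
}

oracleMinImage <- function(d, box, periodic) {
  for (k in 1:3) if (periodic[k]) d[k] <- d[k] - box[k] * round(d[k] / box[k])
  d
}

oracleNeighbors <- function(pos, i, n, box, periodic) {
  N <- nrow(pos)
  d2 <- numeric(N)
  for (j in 1:N) {
    dd <- oracleMinImage(pos[j, ] - pos[i, ], box, periodic)
    d2[j] <- sum(dd^2)
  }
  d2[i] <- Inf
  order(d2)[1:n]
}

# direct nested-summation qbar_l per the averaged bond-order definition
oracleQbar <- function(pos, box, periodic, l, nNeighbors) {
  N <- nrow(pos)
  nn <- if (length(nNeighbors) == 1) rep(nNeighbors, N) else nNeighbors
  qlmTab <- matrix(0 + 0i, N, 2 * l + 1)
  for (j in 1:N) {
    nbrs <- oracleNeighbors(pos, j, nn[j], box, periodic)
    for (mi in seq(-l, l)) {
      acc <- 0 + 0i
      for (k in nbrs) {
        d <- oracleMinImage(pos[j, ] - pos[k, ], box, periodic)
        acc <- acc + oracleYlm(l, mi, d / sqrt(sum(d^2)))
      }
      qlmTab[j, mi + l + 1] <- acc / length(nbrs)
    }
  }
  out <- numeric(N)
  for (i in 1:N) {
    nbrs <- oracleNeighbors(pos, i, nn[i], box, periodic)
    s <- 0
    for (mi in seq(-l, l)) {
      acc <- qlmTab[i, mi + l + 1]
      for (j in nbrs) acc <- acc + qlmTab[j, mi + l + 1]
      s <- s + Mod(acc / (length(nbrs) + 1))^2
    }
    out[i] <- sqrt(4 * pi / (2 * l + 1) * s)
  }
  out
}

# brute-force connected components over all pairs (BFS)
oracleClusters <- function(pos, idx, box, periodic, cutoff) {
  n <- length(idx)
  if (n == 0) return(list())
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    d <- oracleMinImage(pos[idx[b], ] - pos[idx[a], ], box, periodic)
    adj[a, b] <- sum(d^2) <= cutoff^2
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(adj[u, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb); comp <- c(comp, nb)
    }
    comps[[length(comps) + 1]] <- sort(idx[comp])
  }
  comps
}

# Monte-Carlo forward committor by shooting trajectories
oracleCommittorMC <- function(T, A, B, nShots = 2000, maxLen = 10000) {
  n <- nrow(T)
  cum <- t(apply(T, 1, cumsum))
  q <- numeric(n)
  for (s in seq_len(n)) {
    if (s %in% A) { q[s] <- 0; next }
    if (s %in% B) { q[s] <- 1; next }
    hit <- 0
    for (shot in seq_len(nShots)) {
      x <- s
      for (t in seq_len(maxLen)) {
        x <- findInterval(runif(1), cum[x, ]) + 1L
        if (x %in% A) break
        if (x %in% B) { hit <- hit + 1; break }
      }
    }
    q[s] <- hit / nShots
  }
  q
}

# mean first passage time by direct trajectory sampling
oracleMfptMC <- function(T, start, targets, nSamples = 1000,
                         maxLen = 100000) {
  cum <- t(apply(T, 1, cumsum))
  times <- numeric(nSamples)
  for (s in seq_len(nSamples)) {
    x <- start; t <- 0
    while (!(x %in% targets) && t < maxLen) {
      x <- findInterval(runif(1), cum[x, ]) + 1L
      t <- t + 1
    }
    times[s] <- t
  }
  times
}

# random reversible transition matrix from symmetric positive weights
randomReversibleT <- function(n, selfWeight = 2) {
  W <- matrix(runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- diag(W) + selfWeight
  W / rowSums(W)
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
randomRotation <- function() {
  qr0 <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr0)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
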