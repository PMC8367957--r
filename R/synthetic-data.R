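# Ground-truth synthetic inputs: a metastable two-pathway nucleation
# network emitting collective-variable trajectories, and ideal molecular
# configurations (hexagonal ice slab, planar rhombic monolayer, disordered
# liquid) for the detector.

# lattice constants matched to hexagonal ice on the wurtzite surface
.iceLattice <- list(a = 0.4519, c = 0.7357)

# symmetric edge weights of the 8-state two-pathway topology:
# I-II-IV-VI-VII/VIII classical spine; II-III-{IV,V}-VI non-classical branch
twoPathwayWeights <- function(s) {
  W <- matrix(0, 8, 8,
              dimnames = list(st <- c("I", "II", "III", "IV", "V", "VI",
                                      "VII", "VIII"), st))
  edge <- function(a, b, w) {
    W[a, b] <<- w; W[b, a] <<- w
  }
  edge("I", "II", 1)
  edge("II", "IV", s)          # classical branch
  edge("II", "III", 1 - s)     # non-classical branch
  edge("III", "IV", 0.5)
  edge("III", "V", 0.5)
  edge("IV", "VI", 1)
  edge("V", "VI", 1)
  edge("VI", "VII", 1)
  edge("VI", "VIII", 1)
  W
}

# transition matrix from symmetric weights: uniform self-probability mu,
# off-diagonal (1 - mu) * w_ij / sum_j w_ij; reversible with pi ~ rowSums(W)
weightsToT <- function(W, mu) {
  T <- (1 - mu) * W / rowSums(W)
  diag(T) <- mu
  T
}

# classical fraction of the I -> {VII, VIII} reactive flux: the share of
# the net flux leaving state II through the direct II -> IV edge
classicalFraction <- function(T) {
  res <- tptAnalysis(T, A = 1L, B = c(7L, 8L))
  f24 <- res@netFlux[2, 4]
  f23 <- res@netFlux[2, 3]
  f24 / (f24 + f23)
}

#' Build the synthetic two-pathway nucleation network
#'
#' Constructs an 8-state reversible metastable network (states I-VIII) with
#' a classical branch II -> IV and a non-classical branch II -> III ->
#' IV/V, both draining through VI into the grown states VII/VIII. The
#' branch weight at state II is tuned by bisection so transition path
#' theory on the exact matrix assigns the requested fraction of the
#' I -> VII/VIII flux to the classical branch (within 0.01). Each state
#' emits the five selected collective variables with Gaussian noise around
#' state-specific means that trace a nucleation pathway (nucleus growth,
#' transient rhombic enrichment in state III, layer-by-layer hexagonal
#' growth).
#'
#' @param pathwaySplit target classical flux fraction in [0, 1].
#' @param metastability per-state self-transition probability (default
#'   0.98).
#' @param emissionSd emission noise standard deviation, molecules (default
#'   8; a single value or an 8 x 5 matrix).
#' @return a [GroundTruthNetwork-class].
#' @export
buildTwoPathwayNetwork <- function(pathwaySplit = 0.5, metastability = 0.98,
                                   emissionSd = 8) {
  stopifnot(pathwaySplit >= 0, pathwaySplit <= 1,
            metastability > 0, metastability < 1)
  f <- function(s) classicalFraction(weightsToT(twoPathwayWeights(s),
                                                metastability))
  if (pathwaySplit <= 0) s <- 0
  else if (pathwaySplit >= 1) s <- 1
  else {
    lo <- 1e-6; hi <- 1 - 1e-6
    for (it in 1:60) {
      s <- (lo + hi) / 2
      if (f(s) < pathwaySplit) lo <- s else hi <- s
      if (hi - lo < 1e-10) break
    }
  }
  T <- weightsToT(twoPathwayWeights(s), metastability)
  means <- matrix(c(
    #  n_ice_nuc  n_rho_nuc  n_hex_l2  n_hex_l3  n_hex_upper
            5,        1,        0,        0,        0,   # I   liquid
           80,       10,       10,        2,        0,   # II  early nucleus
          220,       90,       30,        8,        2,   # III rhombic-rich
          250,       15,       70,       30,        8,   # IV  hex critical
          310,       40,       85,       42,       12,   # V   late conversion
          420,       12,      110,       70,       30,   # VI  growth
          560,        8,      140,      100,       60,   # VII grown
          630,        6,      150,      112,       80    # VIII grown
  ), nrow = 8, byrow = TRUE,
  dimnames = list(c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"),
                  cvSelectedNames))
  sds <- if (is.matrix(emissionSd)) emissionSd else
    matrix(emissionSd, 8, 5, dimnames = dimnames(means))
  new("GroundTruthNetwork", transition = T, emissionMeans = means,
      emissionSds = sds, pathwaySplit = pathwaySplit,
      metastability = metastability)
}

#' Emit CV trajectories from a ground-truth network
#'
#' Samples hidden state chains from the true transition matrix and draws
#' per-frame observed CVs from each state's Gaussian emission law
#' (independent per-CV noise, rounded to non-negative integer counts). The
#' true discrete trajectories are returned for recovery scoring.
#'
#' @param net a [GroundTruthNetwork-class].
#' @param nTraj number of trajectories.
#' @param nSteps steps per trajectory.
#' @param seed integer seed.
#' @param start starting state (default 1 = liquid basin I).
#' @return list with `series` (list of [CVSeries-class]) and `dtrajs`
#'   (list of true hidden-state sequences).
#' @export
emitTrajectories <- function(net, nTraj, nSteps, seed = 1, start = 1L) {
  dtrajs <- sampleChain(net@transition, nSteps, nTraj, seed = seed,
                        start = start)
  series <- lapply(seq_len(nTraj), function(tr) {
    d <- dtrajs[[tr]]
    noise <- withSeed(seed + 1000 + tr,
      matrix(stats::rnorm(length(d) * 5), length(d), 5))
    x <- net@emissionMeans[d, , drop = FALSE] +
      noise * net@emissionSds[d, , drop = FALSE]
    x <- pmax(round(x), 0)
    colnames(x) <- colnames(net@emissionMeans)
    CVSeries(x, stride = 1)
  })
  list(series = series, dtrajs = dtrajs)
}

#' Build an ideal molecular configuration
#'
#' Three generators with tunable Gaussian positional noise:
#' \describe{
#'   \item{hex_slab}{wurtzite-like oxygen sublattice of stacked bilayers
#'     (every interior molecule tetrahedrally 4-coordinated at ~0.276 nm),
#'     lattice constants a = 0.4519 nm, c = 0.7357 nm. `nx`, `ny` replicate
#'     the orthorhombic cell (a x sqrt(3) a); `nBilayers` stacks bilayers.
#'     The box is fully periodic when `nBilayers` is even, otherwise open
#'     in z.}
#'   \item{rhombic_monolayer}{planar square-like net with 4 intralayer
#'     neighbors at 0.276 nm, periodic in x and y.}
#'   \item{liquid}{hard-sphere-rejection random packing at 33 molecules per
#'     nm^3 with a 0.2 nm overlap exclusion.}
#' }
#'
#' @param kind `"hex_slab"`, `"rhombic_monolayer"` or `"liquid"`.
#' @param nx,ny in-plane cell replications (hex/rhombic kinds).
#' @param nBilayers number of stacked bilayers (hex_slab).
#' @param box box lengths for `"liquid"` (nm).
#' @param noiseSd Gaussian displacement noise, nm (default 0).
#' @param seed seed for noise and liquid packing.
#' @param surfaceTopZ optional surface height recorded in the frame, nm.
#' @return a [Frame-class].
#' @export
buildLattice <- function(kind = c("hex_slab", "rhombic_monolayer", "liquid"),
                         nx = 3, ny = 2, nBilayers = 4, box = c(2.5, 2.5, 2.5),
                         noiseSd = 0, seed = 1, surfaceTopZ = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(noiseSd >= 0)
  a <- .iceLattice$a; cc <- .iceLattice$c
  if (kind == "hex_slab") {
    xyA <- rbind(c(0, a / sqrt(3)), c(a / 2, a / sqrt(3) + sqrt(3) * a / 2))
    xyB <- rbind(c(a / 2, a / (2 * sqrt(3))),
                 c(0, a / (2 * sqrt(3)) + sqrt(3) * a / 2))
    pos <- NULL
    for (b in seq_len(nBilayers) - 1) {
      xy <- if (b %% 2 == 0) xyA else xyB
      for (dz in c(0, 3 * cc / 8)) {
        z <- b * cc / 2 + dz
        for (i in seq_len(nx) - 1) for (j in seq_len(ny) - 1)
          pos <- rbind(pos, cbind(xy[, 1] + i * a,
                                  xy[, 2] + j * sqrt(3) * a, z))
      }
    }
    periodic <- c(TRUE, TRUE, nBilayers %% 2 == 0)
    bx <- c(nx * a, ny * sqrt(3) * a,
            if (periodic[3]) nBilayers * cc / 2 else
              nBilayers * cc / 2 + 2)
  } else if (kind == "rhombic_monolayer") {
    d0 <- 0.276
    g <- expand.grid(x = (seq_len(nx * 2) - 1) * d0,
                     y = (seq_len(ny * 2) - 1) * d0)
    pos <- cbind(g$x, g$y, 0)
    periodic <- c(TRUE, TRUE, FALSE)
    bx <- c(nx * 2 * d0, ny * 2 * d0, 3)
  } else {
    n <- round(33 * prod(box))
    pos <- matrix(NA_real_, n, 3)
    withSeed(seed, {
      cnt <- 0; tries <- 0
      while (cnt < n && tries < 1e6) {
        p <- stats::runif(3) * box
        ok <- TRUE
        if (cnt > 0) {
          d2 <- minImageDist2(pos[seq_len(cnt), , drop = FALSE], p, box,
                              c(TRUE, TRUE, TRUE))
          ok <- min(d2) > 0.2^2
        }
        if (ok) { cnt <- cnt + 1; pos[cnt, ] <- p }
        tries <- tries + 1
      }
      if (cnt < n) stop("liquid packing failed at density 33/nm^3")
    })
    periodic <- c(TRUE, TRUE, TRUE)
    bx <- box
  }
  if (noiseSd > 0)
    pos <- pos + withSeed(seed + 1,
      matrix(stats::rnorm(length(pos), sd = noiseSd), nrow(pos), 3))
  Frame(oxygen = pos, box = bx, periodic = periodic,
        surfaceTopZ = surfaceTopZ)
}
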