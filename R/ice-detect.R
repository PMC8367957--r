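# Averaged Steinhardt bond-order ice detection.
#
# Each water molecule i is classified from the averaged bond-order parameters
#   qbar_l(i) = sqrt( 4*pi/(2l+1) * sum_m | (1/(N_i+1)) sum_{j in {i} u nbrs(i)}
#                                            q_lm(j) |^2 ),
#   q_lm(j)   = (1/N_j) sum_{k in nbrs(j)} Y_lm( r_j - r_k ),
# with N = 4 nearest neighbors for bulk molecules and N = 3 for molecules at
# the water-surface interface. Hexagonal ice in the bulk: qbar6 > 0.45.
# At the interface: hexagonal iff qbar6 > 0.5 and qbar4 < 0.6; rhombic iff
# qbar4 > 0.6 (the rhombic rule takes precedence).

#' Detection parameters for ice classification
#'
#' Thresholds and geometric cutoffs for the averaged bond-order classifier.
#' Defaults follow the supercooled-water-on-wurtzite setting: bulk molecules
#' use 4 nearest neighbors and the hexagonal threshold qbar6 > 0.45;
#' interface molecules (within `interfaceZCutoff` of the surface top layer)
#' use 3 neighbors with hexagonal (qbar6 > 0.5, qbar4 < 0.6) and rhombic
#' (qbar4 > 0.6) rules. `layerSpacing` defaults to c/2 of the ice lattice
#' (c = 0.7357 nm), `clusterCutoff` to the first minimum of the O-O pair
#' correlation (0.35 nm).
#'
#' @slot nNeighborsBulk,nNeighborsInterface neighbor counts (4 and 3).
#' @slot qbar6Bulk bulk hexagonal threshold on qbar6 (0.45).
#' @slot qbar6Interface interface hexagonal threshold on qbar6 (0.5).
#' @slot qbar4Low interface hexagonal upper bound on qbar4 (0.6).
#' @slot qbar4High interface rhombic threshold on qbar4 (0.6).
#' @slot clusterCutoff O-O distance defining nucleus connectivity, nm.
#' @slot interfaceZCutoff height above the surface within which the
#'   interface rules apply, nm.
#' @slot layerSpacing layer thickness for layer indexing, nm.
#' @export
setClass("DetectionParams",
  representation(
    nNeighborsBulk = "integer", nNeighborsInterface = "integer",
    qbar6Bulk = "numeric", qbar6Interface = "numeric",
    qbar4Low = "numeric", qbar4High = "numeric",
    clusterCutoff = "numeric", interfaceZCutoff = "numeric",
    layerSpacing = "numeric"
  ),
  prototype(
    nNeighborsBulk = 4L, nNeighborsInterface = 3L,
    qbar6Bulk = 0.45, qbar6Interface = 0.5,
    qbar4Low = 0.6, qbar4High = 0.6,
    clusterCutoff = 0.35, interfaceZCutoff = 0.35, layerSpacing = 0.7357 / 2
  )
)

setValidity("DetectionParams", function(object) {
  msg <- character()
  th <- c(object@qbar6Bulk, object@qbar6Interface, object@qbar4Low,
          object@qbar4High)
  if (any(th <= 0) || any(th >= 1))
    msg <- c(msg, "thresholds must lie in (0, 1)")
  if (object@nNeighborsBulk < 1L || object@nNeighborsInterface < 1L)
    msg <- c(msg, "neighbor counts must be >= 1")
  if (any(c(object@clusterCutoff, object@interfaceZCutoff,
            object@layerSpacing) <= 0))
    msg <- c(msg, "cutoffs must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname DetectionParams-class
#' @param ... named slot overrides, e.g. `DetectionParams(clusterCutoff = 0.4)`.
#' @export
DetectionParams <- function(...) {
  args <- list(...)
  for (nm in c("nNeighborsBulk", "nNeighborsInterface"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list(Class = "DetectionParams"), args))
}

# Complex spherical harmonics Y_lm for unit vectors u (n x 3); returns an
# n x (2l+1) complex matrix with columns m = -l, ..., l. Built on the
# associated Legendre functions of pracma (Condon-Shortley convention).
sphericalHarmonics <- function(l, u) {
  ct <- pmin(1, pmax(-1, u[, 3]))
  phi <- atan2(u[, 2], u[, 1])
  P <- pracma::legendre(l, ct)           # (l+1) x n, orders m = 0..l
  if (is.vector(P)) P <- matrix(P, ncol = 1)
  out <- matrix(0 + 0i, nrow(u), 2L * l + 1L)
  for (m in 0:l) {
    nf <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) -
                                            lgamma(l + m + 1)))
    Yp <- nf * P[m + 1L, ] * exp(1i * m * phi)
    out[, l + 1L + m] <- Yp
    if (m > 0L) out[, l + 1L - m] <- (-1)^m * Conj(Yp)
  }
  out
}

#' Local bond-order vector q_lm of one molecule
#'
#' Averages the order-l spherical harmonics over the minimum-image unit
#' separation vectors from molecule `j` to the given neighbors.
#'
#' @param frame a [Frame-class].
#' @param j molecule index.
#' @param neighbors integer vector of neighbor indices.
#' @param l spherical-harmonic order.
#' @return complex vector of length `2l + 1` (components m = -l..l).
#' @export
qlm <- function(frame, j, neighbors, l) {
  if (!length(neighbors)) stop("neighbor list must be non-empty")
  d <- -minImageDisp(frame@oxygen[neighbors, , drop = FALSE],
                     frame@oxygen[j, ], frame@box, frame@periodic)
  r <- sqrt(rowSums(d * d))
  if (any(r < 1e-12))
    stop("degenerate zero-length separation vector at molecule ", j)
  colMeans(sphericalHarmonics(l, d / r))
}

# per-molecule neighbor lists under a per-molecule neighbor count
neighborLists <- function(frame, nNeighbors) {
  lapply(seq_len(nrow(frame@oxygen)), function(i)
    nearestNeighbors(frame, i, nNeighbors[i]))
}

# interface mask: molecules within interfaceZCutoff above the surface top
interfaceMask <- function(frame, params) {
  if (is.na(frame@surfaceTopZ))
    return(rep(FALSE, nrow(frame@oxygen)))
  (frame@oxygen[, 3] - frame@surfaceTopZ) <= params@interfaceZCutoff
}

# qbar_l for all molecules given per-molecule neighbor lists
qbarFromNeighbors <- function(frame, l, nbrs) {
  N <- nrow(frame@oxygen)
  qmat <- matrix(0 + 0i, N, 2L * l + 1L)
  for (j in seq_len(N)) qmat[j, ] <- qlm(frame, j, nbrs[[j]], l)
  vapply(seq_len(N), function(i) {
    avg <- colMeans(qmat[c(i, nbrs[[i]]), , drop = FALSE])
    sqrt(4 * pi / (2 * l + 1) * sum(Mod(avg)^2))
  }, numeric(1))
}

#' Averaged bond-order parameter qbar_l for every molecule
#'
#' Evaluates the neighbor-averaged Steinhardt parameter of order `l` for all
#' molecules of a frame. Each molecule uses its own rule-dependent neighbor
#' count: `nNeighborsInterface` within `interfaceZCutoff` of the surface,
#' `nNeighborsBulk` otherwise (all bulk when the frame has no surface).
#'
#' @param frame a [Frame-class].
#' @param l spherical-harmonic order (4 or 6 for ice polymorph detection).
#' @param params a [DetectionParams-class].
#' @return numeric vector of per-molecule qbar_l values in [0, 1].
#' @export
averagedQbar <- function(frame, l, params = DetectionParams()) {
  iface <- interfaceMask(frame, params)
  nn <- ifelse(iface, params@nNeighborsInterface, params@nNeighborsBulk)
  qbarFromNeighbors(frame, l, neighborLists(frame, nn))
}

#' Classify every molecule as hexagonal ice, rhombic ice, or liquid
#'
#' Applies the averaged bond-order rules, finds the largest ice nucleus, and
#' assigns surface layers. Molecules within `interfaceZCutoff` of the surface
#' top use the interface rules (3 neighbors; rhombic iff qbar4 > 0.6,
#' otherwise hexagonal iff qbar6 > 0.5 and qbar4 < 0.6); all others use the
#' bulk rule (4 neighbors; hexagonal iff qbar6 > 0.45, never rhombic).
#'
#' @param frame a [Frame-class]; `surfaceTopZ` must be set whenever any
#'   molecule lies within `interfaceZCutoff` of a surface.
#' @param params a [DetectionParams-class].
#' @return a [PhaseLabels-class] with labels, layers, nucleus membership and
#'   both qbar4 and qbar6 stored.
#' @export
classifyFrame <- function(frame, params = DetectionParams()) {
  iface <- interfaceMask(frame, params)
  nn <- ifelse(iface, params@nNeighborsInterface, params@nNeighborsBulk)
  nbrs <- neighborLists(frame, nn)
  q4 <- qbarFromNeighbors(frame, 4L, nbrs)
  q6 <- qbarFromNeighbors(frame, 6L, nbrs)
  labels <- rep("LIQUID", nrow(frame@oxygen))
  labels[!iface & q6 > params@qbar6Bulk] <- "HEX"
  hexI <- iface & q6 > params@qbar6Interface & q4 < params@qbar4Low
  labels[hexI] <- "HEX"
  labels[iface & q4 > params@qbar4High] <- "RHOMBIC"  # rhombic rule wins
  lab <- PhaseLabels(labels,
                     layer = assignLayers(frame, params),
                     nucleus = integer(),
                     qbar4 = q4, qbar6 = q6)
  lab@nucleus <- largestIceCluster(lab, frame, params@clusterCutoff)
  validObject(lab)
  lab
}

#' Largest connected ice nucleus
#'
#' Connected components over ice-labeled molecules (HEX or RHOMBIC) with
#' edges between pairs at minimum-image O-O distance at most `cutoff`;
#' returns the largest component. Size ties are broken in favour of the
#' component containing the smallest molecule index.
#'
#' @param labels a [PhaseLabels-class].
#' @param frame the corresponding [Frame-class].
#' @param cutoff O-O connectivity distance, nm.
#' @return integer vector of molecule indices (empty if no ice).
#' @export
largestIceCluster <- function(labels, frame, cutoff = 0.35) {
  stopifnot(cutoff > 0)
  ice <- which(labels@labels != "LIQUID")
  if (!length(ice)) return(integer())
  pos <- frame@oxygen[ice, , drop = FALSE]
  n <- length(ice)
  # union-find over ice molecules
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  c2 <- cutoff^2
  if (n > 1) for (a in seq_len(n - 1)) {
    d2 <- minImageDist2(pos[(a + 1):n, , drop = FALSE], pos[a, ],
                        frame@box, frame@periodic)
    for (b in which(d2 <= c2)) {
      ra <- find(a); rb <- find(a + b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(ice, roots)
  sizes <- lengths(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    mins <- vapply(comp[best], min, integer(1))
    best <- best[which.min(mins)]
  }
  sort(comp[[best]])
}

#' Assign surface layer indices
#'
#' `layer(i) = floor((z_i - surfaceTopZ) / layerSpacing)`, clamped at 0.
#' Molecules more than 0.05 nm below the surface top trigger a geometry
#' warning and are clamped to layer 0. Frames without a surface
#' (`surfaceTopZ` = `NA`) are layered from the lowest oxygen.
#'
#' @param frame a [Frame-class].
#' @param params a [DetectionParams-class] (uses `layerSpacing`).
#' @return integer vector of per-molecule layer indices.
#' @export
assignLayers <- function(frame, params = DetectionParams()) {
  z0 <- if (is.na(frame@surfaceTopZ)) min(frame@oxygen[, 3]) else
    frame@surfaceTopZ
  dz <- frame@oxygen[, 3] - z0
  if (any(dz < -0.05))
    warning(sum(dz < -0.05), " molecule(s) more than 0.05 nm below the ",
            "surface top; clamped to layer 0")
  pmax(0L, as.integer(floor(dz / params@layerSpacing)))
}

#' Classify every frame of a trajectory
#'
#' @param traj a [Trajectory-class].
#' @param params a [DetectionParams-class].
#' @return list of [PhaseLabels-class], one per frame.
#' @export
detectTrajectory <- function(traj, params = DetectionParams()) {
  lapply(traj@frames, classifyFrame, params = params)
}
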