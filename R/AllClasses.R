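#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Frame: one molecular configuration
#'
#' A single configuration of water (oxygen positions, optionally hydrogens) in
#' an orthorhombic, possibly periodic box. Coordinates are stored in
#' nanometres. `surfaceTopZ` is the z coordinate of the topmost fixed
#' surface-atom layer, used to decide which molecules sit at the water-surface
#' interface; it may be `NA` for configurations without a surface.
#'
#' @slot oxygen numeric matrix (N x 3), oxygen coordinates in nm.
#' @slot hydrogen numeric matrix (2N x 3) of hydrogen coordinates, or `NULL`.
#' @slot box numeric(3), orthorhombic box edge lengths in nm.
#' @slot periodic logical(3), per-axis periodicity flags.
#' @slot time numeric(1), frame time in ps.
#' @slot surfaceTopZ numeric(1), z of topmost surface layer in nm, or `NA`.
#' @export
setClass("Frame",
  representation(
    oxygen = "matrix",
    hydrogen = "matrixOrNULL",
    box = "numeric",
    periodic = "logical",
    time = "numeric",
    surfaceTopZ = "numeric"
  ),
  prototype(
    hydrogen = NULL, periodic = c(TRUE, TRUE, TRUE),
    time = 0, surfaceTopZ = NA_real_
  )
)

setValidity("Frame", function(object) {
  msg <- character()
  if (!is.numeric(object@oxygen) || ncol(object@oxygen) != 3L)
    msg <- c(msg, "oxygen must be a numeric N x 3 matrix")
  if (nrow(object@oxygen) < 1L)
    msg <- c(msg, "at least one oxygen required")
  if (!all(is.finite(object@oxygen)))
    msg <- c(msg, "oxygen coordinates must be finite")
  if (length(object@box) != 3L || any(!is.finite(object@box)) ||
      any(object@box <= 0))
    msg <- c(msg, "box must be three positive finite lengths")
  if (length(object@periodic) != 3L || anyNA(object@periodic))
    msg <- c(msg, "periodic must be three logical flags")
  if (!is.null(object@hydrogen)) {
    if (ncol(object@hydrogen) != 3L)
      msg <- c(msg, "hydrogen must be an M x 3 matrix")
    else if (nrow(object@hydrogen) != 2L * nrow(object@oxygen))
      msg <- c(msg, "hydrogen count must equal 2 x oxygen count")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Frame
#'
#' @param oxygen N x 3 numeric matrix of oxygen coordinates (nm).
#' @param box numeric(3) box lengths (nm).
#' @param hydrogen optional 2N x 3 matrix of hydrogen coordinates (nm).
#' @param periodic logical(3) periodicity flags.
#' @param time frame time (ps).
#' @param surfaceTopZ z of the topmost surface layer (nm) or `NA`.
#' @return A [Frame-class] object.
#' @export
Frame <- function(oxygen, box, hydrogen = NULL,
                  periodic = c(TRUE, TRUE, TRUE), time = 0,
                  surfaceTopZ = NA_real_) {
  new("Frame", oxygen = as.matrix(oxygen), box = as.numeric(box),
      hydrogen = if (is.null(hydrogen)) NULL else as.matrix(hydrogen),
      periodic = as.logical(periodic), time = as.numeric(time),
      surfaceTopZ = as.numeric(surfaceTopZ))
}

setMethod("show", "Frame", function(object) {
  cat(sprintf("Frame: %d waters, box %.3f x %.3f x %.3f nm, t = %g ps\n",
              nrow(object@oxygen), object@box[1], object@box[2],
              object@box[3], object@time))
})

#' Trajectory: an ordered sequence of Frames
#'
#' @slot frames list of [Frame-class] objects with a constant oxygen count.
#' @slot stride numeric(1), time between consecutive frames in ps.
#' @export
setClass("Trajectory",
  representation(frames = "list", stride = "numeric"),
  prototype(stride = 1)
)

setValidity("Trajectory", function(object) {
  if (length(object@frames) == 0L) return("trajectory must be non-empty")
  if (!all(vapply(object@frames, is, logical(1), class2 = "Frame")))
    return("frames must all be Frame objects")
  ns <- vapply(object@frames, function(f) nrow(f@oxygen), integer(1))
  if (length(unique(ns)) != 1L)
    return("oxygen count must be constant across frames")
  if (length(object@stride) != 1L || object@stride <= 0)
    return("stride must be a single positive time in ps")
  TRUE
})

#' @rdname Trajectory-class
#' @param frames list of [Frame-class] objects.
#' @param stride time between frames (ps).
#' @export
Trajectory <- function(frames, stride = 1) {
  new("Trajectory", frames = frames, stride = as.numeric(stride))
}

#' @describeIn Trajectory-class number of frames.
#' @param x a `Trajectory`.
#' @export
setMethod("length", "Trajectory", function(x) length(x@frames))

#' @export
setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames of %d waters, stride %g ps\n",
              length(object@frames), nrow(object@frames[[1]]@oxygen),
              object@stride))
})

#' Frame accessor
#' @param x a [Trajectory-class].
#' @param i frame index.
#' @return The i-th [Frame-class].
#' @export
getFrame <- function(x, i) {
  stopifnot(is(x, "Trajectory"))
  x@frames[[i]]
}

#' PhaseLabels: per-molecule polymorph classification of one frame
#'
#' Output of [classifyFrame()]: one label per water molecule (`"LIQUID"`,
#' `"HEX"` or `"RHOMBIC"`), its surface layer index (0 = contact layer),
#' membership of the largest ice nucleus, and the averaged bond-order
#' parameters that produced the labels.
#'
#' @slot labels character vector of per-molecule labels.
#' @slot layer integer vector of layer indices (0-based, clamped at 0).
#' @slot nucleus integer vector of molecule indices in the largest ice nucleus.
#' @slot qbar4,qbar6 per-molecule averaged bond-order parameters in [0, 1].
#' @export
setClass("PhaseLabels",
  representation(labels = "character", layer = "integer",
                 nucleus = "integer", qbar4 = "numeric", qbar6 = "numeric")
)

setValidity("PhaseLabels", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (!all(object@labels %in% c("LIQUID", "HEX", "RHOMBIC")))
    msg <- c(msg, "labels must be LIQUID, HEX or RHOMBIC")
  if (length(object@layer) != n || any(object@layer < 0L))
    msg <- c(msg, "layer must be per-molecule non-negative integers")
  if (length(object@nucleus) &&
      (any(object@nucleus < 1L) || any(object@nucleus > n)))
    msg <- c(msg, "nucleus indices out of range")
  if (any(object@labels[object@nucleus] == "LIQUID"))
    msg <- c(msg, "nucleus may contain only ice-labeled molecules")
  for (s in c("qbar4", "qbar6")) {
    q <- slot(object, s)
    if (length(q) != n || any(q < -1e-9) || any(q > 1 + 1e-9))
      msg <- c(msg, sprintf("%s must be per-molecule values in [0, 1]", s))
  }
  if (length(msg)) msg else TRUE
})

PhaseLabels <- function(labels, layer, nucleus, qbar4, qbar6) {
  new("PhaseLabels", labels = as.character(labels),
      layer = as.integer(layer), nucleus = as.integer(nucleus),
      qbar4 = as.numeric(qbar4), qbar6 = as.numeric(qbar6))
}

setMethod("show", "PhaseLabels", function(object) {
  tab <- table(factor(object@labels, c("LIQUID", "HEX", "RHOMBIC")))
  cat(sprintf(
    "PhaseLabels: %d molecules (%d LIQUID, %d HEX, %d RHOMBIC), nucleus %d\n",
    length(object@labels), tab[["LIQUID"]], tab[["HEX"]], tab[["RHOMBIC"]],
    length(object@nucleus)))
})

#' CVSeries: per-frame collective-variable vectors
#'
#' A frames x K matrix of collective variables (layer-resolved ice counts in
#' the largest nucleus plus geometric descriptors), either the full candidate
#' pool (K = 18) or the selected subset (K = 5).
#'
#' @slot data numeric matrix (frames x K), no missing values.
#' @slot stride numeric(1), frame spacing in ps.
#' @export
setClass("CVSeries",
  representation(data = "matrix", stride = "numeric"),
  prototype(stride = 1)
)

setValidity("CVSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (anyNA(object@data)) msg <- c(msg, "data must have no missing values")
  nm <- colnames(object@data)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "columns must carry unique CV names")
  if (length(object@stride) != 1L || object@stride <= 0)
    msg <- c(msg, "stride must be a single positive time in ps")
  if (length(msg)) msg else TRUE
})

#' @rdname CVSeries-class
#' @param data frames x K numeric matrix with column names.
#' @param stride frame spacing (ps).
#' @export
CVSeries <- function(data, stride = 1) {
  new("CVSeries", data = as.matrix(data), stride = as.numeric(stride))
}

#' @describeIn CVSeries-class the frames x K matrix.
#' @param object a `CVSeries`.
#' @export
cvMatrix <- function(object) {
  stopifnot(is(object, "CVSeries"))
  object@data
}

#' @export
setMethod("dim", "CVSeries", function(x) dim(x@data))

setMethod("show", "CVSeries", function(object) {
  cat(sprintf("CVSeries: %d frames x %d CVs, stride %g ps\n",
              nrow(object@data), ncol(object@data), object@stride))
  cat(" CVs:", paste(colnames(object@data), collapse = ", "), "\n")
})

#' MicrostateModel: a discrete-state Markov state model
#'
#' Holds the k-centers discretization (cluster centers in CV space and
#' discrete trajectories), the transition-count matrix at the estimation lag,
#' the row-stochastic transition matrix restricted to the largest
#' strongly-connected set of states, and its stationary distribution.
#'
#' @slot centers n_states x K matrix of cluster centers (original CV units).
#' @slot dtrajs list of integer vectors, one per trajectory (1-based states).
#' @slot lag integer(1), estimation lag in frames.
#' @slot lagTime numeric(1), physical time per lag in ps.
#' @slot counts transition count matrix over all states.
#' @slot transition row-stochastic matrix over the active set.
#' @slot stationary stationary distribution over the active set.
#' @slot active integer vector mapping active-set rows to original states.
#' @slot reversible logical(1), whether detailed balance was enforced.
#' @export
setClass("MicrostateModel",
  representation(centers = "matrix", dtrajs = "list", lag = "integer",
                 lagTime = "numeric", counts = "matrix",
                 transition = "matrix", stationary = "numeric",
                 active = "integer", reversible = "logical")
)

setValidity("MicrostateModel", function(object) {
  msg <- character()
  T <- object@transition
  if (nrow(T) != ncol(T)) msg <- c(msg, "transition matrix must be square")
  if (max(abs(rowSums(T) - 1)) > 1e-10)
    msg <- c(msg, "transition rows must sum to 1")
  pi <- object@stationary
  if (length(pi) != nrow(T) || any(pi < -1e-12) || abs(sum(pi) - 1) > 1e-8)
    msg <- c(msg, "stationary distribution must be a probability vector")
  if (max(abs(pi %*% T - pi)) > 1e-8)
    msg <- c(msg, "stationary vector must satisfy pi T = pi")
  if (length(object@active) != nrow(T))
    msg <- c(msg, "active map must match transition dimension")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MicrostateModel", function(object) {
  ev <- sort(Re(eigen(object@transition, only.values = TRUE)$values),
             decreasing = TRUE)
  cat(sprintf(
    "MicrostateModel: %d/%d active states, lag %d frames (%g ps), %s\n",
    nrow(object@transition), nrow(object@centers), object@lag,
    object@lagTime, if (object@reversible) "reversible" else "non-reversible"))
  if (length(ev) > 1)
    cat(sprintf(" slowest implied timescale: %.3g frames\n",
                -object@lag / log(max(min(ev[2], 1 - 1e-15), 1e-15))))
})

#' @describeIn MicrostateModel-class the row-stochastic transition matrix.
#' @param object a `MicrostateModel`.
#' @export
transitionMatrix <- function(object) {
  stopifnot(is(object, "MicrostateModel"))
  object@transition
}

#' @describeIn MicrostateModel-class the stationary distribution.
#' @export
stationaryDistribution <- function(object) {
  stopifnot(is(object, "MicrostateModel"))
  object@stationary
}

#' @describeIn MicrostateModel-class discrete trajectories re-indexed to the
#'   active set (states outside the active set become `NA`).
#' @export
activeDtrajs <- function(object) {
  stopifnot(is(object, "MicrostateModel"))
  map <- rep(NA_integer_, nrow(object@centers))
  map[object@active] <- seq_along(object@active)
  lapply(object@dtrajs, function(d) map[d])
}

#' MacroModel: PCCA+ lumping of a microstate model
#'
#' @slot membership n_micro x n_macro matrix of fuzzy memberships (rows on
#'   the probability simplex).
#' @slot crisp integer vector, micro -> macro assignment (argmax membership).
#' @slot macroT coarse-grained row-stochastic transition matrix.
#' @slot macroPi aggregated stationary distribution.
#' @export
setClass("MacroModel",
  representation(membership = "matrix", crisp = "integer",
                 macroT = "matrix", macroPi = "numeric")
)

setValidity("MacroModel", function(object) {
  msg <- character()
  M <- object@membership
  if (any(M < -1e-10)) msg <- c(msg, "memberships must be non-negative")
  if (max(abs(rowSums(M) - 1)) > 1e-10)
    msg <- c(msg, "membership rows must sum to 1")
  if (length(object@crisp) != nrow(M))
    msg <- c(msg, "crisp map must cover all microstates")
  if (max(abs(rowSums(object@macroT) - 1)) > 1e-10)
    msg <- c(msg, "macro transition rows must sum to 1")
  if (abs(sum(object@macroPi) - 1) > 1e-8)
    msg <- c(msg, "macro stationary distribution must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MacroModel", function(object) {
  cat(sprintf("MacroModel: %d microstates -> %d macro-states\n",
              nrow(object@membership), ncol(object@membership)))
  cat(" macro populations:",
      paste(sprintf("%.3f", object@macroPi), collapse = " "), "\n")
})

#' @describeIn MacroModel-class the crisp micro-to-macro assignment.
#' @param object a `MacroModel`.
#' @export
crispAssignment <- function(object) {
  stopifnot(is(object, "MacroModel"))
  object@crisp
}

#' @describeIn MacroModel-class the fuzzy membership matrix.
#' @export
memberships <- function(object) {
  stopifnot(is(object, "MacroModel"))
  object@membership
}

#' TPTResult: transition path theory analysis of a Markov chain
#'
#' @slot A,B integer vectors, source and sink state sets.
#' @slot qPlus,qMinus forward and backward committors.
#' @slot flux gross reactive flux matrix (per lag).
#' @slot netFlux net reactive flux matrix, zero diagonal.
#' @slot totalFlux scalar total A -> B reactive flux per lag.
#' @slot pathways list of `list(path = <state vector>, flux = <scalar>)`,
#'   sorted by flux, from the iterative bottleneck decomposition.
#' @export
setClass("TPTResult",
  representation(A = "integer", B = "integer", qPlus = "numeric",
                 qMinus = "numeric", flux = "matrix", netFlux = "matrix",
                 totalFlux = "numeric", pathways = "list")
)

setValidity("TPTResult", function(object) {
  msg <- character()
  if (any(object@qPlus < -1e-10) || any(object@qPlus > 1 + 1e-10))
    msg <- c(msg, "committors must lie in [0, 1]")
  if (max(abs(object@qPlus[object@A])) > 1e-12 ||
      max(abs(object@qPlus[object@B] - 1)) > 1e-12)
    msg <- c(msg, "committor boundary conditions violated")
  if (any(object@flux < -1e-14)) msg <- c(msg, "flux must be non-negative")
  if (any(diag(object@netFlux) != 0))
    msg <- c(msg, "net flux diagonal must be zero")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TPTResult", function(object) {
  cat(sprintf(
    "TPTResult: |A| = %d, |B| = %d, total flux %.4g per lag, %d pathways\n",
    length(object@A), length(object@B), object@totalFlux,
    length(object@pathways)))
})

#' GroundTruthNetwork: synthetic metastable two-pathway nucleation network
#'
#' An 8-state kinetic network (states named I-VIII) with a classical branch
#' II -> IV and a non-classical branch II -> III -> IV/V, whose branch
#' probabilities are tuned so a requested fraction of the reactive I -> VII/
#' VIII flux follows the classical branch. Each state emits the five selected
#' collective variables with Gaussian noise.
#'
#' @slot transition true row-stochastic transition matrix (8 x 8).
#' @slot emissionMeans 8 x 5 matrix of state CV means.
#' @slot emissionSds 8 x 5 matrix of per-state CV standard deviations.
#' @slot pathwaySplit target classical fraction of the A -> B flux.
#' @slot metastability per-state self-transition probability.
#' @export
setClass("GroundTruthNetwork",
  representation(transition = "matrix", emissionMeans = "matrix",
                 emissionSds = "matrix", pathwaySplit = "numeric",
                 metastability = "numeric")
)

setValidity("GroundTruthNetwork", function(object) {
  msg <- character()
  T <- object@transition
  if (nrow(T) != 8L || ncol(T) != 8L)
    msg <- c(msg, "network must have 8 states")
  if (max(abs(rowSums(T) - 1)) > 1e-10 || any(T < -1e-14))
    msg <- c(msg, "transition matrix must be row-stochastic")
  if (!all(is.finite(object@emissionMeans)) ||
      !all(is.finite(object@emissionSds)))
    msg <- c(msg, "emissions must be finite")
  if (object@pathwaySplit < 0 || object@pathwaySplit > 1)
    msg <- c(msg, "pathwaySplit must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruthNetwork", function(object) {
  cat(sprintf(
    "GroundTruthNetwork: 8 states I-VIII, classical split %.2f, metastability %.3f\n",
    object@pathwaySplit, object@metastability))
})
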