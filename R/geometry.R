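# Minimum-image geometry helpers for orthorhombic, possibly periodic boxes.

# displacement vectors pos[k,] - ref for all rows, minimum image per periodic axis
minImageDisp <- function(pos, ref, box, periodic) {
  d <- sweep(pos, 2, ref)
  for (k in 1:3)
    if (periodic[k]) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

minImageDist2 <- function(pos, ref, box, periodic) {
  d <- minImageDisp(pos, ref, box, periodic)
  rowSums(d * d)
}

#' Nearest oxygen neighbors under the minimum-image convention
#'
#' Returns the indices of the `n` oxygens closest to molecule `i`, using
#' minimum-image distances in the frame's orthorhombic box. Exact distance
#' ties are broken in favour of the lower molecule index, so the result is
#' deterministic on ideal lattices.
#'
#' @param frame a [Frame-class].
#' @param i molecule index (1-based).
#' @param n number of neighbors to return.
#' @return integer vector of `n` neighbor indices, `i` excluded.
#' @export
nearestNeighbors <- function(frame, i, n) {
  N <- nrow(frame@oxygen)
  if (n >= N)
    stop("requested ", n, " neighbors but frame has only ", N, " molecules")
  r2 <- minImageDist2(frame@oxygen, frame@oxygen[i, ], frame@box,
                      frame@periodic)
  r2[i] <- Inf
  order(r2)[seq_len(n)]  # order() is stable: ties go to the lower index
}

# wrap coordinates into [0, box) on periodic axes
wrapPositions <- function(pos, box, periodic) {
  for (k in 1:3)
    if (periodic[k]) pos[, k] <- pos[, k] - box[k] * floor(pos[, k] / box[k])
  pos
}
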