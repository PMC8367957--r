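# Collective-variable featurization: layer-resolved ice counts in the
# largest nucleus plus geometric descriptors of the nucleus.

#' Names of the candidate CV pool and the selected subset
#'
#' The 18-member candidate pool counts hexagonal/rhombic molecules in the
#' largest ice nucleus resolved by surface layer ("layer1" is the contact
#' layer, "upper" is every layer above the third), whole-frame totals, and
#' geometric descriptors of the nucleus. The selected subset comprises the
#' total ice and rhombic ice in the largest nucleus and the hexagonal ice in
#' the 2nd, 3rd and upper layers of the nucleus.
#'
#' @format character vectors of CV names.
#' @export
cvPoolNames <- c(
  "n_ice_nucleus", "n_rhombic_nucleus",
  "n_hex_layer1", "n_hex_layer2", "n_hex_layer3", "n_hex_upper",
  "n_rhombic_layer1", "n_rhombic_layer2", "n_rhombic_layer3",
  "n_rhombic_upper",
  "n_hex_total", "n_rhombic_total", "n_ice_total", "n_hex_nucleus",
  "max_layer_occupied", "nucleus_xy_extent", "nucleus_height", "sphericity"
)

#' @rdname cvPoolNames
#' @export
cvSelectedNames <- c("n_ice_nucleus", "n_rhombic_nucleus",
                     "n_hex_layer2", "n_hex_layer3", "n_hex_upper")

#' Compute collective variables from labeled frames
#'
#' For each frame, counts are computed by intersecting phase labels, layer
#' indices and largest-nucleus membership; layer-resolved counts refer to
#' molecules inside the largest nucleus ("layer2" = 1-based 2nd layer =
#' layer index 1). In `"pool18"` mode the geometric descriptors
#' (`nucleus_xy_extent`, `nucleus_height`, `sphericity`) additionally
#' require the trajectory frames. `"selected5"` is a pure column subset of
#' `"pool18"`.
#'
#' @param labels list of [PhaseLabels-class], one per frame.
#' @param mode `"selected5"` (default) or `"pool18"`.
#' @param traj optional [Trajectory-class]; required for `"pool18"`.
#' @param stride frame spacing in ps (taken from `traj` when given).
#' @return a [CVSeries-class].
#' @export
computeCVs <- function(labels, mode = c("selected5", "pool18"),
                       traj = NULL, stride = 1) {
  mode <- match.arg(mode)
  if (!length(labels)) stop("no labeled frames")
  if (mode == "pool18" && is.null(traj))
    stop("pool18 mode needs the trajectory for the geometric CVs")
  if (!is.null(traj)) stride <- traj@stride
  rows <- lapply(seq_along(labels), function(f) {
    lb <- labels[[f]]
    if (!length(lb@layer)) stop("labels are missing layer assignments")
    inNuc <- seq_along(lb@labels) %in% lb@nucleus
    hex <- lb@labels == "HEX"; rho <- lb@labels == "RHOMBIC"
    lay <- lb@layer
    v <- c(
      n_ice_nucleus = sum(inNuc),
      n_rhombic_nucleus = sum(inNuc & rho),
      n_hex_layer1 = sum(inNuc & hex & lay == 0L),
      n_hex_layer2 = sum(inNuc & hex & lay == 1L),
      n_hex_layer3 = sum(inNuc & hex & lay == 2L),
      n_hex_upper = sum(inNuc & hex & lay >= 3L),
      n_rhombic_layer1 = sum(inNuc & rho & lay == 0L),
      n_rhombic_layer2 = sum(inNuc & rho & lay == 1L),
      n_rhombic_layer3 = sum(inNuc & rho & lay == 2L),
      n_rhombic_upper = sum(inNuc & rho & lay >= 3L),
      n_hex_total = sum(hex),
      n_rhombic_total = sum(rho),
      n_ice_total = sum(hex | rho),
      n_hex_nucleus = sum(inNuc & hex),
      max_layer_occupied = if (any(hex | rho)) max(lay[hex | rho]) else 0,
      nucleus_xy_extent = 0, nucleus_height = 0, sphericity = 0
    )
    if (mode == "pool18" && sum(inNuc) > 0) {
      fr <- getFrame(traj, f)
      pos <- clusterUnwrap(fr@oxygen[lb@nucleus, , drop = FALSE],
                           fr@box, fr@periodic)
      ext <- apply(pos, 2, function(x) diff(range(x)))
      v["nucleus_xy_extent"] <- max(ext[1:2])
      v["nucleus_height"] <- ext[3]
      if (sum(inNuc) >= 4)
        v["sphericity"] <- sphericity(fr@oxygen[lb@nucleus, , drop = FALSE],
                                      fr)
    }
    v
  })
  mat <- do.call(rbind, rows)
  if (mode == "selected5") mat <- mat[, cvSelectedNames, drop = FALSE]
  CVSeries(mat, stride = stride)
}

# unwrap a compact cluster across periodic boundaries: minimum-image
# displacements relative to the first member
clusterUnwrap <- function(pos, box, periodic) {
  sweep(minImageDisp(pos, pos[1, ], box, periodic), 2, pos[1, ], `+`)
}

#' Sphericity of a molecular cluster
#'
#' Ratio of the smallest to the largest eigenvalue of the gyration tensor of
#' the (minimum-image unwrapped) cluster: 1 for a perfectly spherical
#' arrangement, approaching 0 for flat or linear shapes. Requires at least 4
#' molecules; smaller clusters return 0 with a warning.
#'
#' @param positions n x 3 matrix of cluster member coordinates (nm).
#' @param frame the [Frame-class] supplying box and periodicity.
#' @return scalar in [0, 1].
#' @export
sphericity <- function(positions, frame) {
  if (nrow(positions) < 4) {
    warning("sphericity undefined for fewer than 4 molecules; returning 0")
    return(0)
  }
  pos <- clusterUnwrap(positions, frame@box, frame@periodic)
  pos <- sweep(pos, 2, colMeans(pos))
  g <- crossprod(pos) / nrow(pos)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(0, min(ev) / max(ev))
}

#' Write a CVSeries as TSV
#' @param series a [CVSeries-class].
#' @param path output path.
#' @export
writeCVs <- function(series, path) {
  utils::write.table(cvMatrix(series), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a CVSeries from TSV
#' @param path file path.
#' @param stride frame spacing in ps.
#' @return a [CVSeries-class].
#' @export
readCVs <- function(path, stride = 1) {
  CVSeries(as.matrix(utils::read.table(path, header = TRUE, sep = "\t")),
           stride = stride)
}
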