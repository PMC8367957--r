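# Readers and writers for XYZ and LAMMPS text-dump trajectories and for
# per-molecule label tables. Coordinates are stored internally in nm;
# orthorhombic boxes only.

splitFields <- function(line) strsplit(trimws(line), "[[:space:]]+")[[1]]

#' Read an XYZ trajectory
#'
#' Reads plain or extended XYZ. The element column distinguishes oxygen,
#' hydrogen and surface species: every species not named in `oxygenSpecies`
#' or `hydrogenSpecies` is treated as a fixed surface atom, excluded from the
#' water coordinates, and the maximum z over surface atoms is recorded as the
#' frame's `surfaceTopZ`. Extended-XYZ `Lattice="ax 0 0 0 by 0 0 0 cz"`
#' comment entries override the `box` argument (orthorhombic only).
#'
#' @param path file path.
#' @param box numeric(3) box lengths in the file's length unit; required when
#'   no Lattice entry is present.
#' @param unit length unit of the file, `"nm"` (default) or `"angstrom"`.
#' @param oxygenSpecies,hydrogenSpecies element symbols for water O and H.
#' @param periodic logical(3) periodicity flags.
#' @param stride frame spacing in ps.
#' @return a [Trajectory-class].
#' @export
readXYZ <- function(path, box = NULL, unit = c("nm", "angstrom"),
                    oxygenSpecies = "O", hydrogenSpecies = "H",
                    periodic = c(TRUE, TRUE, TRUE), stride = 1) {
  unit <- match.arg(unit)
  scale <- if (unit == "angstrom") 0.1 else 1
  lines <- readLines(path)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nat) || nat < 1L)
      stop("malformed atom count at line ", ln, ": '", lines[ln], "'")
    if (ln + 1L + nat > length(lines))
      stop("truncated XYZ block starting at line ", ln)
    comment <- lines[ln + 1L]
    fbox <- box
    m <- regmatches(comment,
                    regexpr('Lattice="[^"]*"', comment))
    if (length(m) && nzchar(m)) {
      lat <- as.numeric(splitFields(gsub('Lattice="|"', "", m)))
      if (length(lat) != 9L)
        stop("malformed Lattice entry at line ", ln + 1L)
      off <- lat[c(2, 3, 4, 6, 7, 8)]
      if (any(abs(off) > 1e-9))
        stop("non-orthorhombic Lattice at line ", ln + 1L,
             "; orthorhombic boxes only")
      fbox <- lat[c(1, 5, 9)]
    }
    if (is.null(fbox))
      stop("no box: supply `box` or use extended XYZ with a Lattice entry")
    rows <- lines[(ln + 2L):(ln + 1L + nat)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    nf <- lengths(parts)
    if (any(nf < 4L))
      stop("malformed atom line at line ", ln + 1L + which(nf < 4L)[1])
    species <- vapply(parts, `[[`, character(1), 1L)
    xyz <- matrix(as.numeric(unlist(lapply(parts, function(p) p[2:4]))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(xyz))
      stop("non-numeric coordinates in XYZ block starting at line ", ln)
    isO <- species %in% oxygenSpecies
    isH <- species %in% hydrogenSpecies
    isSurf <- !isO & !isH
    surfTop <- if (any(isSurf)) max(xyz[isSurf, 3]) * scale else NA_real_
    hyd <- if (any(isH)) xyz[isH, , drop = FALSE] * scale else NULL
    if (!is.null(hyd) && nrow(hyd) != 2L * sum(isO)) hyd <- NULL
    frames[[length(frames) + 1L]] <-
      Frame(oxygen = xyz[isO, , drop = FALSE] * scale,
            box = fbox * scale, hydrogen = hyd, periodic = periodic,
            time = (length(frames)) * stride, surfaceTopZ = surfTop)
    ln <- ln + 2L + nat
  }
  if (!length(frames)) stop("no frames found in ", path)
  ns <- vapply(frames, function(f) nrow(f@oxygen), integer(1))
  if (length(unique(ns)) != 1L)
    stop("inconsistent oxygen count across frames: ",
         paste(unique(ns), collapse = ", "))
  Trajectory(frames, stride = stride)
}

#' Write a Trajectory as extended XYZ
#'
#' Oxygens are written as element `O` (hydrogens as `H` when present) with a
#' `Lattice` comment entry; coordinates in the requested unit.
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @param unit `"nm"` (default) or `"angstrom"`.
#' @export
writeXYZ <- function(traj, path, unit = c("nm", "angstrom")) {
  unit <- match.arg(unit)
  scale <- if (unit == "angstrom") 10 else 1
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj@frames) {
    nH <- if (is.null(fr@hydrogen)) 0L else nrow(fr@hydrogen)
    b <- fr@box * scale
    writeLines(as.character(nrow(fr@oxygen) + nH), con)
    writeLines(sprintf(
      'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3',
      b[1], b[2], b[3]), con)
    o <- fr@oxygen * scale
    writeLines(sprintf("O %.10f %.10f %.10f", o[, 1], o[, 2], o[, 3]), con)
    if (nH) {
      h <- fr@hydrogen * scale
      writeLines(sprintf("H %.10f %.10f %.10f", h[, 1], h[, 2], h[, 3]), con)
    }
  }
  invisible(path)
}

#' Read a LAMMPS text dump
#'
#' Supports orthorhombic `ITEM: BOX BOUNDS` (triclinic tilt headers are
#' rejected), atom sections with `id type x y z` or scaled `xs ys zs`
#' columns, and a user map from numeric atom types to species. Atoms are
#' sorted by id within each frame. Dump coordinates are assumed to be in
#' Angstrom and converted to nm (override with `unit = "nm"`).
#'
#' @param path file path.
#' @param typeMap named character vector mapping type numbers to species,
#'   e.g. `c("1" = "O", "2" = "H", "3" = "surface")`. Species other than
#'   `"O"`/`"H"` are surface atoms.
#' @param unit length unit of the dump, `"angstrom"` (default) or `"nm"`.
#' @param stride frame spacing in ps.
#' @return a [Trajectory-class].
#' @export
readLAMMPSDump <- function(path, typeMap, unit = c("angstrom", "nm"),
                           stride = 1) {
  unit <- match.arg(unit)
  scale <- if (unit == "angstrom") 0.1 else 1
  lines <- readLines(path)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    if (!startsWith(lines[ln], "ITEM: TIMESTEP"))
      stop("expected ITEM: TIMESTEP at line ", ln)
    ln <- ln + 2L
    if (!startsWith(lines[ln], "ITEM: NUMBER OF ATOMS"))
      stop("expected ITEM: NUMBER OF ATOMS at line ", ln)
    nat <- as.integer(trimws(lines[ln + 1L]))
    ln <- ln + 2L
    if (!startsWith(lines[ln], "ITEM: BOX BOUNDS"))
      stop("missing ITEM: BOX BOUNDS at line ", ln)
    if (grepl("xy|xz|yz", lines[ln]))
      stop("triclinic BOX BOUNDS not supported; orthorhombic boxes only")
    per <- grepl("pp", lines[ln])  # single flag per header in simple dumps
    bounds <- matrix(NA_real_, 3, 2)
    for (k in 1:3) {
      v <- as.numeric(splitFields(lines[ln + k]))
      if (length(v) < 2 || anyNA(v[1:2]))
        stop("malformed BOX BOUNDS line at line ", ln + k)
      bounds[k, ] <- v[1:2]
    }
    ln <- ln + 4L
    if (!startsWith(lines[ln], "ITEM: ATOMS"))
      stop("expected ITEM: ATOMS at line ", ln)
    cols <- splitFields(sub("ITEM: ATOMS", "", lines[ln]))
    need <- function(nm) {
      k <- match(nm, cols)
      if (is.na(k)) NA_integer_ else k
    }
    iId <- need("id"); iTy <- need("type")
    scaled <- !is.na(need("xs"))
    iX <- if (scaled) need("xs") else need("x")
    iY <- if (scaled) need("ys") else need("y")
    iZ <- if (scaled) need("zs") else need("z")
    if (anyNA(c(iId, iTy, iX, iY, iZ)))
      stop("ATOMS section must provide id, type and x y z (or xs ys zs)")
    rows <- lines[(ln + 1L):(ln + nat)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(rows), "[[:space:]]+"))),
                nrow = nat, byrow = TRUE)
    m <- m[order(m[, iId]), , drop = FALSE]
    blen <- bounds[, 2] - bounds[, 1]
    xyz <- cbind(m[, iX], m[, iY], m[, iZ])
    if (scaled) {
      xyz <- sweep(xyz, 2, blen, `*`)
      xyz <- sweep(xyz, 2, bounds[, 1], `+`)
    }
    types <- as.character(as.integer(m[, iTy]))
    unknown <- setdiff(unique(types), names(typeMap))
    if (length(unknown))
      stop("atom type(s) with no species map entry: ",
           paste(unknown, collapse = ", "))
    species <- unname(typeMap[types])
    isO <- species == "O"; isH <- species == "H"
    isSurf <- !isO & !isH
    surfTop <- if (any(isSurf)) max(xyz[isSurf, 3]) * scale else NA_real_
    hyd <- if (any(isH)) xyz[isH, , drop = FALSE] * scale else NULL
    if (!is.null(hyd) && nrow(hyd) != 2L * sum(isO)) hyd <- NULL
    frames[[length(frames) + 1L]] <-
      Frame(oxygen = xyz[isO, , drop = FALSE] * scale, box = blen * scale,
            hydrogen = hyd, periodic = rep(any(per), 3),
            time = (length(frames)) * stride, surfaceTopZ = surfTop)
    ln <- ln + 1L + nat
  }
  if (!length(frames)) stop("no frames found in ", path)
  Trajectory(frames, stride = stride)
}

#' Write per-molecule phase labels as a TSV table
#'
#' One row per molecule per frame with columns `frame`, `molecule`, `label`,
#' `layer`, `in_nucleus`, `qbar4`, `qbar6`; round-trips losslessly through
#' [readLabels()].
#'
#' @param labels list of [PhaseLabels-class], one per frame.
#' @param path output file path.
#' @export
writeLabels <- function(labels, path) {
  if (!length(labels)) stop("label sequence must be non-empty")
  rows <- lapply(seq_along(labels), function(f) {
    lb <- labels[[f]]
    data.frame(frame = f, molecule = seq_along(lb@labels),
               label = lb@labels, layer = lb@layer,
               in_nucleus = seq_along(lb@labels) %in% lb@nucleus,
               qbar4 = lb@qbar4, qbar6 = lb@qbar6)
  })
  df <- do.call(rbind, rows)
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop("cannot write labels to '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}

#' Read a phase-label table written by [writeLabels()]
#'
#' @param path TSV file path.
#' @return list of [PhaseLabels-class], one per frame.
#' @export
readLabels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(split(df, df$frame), function(d) {
    d <- d[order(d$molecule), ]
    PhaseLabels(d$label, d$layer, which(d$in_nucleus), d$qbar4, d$qbar6)
  })
}
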