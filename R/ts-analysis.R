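# Transition-state ensemble characterization: nucleus composition,
# disorderliness (rhombic:hexagonal ratio), and bootstrapped potential-energy
# statistics. Potential energies are consumed from a per-frame table
# produced by the user's MD toolchain; no force field is evaluated here.

#' Disorderliness of an ice nucleus
#'
#' The ratio of the number of rhombic to hexagonal ice molecules.
#'
#' @param nRhombic rhombic molecule count.
#' @param nHex hexagonal molecule count (> 0).
#' @return scalar ratio.
#' @export
disorderliness <- function(nRhombic, nHex) {
  if (nHex <= 0) stop("disorderliness undefined for nHex = 0")
  nRhombic / nHex
}

#' Bootstrap standard error of the mean
#'
#' Standard deviation of the sample mean across `nBoot` resamples with
#' replacement; deterministic under a fixed seed.
#'
#' @param values numeric sample.
#' @param nBoot number of bootstrap resamples (default 200).
#' @param seed integer seed.
#' @return scalar standard error.
#' @export
bootstrapSE <- function(values, nBoot = 200, seed = 1) {
  n <- length(values)
  stopifnot(n >= 1)
  means <- withSeed(seed, replicate(nBoot,
    mean(values[sample.int(n, n, replace = TRUE)])))
  stats::sd(means)
}

#' Summary statistics of a transition-state ensemble
#'
#' Averages the hexagonal and rhombic nucleus counts and the per-molecule
#' potential energy over the frames of a transition-state ensemble, with
#' bootstrap standard errors. Run once per transition state; the difference
#' of `meanPePerMolecule` between two ensembles gives the potential-energy
#' gap between critical nuclei.
#'
#' @param labels list of [PhaseLabels-class] restricted to the
#'   transition-state frames.
#' @param peTable numeric vector, mean potential energy per nucleus molecule
#'   (kJ/mol) for each frame, aligned with `labels`.
#' @param nBoot bootstrap resamples (default 200).
#' @param seed integer seed.
#' @return list with `nHex`, `nRhombic`, `disorderliness`,
#'   `meanPePerMolecule`, their standard errors (`seHex`, `seRhombic`,
#'   `seDisorderliness`, `sePe`), and `nFrames`.
#' @export
tsEnsembleStats <- function(labels, peTable, nBoot = 200, seed = 1) {
  if (!length(labels)) stop("empty transition-state ensemble")
  if (length(peTable) != length(labels))
    stop("potential-energy table (", length(peTable),
         ") is not aligned with the ", length(labels), " frames")
  nHex <- vapply(labels, function(lb)
    sum(lb@labels[lb@nucleus] == "HEX"), numeric(1))
  nRho <- vapply(labels, function(lb)
    sum(lb@labels[lb@nucleus] == "RHOMBIC"), numeric(1))
  if (mean(nHex) <= 0) stop("ensemble contains no hexagonal ice")
  list(
    nHex = mean(nHex), nRhombic = mean(nRho),
    disorderliness = disorderliness(mean(nRho), mean(nHex)),
    meanPePerMolecule = mean(peTable),
    seHex = bootstrapSE(nHex, nBoot, seed),
    seRhombic = bootstrapSE(nRho, nBoot, seed + 1),
    seDisorderliness = withSeed(seed + 2, {
      n <- length(nHex)
      stats::sd(replicate(nBoot, {
        k <- sample.int(n, n, replace = TRUE)
        mean(nRho[k]) / max(mean(nHex[k]), 1e-12)
      }))
    }),
    sePe = bootstrapSE(peTable, nBoot, seed + 3),
    nFrames = length(labels))
}

#' Read a per-frame potential-energy table
#'
#' TSV with columns `frame` and `pe_kj_per_mol`.
#'
#' @param path file path.
#' @return numeric vector ordered by frame.
#' @export
readEnergyTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  df$pe_kj_per_mol[order(df$frame)]
}
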