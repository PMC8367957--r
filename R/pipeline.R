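# End-to-end orchestration: detect -> featurize -> select CVs -> build MSM
# -> validate -> coarse-grain -> transition path theory -> report, with
# strict config validation, per-stage caching and a JSON report.

#' Default pipeline configuration
#'
#' Returns the complete configuration template for [runPipeline()]. Every
#' key a config may contain appears here; unknown keys are rejected before
#' any computation. Exactly one input source must be set: a trajectory file
#' (`input$trajectory`, XYZ), a CV table (`input$cvs`, TSV), or the
#' synthetic two-pathway network (`input$synthetic`).
#'
#' @return nested named list of defaults.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    outDir = "pipeline-out",
    temperature = 230,
    input = list(
      trajectory = NULL,        # XYZ path
      trajectoryUnit = "nm",
      cvs = NULL,               # TSV path (one file or character vector)
      synthetic = list(
        enabled = FALSE, pathwaySplit = 0.5, metastability = 0.98,
        emissionSd = 8, nTraj = 10L, nSteps = 20000L)
    ),
    detect = list(interfaceZCutoff = 0.35, clusterCutoff = 0.35,
                  layerSpacing = 0.7357 / 2),
    featurize = list(mode = "selected5"),
    select = list(enabled = FALSE, lag = 10L, nSelect = 5L, m = 3L),
    msm = list(nStates = 64L, lag = 1L, reversible = TRUE),
    validate = list(lags = c(1L, 2L, 5L), m = 3L, ckSets = NULL,
                    ckMax = 3L),
    macro = list(nMacro = 8L),
    tpt = list(source = 1L, sink = c(7L, 8L), minFraction = 0,
               tsWindow = c(0.45, 0.55)),
    rate = list(volumeM3 = 5.43e-9 * 5.89e-9 * 7.0e-9, lagTimePs = NULL)
  )
}

# recursive strict merge: unknown keys in cfg raise an error
mergeConfig <- function(template, cfg, path = "") {
  if (!is.list(cfg)) return(cfg)
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(cfg)) {
    template[[nm]] <- if (is.list(template[[nm]]) && is.list(cfg[[nm]]))
      mergeConfig(template[[nm]], cfg[[nm]], paste0(path, nm, "$"))
    else cfg[[nm]]
  }
  template
}

# tiny deterministic string hash (djb2) for stale-cache detection
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%x", h)
}

# stage cache: recompute unless a cached artifact with a matching hash exists
stageCached <- function(dir, name, hash, compute, resume) {
  metaPath <- file.path(dir, paste0(name, ".cache.json"))
  dataPath <- file.path(dir, paste0(name, ".rds"))
  if (resume && file.exists(metaPath) && file.exists(dataPath)) {
    meta <- jsonlite::read_json(metaPath)
    if (!identical(meta$hash, hash))
      stop("stale cache for stage '", name,
           "': config changed; delete ", dataPath, " to recompute")
    message("  [", name, "] cached")
    return(readRDS(dataPath))
  }
  t0 <- proc.time()[["elapsed"]]
  out <- compute()
  saveRDS(out, dataPath)
  jsonlite::write_json(
    list(hash = hash, seconds = proc.time()[["elapsed"]] - t0),
    metaPath, auto_unbox = TRUE)
  message(sprintf("  [%s] %.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full nucleation-kinetics pipeline
#'
#' Executes detection, featurization, CV selection, MSM construction,
#' validation (implied timescales and Chapman-Kolmogorov), PCCA+
#' coarse-graining, transition path theory and MFPT/rate analysis, driven
#' by a config list validated against [defaultPipelineConfig()]. Each stage
#' caches its artifact under `outDir`; with `resume = TRUE` cached stages
#' whose config is unchanged are reused, and a changed config refuses to
#' resume. A resolved copy of the config and a JSON report are written
#' next to the outputs.
#'
#' @param config nested list overriding [defaultPipelineConfig()].
#' @param resume reuse cached stage artifacts (default `TRUE`).
#' @return the report, invisibly (also written to `outDir/report.json`).
#' @export
runPipeline <- function(config = list(), resume = TRUE) {
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(cfg$outDir, "resolved_config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  report <- list(seed = cfg$seed, temperature = cfg$temperature)
  nInputs <- sum(!is.null(cfg$input$trajectory), !is.null(cfg$input$cvs),
                 isTRUE(cfg$input$synthetic$enabled))
  if (nInputs != 1L)
    stop("exactly one input source must be configured ",
         "(trajectory, cvs, or synthetic)")

  trueDtrajs <- NULL
  if (isTRUE(cfg$input$synthetic$enabled)) {
    syn <- stageCached(cfg$outDir, "synthetic",
                       configHash(cfg[c("seed", "input")]), function() {
      net <- buildTwoPathwayNetwork(cfg$input$synthetic$pathwaySplit,
                                    cfg$input$synthetic$metastability,
                                    cfg$input$synthetic$emissionSd)
      em <- emitTrajectories(net, cfg$input$synthetic$nTraj,
                             cfg$input$synthetic$nSteps, seed = cfg$seed)
      list(net = net, series = em$series, dtrajs = em$dtrajs)
    }, resume)
    series <- syn$series
    trueDtrajs <- syn$dtrajs
    report$synthetic <- list(pathwaySplit = syn$net@pathwaySplit)
  } else if (!is.null(cfg$input$trajectory)) {
    series <- stageCached(cfg$outDir, "detect",
                          configHash(cfg[c("input", "detect", "featurize")]),
                          function() {
      traj <- readXYZ(cfg$input$trajectory, unit = cfg$input$trajectoryUnit)
      params <- DetectionParams(
        interfaceZCutoff = cfg$detect$interfaceZCutoff,
        clusterCutoff = cfg$detect$clusterCutoff,
        layerSpacing = cfg$detect$layerSpacing)
      labels <- detectTrajectory(traj, params)
      writeLabels(labels, file.path(cfg$outDir, "labels.tsv"))
      cvs <- computeCVs(labels, mode = cfg$featurize$mode, traj = traj)
      writeCVs(cvs, file.path(cfg$outDir, "cvs.tsv"))
      list(cvs)
    }, resume)
  } else {
    paths <- cfg$input$cvs
    series <- lapply(paths, readCVs)
  }

  if (isTRUE(cfg$select$enabled)) {
    sel <- stageCached(cfg$outDir, "select",
                       configHash(cfg[c("seed", "input", "select")]),
                       function()
      spectralOasisSelect(series, cfg$select$lag, cfg$select$nSelect,
                          cfg$select$m), resume)
    series <- lapply(series, function(s)
      CVSeries(cvMatrix(s)[, sel$selected, drop = FALSE],
               stride = s@stride))
    report$select <- list(selected = sel$names,
                          timescales = sel$timescaleCurves[[length(
                            sel$timescaleCurves)]])
  }

  msmHash <- configHash(cfg[c("seed", "input", "select", "msm")])
  model <- stageCached(cfg$outDir, "msm", msmHash, function() {
    m <- buildMSM(series, cfg$msm$nStates, cfg$msm$lag,
                  reversible = cfg$msm$reversible, seed = cfg$seed)
    saveMSM(m, file.path(cfg$outDir, "msm"))
    m
  }, resume)
  report$msm <- list(nStates = cfg$msm$nStates,
                     activeStates = length(model@active),
                     lag = model@lag)

  val <- stageCached(cfg$outDir, "validate",
                     configHash(cfg[c("seed", "input", "msm", "validate")]),
                     function() {
    its <- impliedTimescales(model@dtrajs, cfg$validate$lags,
                             m = cfg$validate$m,
                             reversible = cfg$msm$reversible)
    sets <- cfg$validate$ckSets
    if (is.null(sets)) {
      pcca2 <- pccaPlus(model@transition, model@stationary,
                        min(2L, nrow(model@transition)))
      sets <- lapply(seq_len(max(pcca2@crisp)), function(k)
        model@active[pcca2@crisp == k])
    }
    ck <- ckTest(model@dtrajs, model@lag, sets, kMax = cfg$validate$ckMax,
                 seed = cfg$seed)
    list(its = its, ck = ck)
  }, resume)
  report$validate <- list(
    slowestTimescale = max(val$its$timescale, na.rm = TRUE),
    ckMaxDeviation = max(abs(val$ck$model - val$ck$estimated),
                         na.rm = TRUE))

  macro <- stageCached(cfg$outDir, "macro",
                       configHash(c(msmHash, cfg$macro)), function()
    pccaPlus(model@transition, model@stationary, cfg$macro$nMacro), resume)
  report$macro <- list(populations = as.numeric(macro@macroPi))

  tpt <- stageCached(cfg$outDir, "tpt",
                     configHash(c(msmHash, cfg$macro, cfg$tpt)), function() {
    srcMacro <- cfg$tpt$source; snkMacro <- cfg$tpt$sink
    A <- which(macro@crisp %in% srcMacro)
    B <- which(macro@crisp %in% snkMacro)
    res <- tptAnalysis(model@transition, A, B,
                       pi = model@stationary,
                       minFraction = cfg$tpt$minFraction)
    mf <- macroFlux(res@netFlux, macro@crisp, cfg$macro$nMacro)
    ts <- transitionStateMicrostates(res@qPlus, cfg$tpt$tsWindow)
    lagPs <- if (is.null(cfg$rate$lagTimePs)) model@lagTime else
      cfg$rate$lagTimePs
    mfptAB <- mfpt(model@transition, B, lagTime = lagPs)
    mfptMean <- sum(model@stationary[A] * mfptAB[A]) /
      sum(model@stationary[A])
    rate <- nucleationRate(mfptMean * 1e-12, cfg$rate$volumeM3)
    list(res = res, macroFlux = mf, tsStates = ts,
         mfptPs = mfptMean, rate = rate)
  }, resume)
  report$tpt <- list(totalFlux = tpt$res@totalFlux,
                     macroFlux = tpt$macroFlux,
                     nPathways = length(tpt$res@pathways),
                     tsStates = tpt$tsStates,
                     mfptPs = tpt$mfptPs, ratePerSecPerM3 = tpt$rate)
  if (!is.null(trueDtrajs)) {
    f <- report$tpt$macroFlux
    # identify macro-states by majority vote against the true basins
    maj <- majorityMacroMap(model, macro, trueDtrajs)
    if (all(c(2, 3, 4) %in% maj)) {
      ii <- which(maj == 2); iii <- which(maj == 3); iv <- which(maj == 4)
      fc <- sum(f[ii, iv]); fn <- sum(f[ii, iii])
      if (fc + fn > 0)
        report$tpt$classicalFraction <- fc / (fc + fn)
    }
  }

  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

# majority-vote map from estimated macro-states to true generative basins
majorityMacroMap <- function(model, macro, trueDtrajs) {
  microOfFrame <- unlist(model@dtrajs)
  trueOfFrame <- unlist(trueDtrajs)
  map <- rep(NA_integer_, nrow(model@counts))
  for (s in model@active) {
    sel <- microOfFrame == s
    if (any(sel)) map[s] <- as.integer(names(which.max(table(
      trueOfFrame[sel]))))
  }
  macroMaj <- integer(ncol(macro@membership))
  for (k in seq_along(macroMaj)) {
    micro <- model@active[macro@crisp == k]
    votes <- table(map[micro])
    macroMaj[k] <- if (length(votes))
      as.integer(names(which.max(votes))) else NA_integer_
  }
  macroMaj
}

#' Serialize a microstate model to a plain-text bundle
#'
#' Writes centers, discrete trajectories, counts, transition matrix,
#' stationary distribution and metadata (lag, active set, flags) as TSV and
#' JSON files under a directory; portable and diff-able.
#'
#' @param model a [MicrostateModel-class].
#' @param dir output directory (created).
#' @export
saveMSM <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  w(model@centers, "centers.tsv")
  w(model@counts, "counts.tsv")
  w(model@transition, "transition.tsv")
  w(matrix(model@stationary, ncol = 1), "stationary.tsv")
  dt <- data.frame(
    traj = rep(seq_along(model@dtrajs), lengths(model@dtrajs)),
    state = unlist(model@dtrajs))
  utils::write.table(dt, file.path(dir, "dtrajs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(lag = model@lag, lagTime = model@lagTime,
         active = model@active, reversible = model@reversible,
         version = as.character(utils::packageVersion("icekinetics"))),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a microstate model saved by [saveMSM()]
#'
#' @param dir bundle directory.
#' @return a [MicrostateModel-class].
#' @export
loadMSM <- function(dir) {
  r <- function(f) as.matrix(utils::read.table(
    file.path(dir, f), sep = "\t", header = FALSE))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  dt <- utils::read.table(file.path(dir, "dtrajs.tsv"), header = TRUE,
                          sep = "\t")
  m <- r("transition.tsv"); dimnames(m) <- NULL
  cnt <- r("counts.tsv"); dimnames(cnt) <- NULL
  ctr <- r("centers.tsv"); dimnames(ctr) <- NULL
  new("MicrostateModel", centers = ctr,
      dtrajs = unname(lapply(split(dt$state, dt$traj), as.integer)),
      lag = as.integer(meta$lag), lagTime = as.numeric(meta$lagTime),
      counts = cnt, transition = m,
      stationary = as.numeric(r("stationary.tsv")),
      active = as.integer(meta$active),
      reversible = isTRUE(meta$reversible))
}
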