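test_that("pathway split limits and bisection self-consistency", {
  net1 <- buildTwoPathwayNetwork(1.0, 0.98)
  expect_equal(net1@transition[2, 3], 0)      # no non-classical branch
  net0 <- buildTwoPathwayNetwork(0.0, 0.98)
  expect_equal(net0@transition[2, 4], 0)
  for (target in c(0.3, 0.5, 0.8)) {
    net <- buildTwoPathwayNetwork(target, 0.98)
    res <- tptAnalysis(net@transition, 1, c(7, 8))
    frac <- res@netFlux[2, 4] / (res@netFlux[2, 4] + res@netFlux[2, 3])
    expect_lt(abs(frac - target), 0.01)
  }
})

test_that("the network is reversible and metastable as requested", {
  net <- buildTwoPathwayNetwork(0.5, 0.99)
  T <- net@transition
  pi <- icekinetics:::stationaryVector(T)
  expect_lt(max(abs(pi * T - t(pi * T))), 1e-12)
  expect_equal(unname(diag(T)), rep(0.99, 8))
  lam2 <- sort(eigen(T, only.values = TRUE)$values, decreasing = TRUE)[2]
  expect_gt(-1 / log(lam2), 100)   # slowest implied timescale > 100 steps
})

test_that("zero-noise emissions are perfectly separable by k-centers", {
  net <- buildTwoPathwayNetwork(0.5, 0.95, emissionSd = 0)
  em <- emitTrajectories(net, 2, 4000, seed = 6)
  cl <- kcentersCluster(em$series, 8, seed = 2)
  d <- unlist(cl$dtrajs)
  truth <- unlist(em$dtrajs)
  # purity 1: each cluster maps to exactly one hidden state
  tab <- table(d, truth)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("emission is bit-identical under the same seed", {
  net <- buildTwoPathwayNetwork(0.5, 0.98)
  a <- emitTrajectories(net, 2, 500, seed = 9)
  b <- emitTrajectories(net, 2, 500, seed = 9)
  expect_identical(lapply(a$series, cvMatrix), lapply(b$series, cvMatrix))
  expect_identical(a$dtrajs, b$dtrajs)
})

test_that("hex slab geometry: interior molecules are 4-coordinated", {
  fr <- buildLattice("hex_slab", nx = 3, ny = 2, nBilayers = 4)
  for (i in c(1, 10, 50, 96)) {
    d2 <- sort(icekinetics:::minImageDist2(fr@oxygen, fr@oxygen[i, ],
                                           fr@box, fr@periodic))
    expect_equal(sum(d2[2:6] < 0.32^2), 4)  # exactly 4 within 0.32 nm
  }
})

test_that("rhombic monolayer is planar with 4 intralayer neighbors", {
  fr <- buildLattice("rhombic_monolayer", nx = 3, ny = 3)
  expect_lt(diff(range(fr@oxygen[, 3])), 1e-6)
  d2 <- sort(icekinetics:::minImageDist2(fr@oxygen, fr@oxygen[5, ],
                                         fr@box, fr@periodic))
  expect_equal(sum(abs(sqrt(d2[2:5]) - 0.276) < 1e-9), 4)
})

test_that("lattice noise is seeded and reproducible", {
  a <- buildLattice("hex_slab", nx = 2, ny = 2, nBilayers = 2,
                    noiseSd = 0.01, seed = 3)
  b <- buildLattice("hex_slab", nx = 2, ny = 2, nBilayers = 2,
                    noiseSd = 0.01, seed = 3)
  expect_identical(a@oxygen, b@oxygen)
  expect_gt(max(abs(a@oxygen -
    buildLattice("hex_slab", nx = 2, ny = 2, nBilayers = 2)@oxygen)), 0)
})

test_that("small lattice noise does not flip the detector labels", {
  fr <- buildLattice("hex_slab", nx = 3, ny = 2, nBilayers = 4,
                     noiseSd = 0.01, seed = 8)
  expect_true(all(classifyFrame(fr)@labels == "HEX"))
})

test_that("liquid packing respects the overlap exclusion and density", {
  fr <- buildLattice("liquid", box = c(2, 2, 2), seed = 10)
  expect_equal(nrow(fr@oxygen), round(33 * 8))
  dmin <- min(vapply(seq_len(nrow(fr@oxygen) - 1), function(i) {
    d2 <- icekinetics:::minImageDist2(
      fr@oxygen[(i + 1):nrow(fr@oxygen), , drop = FALSE],
      fr@oxygen[i, ], fr@box, fr@periodic)
    min(d2)
  }, numeric(1)))
  expect_gt(sqrt(dmin), 0.2)
})

test_that("detect -> featurize on a noiseless slab reproduces exact counts", {
  # 4 bilayers sitting on the surface plane occupy layers 0..3 at the
  # default layerSpacing c/2; every molecule is HEX and in one nucleus
  fr <- buildLattice("hex_slab", nx = 3, ny = 2, nBilayers = 4,
                     surfaceTopZ = 0)
  nPerBilayer <- nrow(fr@oxygen) / 4
  labels <- list(classifyFrame(fr))
  cvs <- cvMatrix(computeCVs(labels))
  expect_equal(unname(cvs[1, "n_ice_nucleus"]), nrow(fr@oxygen))
  expect_equal(unname(cvs[1, "n_rhombic_nucleus"]), 0)
  expect_equal(unname(cvs[1, "n_hex_layer2"]), nPerBilayer)
  expect_equal(unname(cvs[1, "n_hex_layer3"]), nPerBilayer)
  expect_equal(unname(cvs[1, "n_hex_upper"]), nPerBilayer)
})
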