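chainFrame <- function(box = c(100, 100, 100), periodic = rep(FALSE, 3)) {
  Frame(cbind(0:3, 0, 0), box = box, periodic = periodic)
}

test_that("nearest neighbors honour geometry, images and tie-breaks", {
  expect_equal(sort(nearestNeighbors(chainFrame(), 2, 2)), c(1, 3))
  # periodic 4-nm box: images across the boundary count
  fr <- chainFrame(box = c(4, 4, 4), periodic = rep(TRUE, 3))
  expect_equal(sort(nearestNeighbors(fr, 1, 2)), c(2, 4))
  expect_error(nearestNeighbors(chainFrame(), 1, 4), "neighbors")
})

test_that("nearest neighbors match a brute-force distance sort", {
  set.seed(11)
  for (rep in 1:3) {
    pos <- matrix(runif(150, 0, 2.5), 50, 3)
    fr <- Frame(pos, box = c(2.5, 2.5, 2.5))
    for (i in c(1, 17, 50))
      expect_equal(sort(nearestNeighbors(fr, i, 6)),
                   sort(oracleNeighbors(pos, i, 6, fr@box, fr@periodic)))
  }
})

test_that("qlm of a single +z neighbor is Y_l0 at theta = 0", {
  fr <- Frame(rbind(c(0, 0, 1), c(0, 0, 0)), box = c(10, 10, 10),
              periodic = rep(FALSE, 3))
  q <- qlm(fr, 1, 2L, 6L)           # separation r_1 - r_2 = +z
  expect_equal(Mod(q[1:6]), rep(0, 6), tolerance = 1e-14)
  expect_equal(Re(q[7]), sqrt(13 / (4 * pi)), tolerance = 1e-12)
  expect_equal(Mod(q[8:13]), rep(0, 6), tolerance = 1e-14)
  expect_error(qlm(fr, 1, integer(), 6L), "non-empty")
})

test_that("averaged qbar equals the direct-summation oracle to 1e-12", {
  set.seed(21)
  for (rep in 1:3) {
    pos <- matrix(runif(150, 0, 2.4), 50, 3)
    fr <- Frame(pos, box = c(2.4, 2.4, 2.4))
    for (l in c(4L, 6L)) {
      mine <- averagedQbar(fr, l)
      orac <- oracleQbar(pos, fr@box, fr@periodic, l, 4)
      expect_lt(max(abs(mine - orac)), 1e-12)
    }
  }
})

test_that("qbar respects each molecule's own interface/bulk neighbor count", {
  set.seed(22)
  pos <- matrix(runif(90, 0, 2.0), 30, 3)
  fr <- Frame(pos, box = c(2.0, 2.0, 2.0), surfaceTopZ = 0)
  params <- DetectionParams()
  iface <- (pos[, 3] - 0) <= params@interfaceZCutoff
  expect_true(any(iface) && any(!iface))
  mine <- averagedQbar(fr, 6L, params)
  orac <- oracleQbar(pos, fr@box, fr@periodic, 6L, ifelse(iface, 3, 4))
  expect_lt(max(abs(mine - orac)), 1e-12)
})

test_that("qbar is invariant under rigid rotation and translation", {
  set.seed(31)
  pos <- matrix(runif(90, 1, 3), 30, 3)
  fr <- Frame(pos, box = c(30, 30, 30), periodic = rep(FALSE, 3))
  q0 <- averagedQbar(fr, 6L)
  for (rep in 1:3) {
    R <- randomRotation()
    shift <- runif(3, -0.5, 0.5)
    fr2 <- Frame(sweep(pos %*% t(R), 2, shift, `+`) + 10,
                 box = c(30, 30, 30), periodic = rep(FALSE, 3))
    expect_lt(max(abs(averagedQbar(fr2, 6L) - q0)), 1e-10)
  }
})

test_that("noiseless hexagonal slab classifies 100% HEX under the bulk rule", {
  fr <- buildLattice("hex_slab", nx = 3, ny = 2, nBilayers = 4)
  q6 <- averagedQbar(fr, 6L)
  expect_true(all(q6 > 0.45))
  lb <- classifyFrame(fr)
  expect_true(all(lb@labels == "HEX"))
  expect_false(any(lb@labels == "RHOMBIC"))
  expect_equal(sort(lb@nucleus), seq_len(nrow(fr@oxygen)))
})

test_that("noiseless rhombic monolayer classifies 100% RHOMBIC at interface", {
  fr <- buildLattice("rhombic_monolayer", nx = 3, ny = 3,
                     surfaceTopZ = -0.25)
  q4 <- averagedQbar(fr, 4L)
  expect_true(all(q4 > 0.6))
  lb <- classifyFrame(fr)
  expect_true(all(lb@labels == "RHOMBIC"))
  # precedence: many monolayer molecules also satisfy the interface hex
  # condition qbar6 > 0.5, yet the rhombic rule (qbar4 > 0.6) wins
  expect_true(any(lb@qbar6 > 0.5))
})

test_that("random liquid yields under 5% false ice", {
  fr <- buildLattice("liquid", box = c(2.3, 2.3, 2.3), seed = 4)
  lb <- classifyFrame(fr)
  expect_gt(mean(lb@labels == "LIQUID"), 0.95)
})

test_that("classification is deterministic and pure", {
  fr <- buildLattice("liquid", box = c(1.8, 1.8, 1.8), seed = 9)
  a <- classifyFrame(fr); b <- classifyFrame(fr)
  expect_identical(a@labels, b@labels)
  expect_identical(a@nucleus, b@nucleus)
  expect_identical(a@qbar6, b@qbar6)
})

test_that("largest ice cluster picks the biggest island", {
  # two islands: 7 molecules near origin, 3 far away, well beyond cutoff
  pos <- rbind(
    cbind(seq(0, 1.8, by = 0.3), 0, 0),       # 7 in a 0.3-spaced chain
    cbind(seq(0, 0.6, by = 0.3) + 5, 0, 0))   # 3 far away
  fr <- Frame(pos, box = c(20, 20, 20), periodic = rep(FALSE, 3))
  lb <- PhaseLabels(rep("HEX", 10), rep(0L, 10), integer(),
                    rep(0.5, 10), rep(0.5, 10))
  expect_equal(largestIceCluster(lb, fr, 0.35), 1:7)
  # all-liquid frame: empty cluster
  lbLiq <- PhaseLabels(rep("LIQUID", 10), rep(0L, 10), integer(),
                       rep(0.1, 10), rep(0.1, 10))
  expect_equal(largestIceCluster(lbLiq, fr, 0.35), integer())
})

test_that("largest ice cluster agrees with brute-force components", {
  set.seed(41)
  for (rep in 1:4) {
    pos <- matrix(runif(120, 0, 2.0), 40, 3)
    fr <- Frame(pos, box = c(2.0, 2.0, 2.0))
    labs <- sample(c("HEX", "RHOMBIC", "LIQUID"), 40, replace = TRUE)
    lb <- PhaseLabels(labs, rep(0L, 40), integer(),
                      rep(0.5, 40), rep(0.5, 40))
    mine <- largestIceCluster(lb, fr, 0.35)
    comps <- oracleClusters(pos, which(labs != "LIQUID"), fr@box,
                            fr@periodic, 0.35)
    if (!length(comps)) {
      expect_equal(mine, integer())
    } else {
      sizes <- lengths(comps)
      expect_equal(length(mine), max(sizes))
      expect_true(any(vapply(comps, identical, logical(1), y = mine)))
    }
  }
})

test_that("layer assignment is floor((z - surface)/spacing), clamped", {
  fr <- Frame(rbind(c(0, 0, 0.6), c(0, 0, 0.9), c(0, 0, 0.4)),
              box = c(5, 5, 5), periodic = rep(FALSE, 3), surfaceTopZ = 0.5)
  lay <- assignLayers(fr, DetectionParams(layerSpacing = 0.368))
  expect_equal(lay, c(0L, 1L, 0L))  # 0.1 -> 0, 0.4 -> 1, below -> clamped 0
  frLow <- Frame(rbind(c(0, 0, 0.3)), box = c(5, 5, 5),
                 periodic = rep(FALSE, 3), surfaceTopZ = 0.5)
  expect_warning(assignLayers(frLow), "below the surface")
})

test_that("a 3-bilayer slab occupies exactly 3 layers", {
  fr <- buildLattice("hex_slab", nx = 2, ny = 2, nBilayers = 3,
                     surfaceTopZ = 0)
  lay <- assignLayers(fr)
  expect_equal(sort(unique(lay)), 0:2)
})
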