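walk5 <- function() {
  rbind(c(0.5, 0.5, 0, 0, 0),
        c(0.25, 0.5, 0.25, 0, 0),
        c(0, 0.25, 0.5, 0.25, 0),
        c(0, 0, 0.25, 0.5, 0.25),
        c(0, 0, 0, 0.5, 0.5))
}

test_that("the unbiased walk has the linear committor", {
  q <- committors(walk5(), 1, 5)
  expect_equal(q$qPlus, c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-12)
  expect_equal(q$qMinus, 1 - q$qPlus, tolerance = 1e-10)
})

test_that("reversible chains satisfy qMinus = 1 - qPlus", {
  set.seed(101)
  for (rep in 1:4) {
    T <- randomReversibleT(10)
    q <- committors(T, c(1, 2), c(9, 10))
    expect_lt(max(abs(q$qMinus - (1 - q$qPlus))), 1e-10)
    expect_true(all(q$qPlus >= 0 & q$qPlus <= 1))
  }
})

test_that("committors match Monte-Carlo shooting within 3 standard errors", {
  set.seed(102)
  T <- randomReversibleT(8, selfWeight = 1)
  q <- committors(T, 1, 8)$qPlus
  nShots <- 2000
  qmc <- oracleCommittorMC(T, 1, 8, nShots = nShots)
  for (s in 2:7) {
    se <- sqrt(q[s] * (1 - q[s]) / nShots)
    expect_lt(abs(q[s] - qmc[s]), 3 * se + 0.01)
  }
})

test_that("net flux is divergence-free at intermediate states", {
  set.seed(103)
  for (rep in 1:3) {
    T <- randomReversibleT(12)
    pi <- icekinetics:::stationaryVector(T)
    A <- 1:2; B <- 11:12
    q <- committors(T, A, B, pi)
    fl <- reactiveFlux(T, pi, q$qPlus, q$qMinus, A)
    div <- rowSums(fl$netFlux) - colSums(fl$netFlux)
    expect_lt(max(abs(div[setdiff(1:12, c(A, B))])), 1e-12)
    expect_true(all(fl$flux >= 0))
  }
})

test_that("the 3-state chain total flux matches the hand evaluation", {
  T <- rbind(c(0.9, 0.1, 0), c(0.05, 0.9, 0.05), c(0, 0.1, 0.9))
  pi <- icekinetics:::stationaryVector(T)
  q <- committors(T, 1, 3, pi)
  fl <- reactiveFlux(T, pi, q$qPlus, q$qMinus, 1)
  # only exit from A={1} is 1 -> 2: f = pi_1 * qminus(1) * T_12 * qplus(2)
  expect_equal(fl$totalFlux, pi[1] * 0.1 * q$qPlus[2], tolerance = 1e-12)
})

test_that("swapping source and sink preserves the total flux (reversible)", {
  set.seed(104)
  T <- randomReversibleT(9)
  pi <- icekinetics:::stationaryVector(T)
  qf <- committors(T, 1, 9, pi)
  qb <- committors(T, 9, 1, pi)
  fAB <- reactiveFlux(T, pi, qf$qPlus, qf$qMinus, 1)$totalFlux
  fBA <- reactiveFlux(T, pi, qb$qPlus, qb$qMinus, 9)$totalFlux
  expect_equal(fAB, fBA, tolerance = 1e-10)
})

test_that("pathway decomposition: unique path, parallel ratios, completeness", {
  # single chain 1 -> 2 -> 3: one pathway with the whole flux
  net1 <- matrix(0, 3, 3); net1[1, 2] <- 0.4; net1[2, 3] <- 0.4
  pw <- decomposePathways(net1, 1, 3)
  expect_length(pw, 1)
  expect_equal(pw[[1]]$path, c(1, 2, 3))
  expect_equal(pw[[1]]$flux, 0.4)
  # two parallel 2-edge branches with bottlenecks 0.7 and 0.3
  net2 <- matrix(0, 4, 4)
  net2[1, 2] <- 0.7; net2[2, 4] <- 0.7
  net2[1, 3] <- 0.3; net2[3, 4] <- 0.3
  pw2 <- decomposePathways(net2, 1, 4)
  expect_length(pw2, 2)
  expect_equal(pw2[[1]]$flux / pw2[[2]]$flux, 7 / 3, tolerance = 1e-10)
  # full decomposition conserves total flux on a real TPT flux network
  set.seed(105)
  T <- randomReversibleT(10)
  pi <- icekinetics:::stationaryVector(T)
  res <- tptAnalysis(T, 1, 10, pi, minFraction = 0)
  expect_equal(sum(vapply(res@pathways, `[[`, numeric(1), "flux")),
               res@totalFlux, tolerance = 1e-10)
})

test_that("empty flux networks warn and return no pathways", {
  expect_warning(pw <- decomposePathways(matrix(0, 3, 3), 1, 3), "no A")
  expect_length(pw, 0)
})

test_that("macro flux aggregation preserves identity and conservation", {
  set.seed(106)
  T <- randomReversibleT(12)
  pi <- icekinetics:::stationaryVector(T)
  res <- tptAnalysis(T, 1:2, 11:12, pi)
  expect_equal(macroFlux(res@netFlux, 1:12), res@netFlux)
  crisp <- rep(1:4, each = 3)
  mf <- macroFlux(res@netFlux, crisp)
  # conservation at intermediate macro-states (macro 1 holds A, 4 holds B)
  div <- rowSums(mf) - colSums(mf)
  expect_lt(max(abs(div[2:3])), 1e-10)
})

test_that("transition states sit in the committor window, on their branch", {
  q <- committors(walk5(), 1, 5)$qPlus
  expect_equal(transitionStateMicrostates(q), 3L)
  expect_warning(transitionStateMicrostates(q, c(0.44, 0.449)), "no micro")
  # two independent TPT analyses on the synthetic network give TS sets on
  # distinct branches
  net <- buildTwoPathwayNetwork(0.5, 0.98)
  T <- net@transition
  qIII <- committors(T, 1, 3)$qPlus   # source I, sink III (non-classical)
  qIV <- committors(T, 1, 4)$qPlus    # source I, sink IV (classical)
  tsII <- transitionStateMicrostates(qIII, c(0.2, 0.8))
  tsI <- transitionStateMicrostates(qIV, c(0.2, 0.8))
  expect_true(length(tsI) > 0 && length(tsII) > 0)
})

test_that("MFPT linear solve: analytic, boundary, and sampling oracle", {
  T <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  m <- mfpt(T, 2)
  expect_equal(m[1], 10, tolerance = 1e-12)
  expect_equal(m[2], 0)
  set.seed(107)
  T10 <- randomReversibleT(10, selfWeight = 1)
  m10 <- mfpt(T10, c(9, 10))
  nS <- 3000
  samp <- oracleMfptMC(T10, 3, c(9, 10), nSamples = nS)
  se <- sd(samp) / sqrt(nS)
  expect_lt(abs(m10[3] - mean(samp)), 3 * se + 0.05)
  expect_error(mfpt(T, integer()), "length")
})

test_that("MFPT scales with the physical lag time", {
  T <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(mfpt(T, 2, lagTime = 50)[1], 500)
})

test_that("chain sampling is faithful and reproducible", {
  expect_equal(unique(sampleChain(diag(3), 50, 1, seed = 1,
                                  start = 2)[[1]]), 2L)
  T <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(0.3, 0.3, 0.4))
  d <- sampleChain(T, 1e5, 1, seed = 5)[[1]]
  C <- countTransitions(list(d), 1, 3)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt(T[i, j] * (1 - T[i, j]) / rowSums(C)[i])
    expect_lt(abs(C[i, j] / rowSums(C)[i] - T[i, j]), 3 * se + 1e-3)
  }
  expect_identical(sampleChain(T, 100, 2, seed = 9),
                   sampleChain(T, 100, 2, seed = 9))
})

test_that("nucleation rate arithmetic and units", {
  expect_equal(nucleationRate(1, 1), 1)
  # study-scale arithmetic: MFPT 1.34 us in the 5.43 x 5.89 x 7.0 nm box
  V <- 5.43e-9 * 5.89e-9 * 7.0e-9
  J <- nucleationRate(1.34e-6, V)
  expect_gt(J, 1e29); expect_lt(J, 1e31)
  expect_equal(nucleationRate(1.34e-6, 2 * V), J / 2)
  expect_error(nucleationRate(-1, 1), "positive")
  expect_error(nucleationRate(1, 0), "positive")
})
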