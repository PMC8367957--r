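blobSeries <- function(n = 500, sep = 10, seed = 81) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2, mean = sep), n, 2))
  colnames(x) <- c("a", "b")
  CVSeries(x[sample(nrow(x)), ])
}

test_that("k-centers separates well-separated blobs purely", {
  s <- blobSeries()
  cl <- kcentersCluster(s, 2, seed = 1)
  d <- cl$dtrajs[[1]]
  grp <- cvMatrix(s)[, 1] > 5
  purity <- max(mean(d[grp] == d[grp][1]), mean(d[!grp] == d[!grp][1]))
  expect_equal(purity, 1.0)
  expect_equal(mean(d[grp] == d[grp][1]), 1.0)
  expect_equal(mean(d[!grp] == d[!grp][1]), 1.0)
})

test_that("k = n gives zero covering radius; fixed seed reproduces", {
  set.seed(82)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  s <- CVSeries(x)
  cl <- kcentersCluster(s, 20, seed = 3)
  expect_equal(cl$radius, 0)
  expect_equal(sort(cl$dtrajs[[1]]), 1:20)
  cl2 <- kcentersCluster(s, 5, seed = 7)
  cl3 <- kcentersCluster(s, 5, seed = 7)
  expect_identical(cl2$centers, cl3$centers)
  expect_identical(cl2$dtrajs, cl3$dtrajs)
  expect_error(kcentersCluster(s, 21, seed = 1), "exceeds")
})

test_that("transition counting enumerates sliding pairs within bounds", {
  expect_equal(countTransitions(list(c(1, 1, 2, 2)), 1),
               rbind(c(1, 1), c(0, 1)))
  # no pairs across trajectory boundaries
  expect_equal(countTransitions(list(c(1, 2), c(2, 1)), 1),
               rbind(c(0, 1), c(1, 0)))
  set.seed(83)
  d <- sample(1:4, 1000, replace = TRUE)
  C <- countTransitions(list(d), 3)
  occ <- table(factor(d[1:(1000 - 3)], 1:4))
  expect_equal(rowSums(C), as.numeric(occ))
})

test_that("transition matrix estimation: analytic cases", {
  est <- estimateTransitionMatrix(rbind(c(8, 2), c(2, 8)))
  expect_equal(est$transition, rbind(c(0.8, 0.2), c(0.2, 0.8)),
               tolerance = 1e-9)
  expect_equal(est$stationary, c(0.5, 0.5), tolerance = 1e-9)
  est2 <- estimateTransitionMatrix(rbind(c(90, 10), c(20, 80)),
                                   reversible = FALSE)
  expect_equal(est2$transition, rbind(c(0.9, 0.1), c(0.2, 0.8)))
  expect_equal(est2$stationary, c(2 / 3, 1 / 3), tolerance = 1e-10)
})

countLogLik <- function(T, C) sum(C[C > 0] * log(T[C > 0]))

test_that("reversible MLE satisfies detailed balance and beats the baseline", {
  set.seed(84)
  for (rep in 1:3) {
    C <- matrix(rpois(25, 12), 5, 5) + 1
    est <- estimateTransitionMatrix(C, reversible = TRUE)
    T <- est$transition; pi <- est$stationary
    expect_lt(max(abs(pi * T - t(pi * T))), 1e-8)
    # likelihood at least that of the symmetrized-count estimator
    Cs <- (C + t(C)) / 2
    base <- Cs / rowSums(Cs)
    expect_gte(countLogLik(T, C) - countLogLik(base, C), -1e-6)
  }
})

test_that("ergodic trimming keeps the largest strongly connected set", {
  C <- rbind(c(5, 2, 0), c(3, 5, 1), c(0, 0, 4))  # state 3 absorbing-ish
  est <- estimateTransitionMatrix(C)
  expect_equal(est$active, c(1, 2))
  expect_equal(dim(est$transition), c(2, 2))
})

test_that("implied timescales match the closed form and stay flat", {
  T <- rbind(c(0.85, 0.15), c(0.15, 0.85))        # lambda2 = 0.7
  d <- sampleChain(T, 2e5, 1, seed = 11)
  its <- impliedTimescales(d, lags = c(1, 2, 4), m = 1)
  expect_equal(its$timescale, rep(-1 / log(0.7), 3) * c(1, 1, 1),
               tolerance = 0.05)
})

test_that("non-Markovian observations show rising-then-plateauing timescales", {
  # 4-state Markov chain observed through a 2-state lumping that is NOT
  # lumpable: the lumped process is non-Markovian at short lags
  T <- rbind(c(0.90, 0.10, 0.00, 0.00),
             c(0.10, 0.80, 0.10, 0.00),
             c(0.00, 0.10, 0.80, 0.10),
             c(0.00, 0.00, 0.10, 0.90))
  d4 <- unlist(sampleChain(T, 3e5, 1, seed = 12))
  lump <- c(1L, 1L, 1L, 2L)[d4]
  its <- impliedTimescales(list(lump), lags = c(1, 5, 10, 15), m = 1)
  expect_gt(its$timescale[2], its$timescale[1])
  # plateau: growth slows at longer lags
  lateGrowth <- its$timescale[4] / its$timescale[3]
  earlyGrowth <- its$timescale[2] / its$timescale[1]
  expect_lt(lateGrowth, earlyGrowth)
})

test_that("negative-eigenvalue lags report undefined timescales", {
  # period-2 flipper: lambda2 = -0.8
  T <- rbind(c(0.1, 0.9), c(0.9, 0.1))
  d <- sampleChain(T, 5e4, 1, seed = 13)
  its <- impliedTimescales(d, lags = 1, m = 1)
  expect_true(is.na(its$timescale[1]))
})

test_that("Chapman-Kolmogorov holds on Markovian data, fails on lumped data", {
  T <- rbind(c(0.92, 0.08), c(0.08, 0.92))
  d <- sampleChain(T, 5e4, 10, seed = 14)
  ck <- ckTest(d, lag = 1, sets = list(1L, 2L), kMax = 5, seed = 2)
  expect_lt(max(abs(ck$model - ck$estimated)), 0.02)
  expect_true(all(ck$model >= ck$lower - 0.05 & ck$model <= ck$upper + 0.05))
  # lumpable 2-state grouping of a 4-state block chain agrees
  Tb <- rbind(c(0.45, 0.45, 0.05, 0.05),
              c(0.45, 0.45, 0.05, 0.05),
              c(0.05, 0.05, 0.45, 0.45),
              c(0.05, 0.05, 0.45, 0.45))
  db <- sampleChain(Tb, 5e4, 10, seed = 15)
  ckb <- ckTest(db, lag = 1, sets = list(c(1L, 2L), c(3L, 4L)), kMax = 5,
                seed = 2)
  expect_lt(max(abs(ckb$model - ckb$estimated)), 0.02)
  # non-Markovian lumped chain at short lag: visible divergence
  Tn <- rbind(c(0.90, 0.10, 0.00, 0.00),
              c(0.10, 0.80, 0.10, 0.00),
              c(0.00, 0.10, 0.80, 0.10),
              c(0.00, 0.00, 0.10, 0.90))
  dn <- lapply(sampleChain(Tn, 5e4, 10, seed = 16), function(x)
    c(1L, 1L, 2L, 2L)[x])
  ckn <- ckTest(dn, lag = 1, sets = list(c(1L), c(2L)), kMax = 5, seed = 2)
  expect_gt(max(abs(ckn$model - ckn$estimated)), 0.02)
})

test_that("GMRQ: m = 2 score approaches 1 + lambda2; m = 1 scores 1", {
  T <- rbind(c(0.9, 0.1), c(0.1, 0.9))  # lambda2 = 0.8
  d <- sampleChain(T, 1e5, 1, seed = 17)
  est <- estimateTransitionMatrix(countTransitions(d, 1, 2))
  V2 <- icekinetics:::msmEigenvectors(est, 2, 2)
  expect_equal(gmrqScore(V2, d, 1, 2), 1 + 0.8, tolerance = 0.02)
  V1 <- icekinetics:::msmEigenvectors(est, 1, 2)
  expect_equal(gmrqScore(V1, d, 1, 2), 1, tolerance = 1e-6)
})

test_that("cross-validated GMRQ does not reward gross overfitting", {
  # scarce 2-blob metastable data (lambda2 = 0.9, variational bound 1.9):
  # a grossly over-discretized model overshoots the bound in training, but
  # its cross-validated test score stays at or below the bound
  T <- rbind(c(0.95, 0.05), c(0.05, 0.95))
  trajs <- lapply(1:6, function(i) {
    d <- unlist(sampleChain(T, 300, 1, seed = 20 + i))
    x <- matrix(rnorm(length(d), mean = 6 * (d == 2)), ncol = 1,
                dimnames = list(NULL, "a"))
    CVSeries(x)
  })
  trainScore <- function(series, nStates) {
    cl <- kcentersCluster(series, nStates, seed = 1)
    est <- estimateTransitionMatrix(countTransitions(cl$dtrajs, 1, nStates))
    V <- icekinetics:::msmEigenvectors(est, 2, nStates)
    gmrqScore(V, cl$dtrajs, 1, nStates)
  }
  bound <- 1 + 0.9
  tr100 <- trainScore(trajs[1:4], 100)
  s100 <- gmrqCV(trajs, nStates = 100, lag = 1, m = 2, nFolds = 3, seed = 1)
  expect_gt(tr100, bound)              # training rewards overfitting ...
  expect_lt(s100$mean, bound + 0.01)   # ... cross-validation does not
  expect_lt(s100$mean, tr100)
})

test_that("parameter recovery on the synthetic 8-state network", {
  net <- buildTwoPathwayNetwork(0.5, 0.98)
  T <- net@transition
  d <- sampleChain(T, 2e5, 1, seed = 30)
  C <- countTransitions(d, 1, 8)
  est <- estimateTransitionMatrix(C, reversible = FALSE)
  That <- matrix(0, 8, 8)
  That[est$active, est$active] <- est$transition
  rowN <- rowSums(C)[est$active]
  for (i in est$active) for (j in 1:8) {
    se <- sqrt(T[i, j] * (1 - T[i, j]) / rowSums(C)[i])
    expect_lt(abs(That[i, j] - T[i, j]), 3 * se + 1e-6)
  }
})

test_that("model bundles survive a save/load round trip", {
  net <- buildTwoPathwayNetwork(0.5, 0.98)
  em <- emitTrajectories(net, 2, 3000, seed = 3)
  m <- buildMSM(em$series, 16, 1, seed = 5)
  dir <- tempfile()
  saveMSM(m, dir)
  m2 <- loadMSM(dir)
  expect_equal(m2@transition, m@transition, tolerance = 1e-12)
  expect_equal(m2@stationary, m@stationary, tolerance = 1e-12)
  expect_identical(m2@dtrajs, m@dtrajs)
  expect_identical(m2@active, m@active)
})
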