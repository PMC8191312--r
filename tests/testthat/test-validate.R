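# GMRQ cross-validation (variational behaviour) and the residence
# probability test (self-consistency and violation detection).

.permuteLabels <- function(ds, seed) {
  set.seed(seed)
  lapply(ds, function(s) sample.int(max(s), length(s), replace = TRUE))
}

test_that("a kinetically resolving partition beats random labels on test GMRQ", {
  T3 <- rbind(c(0.95, 0.04, 0.01), c(0.04, 0.92, 0.04),
              c(0.01, 0.04, 0.95))
  dtrajs <- lapply(1:8, function(i) sampleMarkovChain(T3, 4000, 1,
                                                      seed = 300 + i))
  rep <- gmrqCrossValidate(
    dtrajs, list(resolved = list(), permuted = list(relabel = .permuteLabels)),
    lag = 1, m = 3, seed = 4)
  s <- rep@summary
  expect_gt(s$meanTest[s$name == "resolved"], s$meanTest[s$name == "permuted"])
  expect_identical(rep@best, "resolved")
  ## scores are bounded by m
  expect_true(all(rep@scores$test <= 3 + 0.1))
})

test_that("m = 1 scores the stationary eigenfunction at 1", {
  T3 <- randReversibleT(3, seed = 2)
  dtrajs <- lapply(1:4, function(i) sampleMarkovChain(T3, 2000, 1, seed = i))
  rep <- gmrqCrossValidate(dtrajs, list(only = list()), lag = 1, m = 1,
                           seed = 1)
  expect_equal(rep@scores$train, rep(1, rep@nSplits), tolerance = 1e-9)
  expect_equal(rep@scores$test, rep(1, rep@nSplits), tolerance = 1e-9)
})

test_that("train GMRQ exceeds test GMRQ on average (variational bound)", {
  ## overfitting needs enough spectral freedom relative to the data: a
  ## 10-state chain scored with m = 5 on short trajectories
  diffs <- vapply(1:20, function(s) {
    T10 <- randReversibleT(10, seed = 700 + s, diagBoost = 3)
    dtrajs <- lapply(1:6, function(i)
      sampleMarkovChain(T10, 150, start = sample.int(10, 1),
                        seed = s * 37 + i))
    rep <- gmrqCrossValidate(dtrajs, list(g = list()), lag = 1, m = 5,
                             seed = s)
    mean(rep@scores$train) - mean(rep@scores$test)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("GMRQ clusters continuous projections through the grid", {
  set.seed(5)
  trajs <- lapply(1:4, function(i) {
    s <- sampleMarkovChain(rbind(c(0.98, 0.02), c(0.02, 0.98)), 1500, 1,
                           seed = 40 + i)
    matrix(c(-1, 1)[s] + rnorm(1500, sd = 0.3), ncol = 1)
  })
  rep <- gmrqCrossValidate(trajs, list(k2 = list(nClusters = 2),
                                       k20 = list(nClusters = 20)),
                           lag = 1, m = 2, seed = 2)
  expect_identical(sort(unique(rep@scores$name)), c("k2", "k20"))
  expect_true(all(rep@scores$test > 1))    # both resolve the slow process
})

test_that("residence curves are exactly 1 at zero lag multiples", {
  T <- randReversibleT(6, seed = 1, diagBoost = 5)
  m <- markovModelFromT(T)
  dtrajs <- lapply(1:4, function(i) sampleMarkovChain(T, 5000, 1, seed = i))
  rr <- residenceProbabilityTest(m, dtrajs, nTop = 4, lagMultiples = 0:2,
                                 minStartSpacing = 3, nBoot = 100, seed = 1)
  expect_equal(unname(rr@model[, "0"]), rep(1, 4))
  expect_equal(unname(rr@data[, "0"]), rep(1, 4))
})

test_that("the test passes on self-consistent data and flags a perturbed model", {
  set.seed(3)
  S <- matrix(runif(225), 15, 15) * 0.2
  S <- S + t(S); diag(S) <- diag(S) + rexp(15, rate = 0.2)
  Tr <- S / rowSums(S)
  m <- markovModelFromT(Tr)
  dts <- lapply(1:10, function(i)
    sampleMarkovChain(Tr, 20000, start = sample.int(15, 1,
                                                    prob = stationaryDist(m)),
                      seed = 200 + i))
  rr <- residenceProbabilityTest(m, dts, nTop = 12, lagMultiples = 0:2,
                                 minStartSpacing = 5, nBoot = 500, seed = 1)
  expect_true(all(rr@pass, na.rm = TRUE))
  ## swap metastability: deep states become shallow and vice versa
  Sp <- S
  diag(Sp) <- rev(diag(S))
  Tp <- Sp / rowSums(Sp)
  mp <- markovModelFromT(Tp)
  rr2 <- residenceProbabilityTest(mp, dts, nTop = 12, lagMultiples = 0:2,
                                  minStartSpacing = 5, nBoot = 500, seed = 1)
  expect_gt(sum(!rr2@pass, na.rm = TRUE), 0)
})

test_that("states with too few qualifying starts are excluded with a warning", {
  T <- rbind(c(0.998, 0.002), c(0.5, 0.5))    # state 2 rarely visited
  m <- markovModelFromT(T)
  dts <- list(sampleMarkovChain(T, 800, 1, seed = 1))
  expect_warning(
    rr <- residenceProbabilityTest(m, dts, nTop = 2, lagMultiples = 0:1,
                                   minStartSpacing = 50, nBoot = 50,
                                   seed = 1),
    "fewer than")
  expect_true(any(is.na(rr@pass)))
})
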