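# Transition counting, connectivity trimming, MSM estimation and implied
# timescales, against hand counts and 2x2 closed forms.

test_that("sliding-window counting matches hand counts", {
  C1 <- countTransitions(c(1L, 1L, 2L, 2L, 1L), lag = 1)
  expect_equal(C1@counts, rbind(c(1, 1), c(1, 1)))
  C2 <- countTransitions(c(1L, 1L, 2L, 2L, 1L), lag = 2)
  expect_equal(C2@counts, rbind(c(0, 2), c(1, 0)))
  Cc <- countTransitions(rep(1L, 10), lag = 1)
  expect_equal(Cc@counts[1, 1], 9)
  expect_error(countTransitions(c(1L, 2L), lag = 5), "shorter than the lag")
  ## counts pool across trajectories
  Cp <- countTransitions(list(c(1L, 2L), c(2L, 1L)), lag = 1)
  expect_equal(Cp@counts, rbind(c(0, 1), c(1, 0)))
})

test_that("trimming keeps the largest strongly connected component", {
  C <- countTransitions(c(1L, 1L, 2L, 2L, 1L, 3L), lag = 1)
  Ct <- trimToConnected(C)
  expect_identical(Ct@activeSet, 1:2)           # state 3 has no exit
  full <- countTransitions(c(1L, 2L, 3L, 1L, 2L, 3L, 1L), lag = 1)
  expect_identical(trimToConnected(full)@activeSet, 1:3)
  ## two disjoint blocks: sizes 3 and 2 -> the 3-block is retained
  blocks <- list(c(1L, 2L, 3L, 1L, 2L, 3L, 1L), c(4L, 5L, 4L, 5L))
  Cb <- trimToConnected(countTransitions(blocks, lag = 1))
  expect_identical(Cb@activeSet, 1:3)
  ## count floor removes rarely visited states before the SCC search
  noisy <- c(rep(c(1L, 2L), 50), 3L, rep(c(1L, 2L), 50))
  Cf <- trimToConnected(countTransitions(noisy, lag = 1), minCounts = 5)
  expect_identical(Cf@activeSet, 1:2)
})

test_that("estimation matches 2x2 closed forms", {
  Cs <- new("CountMatrix", counts = rbind(c(1, 1), c(1, 1)), lag = 1L,
            activeSet = 1:2, trimmed = TRUE)
  m <- estimateMarkovModel(Cs)
  expect_equal(transitionMatrix(m), matrix(0.5, 2, 2))
  expect_equal(stationaryDist(m), c(0.5, 0.5))
  expect_equal(modelEigenvalues(m)[2], 0, tolerance = 1e-12)

  m2 <- markovModelFromT(T2)
  expect_equal(stationaryDist(m2), c(2, 1) / 3, tolerance = 1e-12)
  expect_equal(modelEigenvalues(m2)[2], 0.7, tolerance = 1e-12)
  expect_equal(impliedTimescales(m2)[1], -1 / log(0.7), tolerance = 1e-12)

  ## implied timescale formula at the published lag
  m45 <- markovModelFromT(rbind(c(0.9, 0.1), c(0.1, 0.9)), lag = 45L)
  ## lambda2 = 0.8 at tau = 45 time units
  expect_equal(modelEigenvalues(m45)[2], 0.8, tolerance = 1e-12)
  expect_equal(impliedTimescales(m45)[1], -45 / log(0.8), tolerance = 1e-12)
  expect_equal(signif(impliedTimescales(m45)[1], 4), 201.7)
})

test_that("pi is a fixed point and detailed balance holds for reversible fits", {
  for (s in 1:5) {
    T <- randReversibleT(6, seed = s)
    dtraj <- sampleMarkovChain(T, 5000, 1, seed = s)
    m <- estimateMarkovModel(list(dtraj), lag = 1)
    piv <- stationaryDist(m)
    expect_lt(sum(abs(piv %*% transitionMatrix(m) - piv)), 1e-10)
    F <- piv * transitionMatrix(m)
    expect_lt(max(abs(F - t(F))), 1e-10)
    expect_true(all(diff(impliedTimescales(m)[
      !is.na(impliedTimescales(m))]) <= 1e-12))
  }
})

test_that("the non-reversible estimator reports complex spectra with a warning", {
  rot <- rbind(c(0.1, 0.9, 0), c(0, 0.1, 0.9), c(0.9, 0, 0.1))
  dtraj <- sampleMarkovChain(rot, 3000, 1, seed = 1)
  C <- trimToConnected(countTransitions(dtraj, 1))
  expect_warning(m <- estimateMarkovModel(C, reversible = FALSE), "complex")
  piv <- stationaryDist(m)
  expect_lt(sum(abs(piv %*% transitionMatrix(m) - piv)), 1e-10)
})

test_that("implied timescales are flat across lags for Markovian data", {
  T <- randReversibleT(4, seed = 3, diagBoost = 6)
  dtrajs <- lapply(1:4, function(i) sampleMarkovChain(T, 30000, 1, seed = i))
  tab <- impliedTimescalesScan(dtrajs, lags = c(1, 2, 4, 8), nTimescales = 1)
  expect_equal(nrow(tab), 4L)
  spread <- diff(range(tab$ts1)) / mean(tab$ts1)
  expect_lt(spread, 0.25)
  ## white-noise states: fastest relaxation, t2 near zero
  wn <- lapply(1:3, function(i) sample.int(3, 2000, replace = TRUE))
  tw <- impliedTimescalesScan(wn, lags = c(1, 2), nTimescales = 1)
  expect_true(all(is.na(tw$ts1) | tw$ts1 < 1))
  ## lag = length - 1: one transition per trajectory, low-count flag
  short <- list(c(1L, 2L, 1L, 2L), c(2L, 1L, 2L, 1L))
  ts <- impliedTimescalesScan(short, lags = 3, nTimescales = 1)
  expect_true(ts$lowCounts[1])
})
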