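# Synthetic generators: Langevin dynamics against closed forms, Markov-chain
# sampling against stationary solves, helix construction geometry, and
# hydrogen-bond geometry round-trips.

test_that("free diffusion has zero drift and MSD = 2 D t", {
  L <- makeLandscape("flat", dimension = 1L)
  n <- 400L; steps <- 200L; dt <- 0.01; D <- 1
  trajs <- simulateOverdamped(L, nSteps = steps, nTrajectories = n, dt = dt,
                              D = D, seed = 1, x0 = matrix(0))
  finals <- vapply(trajs, function(tr) values(tr)[steps + 1L, 1L], numeric(1))
  tEnd <- steps * dt
  seMean <- sd(finals) / sqrt(n)
  expect_lt(abs(mean(finals)), 3 * seMean)
  msd <- finals^2
  expect_lt(abs(mean(msd) - 2 * D * tEnd), 3 * sd(msd) / sqrt(n))
})

test_that("harmonic well reaches the Ornstein-Uhlenbeck stationary variance", {
  L <- makeLandscape("harmonic", kappa = 2)
  trajs <- simulateOverdamped(L, nSteps = 4000L, nTrajectories = 50L,
                              dt = 0.002, seed = 2, x0 = matrix(0))
  ## per-trajectory variance after burn-in; 3-SE band across trajectories
  vars <- vapply(trajs, function(tr) var(values(tr)[-(1:500), 1L]), numeric(1))
  expect_lt(abs(mean(vars) - 0.5), 3 * sd(vars) / sqrt(length(vars)))
})

test_that("symmetric double well splits its population evenly", {
  L <- makeLandscape("double-well", h = 2)
  trajs <- simulateOverdamped(L, nSteps = 10000L, nTrajectories = 40L,
                              dt = 0.002, seed = 3, x0 = "minima")
  fracs <- vapply(trajs, function(tr) mean(values(tr)[, 1L] > 0), numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 3 * sd(fracs) / sqrt(length(fracs)))
})

test_that("Langevin sampling reproduces the Boltzmann density (quadrature oracle)", {
  L <- makeLandscape("double-well", h = 2)
  tr <- simulateOverdamped(L, nSteps = 1e6, dt = 0.002, seed = 4,
                           x0 = matrix(1))[[1]]
  x <- values(tr)[, 1L]
  ## thin beyond the hopping correlation time so counts are ~independent
  xs <- x[seq(1L, length(x), by = 1000L)]
  edges <- seq(-2.2, 2.2, length.out = 12L)
  xs <- xs[xs > edges[1] & xs < edges[length(edges)]]
  grid <- seq(-2.2, 2.2, length.out = 4001L)
  dens <- exp(-potential(L, grid))
  cell <- cut(grid, edges)
  pExp <- tapply(dens, cell, sum)
  pExp <- pExp / sum(pExp)
  obs <- table(cut(xs, edges))
  gof <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pExp))
  expect_gt(gof$p.value, 1e-3)
})

test_that("identical seeds give bit-identical trajectories", {
  L <- makeLandscape("triple-well-2d")
  a <- simulateOverdamped(L, nSteps = 500L, nTrajectories = 3L, seed = 9)
  b <- simulateOverdamped(L, nSteps = 500L, nTrajectories = 3L, seed = 9)
  expect_identical(lapply(a, values), lapply(b, values))
  h1 <- makeHelix(20, noise = 0.3, seed = 5)
  h2 <- makeHelix(20, noise = 0.3, seed = 5)
  expect_identical(h1, h2)
  s1 <- sampleMarkovChain(T2, 100, 1, seed = 11)
  s2 <- sampleMarkovChain(T2, 100, 1, seed = 11)
  expect_identical(s1, s2)
})

test_that("unstable integration aborts with a coordinate diagnostic", {
  L <- makeLandscape("double-well", h = 4)
  expect_error(simulateOverdamped(L, nSteps = 1000L, dt = 10, seed = 1,
                                  x0 = matrix(1.5)),
               "non-finite")
})

test_that("landscape gradients agree with numerical differentiation", {
  for (fam in c("harmonic", "double-well", "tilted-double-well",
                "triple-well-2d")) {
    L <- makeLandscape(fam)
    d <- L@dimension
    set.seed(42)
    for (rep in 1:5) {
      x <- runif(d, -1.5, 1.5)
      g <- potentialGradient(L, x)
      gnum <- vapply(seq_len(d), function(j) {
        e <- numeric(d); e[j] <- 1e-6
        (potential(L, x + e) - potential(L, x - e)) / 2e-6
      }, numeric(1))
      expect_equal(as.numeric(g), gnum, tolerance = 1e-5)
    }
  }
})

test_that("Markov chain sampling matches degenerate and stationary cases", {
  expect_identical(unique(sampleMarkovChain(diag(4), 50, start = 3, seed = 1)),
                   3L)
  alt <- sampleMarkovChain(rbind(c(0, 1), c(1, 0)), 10, start = 1, seed = 1)
  expect_identical(alt, rep(c(1L, 2L), 5))
  s <- sampleMarkovChain(T2, 1e5, start = 1, seed = 2)
  ## effective sample size correction for lambda2 = 0.7 autocorrelation
  neff <- 1e5 * (1 - 0.7) / (1 + 0.7)
  se <- sqrt(2 / 3 * 1 / 3 / neff)
  expect_lt(abs(mean(s == 1) - 2 / 3), 3 * se)
  bad <- rbind(c(0.9, 0.2), c(0.2, 0.8))
  expect_error(sampleMarkovChain(bad, 10, 1), "row sums")
})

test_that("ideal helix geometry matches the chord formula and axis", {
  h <- makeHelix(30)
  d <- sqrt(rowSums((h[-1, ] - h[-30, ])^2))
  chord <- sqrt((2 * 2.3 * sin(50 * pi / 180))^2 + 1.5^2)
  expect_equal(d, rep(chord, 29), tolerance = 1e-10)
  fit <- fitCylinder(h)
  expect_gt(abs(sum(fit$axis * c(0, 0, 1))), cos(1 * pi / 180))
  expect_equal(fit$radius, 2.3, tolerance = 1e-6)
})

test_that("a constructed kink rotates the downstream axis by the stated angle", {
  h <- makeHelix(30, kinks = list(c(15, 40, 30)))
  up <- fitCylinder(h[1:12, ])
  dn <- fitCylinder(h[18:30, ])
  ang <- acos(abs(sum(up$axis * dn$axis))) * 180 / pi
  expect_equal(ang, 40, tolerance = 2)
  expect_error(makeHelix(30, kinks = list(c(4, 30, 0))), "terminus")
  expect_error(makeHelix(10, kinks = list(c(5, 30, 0))), "12 residues")
})

test_that("hydrogen-bond geometries round-trip their descriptors", {
  for (case in list(c(0.30, 0), c(0.34, 29), c(0.36, 10))) {
    g <- makeHBondGeometry(case[1], case[2])
    dDA <- sqrt(sum((g$acceptor - g$donor)^2))
    v1 <- g$hydrogen - g$donor; v2 <- g$acceptor - g$donor
    ## atan2 form stays accurate at zero angle, unlike acos
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    ang <- atan2(sqrt(sum(cr^2)), sum(v1 * v2)) * 180 / pi
    expect_equal(dDA, case[1], tolerance = 1e-9)
    expect_equal(ang, case[2], tolerance = 1e-9)
  }
  expect_error(makeHBondGeometry(0.3, 95))
})

test_that("quadrature Boltzmann weights are a proper distribution", {
  bw <- boltzmannWeights(makeLandscape("triple-well-2d"))
  expect_equal(sum(bw$weights), 1, tolerance = 1e-12)
  expect_length(bw$weights, 3L)
  ## middle well is the deepest by construction
  expect_equal(which.max(bw$weights), 2L)
})
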