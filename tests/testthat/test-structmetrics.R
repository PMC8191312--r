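# Structural observables: cylinder fits, kink profiling and classification,
# hinge aggregation, the hydrogen-bond criterion, per-state averaging, odds
# ratios, tIC shift histograms and barrier start selection.

test_that("cylinder fits are exact on exact cylinders", {
  t <- seq(0, 4 * pi, length.out = 30)
  pts <- cbind(5 * cos(t), 5 * sin(t), seq(0, 20, length.out = 30))
  fit <- fitCylinder(pts)
  expect_lt(fit$residual, 1e-8)
  expect_equal(abs(fit$axis[3]), 1, tolerance = 1e-8)
  expect_equal(fit$radius, 5, tolerance = 1e-7)
  ## one cylinder window of a noiseless ideal helix
  h <- makeHelix(12)
  f6 <- fitCylinder(h[1:6, ])
  expect_gt(abs(f6$axis[3]), cos(1 * pi / 180))
  expect_equal(f6$radius, 2.3, tolerance = 0.05)
  expect_error(fitCylinder(cbind(1:6, 1:6, 1:6)), "collinear")
  expect_error(fitCylinder(h[1:4, ]), "6 points")
})

test_that("cylinder axes are robust to coordinate noise", {
  angs <- vapply(1:100, function(s) {
    h <- makeHelix(12, noise = 0.2, seed = s)
    f <- fitCylinder(h)
    acos(min(1, abs(f$axis[3]))) * 180 / pi
  }, numeric(1))
  expect_lt(max(angs), 5)
})

test_that("kink profiles round-trip generator ground truth", {
  ideal <- kinkProfile(makeHelix(30))
  expect_lt(ideal@maxAngle, 3)
  expect_true(ideal@straight)
  k40 <- kinkProfile(makeHelix(30, kinks = list(c(15, 40, 60))))
  peak <- k40@residues[which.max(k40@angles)]
  expect_equal(k40@maxAngle, 40, tolerance = 2)
  expect_lte(abs(peak - 15), 1)
  expect_false(k40@straight)
  ## the 35-degree classifier: a 20-degree kink is still straight
  k20 <- kinkProfile(makeHelix(30, kinks = list(c(15, 20, 60))))
  expect_equal(k20@maxAngle, 20, tolerance = 2)
  expect_true(k20@straight)
  expect_error(kinkProfile(makeHelix(10)), "too short")
})

test_that("wobble azimuth tracks the requested bend direction", {
  w1 <- kinkProfile(makeHelix(30, kinks = list(c(15, 40, 0))))
  w2 <- kinkProfile(makeHelix(30, kinks = list(c(15, 40, 90))))
  a1 <- w1@wobbles[w1@residues == 15]
  a2 <- w2@wobbles[w2@residues == 15]
  dd <- (a2 - a1) %% 360
  expect_equal(min(dd, 360 - dd), 90, tolerance = 10)
})

test_that("kink angles are rigid-motion invariant", {
  h <- makeHelix(24, kinks = list(c(12, 30, 45)), noise = 0.1, seed = 3)
  ref <- kinkProfile(h)@angles
  for (s in 1:4) {
    R <- randomRotation(50 + s)
    moved <- h %*% t(R) + matrix(c(10, -4, 7), 24, 3, byrow = TRUE)
    expect_equal(kinkProfile(moved)@angles, ref, tolerance = 1e-6)
  }
})

test_that("raising the threshold never decreases the straight fraction", {
  set.seed(6)
  profiles <- lapply(1:20, function(i) {
    ang <- sample(c(10, 25, 40, 55), 1)
    kinkProfile(makeHelix(24, kinks = list(c(12, ang, 30)), noise = 0.05,
                          seed = i))
  })
  fracs <- vapply(c(15, 35, 60), function(thr)
    mean(vapply(profiles, function(p) p@maxAngle < thr, logical(1))),
    numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("hinge aggregation localizes kinks and normalizes histograms", {
  hinges <- list(hingeA = 10:13, hingeB = 16:19)
  straight <- lapply(1:5, function(i) kinkProfile(makeHelix(28)))
  aggS <- aggregateHinges(straight, hinges)
  expect_true(all(aggS$kinkFrequency == 0))
  expect_true(all(aggS$hingeFrequency == 0))
  kinked <- lapply(1:5, function(i)
    kinkProfile(makeHelix(28, kinks = list(c(17, 45, 20)))))
  aggK <- aggregateHinges(kinked, hinges)
  expect_equal(unname(aggK$hingeFrequency["hingeB"]), 1)
  expect_equal(unname(aggK$hingeFrequency["hingeA"]), 0)
  ## cylinder windows smear the peak by at most one residue around the kink
  expect_equal(sum(aggK$kinkFrequency[c("16", "17", "18")]), 1)
  for (h in aggK$histograms)
    expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-12)
  expect_error(aggregateHinges(list(), hinges), "empty")
  expect_error(aggregateHinges(straight, list(x = 1:40)), "outside")
})

test_that("the geometric hydrogen-bond criterion applies strict thresholds", {
  expect_true(detectHBond(makeHBondGeometry(0.34, 29)))
  expect_false(detectHBond(makeHBondGeometry(0.36, 10)))   # distance fails
  expect_false(detectHBond(makeHBondGeometry(0.30, 31)))   # angle fails
  expect_false(detectHBond(makeHBondGeometry(0.35, 0)))    # strict boundary
  ## rigid motions leave the verdict unchanged; uniform scaling breaks the
  ## distance rule while the angle is scale-free
  g <- makeHBondGeometry(0.34, 29)
  R <- randomRotation(9)
  moved <- lapply(g, function(p) drop(R %*% p) + c(1, 2, 3))
  expect_true(detectHBond(moved$donor, moved$hydrogen, moved$acceptor))
  scaled <- lapply(g, function(p) p * 2)
  expect_false(detectHBond(scaled$donor, scaled$hydrogen, scaled$acceptor))
  expect_error(detectHBond(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")
})

test_that("per-state averaging matches planted constructions", {
  expect_equal(as.numeric(perStateObservable(c(1L, 1L, 2L), c(1, 1, 1))),
               c(1, 1))
  dtraj <- c(rep(1L, 10), rep(2L, 5))
  vals <- c(rep(c(1, 0, 0, 0, 0, 1, 0, 1, 0, 0), 1), rep(1, 5))
  ps <- perStateObservable(dtraj, vals)
  expect_equal(unname(ps[1]), 0.3)
  expect_equal(unname(ps[2]), 1)
  expect_warning(perStateObservable(c(1L, 3L), c(1, 1)), "without frames")
})

test_that("MSM-weighted macrostate percentages combine per-state means", {
  m <- markovModelFromT(T2)
  ob <- sampleObservableMCMC(m, c(0.9, 0.3), nChains = 10, nSteps = 20000,
                             seed = 2)
  expect_lt(abs(ob$mean - 0.7), 3 * ob$sd + 0.01)
})

test_that("odds ratios follow the cross-ratio identities", {
  expect_equal(oddsRatio(20, 10, 30, 60), 4)
  expect_equal(oddsRatio(8, 4, 6, 3), 1)          # equal odds -> no coupling
  ## swapping bond and no-bond labels inverts the ratio
  expect_equal(oddsRatio(30, 60, 20, 10), 1 / 4)
  expect_error(oddsRatio(1, 0, 2, 3), "Bk")
  ## under independence the log odds ratio is centred at zero
  set.seed(11)
  pCell <- c(0.4 * 0.3, 0.6 * 0.3, 0.4 * 0.7, 0.6 * 0.7)
  ors <- replicate(1000, {
    tab <- as.numeric(rmultinom(1, 400, pCell))
    oddsRatio(tab[1], tab[2], tab[3], tab[4])
  })
  expect_lt(abs(mean(log(ors))), 0.06)
})

test_that("tIC shift histograms are normalized and centred on the drift", {
  set.seed(12)
  base <- lapply(1:3, function(i)
    cbind(as.numeric(stats::filter(rnorm(3000), .9, "recursive")),
          rnorm(3000)))
  model <- fitTICA(base, lag = 5)
  const <- matrix(rep(c(1, 2), each = 50), ncol = 2)
  hc <- ticShiftHistogram(model, list(const), component = 1)
  expect_lt(max(abs(hc$deltas)), 1e-12)
  drift <- lapply(1:5, function(i)
    matrix(c(seq(0, 3, length.out = 200), rep(0, 200)), ncol = 2))
  hd <- ticShiftHistogram(model, drift, component = 1, breaks = 30)
  expect_equal(sum(hd$density * diff(hd$breaks)), 1, tolerance = 1e-12)
  proj <- projectTICA(model, drift[[1]], 1)
  expect_equal(mean(hd$deltas), mean(proj - proj[1]), tolerance = 1e-9)
})

test_that("barrier start selection picks the boundary microstates", {
  m <- markovModelFromT(T4block)
  lump <- spectralLump(m, 2)
  a <- macroAssignment(lump)
  blockA <- sort(which(a == a[1]))
  sel <- barrierStartSelection(m, lump, a[1], a[3], n = 1)
  ## in T4block, states 1 and 3 carry the 0.01 inter-block coupling
  expect_identical(sort(c(sel$fromA, sel$fromB)), c(1L, 3L))
  ## both sides have fewer than n members, so each pick warns once
  expect_warning(expect_warning(
    selAll <- barrierStartSelection(m, lump, a[1], a[3], n = 5), "only"))
  expect_length(selAll$fromA, 2L)
  ## sorted contract: selected have transition-out probability >= unselected
  pOut <- rowSums(m@T[blockA, which(a == a[3]), drop = FALSE])
  expect_gte(min(pOut[match(sel$fromA, blockA)]),
             max(pOut[-match(sel$fromA, blockA)]))
})
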