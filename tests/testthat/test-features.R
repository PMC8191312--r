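# Pair-distance feature construction and loading-based pruning.

test_that("pair distances reproduce hand geometry and reject bad input", {
  coords <- array(0, c(3, 2, 3))          # 3 frames, 2 static atoms
  coords[, 2, 1] <- 3; coords[, 2, 2] <- 4
  ft <- computePairDistances(coords, cbind(1, 2))
  expect_equal(unname(values(ft)[, 1]), rep(5, 3))
  expect_error(computePairDistances(coords, matrix(numeric(0), 0, 2)),
               "empty pair list")
  named <- array(0, c(2, 2, 3), dimnames = list(NULL, c("CA1", "CA2"), NULL))
  expect_error(computePairDistances(named, cbind("CA1", "CAX")), "CAX")
  expect_error(computePairDistances(coords, cbind(1, 1)), "self-pairs")
  expect_error(computePairDistances(coords, rbind(c(1, 2), c(2, 1))),
               "duplicate")
})

test_that("helix pair distances equal the generator chord formula", {
  h <- makeHelix(12)
  coords <- array(0, c(2, 12, 3))
  coords[1, , ] <- h; coords[2, , ] <- h
  pairs <- cbind(1:11, 2:12)
  ft <- computePairDistances(coords, pairs)
  chord <- sqrt((2 * 2.3 * sin(50 * pi / 180))^2 + 1.5^2)
  expect_equal(unname(values(ft)[1, ]), rep(chord, 11), tolerance = 1e-10)
})

test_that("distance features are rigid-motion invariant", {
  set.seed(7)
  base <- matrix(rnorm(15), 5, 3)
  frames <- array(0, c(4, 5, 3))
  for (t in 1:4) frames[t, , ] <- base + rnorm(15, sd = 0.1)
  pairs <- rbind(c(1, 2), c(2, 5), c(3, 4))
  ref <- values(computePairDistances(frames, pairs))
  for (s in 1:5) {
    R <- randomRotation(s)
    shift <- rnorm(3, sd = 10)
    moved <- frames
    for (t in 1:4) moved[t, , ] <- frames[t, , ] %*% t(R) +
        matrix(shift, 5, 3, byrow = TRUE)
    expect_equal(values(computePairDistances(moved, pairs)), ref,
                 tolerance = 1e-10)
  }
})

.toyTICA <- function(components) {
  d <- nrow(components)
  new("TICAModel", mean = numeric(d), C0 = diag(d), Ctau = diag(d) * 0.5,
      lag = 1L, frameInterval = 1, eigenvalues = rep(0.5, ncol(components)),
      components = components, epsilon = 0,
      featureLabels = paste0("f", seq_len(d)))
}

test_that("loading-based pruning keeps the top features per component", {
  V <- cbind(c(0.9, 0.1, 0.05), c(0.2, 0.8, 0.1), c(0.1, 0.0, 0.7))
  sel <- pruneFeaturesByLoading(.toyTICA(V), counts = c(1, 1, 1))
  expect_identical(as.character(sel), c("f1", "f2", "f3"))
  expect_identical(attr(sel, "indices"), 1:3)
  ## counts at the dimension keep everything, clamped with a warning
  expect_warning(all3 <- pruneFeaturesByLoading(.toyTICA(V), c(5, 5, 5)),
                 "clamped")
  expect_length(all3, 3L)
})

test_that("rank ties are all retained", {
  V <- cbind(c(0.9, 0.5, 0.5, 0.1), c(0.8, 0.3, 0.2, 0.1),
             c(0.7, 0.3, 0.2, 0.1))
  sel <- pruneFeaturesByLoading(.toyTICA(V), counts = c(2, 1, 1))
  ## tIC1 rank-2 value 0.5 is tied between features 2 and 3: both kept
  expect_identical(attr(sel, "indices"), 1:3)
})

test_that("pruning is idempotent on the restricted model", {
  set.seed(21)
  V <- matrix(rnorm(10 * 3), 10, 3)
  sel <- pruneFeaturesByLoading(.toyTICA(V), counts = c(4, 3, 2))
  idx <- attr(sel, "indices")
  m2 <- .toyTICA(V[idx, , drop = FALSE])
  m2@featureLabels <- as.character(sel)
  sel2 <- suppressWarnings(
    pruneFeaturesByLoading(m2, counts = c(4, 3, 2)))
  expect_identical(sort(as.character(sel2)), sort(as.character(sel)))
})

test_that("feature selection subsets trajectories by label", {
  tr <- featureTrajectory(matrix(1:12, 3, 4),
                          featureLabels = c("a", "b", "c", "d"))
  sub <- selectFeatures(tr, c("d", "b"))
  expect_identical(featureLabels(sub), c("d", "b"))
  expect_equal(values(sub)[, 1], values(tr)[, 4])
  expect_error(selectFeatures(tr, "zz"), "missing feature")
})

test_that("projection connectivity distinguishes connected from split clouds", {
  set.seed(3)
  one <- matrix(rnorm(400), ncol = 2)
  split <- rbind(one, matrix(rnorm(400, mean = 50), ncol = 2))
  expect_gt(projectionConnectivity(one, threshold = 1), 0.99)
  full <- projectionConnectivity(split, threshold = 1)
  expect_gt(full, 0.99)   # each island is internally connected
  lonely <- rbind(one, c(500, 500))
  expect_lt(projectionConnectivity(lonely, threshold = 1), 1)
})
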