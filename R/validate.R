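## Model validation: GMRQ cross-validation over a hyperparameter grid and
## the residence-probability test (model-propagated self-transition
## probabilities against trajectory-estimated residence, with a bootstrap
## band over trajectories).

#' GMRQ cross-validation over a hyperparameter grid
#'
#' Trajectories (the split unit) are divided `nSplits` times into training
#' and test sets at the given ratio. Per split and grid point, a
#' discretization is fit on the training trajectories, a reversible MSM is
#' estimated from the training assignments, and the sum of the top-`m`
#' generalized Rayleigh quotients of the training eigenvectors is evaluated
#' against the test set's correlation matrices:
#' `score = trace( (V' C0 V)^-1 (V' Ctau V) )` with `C0 = diag(test state
#' frequencies)` and `Ctau` the symmetrized test transition density. By the
#' variational principle the test score of a kinetically resolving
#' discretization exceeds that of an uninformative one, and scores are
#' bounded by `m` (up to sampling noise).
#'
#' Each grid point is a named list and may carry:
#' \describe{
#'   \item{nClusters}{fit [kCenters()] with this k on the (projected)
#'     training frames and assign all trajectories (continuous input).}
#'   \item{ticaLag}{fit [fitTICA()] on the training trajectories at this lag
#'     before clustering (continuous input; requires `nClusters`).}
#'   \item{relabel}{`function(dtrajs, seed)` returning relabelled dtrajs
#'     (discrete input), e.g. a label permutation control.}
#' }
#' Discrete trajectories with no `relabel` entry are scored as-is.
#'
#' @param trajs list of [FeatureTrajectory-class]/matrices, or list of
#'   integer dtrajs (at least 2; whole trajectories are the split unit).
#' @param grid list of grid points (named lists, see above); names label the
#'   report rows.
#' @param lag MSM estimation lag in frames.
#' @param nSplits number of random splits (default 5).
#' @param splitRatio fraction of trajectories in the training set
#'   (default 0.5, i.e. 1:1).
#' @param m number of eigenvalues scored (default 5, clamped to the model).
#' @param seed integer seed for the splits.
#' @return a [GMRQReport-class].
#' @export
gmrqCrossValidate <- function(trajs, grid, lag, nSplits = 5L,
                              splitRatio = 0.5, m = 5L, seed = 1L) {
  if (length(trajs) < 2L) stop("at least 2 trajectories are required")
  discrete <- is.numeric(trajs[[1L]]) && is.null(dim(trajs[[1L]]))
  if (is.null(names(grid)))
    names(grid) <- paste0("grid", seq_along(grid))
  set.seed(seed)
  nTr <- length(trajs)
  splits <- lapply(seq_len(nSplits), function(s) {
    tr <- sample.int(nTr, max(1L, round(nTr * splitRatio)))
    list(train = tr, test = setdiff(seq_len(nTr), tr))
  })
  rows <- list()
  for (g in seq_along(grid)) {
    gp <- grid[[g]]
    for (s in seq_len(nSplits)) {
      tr <- splits[[s]]$train; te <- splits[[s]]$test
      if (discrete) {
        dtr <- trajs[tr]; dte <- trajs[te]
        if (!is.null(gp$relabel)) {
          all <- gp$relabel(trajs, deriveSeed(seed, names(grid)[g]))
          dtr <- all[tr]; dte <- all[te]
        }
      } else {
        use <- trajs
        if (!is.null(gp$ticaLag)) {
          tica <- fitTICA(trajs[tr], lag = gp$ticaLag)
          use <- projectTICA(tica, trajs, nComponents = 2L)
        } else {
          use <- lapply(trajs, function(x)
            if (methods::is(x, "FeatureTrajectory")) x@values else as.matrix(x))
        }
        if (is.null(gp$nClusters))
          stop("continuous input requires nClusters in every grid point")
        pooled <- do.call(rbind, use[tr])
        km <- kCenters(pooled, k = gp$nClusters)
        dtr <- lapply(use[tr], function(x) assignMicrostates(km, x))
        dte <- lapply(use[te], function(x) assignMicrostates(km, x))
      }
      sc <- .gmrq_score_split(dtr, dte, lag, m)
      rows[[length(rows) + 1L]] <- data.frame(
        name = names(grid)[g], split = s, train = sc$train, test = sc$test,
        nStatesShared = sc$shared, flagged = sc$flagged)
    }
  }
  scores <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(scores, scores$name), function(df)
    data.frame(name = df$name[1L], meanTrain = mean(df$train),
               meanTest = mean(df$test))))
  agg <- agg[match(names(grid), agg$name), ]
  rownames(agg) <- NULL
  best <- agg$name[which.max(agg$meanTest)]
  new("GMRQReport", scores = scores, summary = agg, best = best,
      m = as.integer(m), nSplits = as.integer(nSplits),
      splitRatio = splitRatio)
}

.gmrq_score_split <- function(dtrain, dtest, lag, m) {
  Ctr <- trimToConnected(countTransitions(dtrain, lag))
  model <- estimateMarkovModel(Ctr)
  mm <- min(m, nStates(model))
  trainScore <- sum(model@eigenvalues[seq_len(mm)])
  ## test correlation matrices on the states shared with the training model
  k <- max(vapply(dtest, max, 1L), max(Ctr@activeSet))
  Cte <- countTransitions(dtest, lag, nStates = k)@counts
  shared <- intersect(Ctr@activeSet,
                      which(rowSums(Cte) + colSums(Cte) > 0))
  flagged <- length(shared) < nStates(model)
  Vfull <- matrix(0, k, mm)
  Vfull[Ctr@activeSet, ] <- model@rightVectors[, seq_len(mm), drop = FALSE]
  V <- Vfull[shared, , drop = FALSE]
  Cs <- (Cte[shared, shared, drop = FALSE] +
           t(Cte[shared, shared, drop = FALSE])) / 2
  Ntot <- sum(Cte)
  C0 <- diag((rowSums(Cs) + colSums(Cs)) / 2, nrow = length(shared)) / Ntot
  Ct <- Cs / Ntot
  S <- crossprod(V, C0 %*% V)
  Q <- crossprod(V, Ct %*% V)
  testScore <- tryCatch(sum(diag(solve(S, Q))), error = function(e) {
    sum(diag(solve(S + diag(1e-10, nrow(S)), Q)))
  })
  list(train = trainScore, test = testScore, shared = length(shared),
       flagged = flagged)
}

setMethod("show", "GMRQReport", function(object) {
  cat("GMRQReport:", object@nSplits, "splits, top", object@m,
      "eigenvalues\n")
  print(object@summary)
  cat("  best by mean test score:", object@best, "\n")
})

#' Residence-probability test of an MSM against its trajectories
#'
#' For each of the `nTop` most populated microstates, compares the
#' model-propagated residence probability `(T^k)_ii` at each lag multiple k
#' with the trajectory estimate: among (window-smoothed) starts in state i,
#' spaced at least `minStartSpacing` frames apart, the fraction still/again
#' in state i after `k * lag` frames. The uncertainty band is a bootstrap
#' over trajectories; the verdict demands the model curve inside the band at
#' every tested multiple and uses simultaneous (Bonferroni-adjusted across
#' states and nonzero multiples) 95% quantiles, so that the family-wise
#' false-alarm rate of the whole report is ~5%. At k = 0 both curves are
#' exactly 1.
#'
#' @param model a [MarkovModel-class].
#' @param dtrajs the discrete trajectories (original state labels).
#' @param nTop number of most-populated states to test (default 12).
#' @param lagMultiples propagation multiples (default 0:2).
#' @param minStartSpacing minimum frames between accepted starts (default
#'   `lag/10`, the published protocol's ratio).
#' @param smoothingWindow modal smoothing window in frames (default 1 = no
#'   smoothing).
#' @param nBoot bootstrap resamples of the trajectory set.
#' @param conf simultaneous confidence level for the verdict band.
#' @param seed bootstrap seed.
#' @param minStarts states with fewer qualifying starts are excluded with a
#'   warning (default 10).
#' @return a [ResidenceReport-class].
#' @export
residenceProbabilityTest <- function(model, dtrajs, nTop = 12L,
                                     lagMultiples = 0:2,
                                     minStartSpacing = NULL,
                                     smoothingWindow = 1L, nBoot = 1000L,
                                     conf = 0.95, seed = 1L,
                                     minStarts = 10L) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lagF <- model@lag
  if (is.null(minStartSpacing)) minStartSpacing <- max(1L, round(lagF / 10))
  lagMultiples <- sort(unique(as.integer(lagMultiples)))
  topIdx <- order(model@pi, decreasing = TRUE)[seq_len(min(nTop, nStates(model)))]
  topLabels <- model@activeSet[topIdx]
  ## model curves: (T^k)_ii
  nK <- length(lagMultiples)
  modelCurve <- matrix(NA_real_, length(topIdx), nK,
                       dimnames = list(topLabels, lagMultiples))
  Tk <- diag(nStates(model))
  kPrev <- 0L
  for (ki in seq_len(nK)) {
    while (kPrev < lagMultiples[ki]) { Tk <- Tk %*% model@T; kPrev <- kPrev + 1L }
    modelCurve[, ki] <- diag(Tk)[topIdx]
  }
  ## per-trajectory start outcomes
  w <- as.integer(smoothingWindow)
  maxK <- max(lagMultiples)
  perTraj <- lapply(dtrajs, function(s) {
    sm <- if (w > 1L) cpp_mode_filter(as.integer(s), w) else as.integer(s)
    horizon <- length(sm) - maxK * lagF
    if (horizon < 1L) return(NULL)
    out <- vector("list", length(topLabels))
    for (si in seq_along(topLabels)) {
      lab <- topLabels[si]
      cand <- which(sm[seq_len(horizon)] == lab)
      if (!length(cand)) { out[[si]] <- NULL; next }
      starts <- integer(0); last <- -Inf
      for (t in cand) if (t - last >= minStartSpacing) {
        starts <- c(starts, t); last <- t
      }
      occ <- vapply(lagMultiples, function(k)
        vapply(starts, function(t) sm[t + k * lagF] == lab, logical(1L)),
        logical(length(starts)))
      occ <- matrix(occ, nrow = length(starts))
      out[[si]] <- colSums(occ)          # successes per multiple
      attr(out[[si]], "n") <- length(starts)
    }
    out
  })
  perTraj <- perTraj[!vapply(perTraj, is.null, logical(1L))]
  nTrajs <- length(perTraj)
  succ <- array(0, c(nTrajs, length(topLabels), nK))
  cnt <- matrix(0, nTrajs, length(topLabels))
  for (ti in seq_len(nTrajs)) for (si in seq_along(topLabels)) {
    o <- perTraj[[ti]][[si]]
    if (is.null(o)) next
    succ[ti, si, ] <- o
    cnt[ti, si] <- attr(o, "n")
  }
  nStarts <- as.integer(colSums(cnt))
  keep <- nStarts >= minStarts
  if (!all(keep))
    warning("excluded state(s) with fewer than ", minStarts,
            " qualifying starts: ",
            paste(topLabels[!keep], collapse = ", "))
  dataCurve <- matrix(NA_real_, length(topLabels), nK,
                      dimnames = dimnames(modelCurve))
  for (si in seq_along(topLabels))
    if (nStarts[si] > 0)
      dataCurve[si, ] <- colSums(matrix(succ[, si, ], nTrajs)) / nStarts[si]
  ## bootstrap over trajectories
  nonzero <- lagMultiples > 0L
  nComp <- sum(keep) * sum(nonzero)
  alphaAdj <- (1 - conf) / max(1L, nComp)
  set.seed(seed)
  bootCurves <- array(NA_real_, c(nBoot, length(topLabels), nK))
  for (b in seq_len(nBoot)) {
    idx <- sample.int(nTrajs, nTrajs, replace = TRUE)
    s <- apply(succ[idx, , , drop = FALSE], c(2L, 3L), sum)
    n <- colSums(cnt[idx, , drop = FALSE])
    bootCurves[b, , ] <- s / ifelse(n > 0, n, NA_real_)
  }
  ## bootstrap-SE band: with few trajectories the extreme percentiles of the
  ## resample distribution saturate at its range, so the band pairs the
  ## bootstrap SE with a Bonferroni-adjusted t quantile (the SE itself is
  ## estimated from nTrajs trajectories, hence nTrajs - 1 df)
  bootSE <- apply(bootCurves, c(2L, 3L), sd, na.rm = TRUE)
  z <- stats::qt(1 - alphaAdj / 2, df = max(1L, nTrajs - 1L))
  lower <- pmax(dataCurve - z * bootSE, 0)
  upper <- pmin(dataCurve + z * bootSE, 1)
  dimnames(lower) <- dimnames(upper) <- dimnames(modelCurve)
  lower[, !nonzero] <- 1; upper[, !nonzero] <- 1   # k = 0 is exact
  pass <- vapply(seq_along(topLabels), function(si) {
    if (!keep[si]) return(NA)
    all(modelCurve[si, nonzero] >= lower[si, nonzero] - 1e-12 &
        modelCurve[si, nonzero] <= upper[si, nonzero] + 1e-12)
  }, logical(1L))
  new("ResidenceReport", states = as.integer(topLabels),
      lagMultiples = lagMultiples, model = modelCurve, data = dataCurve,
      lower = lower, upper = upper, pass = pass, nStarts = nStarts)
}

setMethod("show", "ResidenceReport", function(object) {
  cat("ResidenceReport:", length(object@states), "states, lag multiples",
      paste(object@lagMultiples, collapse = ","), "\n  pass:",
      sum(object@pass, na.rm = TRUE), "/", sum(!is.na(object@pass)), "\n")
})
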