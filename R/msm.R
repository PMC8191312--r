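## Microstate Markov state model estimation: sliding-window transition
## counting, strong-connectivity trimming, maximum-likelihood estimation
## (reversible via count symmetrization by default), and implied-timescale
## scans over lag times.

#' Count lagged transitions with a sliding window
#'
#' `counts[i, j]` is the number of frame pairs `(t, t + lag)` with state i at
#' t and state j at t + lag, summed over trajectories, window slid by one
#' frame.
#'
#' @param dtrajs integer vector or list of integer vectors (1-based states).
#' @param lag counting lag in frames (>= 1).
#' @param nStates total state count (default: maximum observed label).
#' @return a [CountMatrix-class] (untrimmed).
#' @export
countTransitions <- function(dtrajs, lag, nStates = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be at least 1 frame")
  usable <- vapply(dtrajs, function(s) length(s) > lag, logical(1L))
  if (!any(usable)) stop("all trajectories are shorter than the lag")
  if (is.null(nStates)) nStates <- max(unlist(dtrajs))
  k <- as.integer(nStates)
  counts <- matrix(0, k, k)
  for (s in dtrajs[usable]) {
    n <- length(s)
    i <- s[seq_len(n - lag)]
    j <- s[seq_len(n - lag) + lag]
    tab <- tabulate((i - 1L) * k + j, nbins = k * k)
    counts <- counts + matrix(tab, k, k, byrow = TRUE)
  }
  new("CountMatrix", counts = counts, lag = lag, activeSet = seq_len(k),
      trimmed = FALSE)
}

#' Trim a count matrix to its largest strongly connected component
#'
#' Restricts the counts to the largest strongly connected component of the
#' transition-count digraph (edges where counts > 0), so that a unique
#' stationary distribution exists. The retained original state labels are
#' recorded in the active set.
#'
#' In addition to the connectivity trim, `minCounts` removes states with
#' fewer total off-diagonal (entry plus exit) counts before the component
#' search — the standard ergodic-trimming guard against rarely visited
#' outlier microstates whose few exits masquerade as slow processes.
#'
#' @param C a [CountMatrix-class].
#' @param minCounts off-diagonal count floor per state (default 0: keep
#'   every state, connectivity trim only).
#' @return the trimmed [CountMatrix-class].
#' @export
trimToConnected <- function(C, minCounts = 0) {
  counts <- C@counts
  if (minCounts > 0) {
    off <- rowSums(counts) + colSums(counts) - 2 * diag(counts)
    keep0 <- off >= minCounts
    if (!any(keep0)) stop("count floor removed every state")
    counts <- counts[keep0, keep0, drop = FALSE]
    C <- new("CountMatrix", counts = counts, lag = C@lag,
             activeSet = C@activeSet[keep0], trimmed = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(
    (counts > 0) * 1, mode = "directed", diag = TRUE)
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  ## largest component by size; ties broken by total counts
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    tot <- vapply(cand, function(cc) {
      m <- comp$membership == cc
      sum(counts[m, m])
    }, numeric(1L))
    cand <- cand[which.max(tot)]
  }
  keep <- which(comp$membership == cand[1L])
  sub <- counts[keep, keep, drop = FALSE]
  if (sum(sub) == 0)
    stop("no transitions inside the largest connected component")
  new("CountMatrix", counts = sub, lag = C@lag,
      activeSet = C@activeSet[keep], trimmed = TRUE)
}

#' Estimate a Markov state model from transition counts
#'
#' Reversible mode (default) symmetrizes the counts, `T = rownorm((C +
#' t(C))/2)`, which guarantees a real spectrum and detailed balance with
#' `pi` proportional to the symmetrized row sums. Non-reversible mode
#' row-normalizes the raw counts and takes `pi` as the leading left
#' eigenvector; complex eigenvalue pairs are then reported with a warning.
#'
#' @param C a [CountMatrix-class] (trimmed; untrimmed input is trimmed
#'   automatically), or a dtraj list (counted at `lag`).
#' @param lag counting lag in frames (only when `C` is a dtraj list).
#' @param frameInterval time units per frame; tau = lag * frameInterval.
#' @param reversible logical.
#' @return a [MarkovModel-class].
#' @export
estimateMarkovModel <- function(C, lag = NULL, frameInterval = 1,
                                reversible = TRUE) {
  if (!methods::is(C, "CountMatrix")) {
    if (is.null(lag)) stop("lag is required when counting from dtrajs")
    C <- countTransitions(C, lag)
  }
  if (!C@trimmed) C <- trimToConnected(C)
  cnt <- C@counts
  k <- nrow(cnt)
  if (reversible) {
    S <- (cnt + t(cnt)) / 2
    rs <- rowSums(S)
    if (any(rs == 0)) stop("internal error: zero row after trimming")
    T <- S / rs
    pi <- rs / sum(rs)
    ## symmetric conjugate D^(1/2) T D^(-1/2) has the same spectrum
    sq <- sqrt(pi)
    M <- diag(sq) %*% T %*% diag(1 / sq)
    M <- (M + t(M)) / 2
    eg <- eigen(M, symmetric = TRUE)
    ord <- order(eg$values, decreasing = TRUE)
    lam <- eg$values[ord]
    U <- eg$vectors[, ord, drop = FALSE]
    right <- U / sq            # psi_k, pi-orthonormal
    left <- U * sq             # phi_k = pi * psi_k
    ## fix the trivial pair exactly and the signs deterministically
    right[, 1L] <- 1
    left[, 1L] <- pi
    for (j in seq_len(k)[-1L]) {
      i <- which.max(abs(right[, j]))
      if (right[i, j] < 0) { right[, j] <- -right[, j]; left[, j] <- -left[, j] }
    }
  } else {
    rs <- rowSums(cnt)
    if (any(rs == 0)) stop("internal error: zero row after trimming")
    T <- cnt / rs
    eg <- eigen(t(T))
    if (any(abs(Im(eg$values)) > 1e-12))
      warning("non-reversible estimator produced complex eigenvalue pairs")
    ord <- order(Re(eg$values), decreasing = TRUE)
    lam <- Re(eg$values[ord])
    pivec <- Re(eg$vectors[, ord[1L]])
    pi <- pivec / sum(pivec)
    for (it in 1:50) pi <- drop(pi %*% T) / sum(pi %*% T)  # polish fixed point
    egr <- eigen(T)
    ordr <- order(Re(egr$values), decreasing = TRUE)
    right <- Re(egr$vectors[, ordr, drop = FALSE])
    left <- Re(eg$vectors[, ord, drop = FALSE])
  }
  ## numerical cleanup so the validity contracts hold exactly
  T <- T / rowSums(T)
  pi <- pi / sum(pi)
  new("MarkovModel", T = unname(T), lag = C@lag,
      frameInterval = as.numeric(frameInterval), pi = unname(pi),
      eigenvalues = lam, rightVectors = unname(right),
      leftVectors = unname(left), activeSet = C@activeSet,
      reversible = reversible)
}

#' Build a MarkovModel directly from a transition matrix
#'
#' Computes the stationary distribution, checks detailed balance (the model
#' is marked reversible when `pi_i T_ij = pi_j T_ji` holds within
#' tolerance), and attaches the eigendecomposition. Intended for models
#' whose transition matrix is given rather than estimated from counts.
#'
#' @param T row-stochastic matrix (rows sum to 1 within 1e-9).
#' @param lag lag in frames.
#' @param frameInterval time units per frame.
#' @param tol detailed-balance tolerance.
#' @return a [MarkovModel-class].
#' @export
markovModelFromT <- function(T, lag = 1L, frameInterval = 1, tol = 1e-10) {
  T <- as.matrix(T)
  if (max(abs(rowSums(T) - 1)) > 1e-9) stop("rows must sum to 1")
  T <- T / rowSums(T)
  k <- nrow(T)
  eg <- eigen(t(T))
  pivec <- Re(eg$vectors[, which.max(Re(eg$values))])
  pi <- pivec / sum(pivec)
  for (it in 1:100) pi <- drop(pi %*% T) / sum(pi %*% T)
  reversible <- max(abs(pi * T - t(pi * T))) < tol * max(pi * T)
  ## encode as a count matrix with stationary weighting and re-estimate so
  ## all downstream conventions (eigenvector normalization etc.) match
  C <- new("CountMatrix", counts = pi * T, lag = as.integer(lag),
           activeSet = seq_len(k), trimmed = TRUE)
  m <- estimateMarkovModel(C, frameInterval = frameInterval,
                           reversible = reversible)
  m@T <- unname(T / rowSums(T))
  m@pi <- unname(pi)
  m
}

setMethod("nStates", "MarkovModel", function(object) nrow(object@T))
setMethod("transitionMatrix", "MarkovModel", function(object) object@T)
setMethod("stationaryDist", "MarkovModel", function(object) object@pi)
setMethod("activeSet", "MarkovModel", function(object) object@activeSet)
setMethod("modelEigenvalues", "MarkovModel", function(object) object@eigenvalues)
setMethod("frameInterval", "MarkovModel", function(object) object@frameInterval)

#' @describeIn impliedTimescales implied timescales of a Markov model:
#'   `t_k = -tau / log(lambda_k)` for k >= 2, in time units; nonpositive
#'   eigenvalues yield NA.
#' @export
setMethod("impliedTimescales", "MarkovModel", function(object) {
  lam <- object@eigenvalues[-1L]
  tau <- object@lag * object@frameInterval
  ts <- rep(NA_real_, length(lam))
  ok <- lam > 0 & lam < 1
  ts[ok] <- -tau / log(lam[ok])
  ts
})

setMethod("show", "MarkovModel", function(object) {
  cat("MarkovModel:", nrow(object@T), "states, lag", object@lag,
      "frames (tau =", object@lag * object@frameInterval, "time units),",
      if (object@reversible) "reversible" else "non-reversible", "\n")
  its <- impliedTimescales(object)
  cat("  implied timescales:",
      paste(signif(head(its, 4L), 4), collapse = ", "), "\n")
})

#' Implied timescales across lag times
#'
#' Estimates an MSM at each lag (trimming applied per lag) and tabulates the
#' top implied timescales, the standard diagnostic for choosing the MSM lag
#' ("timescales level off"). Lags at which estimation fails are skipped with
#' a warning; lags leaving fewer than 10 total transition counts are flagged
#' in the `lowCounts` column.
#'
#' @param dtrajs list of integer state trajectories.
#' @param lags integer vector of lags in frames.
#' @param nTimescales number of timescales to report.
#' @param frameInterval time units per frame.
#' @param reversible estimator flag.
#' @return data.frame with columns `lag`, `tau`, `ts1..tsn`, `lowCounts`.
#' @export
impliedTimescalesScan <- function(dtrajs, lags, nTimescales = 3L,
                                  frameInterval = 1, reversible = TRUE) {
  rows <- lapply(lags, function(L) {
    res <- tryCatch({
      C <- trimToConnected(countTransitions(dtrajs, L))
      m <- estimateMarkovModel(C, frameInterval = frameInterval,
                               reversible = reversible)
      its <- impliedTimescales(m)
      low <- sum(C@counts) < 10
      c(its[seq_len(nTimescales)], low)
    }, error = function(e) {
      warning("lag ", L, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) return(NULL)
    data.frame(lag = L, tau = L * frameInterval,
               t(setNames(res[seq_len(nTimescales)],
                          paste0("ts", seq_len(nTimescales)))),
               lowCounts = as.logical(res[nTimescales + 1L]))
  })
  do.call(rbind, rows)
}
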