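## Coarse-graining and transition-path theory: eigenvalue-gap state-count
## selection, spectral lumping, committors, reactive flux, bottleneck
## pathway decomposition to a flux-coverage target, and linear-solve MFPTs.

#' Choose the macrostate count from the eigenvalue gap
#'
#' Returns the k (2 <= k <= maxK, counting lambda1 = 1) that maximizes the
#' spectral gap ratio lambda_k / lambda_(k+1). When lambda_(k+1) <= 0 the
#' ratio is treated as infinite (all slower processes are resolved). A
#' spectrum without a pronounced gap still returns the argmax, flagged
#' `lowConfidence` in the attributes.
#'
#' @param model a [MarkovModel-class] (reversible: real spectrum).
#' @param maxK largest state count considered.
#' @return integer k with attributes `ratios` and `lowConfidence`.
#' @export
macrostateCountByGap <- function(model, maxK = 6L) {
  lam <- model@eigenvalues
  if (length(lam) < 3L) stop("need at least 3 eigenvalues for a gap decision")
  maxK <- min(maxK, length(lam) - 1L)
  ks <- 2:maxK
  ratios <- vapply(ks, function(k) {
    if (lam[k + 1L] <= 0) Inf else lam[k] / lam[k + 1L]
  }, numeric(1L))
  k <- ks[which.max(ratios)]
  out <- k
  attr(out, "ratios") <- setNames(ratios, ks)
  ## confidence flag: the chosen gap is trustworthy when the retained and
  ## discarded processes are separated in timescale (t_k / t_(k+1) >= 2);
  ## smooth (e.g. geometric) spectra fail this separation
  tsRatio <- if (lam[k + 1L] <= 0) Inf
             else if (lam[k] >= 1) Inf
             else log(lam[k + 1L]) / log(lam[k])
  attr(out, "lowConfidence") <- !(tsRatio >= 2)
  out
}

#' Spectral lumping of microstates into macrostates
#'
#' Embeds the microstates by the top right eigenvectors (pi-orthonormal,
#' skipping the constant one) and clusters the embedding with k-means
#' (fixed seed, 10 restarts). Macrostate populations are the summed
#' stationary probabilities of their members.
#'
#' @param model a reversible [MarkovModel-class].
#' @param nMacro number of macrostates (>= 2).
#' @param seed k-means seed.
#' @return a [MacroModel-class].
#' @export
spectralLump <- function(model, nMacro, seed = 1L) {
  stopifnot(nMacro >= 2L)
  if (!model@reversible)
    stop("spectral lumping requires a reversible model (real spectrum)")
  if (nMacro > nStates(model)) stop("more macrostates than microstates")
  emb <- model@rightVectors[, 2:nMacro, drop = FALSE]
  assignment <- NULL
  for (attempt in 0:1) {
    set.seed(seed + attempt)
    km <- tryCatch(kmeans(emb, centers = nMacro, nstart = 10L,
                          iter.max = 100L),
                   error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == nMacro) {
      assignment <- km$cluster
      break
    }
  }
  if (is.null(assignment))
    stop("k-means produced an empty macrostate twice; lumping rejected")
  pops <- vapply(seq_len(nMacro), function(m) sum(model@pi[assignment == m]),
                 numeric(1L))
  ## deterministic labelling: macrostates ordered by decreasing population
  ord <- order(pops, decreasing = TRUE)
  relabel <- integer(nMacro); relabel[ord] <- seq_len(nMacro)
  assignment <- relabel[assignment]
  pops <- pops[ord]
  gaps <- attr(macrostateCountByGap(model,
                                    maxK = min(6L, nStates(model) - 1L)),
               "ratios")
  new("MacroModel", nMacro = as.integer(nMacro),
      assignment = as.integer(assignment), populations = pops,
      eigenvalues = model@eigenvalues,
      gapRatios = gaps)
}

setMethod("nStates", "MacroModel", function(object) object@nMacro)
setMethod("macroAssignment", "MacroModel", function(object) object@assignment)
setMethod("populations", "MacroModel", function(object) object@populations)
setMethod("show", "MacroModel", function(object) {
  cat("MacroModel:", object@nMacro, "macrostates; populations",
      paste(signif(object@populations, 4), collapse = ", "), "\n")
})

#' Pi-weighted coarse-grained transition matrix
#'
#' `T_macro[I, J] = sum_{i in I} pi_i sum_{j in J} T_ij / sum_{i in I} pi_i`.
#' Useful as a diagnostic: on well-separated block chains it reproduces the
#' slow eigenvalues of the microstate model.
#'
#' @param model a [MarkovModel-class].
#' @param macro a [MacroModel-class] on the same states.
#' @return nMacro x nMacro row-stochastic matrix.
#' @export
coarseGrainTransitions <- function(model, macro) {
  a <- macro@assignment
  n <- macro@nMacro
  Tm <- matrix(0, n, n)
  for (I in seq_len(n)) {
    wi <- model@pi[a == I]
    Ti <- model@T[a == I, , drop = FALSE]
    row <- drop(wi %*% Ti) / sum(wi)
    for (J in seq_len(n)) Tm[I, J] <- sum(row[a == J])
  }
  Tm / rowSums(Tm)
}

#' Forward committor by linear solve
#'
#' Solves `(I - T) q = 0` on the intermediate states with boundary
#' conditions q = 0 on A and q = 1 on B.
#'
#' @param model a [MarkovModel-class].
#' @param A,B disjoint nonempty state index sets (model indexing).
#' @return committor vector over all model states.
#' @export
committor <- function(model, A, B) {
  A <- as.integer(A); B <- as.integer(B)
  k <- nStates(model)
  if (!length(A) || !length(B)) stop("A and B must be nonempty")
  if (length(intersect(A, B))) stop("A and B must be disjoint")
  if (any(c(A, B) < 1L | c(A, B) > k)) stop("state index out of range")
  q <- numeric(k)
  q[B] <- 1
  I <- setdiff(seq_len(k), c(A, B))
  if (length(I)) {
    TI <- model@T[I, I, drop = FALSE]
    rhs <- rowSums(model@T[I, B, drop = FALSE])
    M <- diag(length(I)) - TI
    sol <- tryCatch(solve(M, rhs), error = function(e)
      stop("singular committor system (disconnected intermediates?): ",
           conditionMessage(e)))
    q[I] <- sol
  }
  pmin(pmax(q, 0), 1)
}

#' Transition-path-theory reactive flux
#'
#' Gross flux `f_ij = pi_i q-_i T_ij q+_j` (diagonal zero), net flux
#' `f+_ij = max(0, f_ij - f_ji)`, total flux F = net flux out of A. For a
#' reversible model the backward committor is `1 - q+`. Flux units:
#' probability per lag time tau.
#'
#' @param model a reversible [MarkovModel-class].
#' @param A,B source and sink state sets.
#' @return a [FluxNetwork-class].
#' @export
reactiveFlux <- function(model, A, B) {
  if (!model@reversible)
    stop("reactive flux requires a reversible model (q- = 1 - q+)")
  A <- as.integer(A); B <- as.integer(B)
  qp <- committor(model, A, B)
  qm <- 1 - qp
  f <- (model@pi * qm) * model@T * rep(qp, each = nStates(model))
  diag(f) <- 0
  fnet <- pmax(f - t(f), 0)
  Fout <- sum(fnet[A, setdiff(seq_len(nStates(model)), A), drop = FALSE])
  new("FluxNetwork", A = A, B = B, qplus = qp, qminus = qm,
      grossFlux = f, netFlux = fnet, totalFlux = Fout, pi = model@pi)
}

setMethod("totalFlux", "FluxNetwork", function(object) object@totalFlux)
setMethod("forwardCommittor", "FluxNetwork", function(object) object@qplus)
setMethod("netFlux", "FluxNetwork", function(object) object@netFlux)
setMethod("show", "FluxNetwork", function(object) {
  cat("FluxNetwork: |A| =", length(object@A), ", |B| =", length(object@B),
      ", total reactive flux F =", signif(object@totalFlux, 6),
      "per lag time\n")
})

#' Aggregate a microstate flux network to macrostates
#'
#' Sums the gross flux over macrostate pairs and recomputes net fluxes at
#' the macro level; the committor becomes the pi-weighted mean over
#' members. A and B must be unions of macrostates for exact conservation
#' (they are, when A and B were chosen as macrostate member sets).
#'
#' @param flux a [FluxNetwork-class] at the microstate level.
#' @param macro a [MacroModel-class] on the same states.
#' @return a [FluxNetwork-class] whose states are macrostates.
#' @export
aggregateFlux <- function(flux, macro) {
  a <- macro@assignment
  n <- macro@nMacro
  G <- matrix(0, n, n)
  for (I in seq_len(n)) for (J in seq_len(n)) if (I != J)
    G[I, J] <- sum(flux@grossFlux[a == I, a == J, drop = FALSE])
  fnet <- pmax(G - t(G), 0)
  Amac <- sort(unique(a[flux@A]))
  Bmac <- sort(unique(a[flux@B]))
  qmac <- vapply(seq_len(n), function(I) {
    w <- flux@pi[a == I]
    sum(w * flux@qplus[a == I]) / sum(w)
  }, numeric(1L))
  qmac[Amac] <- 0; qmac[Bmac] <- 1
  pimac <- vapply(seq_len(n), function(I) sum(flux@pi[a == I]), numeric(1L))
  Fout <- sum(fnet[Amac, setdiff(seq_len(n), Amac), drop = FALSE])
  new("FluxNetwork", A = Amac, B = Bmac, qplus = qmac, qminus = 1 - qmac,
      grossFlux = G, netFlux = fnet, totalFlux = Fout, pi = pimac)
}

#' Decompose a flux network into bottleneck pathways
#'
#' Repeatedly extracts the widest (maximum bottleneck) source-to-sink path
#' on the current net-flux graph, records it with its bottleneck flux,
#' subtracts that flux along the path, and stops once the recorded flux
#' covers the requested fraction of F (the published decomposition used
#' 95%). The net-flux graph of a reversible chain is acyclic in committor
#' order, which the widest-path pass exploits.
#'
#' @param flux a [FluxNetwork-class].
#' @param coverage target fraction of the total flux (default 0.95).
#' @return a [PathwayDecomposition-class].
#' @export
decomposePathways <- function(flux, coverage = 0.95) {
  Ftot <- flux@totalFlux
  if (Ftot <= 0) stop("total reactive flux must be positive")
  net <- flux@netFlux
  k <- nrow(net)
  A <- flux@A; B <- flux@B
  ord <- order(flux@qplus, seq_len(k))   # committor order, index tie-break
  paths <- list(); fl <- numeric(0)
  got <- 0
  maxIter <- 10L * k + 10L
  for (iter in seq_len(maxIter)) {
    if (got >= coverage * Ftot - 1e-15) break
    width <- rep(-Inf, k); width[A] <- Inf
    pred <- rep(NA_integer_, k)
    for (i in ord) {
      if (width[i] <= 0) next
      out <- which(net[i, ] > 1e-15)
      for (j in out) {
        w <- min(width[i], net[i, j])
        if (w > width[j]) { width[j] <- w; pred[j] <- i }
      }
    }
    bIdx <- B[which.max(width[B])]
    if (!is.finite(width[bIdx]) || width[bIdx] <= 1e-15) break
    path <- bIdx
    while (!path[1L] %in% A) path <- c(pred[path[1L]], path)
    b <- width[bIdx]
    for (e in seq_len(length(path) - 1L))
      net[path[e], path[e + 1L]] <- net[path[e], path[e + 1L]] - b
    paths[[length(paths) + 1L]] <- path
    fl <- c(fl, b)
    got <- got + b
  }
  new("PathwayDecomposition", pathways = paths, fluxes = fl,
      coverage = got / Ftot, totalFlux = Ftot)
}

setMethod("show", "PathwayDecomposition", function(object) {
  cat("PathwayDecomposition:", length(object@pathways),
      "pathways covering", signif(100 * object@coverage, 4),
      "% of F =", signif(object@totalFlux, 6), "\n")
  for (i in seq_along(object@pathways))
    cat(sprintf("  [%d] %s  flux %.4g (%.1f%%)\n", i,
                paste(object@pathways[[i]], collapse = " -> "),
                object@fluxes[i],
                100 * object@fluxes[i] / object@totalFlux))
})

#' Mean first-passage time by linear solve
#'
#' Solves `m_i = tau + sum_{j not in target} T_ij m_j` with m = 0 on the
#' target; the reported value is the pi-weighted average of m over the
#' source states (restricted and renormalized).
#'
#' @param model a [MarkovModel-class].
#' @param source,target state index sets (model indexing).
#' @return MFPT in time units.
#' @export
mfptLinear <- function(model, source, target) {
  source <- as.integer(source); target <- as.integer(target)
  k <- nStates(model)
  if (!length(target)) stop("target must be nonempty")
  if (any(c(source, target) < 1L | c(source, target) > k))
    stop("state index out of range")
  if (all(source %in% target)) return(0)
  tau <- model@lag * model@frameInterval
  rest <- setdiff(seq_len(k), target)
  Tr <- model@T[rest, rest, drop = FALSE]
  m <- tryCatch(solve(diag(length(rest)) - Tr, rep(tau, length(rest))),
                error = function(e)
                  stop("target unreachable from some states: ",
                       conditionMessage(e)))
  mfull <- numeric(k)
  mfull[rest] <- m
  w <- model@pi[source]
  sum(w * mfull[source]) / sum(w)
}
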