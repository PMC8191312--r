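## MCMC-based observable estimation from an MSM (the published protocol:
## ten chains of 1e5 steps, first 20% discarded), MCMC and first-passage
## statistics, and block bootstrapping of trajectory series.

#' Estimate equilibrium observables by MCMC sampling of an MSM
#'
#' Samples `nChains` Markov chains from the model's transition matrix
#' (starts drawn from the stationary distribution), discards the burn-in
#' fraction, and averages the per-state observable values along each chain.
#' Reports the across-chain mean and SD, and optionally a 95% percentile
#' band over bootstrap resamples of the chains.
#'
#' @param model a [MarkovModel-class].
#' @param perStateValues observable definition on the model's states: a
#'   numeric vector (one observable), a states x p matrix (p observables),
#'   or an integer/factor macrostate assignment (expanded to membership
#'   indicators, yielding macrostate populations).
#' @param nChains number of chains (>= 2; default 10).
#' @param nSteps steps per chain (default 1e5).
#' @param burnInFraction initial fraction discarded (default 0.2).
#' @param seed integer seed.
#' @param bootstrap if TRUE also report a percentile band over
#'   `nResamples` bootstrap resamples of the chain means.
#' @param nResamples bootstrap resamples (default 1000).
#' @param conf band level (default 0.95).
#' @return list with `mean`, `sd`, `perChain` (chains x observables), and
#'   optionally `lower`, `upper`.
#' @export
sampleObservableMCMC <- function(model, perStateValues, nChains = 10L,
                                 nSteps = 100000L, burnInFraction = 0.2,
                                 seed = 1L, bootstrap = FALSE,
                                 nResamples = 1000L, conf = 0.95) {
  if (nChains < 2L) stop("at least 2 chains are required for an SD")
  vals <- .per_state_matrix(perStateValues, nStates(model))
  set.seed(seed)
  drop0 <- floor(nSteps * burnInFraction)
  perChain <- matrix(NA_real_, nChains, ncol(vals),
                     dimnames = list(NULL, colnames(vals)))
  for (ch in seq_len(nChains)) {
    start <- sample.int(nStates(model), 1L, prob = model@pi)
    chain <- sampleMarkovChain(model@T, nSteps, start = start)
    kept <- chain[(drop0 + 1L):nSteps]
    occ <- tabulate(kept, nbins = nStates(model))
    perChain[ch, ] <- drop(occ %*% vals) / length(kept)
  }
  out <- list(mean = colMeans(perChain), sd = apply(perChain, 2L, sd),
              perChain = perChain)
  if (bootstrap) {
    bs <- matrix(NA_real_, nResamples, ncol(vals))
    for (b in seq_len(nResamples))
      bs[b, ] <- colMeans(perChain[sample.int(nChains, nChains,
                                              replace = TRUE), , drop = FALSE])
    a <- (1 - conf) / 2
    out$lower <- apply(bs, 2L, quantile, probs = a, names = FALSE)
    out$upper <- apply(bs, 2L, quantile, probs = 1 - a, names = FALSE)
  }
  out
}

.per_state_matrix <- function(perStateValues, k) {
  if (is.factor(perStateValues))
    perStateValues <- as.integer(perStateValues)
  if (is.matrix(perStateValues)) {
    stopifnot(nrow(perStateValues) == k)
    return(perStateValues)
  }
  stopifnot(length(perStateValues) == k)
  if (all(perStateValues == round(perStateValues)) &&
      length(unique(perStateValues)) <= max(2L, k %/% 2L) &&
      min(perStateValues) >= 1) {
    ## integer macrostate assignment -> membership indicators
    macros <- sort(unique(perStateValues))
    ind <- vapply(macros, function(m) as.numeric(perStateValues == m),
                  numeric(k))
    colnames(ind) <- paste0("macro", macros)
    return(ind)
  }
  matrix(perStateValues, ncol = 1L, dimnames = list(NULL, "observable"))
}

#' Mean first-passage time by MCMC sampling
#'
#' Samples chains from the model and averages the recorded source-to-target
#' first-passage segments: each entry into the source set arms a passage
#' that completes at the next visit to the target set. Converted to time
#' units via tau = lag * frameInterval. The linear-solve counterpart is
#' [mfptLinear()].
#'
#' @param model a [MarkovModel-class].
#' @param source,target disjoint nonempty state index sets (model indexing).
#' @param nChains,nSteps,seed sampling parameters (defaults 10 chains of
#'   1e5 steps).
#' @return list with `mfpt` (time units), `nPassages`, `perChain`.
#' @export
mcmcMFPT <- function(model, source, target, nChains = 10L, nSteps = 100000L,
                     seed = 1L) {
  source <- as.integer(source); target <- as.integer(target)
  if (!length(source) || !length(target)) stop("empty source or target set")
  if (length(intersect(source, target)))
    return(list(mfpt = 0, nPassages = 0L, perChain = rep(0, nChains)))
  k <- nStates(model)
  if (any(c(source, target) < 1L | c(source, target) > k))
    stop("state indices outside the active set")
  set.seed(seed)
  tau <- model@lag * model@frameInterval
  tot <- 0; n <- 0L
  perChain <- rep(NA_real_, nChains)
  inS <- logical(k); inS[source] <- TRUE
  inT <- logical(k); inT[target] <- TRUE
  for (ch in seq_len(nChains)) {
    start <- sample.int(k, 1L, prob = model@pi)
    chain <- sampleMarkovChain(model@T, nSteps, start = start)
    s <- inS[chain]; tt <- inT[chain]
    entries <- which(s & !c(FALSE, s[-length(s)]))   # arrivals into source
    hits <- which(tt)
    if (!length(entries) || !length(hits)) next
    nxt <- findInterval(entries, hits) + 1L          # first hit after entry
    ok <- nxt <= length(hits)
    lens <- hits[nxt[ok]] - entries[ok]
    if (length(lens)) {
      perChain[ch] <- mean(lens) * tau
      tot <- tot + sum(lens); n <- n + length(lens)
    }
  }
  if (n == 0L)
    stop("no completed source->target passages in any chain; ",
         "increase nSteps or check connectivity")
  list(mfpt = tot / n * tau, nPassages = n, perChain = perChain)
}

#' Block bootstrap of trajectory series
#'
#' Splits each series into contiguous blocks of `blockLength` samples (the
#' final partial block is kept), pools the blocks, resamples them with
#' replacement up to the original total length, and applies the statistic.
#' Percentile intervals from block resampling respect the temporal
#' correlation inside blocks (the published analyses used 4 ns blocks, 1000
#' resamples).
#'
#' @param series numeric vector or list of numeric vectors.
#' @param blockLength block length in samples (<= each series length).
#' @param nResamples number of resamples (default 1000).
#' @param statistic function applied to each resampled concatenation
#'   (default mean).
#' @param seed integer seed.
#' @param conf interval level (default 0.95).
#' @return list with `observed`, `mean`, `lower`, `upper`, `resamples`.
#' @export
blockBootstrap <- function(series, blockLength, nResamples = 1000L,
                           statistic = mean, seed = 1L, conf = 0.95) {
  if (!is.list(series)) series <- list(series)
  lens <- vapply(series, length, 1L)
  if (blockLength > min(lens))
    stop("blockLength exceeds the shortest series length")
  blocks <- list()
  for (s in series) {
    startsAt <- seq(1L, length(s), by = blockLength)
    blocks <- c(blocks, lapply(startsAt, function(i)
      s[i:min(i + blockLength - 1L, length(s))]))
  }
  totalLen <- sum(lens)
  blockLens <- lengths(blocks)
  set.seed(seed)
  stats <- numeric(nResamples)
  for (b in seq_len(nResamples)) {
    idx <- integer(0); got <- 0L
    while (got < totalLen) {
      need <- ceiling((totalLen - got) / blockLength) + 1L
      more <- sample.int(length(blocks), need, replace = TRUE)
      idx <- c(idx, more)
      got <- got + sum(blockLens[more])
    }
    resample <- unlist(blocks[idx], use.names = FALSE)[seq_len(totalLen)]
    val <- tryCatch(statistic(resample), error = function(e)
      stop("statistic failed on resample ", b, ": ", conditionMessage(e)))
    stats[b] <- val
  }
  a <- (1 - conf) / 2
  list(observed = statistic(unlist(series, use.names = FALSE)),
       mean = mean(stats),
       lower = quantile(stats, a, names = FALSE),
       upper = quantile(stats, 1 - a, names = FALSE),
       resamples = stats)
}
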