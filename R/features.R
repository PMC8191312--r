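## Feature engineering: atom-pair distance trajectories and loading-based
## feature pruning, mirroring the atom-pair distance feature sets used for
## translocation MSMs (the published set kept the 1000/600/400 features with
## the largest tIC1/tIC2/tIC3 loading magnitudes, union 1481 pairs).

#' Compute atom-pair distance features from a coordinate trajectory
#'
#' @param coords frames x atoms x 3 numeric array, or a list of per-frame
#'   atom x 3 matrices. `dimnames` on the atom axis (or rownames of the
#'   matrices) name the atoms; otherwise atoms are addressed by index.
#' @param pairs two-column matrix/data.frame of atom identifiers (names or
#'   1-based indices); no self-pairs, no duplicate unordered pairs.
#' @param frameInterval time units per frame.
#' @return a [FeatureTrajectory-class] with one distance column per pair,
#'   labelled `"a-b"`.
#' @export
computePairDistances <- function(coords, pairs, frameInterval = 1) {
  if (is.list(coords)) {
    atomNames <- rownames(coords[[1L]])
    nAtoms <- nrow(coords[[1L]])
    getFrame <- function(t) coords[[t]]
    nT <- length(coords)
  } else {
    stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
    atomNames <- dimnames(coords)[[2L]]
    nAtoms <- dim(coords)[2L]
    getFrame <- function(t) matrix(coords[t, , ], ncol = 3L)
    nT <- dim(coords)[1L]
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) stop("empty pair list: degenerate feature space")
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  idx <- apply(pairs, 2L, function(col) {
    if (is.numeric(pairs)) return(as.integer(col))
    m <- match(col, atomNames)
    if (anyNA(m))
      stop("unknown atom identifier(s): ",
           paste(unique(col[is.na(m)]), collapse = ", "))
    m
  })
  idx <- matrix(as.integer(idx), ncol = 2L)
  if (any(idx < 1L | idx > nAtoms)) stop("atom index out of range")
  if (any(idx[, 1L] == idx[, 2L])) stop("self-pairs are not allowed")
  key <- paste(pmin(idx[, 1L], idx[, 2L]), pmax(idx[, 1L], idx[, 2L]))
  if (anyDuplicated(key)) stop("duplicate unordered atom pairs")
  labels <- if (is.null(atomNames)) paste(idx[, 1L], idx[, 2L], sep = "-")
            else paste(atomNames[idx[, 1L]], atomNames[idx[, 2L]], sep = "-")
  vals <- matrix(0, nT, nrow(idx))
  for (t in seq_len(nT)) {
    fr <- getFrame(t)
    d <- fr[idx[, 1L], , drop = FALSE] - fr[idx[, 2L], , drop = FALSE]
    vals[t, ] <- sqrt(rowSums(d^2))
  }
  featureTrajectory(vals, frameInterval = frameInterval,
                    featureLabels = labels)
}

#' Prune a feature set by tICA loading magnitude
#'
#' Keeps the union of the `counts[1]` features with the largest absolute
#' loading on tIC1, `counts[2]` on tIC2 and `counts[3]` on tIC3 (the
#' published protocol used 1000/600/400). Ties at the selection rank are all
#' retained, making the result deterministic and order-independent; counts
#' larger than the feature dimension are clamped with a warning.
#'
#' @param model a [TICAModel-class] with at least 3 components.
#' @param counts integer vector `(n1, n2, n3)` of features to keep per
#'   component.
#' @return character vector of retained feature labels (sorted by original
#'   feature order), with the integer indices in attribute `"indices"`.
#' @export
pruneFeaturesByLoading <- function(model, counts = c(1000L, 600L, 400L)) {
  V <- model@components
  if (ncol(V) < 3L) stop("model must have at least 3 tICA components")
  if (any(counts <= 0L)) stop("counts must be positive")
  d <- nrow(V)
  if (any(counts > d)) {
    warning("counts exceed the feature dimension (", d, "); clamped")
    counts <- pmin(counts, d)
  }
  keep <- logical(d)
  for (cpt in 1:3) {
    load <- abs(V[, cpt])
    thr <- sort(load, decreasing = TRUE)[counts[cpt]]
    keep <- keep | (load >= thr)   # >= keeps all rank ties
  }
  idx <- which(keep)
  out <- model@featureLabels[idx]
  attr(out, "indices") <- idx
  out
}

#' Subset feature trajectories to a pruned feature set
#'
#' @param trajs list of [FeatureTrajectory-class] objects (or one).
#' @param features labels (or the result of [pruneFeaturesByLoading()]).
#' @return trajectories restricted to the requested features, in the given
#'   order.
#' @export
selectFeatures <- function(trajs, features) {
  one <- methods::is(trajs, "FeatureTrajectory")
  if (one) trajs <- list(trajs)
  out <- lapply(trajs, function(tr) {
    m <- match(as.character(features), tr@featureLabels)
    if (anyNA(m))
      stop("missing feature labels: ",
           paste(features[is.na(m)], collapse = ", "))
    featureTrajectory(tr@values[, m, drop = FALSE],
                      frameInterval = tr@frameInterval,
                      featureLabels = as.character(features))
  })
  if (one) out[[1L]] else out
}

#' Projection connectivity diagnostic
#'
#' Fraction of frames in a low-dimensional projection that have at least one
#' other frame within `threshold` (Euclidean). Feature sets whose projection
#' fragments into disconnected islands score low; this surfaces, as a
#' diagnostic rather than an automatic pruner, the judgment call of whether
#' a tICA projection is "connected".
#'
#' @param projected numeric matrix of projected frames (e.g., tIC1/tIC2).
#' @param threshold neighbour distance.
#' @param maxFrames subsample cap for the quadratic scan.
#' @param seed subsample seed.
#' @return fraction in `[0, 1]`.
#' @export
projectionConnectivity <- function(projected, threshold, maxFrames = 2000L,
                                   seed = 1L) {
  x <- as.matrix(projected)
  if (nrow(x) > maxFrames) {
    set.seed(seed)
    x <- x[sample.int(nrow(x), maxFrames), , drop = FALSE]
  }
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  mean(apply(d2, 1L, min) <= threshold^2)
}
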