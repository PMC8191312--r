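## K-centers clustering: greedy farthest-point traversal with the classic
## 2-approximation guarantee on the covering radius, plus nearest-center
## assignment of new data to an existing center set.

#' K-centers clustering by greedy farthest-point traversal
#'
#' The first center is the caller-supplied seed frame; every subsequent
#' center is the point farthest from its nearest existing center, ties
#' broken by lowest frame index. Deterministic given `(points, k,
#' seedIndex)`.
#'
#' @param points frames x m numeric matrix (tIC coordinates).
#' @param k number of centers (`k <= nrow(points)`).
#' @param seedIndex row index of the first center (default 1).
#' @return a [MicrostateModel-class].
#' @export
kCenters <- function(points, k, seedIndex = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("k (", k, ") exceeds the number of points (", n, ")")
  if (any(!is.finite(points))) stop("points must be finite")
  stopifnot(seedIndex >= 1L, seedIndex <= n)
  centerIdx <- integer(k)
  centerIdx[1L] <- as.integer(seedIndex)
  nd <- rowSums(sweep(points, 2L, points[seedIndex, ])^2)
  if (k > 1L) for (j in 2:k) {
    centerIdx[j] <- which.max(nd)       # which.max takes the lowest index on ties
    d <- rowSums(sweep(points, 2L, points[centerIdx[j], ])^2)
    nd <- pmin(nd, d)
  }
  new("MicrostateModel", centers = points[centerIdx, , drop = FALSE],
      centerIndices = centerIdx, k = as.integer(k),
      seedIndex = as.integer(seedIndex), maxRadius = sqrt(max(nd)))
}

#' Assign frames to the nearest microstate center
#'
#' Ties go to the lowest center index; assigning the training set reproduces
#' the clustering's own labels.
#'
#' @param model a [MicrostateModel-class].
#' @param points frames x m matrix in the same coordinates as the centers.
#' @return integer vector of 1-based center labels.
#' @export
assignMicrostates <- function(model, points) {
  points <- as.matrix(points)
  if (ncol(points) != ncol(model@centers))
    stop("dimension mismatch: points have ", ncol(points),
         " coordinates, centers have ", ncol(model@centers))
  best <- rep(1L, nrow(points))
  bestd <- rowSums(sweep(points, 2L, model@centers[1L, ])^2)
  for (j in seq_len(model@k)[-1L]) {
    d <- rowSums(sweep(points, 2L, model@centers[j, ])^2)
    hit <- d < bestd                    # strict: ties keep the earlier center
    best[hit] <- j
    bestd[hit] <- d[hit]
  }
  best
}

setMethod("nStates", "MicrostateModel", function(object) object@k)
setMethod("show", "MicrostateModel", function(object) {
  cat("MicrostateModel:", object@k, "centers in", ncol(object@centers),
      "dimensions; covering radius", signif(object@maxRadius, 4), "\n")
})
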