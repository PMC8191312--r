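## Time-lagged independent component analysis with the symmetrized
## (reversible) covariance estimators: C0 and Ctau average the statistics of
## frames t and t+lag, so the generalized eigenvalues are real and bounded by
## 1 for data from a reversible process.

#' Fit a tICA model
#'
#' Estimates the mean, the instantaneous covariance C0 and the symmetrized
#' time-lagged covariance Ctau from all trajectory frames usable at the
#' given lag, then solves the generalized eigenproblem
#' `Ctau v = lambda (C0 + eps I) v`. Eigenpairs are sorted by descending
#' eigenvalue; components are normalized to unit C0-variance and sign-fixed
#' (largest-magnitude entry positive). Multiple trajectories contribute
#' independent lagged pairs; no pairs cross trajectory boundaries.
#'
#' @param trajs list of [FeatureTrajectory-class] objects (or plain numeric
#'   matrices, taken at frame interval 1) sharing feature labels.
#' @param lag lag time, in the trajectories' time units (frames when the
#'   frame interval is 1). Rounded to a whole number of frames.
#' @param epsilon ridge regularization added to C0; default
#'   `1e-10 * trace(C0)/d`. Set 0 to require full-rank C0 (rank-deficient
#'   data are then rejected with instructions to set `epsilon > 0`).
#' @param scale if TRUE, standardize features to unit variance before
#'   covariance estimation (default: mean-centering only).
#' @return a [TICAModel-class].
#' @export
fitTICA <- function(trajs, lag, epsilon = NULL, scale = FALSE) {
  trajs <- .as_traj_list(trajs)
  dtau <- trajs[[1L]]@frameInterval
  labels <- trajs[[1L]]@featureLabels
  for (tr in trajs)
    if (!identical(tr@featureLabels, labels))
      stop("trajectories must share feature labels")
  lagF <- as.integer(round(lag / dtau))
  if (lagF < 1L) stop("lag must be at least one frame interval")
  if (any(vapply(trajs, nFrames, 1L) <= lagF))
    stop("every trajectory must be longer than the lag (", lagF, " frames)")
  d <- length(labels)
  sumx <- numeric(d); n2 <- 0
  for (tr in trajs) {
    X <- tr@values
    Tn <- nrow(X)
    i0 <- seq_len(Tn - lagF)
    sumx <- sumx + colSums(X[i0, , drop = FALSE]) +
      colSums(X[i0 + lagF, , drop = FALSE])
    n2 <- n2 + 2L * length(i0)
  }
  mu <- sumx / n2
  sdev <- rep(1, d)
  if (scale) {
    ssq <- numeric(d)
    for (tr in trajs) {
      Tn <- nrow(tr@values); i0 <- seq_len(Tn - lagF)
      Xc <- sweep(tr@values, 2L, mu)
      ssq <- ssq + colSums(Xc[i0, , drop = FALSE]^2) +
        colSums(Xc[i0 + lagF, , drop = FALSE]^2)
    }
    sdev <- sqrt(ssq / n2)
    sdev[sdev == 0] <- 1
  }
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d)
  for (tr in trajs) {
    Xc <- sweep(tr@values, 2L, mu)
    if (scale) Xc <- sweep(Xc, 2L, sdev, `/`)
    Tn <- nrow(Xc)
    A <- Xc[seq_len(Tn - lagF), , drop = FALSE]
    B <- Xc[seq_len(Tn - lagF) + lagF, , drop = FALSE]
    C0 <- C0 + crossprod(A) + crossprod(B)
    Ct <- Ct + crossprod(A, B)
  }
  C0 <- C0 / n2
  Ct <- (Ct + t(Ct)) / n2
  if (is.null(epsilon)) epsilon <- 1e-10 * sum(diag(C0)) / d
  C0r <- C0 + diag(epsilon, d)
  ch <- tryCatch(chol(C0r), error = function(e) NULL)
  if (is.null(ch))
    stop("C0 is rank-deficient; set epsilon > 0 to regularize")
  Li <- backsolve(ch, diag(d))          # C0r^{-1/2} (upper-tri inverse)
  W <- t(Li) %*% Ct %*% Li
  W <- (W + t(W)) / 2
  eg <- eigen(W, symmetric = TRUE)
  V <- Li %*% eg$vectors                # generalized eigenvectors, v' C0r v = 1
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  lam <- eg$values
  if (any(lam > 1 + 1e-6))
    warning("tICA eigenvalues exceed 1 beyond tolerance; data may violate ",
            "stationarity")
  lam <- pmin(lam, 1 + 1e-6)
  if (scale) V <- V / sdev              # fold scaling into the loadings
  new("TICAModel", mean = mu, C0 = C0, Ctau = Ct, lag = lagF,
      frameInterval = dtau, eigenvalues = lam, components = V,
      epsilon = epsilon, featureLabels = labels)
}

#' Project trajectories onto tICA components
#'
#' Computes `(x_t - mean) %*% components[, 1:nComponents]`.
#'
#' @param model a [TICAModel-class].
#' @param traj a [FeatureTrajectory-class], a plain matrix, or a list of
#'   either.
#' @param nComponents number of leading tICs to keep.
#' @return projected matrix (or list of matrices), one row per frame.
#' @export
projectTICA <- function(model, traj, nComponents = 2L) {
  if (is.list(traj) && !is.matrix(traj))
    return(lapply(traj, projectTICA, model = model,
                  nComponents = nComponents))
  X <- if (methods::is(traj, "FeatureTrajectory")) {
    if (!identical(traj@featureLabels, model@featureLabels)) {
      missing <- setdiff(model@featureLabels, traj@featureLabels)
      if (length(missing))
        stop("trajectory lacks model features: ",
             paste(head(missing, 5L), collapse = ", "))
      traj@values[, match(model@featureLabels, traj@featureLabels),
                  drop = FALSE]
    } else traj@values
  } else as.matrix(traj)
  if (ncol(X) != length(model@mean))
    stop("feature dimension mismatch: ", ncol(X), " vs ", length(model@mean))
  nComponents <- min(nComponents, ncol(model@components))
  sweep(X, 2L, model@mean) %*% model@components[, seq_len(nComponents),
                                                drop = FALSE]
}

.as_traj_list <- function(trajs) {
  if (methods::is(trajs, "FeatureTrajectory")) return(list(trajs))
  if (is.matrix(trajs)) return(list(featureTrajectory(trajs)))
  lapply(trajs, function(tr)
    if (methods::is(tr, "FeatureTrajectory")) tr else featureTrajectory(tr))
}

setMethod("modelEigenvalues", "TICAModel", function(object) object@eigenvalues)
setMethod("ticComponents", "TICAModel", function(object) object@components)
setMethod("featureLabels", "TICAModel", function(object) object@featureLabels)
setMethod("show", "TICAModel", function(object) {
  cat("TICAModel:", length(object@mean), "features, lag", object@lag,
      "frames\n  top eigenvalues:",
      paste(signif(head(object@eigenvalues, 4L), 4), collapse = ", "), "\n")
})

#' Serialize / restore a tICA model (JSON + delimited matrices)
#'
#' @param model a [TICAModel-class].
#' @param dir bundle directory.
#' @return `readTICAModel` returns the restored model.
#' @export
writeTICAModel <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(lag = model@lag, frame_interval = model@frameInterval,
               epsilon = model@epsilon, eigenvalues = model@eigenvalues,
               mean = model@mean, feature_labels = model@featureLabels)
  jsonlite::write_json(meta, file.path(dir, "tica.json"), digits = NA)
  for (nm in c("C0", "Ctau", "components"))
    write.table(slot(model, nm), file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname writeTICAModel
#' @export
readTICAModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "tica.json"),
                              simplifyVector = TRUE)
  mat <- function(nm) unname(as.matrix(read.delim(
    file.path(dir, paste0(nm, ".tsv")), header = FALSE)))
  new("TICAModel", mean = meta$mean, C0 = mat("C0"), Ctau = mat("Ctau"),
      lag = as.integer(meta$lag), frameInterval = meta$frame_interval,
      eigenvalues = meta$eigenvalues, components = mat("components"),
      epsilon = meta$epsilon, featureLabels = meta$feature_labels)
}
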