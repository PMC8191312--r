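## Structural observables: cylinder-fit helix kink/wobble profiling with the
## 35-degree straight/kinked classifier and hinge aggregation, the geometric
## hydrogen-bond criterion, per-microstate observable averaging, the
## kink/H-bond odds ratio, tIC shift histograms, and barrier-adjacent start
## selection for perturbation simulations.

#' Fit a cylinder to a set of points
#'
#' Nonlinear least squares minimizing `sum (dist(p_i, axis) - r)^2` over the
#' axis direction, axis offset and radius (Levenberg-Marquardt), initialized
#' from the principal axis of the point cloud. The returned axis direction
#' is unit-norm and oriented along the residue order (positive dot product
#' with last minus first point).
#'
#' @param points n x 3 coordinate matrix, n >= 6, not collinear.
#' @return list with `axis` (unit 3-vector), `point` (a point on the axis),
#'   `radius`, and `residual` (RMS of distance deviations).
#' @export
fitCylinder <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 6L) stop("at least 6 points are required")
  ctr <- colMeans(points)
  pc <- prcomp(points, center = TRUE)
  if (pc$sdev[2L] < 1e-9) stop("degenerate (collinear) points")
  u0 <- pc$rotation[, 1L]
  ## spherical angles are parameterized in a rotated frame whose x-axis is
  ## the initial guess, keeping the optimizer away from the pole singularity
  R0 <- cbind(u0, .plane_basis(u0))
  par0 <- c(pi / 2, 0, 0, 0)
  axis_of <- function(par) {
    th <- par[1L]; ph <- par[2L]
    drop(R0 %*% c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)))
  }
  dists <- function(par) {
    u <- axis_of(par)
    basis <- .plane_basis(u)
    p0 <- ctr + par[3L] * basis[, 1L] + par[4L] * basis[, 2L]
    rel <- sweep(points, 2L, p0)
    proj <- rel - outer(drop(rel %*% u), u)
    sqrt(rowSums(proj^2))
  }
  resid_fun <- function(par) { d <- dists(par); d - mean(d) }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 400L, ftol = 1e-15, ptol = 1e-15))
  par <- fit$par
  d <- dists(par)
  u <- axis_of(par)
  basis <- .plane_basis(u)
  p0 <- ctr + par[3L] * basis[, 1L] + par[4L] * basis[, 2L]
  if (sum(u * (points[n, ] - points[1L, ])) < 0) u <- -u
  list(axis = u, point = p0, radius = mean(d),
       residual = sqrt(mean((d - mean(d))^2)))
}

.plane_basis <- function(u) {
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(u, e1)
  cbind(e1, e2)
}

#' Per-residue kink and wobble angles of a helix conformation
#'
#' For every residue with a full `window`-residue cylinder window on both
#' sides, the kink angle is the angle between the axes of cylinders fit to
#' residues `[r - window + 1, r]` and `[r, r + window - 1]`; the wobble
#' azimuth is the bend direction in the plane normal to the upstream axis,
#' measured from the helix radial vector at residue r. A conformation is
#' straight when no kink angle reaches the threshold (strict inequality,
#' default 35 degrees).
#'
#' @param coords n x 3 C-alpha coordinates, `n >= 2*window - 1`.
#' @param window cylinder window in residues (default 6).
#' @param threshold straight/kinked threshold in degrees (default 35).
#' @return a [KinkProfile-class].
#' @export
kinkProfile <- function(coords, window = 6L, threshold = 35) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  w <- as.integer(window)
  if (n < 2L * w - 1L)
    stop("helix too short: need at least ", 2L * w - 1L, " residues")
  residues <- w:(n - w + 1L)
  angles <- numeric(length(residues))
  wobbles <- rep(NA_real_, length(residues))
  for (idx in seq_along(residues)) {
    r <- residues[idx]
    up <- fitCylinder(coords[(r - w + 1L):r, , drop = FALSE])
    dn <- fitCylinder(coords[r:(r + w - 1L), , drop = FALSE])
    cosang <- max(-1, min(1, sum(up$axis * dn$axis)))
    ang <- acos(cosang) * 180 / pi
    angles[idx] <- ang
    if (ang >= 1) {
      bend <- dn$axis - sum(dn$axis * up$axis) * up$axis
      bend <- bend / sqrt(sum(bend^2))
      rel <- coords[r, ] - up$point
      radial <- rel - sum(rel * up$axis) * up$axis
      radial <- radial / sqrt(sum(radial^2))
      e2 <- .cross3(up$axis, radial)
      wobbles[idx] <- (atan2(sum(bend * e2), sum(bend * radial)) * 180 / pi) %% 360
    }
  }
  maxA <- max(angles)
  new("KinkProfile", residues = as.integer(residues), angles = angles,
      wobbles = wobbles, maxAngle = maxA,
      straight = maxA < threshold, threshold = threshold,
      window = w)
}

setMethod("show", "KinkProfile", function(object) {
  cat("KinkProfile: residues", min(object@residues), "-",
      max(object@residues), "; max kink",
      signif(object@maxAngle, 4), "deg;",
      if (object@straight) "straight" else "kinked",
      sprintf("(threshold %g)", object@threshold), "\n")
})

#' Aggregate kink profiles over hinges
#'
#' Pools kink angles per named hinge into normalized histograms and reports,
#' per residue, the fraction of ensemble members whose within-hinge maximum
#' kink occurs at that residue and exceeds the threshold.
#'
#' @param profiles list of [KinkProfile-class] objects.
#' @param hingeMap named list of residue index ranges, e.g.
#'   `list(h819 = 816:820)`; ranges must lie within the profile support and
#'   not overlap.
#' @param breaks histogram breaks in degrees (default 0 to 180 by 5).
#' @return list with `histograms` (per hinge: `mids`, `density`),
#'   `kinkFrequency` (named per-residue fractions), `hingeFrequency`
#'   (fraction of members kinked within each hinge).
#' @export
aggregateHinges <- function(profiles, hingeMap,
                            breaks = seq(0, 180, by = 5)) {
  if (!length(profiles)) stop("empty profile ensemble")
  support <- profiles[[1L]]@residues
  allres <- sort(unique(unlist(hingeMap)))
  if (!all(allres %in% support))
    stop("hinge residues outside the profile support")
  if (anyDuplicated(unlist(hingeMap))) stop("hinge ranges overlap")
  thr <- profiles[[1L]]@threshold
  histograms <- list()
  kinkFreq <- setNames(numeric(length(allres)), allres)
  hingeFreq <- setNames(numeric(length(hingeMap)), names(hingeMap))
  for (h in names(hingeMap)) {
    rr <- hingeMap[[h]]
    pos <- match(rr, support)
    pooled <- unlist(lapply(profiles, function(p) p@angles[pos]))
    dens <- hist(pooled, breaks = breaks, plot = FALSE)
    histograms[[h]] <- list(mids = dens$mids, density = dens$density,
                            breaks = breaks)
    hits <- vapply(profiles, function(p) {
      a <- p@angles[pos]
      if (max(a) >= thr) rr[which.max(a)] else NA_integer_
    }, numeric(1L))
    hingeFreq[h] <- mean(!is.na(hits))
    for (r in rr)
      kinkFreq[as.character(r)] <- sum(hits == r, na.rm = TRUE) /
        length(profiles)
  }
  list(histograms = histograms, kinkFrequency = kinkFreq,
       hingeFrequency = hingeFreq)
}

#' Construct a geometric hydrogen-bond criterion
#'
#' Defaults follow the standard geometric definition: donor-acceptor
#' distance below 0.35 nm and hydrogen deviation below 30 degrees from the
#' donor-acceptor line (strict inequalities).
#'
#' @param maxDistance donor-acceptor cutoff (nm).
#' @param maxAngle hydrogen deviation cutoff (degrees).
#' @return an [HBondCriterion-class].
#' @export
hbondCriterion <- function(maxDistance = 0.35, maxAngle = 30) {
  new("HBondCriterion", maxDistance = maxDistance, maxAngle = maxAngle)
}

#' Detect a hydrogen bond from donor/hydrogen/acceptor coordinates
#'
#' TRUE iff `||D - A|| < maxDistance` and the angle between H - D and A - D
#' is `< maxAngle` (both strict).
#'
#' @param donor,hydrogen,acceptor 3-vectors (or a list as returned by
#'   [makeHBondGeometry()] passed as `donor`).
#' @param criterion an [HBondCriterion-class].
#' @return logical.
#' @export
detectHBond <- function(donor, hydrogen = NULL, acceptor = NULL,
                        criterion = hbondCriterion()) {
  if (is.list(donor) && is.null(hydrogen)) {
    hydrogen <- donor$hydrogen; acceptor <- donor$acceptor
    donor <- donor$donor
  }
  stopifnot(all(is.finite(c(donor, hydrogen, acceptor))))
  if (all(donor == acceptor)) stop("donor and acceptor coincide")
  dh <- hydrogen - donor
  if (sqrt(sum(dh^2)) < 1e-12) stop("zero-length donor-hydrogen vector")
  da <- acceptor - donor
  dist <- sqrt(sum(da^2))
  ang <- acos(max(-1, min(1, sum(dh * da) /
                            (sqrt(sum(dh^2)) * dist)))) * 180 / pi
  (dist < criterion@maxDistance) && (ang < criterion@maxAngle)
}

#' Per-microstate means of a per-frame observable
#'
#' Averages frame values over the frames assigned to each microstate; the
#' result feeds [sampleObservableMCMC()] for MSM-weighted macrostate
#' percentages. Microstates without frames are excluded and flagged in the
#' `missing` attribute.
#'
#' @param dtrajs integer vector or list of vectors (1-based states).
#' @param frameValues numeric vector or list matching `dtrajs` frame for
#'   frame.
#' @param nStates total number of states (default max observed).
#' @return named numeric vector of per-state means (NA for frameless
#'   states), with attribute `missing`.
#' @export
perStateObservable <- function(dtrajs, frameValues, nStates = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (!is.list(frameValues)) frameValues <- list(frameValues)
  stopifnot(length(dtrajs) == length(frameValues))
  s <- unlist(dtrajs, use.names = FALSE)
  v <- unlist(frameValues, use.names = FALSE)
  if (length(s) != length(v))
    stop("frame values must align 1:1 with dtraj frames")
  if (is.null(nStates)) nStates <- max(s)
  sums <- tapply(v, factor(s, levels = seq_len(nStates)), sum)
  ns <- tapply(rep(1, length(s)), factor(s, levels = seq_len(nStates)), sum)
  out <- as.numeric(sums) / as.numeric(ns)
  names(out) <- seq_len(nStates)
  missing <- which(is.na(out))
  if (length(missing))
    warning("microstates without frames excluded: ",
            paste(head(missing, 10L), collapse = ", "))
  attr(out, "missing") <- missing
  out
}

#' Kink/hydrogen-bond odds ratio
#'
#' `OR = (B_s / B_k) / (NB_s / NB_k)` comparing straight (s) versus kinked
#' (k) helix populations with (B) and without (NB) a given hydrogen bond.
#' OR > 1 means the bond coincides with straight conformations more often
#' than chance.
#'
#' @param Bs,Bk,NBs,NBk the four populations, or a single length-4 vector /
#'   2x2 matrix `rbind(c(Bs, Bk), c(NBs, NBk))` passed as `Bs`.
#' @return the odds ratio.
#' @export
oddsRatio <- function(Bs, Bk = NULL, NBs = NULL, NBk = NULL) {
  if (is.null(Bk)) {
    x <- as.numeric(Bs)
    stopifnot(length(x) == 4L)
    Bs <- x[1L]; Bk <- x[2L]; NBs <- x[3L]; NBk <- x[4L]
  }
  cells <- c(Bk = Bk, NBs = NBs, NBk = NBk)
  zero <- names(cells)[cells == 0]
  if (length(zero))
    stop("odds ratio undefined: zero cell(s) ", paste(zero, collapse = ", "))
  (Bs / Bk) / (NBs / NBk)
}

#' Normalized histogram of tIC shifts relative to the initial conformation
#'
#' For each trajectory, `delta(t) = projection(frame t) - projection(frame
#' 1)` on the chosen component; deltas are pooled across trajectories and
#' binned into a unit-area histogram (the perturbation-run diagnostic for
#' mutant simulations started at a barrier).
#'
#' @param model a [TICAModel-class].
#' @param trajs list of [FeatureTrajectory-class] objects (or matrices).
#' @param component tIC index (1-based).
#' @param breaks histogram breaks or bin count (passed to [hist()]).
#' @return list with `mids`, `density`, `breaks`, `deltas`.
#' @export
ticShiftHistogram <- function(model, trajs, component = 1L, breaks = 50L) {
  trajs <- .as_traj_list(trajs)
  empty <- vapply(trajs, function(tr) nFrames(tr) == 0L, logical(1L))
  if (any(empty)) {
    warning(sum(empty), " empty trajectories skipped")
    trajs <- trajs[!empty]
  }
  deltas <- unlist(lapply(trajs, function(tr) {
    pr <- projectTICA(model, tr, nComponents = component)[, component]
    pr - pr[1L]
  }), use.names = FALSE)
  h <- hist(deltas, breaks = breaks, plot = FALSE)
  list(mids = h$mids, density = h$density, breaks = h$breaks,
       deltas = deltas)
}

#' Select barrier-adjacent microstates between two macrostates
#'
#' From each of the two macrostates, picks the `n` member microstates with
#' the highest one-step probability mass into the other macrostate (ties by
#' higher stationary probability) — the start-structure selection logic for
#' perturbation (mutant) simulations near a barrier.
#'
#' @param model a [MarkovModel-class].
#' @param macro a [MacroModel-class].
#' @param stateA,stateB the two macrostate labels.
#' @param n microstates per side (default 5).
#' @return list with `fromA` and `fromB` (model state indices, ordered by
#'   decreasing transition-out probability).
#' @export
barrierStartSelection <- function(model, macro, stateA, stateB, n = 5L) {
  a <- macro@assignment
  pick <- function(from, to) {
    members <- which(a == from)
    if (!length(members)) stop("macrostate ", from, " is empty")
    pOut <- rowSums(model@T[members, a == to, drop = FALSE])
    ord <- order(-pOut, -model@pi[members])
    if (length(members) < n)
      warning("macrostate ", from, " has only ", length(members),
              " members; returning all")
    members[ord][seq_len(min(n, length(members)))]
  }
  list(fromA = pick(stateA, stateB), fromB = pick(stateB, stateA))
}
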