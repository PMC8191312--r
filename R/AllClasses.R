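## Central S4 classes. Validity methods enforce the structural contracts the
## downstream estimators rely on (finiteness, stochasticity, normalization).

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Landscape: a closed-form potential energy surface
#'
#' A named family of analytic potentials U(x) used by the synthetic-trajectory
#' generator and by quadrature oracles. Energies are in units of kT unless a
#' different temperature factor is supplied at simulation time.
#'
#' @slot family one of `"flat"`, `"harmonic"`, `"double-well"`,
#'   `"tilted-double-well"`, `"triple-well-2d"`.
#' @slot dimension 1 or 2.
#' @slot params named numeric vector of family parameters.
#' @slot code integer family code shared with the compiled integrator.
#' @slot cpar numeric parameter vector in the layout the integrator expects.
#' @exportClass Landscape
setClass("Landscape",
  representation(family = "character", dimension = "integer",
                 params = "numeric", code = "integer", cpar = "numeric"),
  validity = function(object) {
    if (!object@dimension %in% c(1L, 2L)) return("dimension must be 1 or 2")
    if (any(!is.finite(object@cpar))) return("non-finite landscape parameters")
    TRUE
  })

#' FeatureTrajectory: a time-ordered real-valued feature matrix
#'
#' @slot values T x d numeric matrix, one frame per row.
#' @slot frameInterval time between consecutive frames (arbitrary time units).
#' @slot featureLabels character vector of d unique feature identifiers.
#' @exportClass FeatureTrajectory
setClass("FeatureTrajectory",
  representation(values = "matrix", frameInterval = "numeric",
                 featureLabels = "character"),
  validity = function(object) {
    if (nrow(object@values) < 2L) return("a trajectory needs at least 2 frames")
    if (any(!is.finite(object@values))) return("non-finite feature values")
    if (length(object@featureLabels) != ncol(object@values))
      return("featureLabels length must equal the number of feature columns")
    if (anyDuplicated(object@featureLabels)) return("feature labels must be unique")
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
      return("frameInterval must be a single positive number")
    TRUE
  })

#' TICAModel: time-lagged independent component analysis model
#'
#' Holds the symmetrized covariance estimates, the generalized eigenpairs of
#' Ctau v = lambda (C0 + eps I) v, and the lag at which they were estimated.
#' Components are normalized to unit C0-variance and sign-fixed so the entry
#' of largest magnitude in each component is positive.
#'
#' @slot mean d-vector of feature means.
#' @slot C0 instantaneous covariance (symmetric PSD).
#' @slot Ctau symmetrized time-lagged covariance.
#' @slot lag lag in frames.
#' @slot frameInterval time units per frame.
#' @slot eigenvalues descending generalized eigenvalues.
#' @slot components d x m loading matrix (columns are tICs).
#' @slot epsilon ridge regularization added to C0.
#' @slot featureLabels feature identifiers.
#' @exportClass TICAModel
setClass("TICAModel",
  representation(mean = "numeric", C0 = "matrix", Ctau = "matrix",
                 lag = "integer", frameInterval = "numeric",
                 eigenvalues = "numeric", components = "matrix",
                 epsilon = "numeric", featureLabels = "character"),
  validity = function(object) {
    if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
      return("eigenvalues must be sorted in descending order")
    if (any(object@eigenvalues > 1 + 1e-6))
      return("tICA eigenvalues exceed 1 beyond numerical tolerance")
    if (max(abs(object@C0 - t(object@C0))) > 1e-8) return("C0 must be symmetric")
    TRUE
  })

#' MicrostateModel: k-centers clustering of projected conformations
#'
#' @slot centers k x m matrix of cluster centers (rows are input frames).
#' @slot centerIndices row indices of the chosen centers in the input matrix.
#' @slot k number of centers.
#' @slot seedIndex index of the frame used as the first center.
#' @slot maxRadius largest point-to-assigned-center distance (covering radius).
#' @exportClass MicrostateModel
setClass("MicrostateModel",
  representation(centers = "matrix", centerIndices = "integer", k = "integer",
                 seedIndex = "integer", maxRadius = "numeric"),
  validity = function(object) {
    if (nrow(object@centers) != object@k) return("centers must have k rows")
    if (object@maxRadius < 0) return("maxRadius must be nonnegative")
    TRUE
  })

#' CountMatrix: lagged transition counts on a connected active set
#'
#' @slot counts k x k nonnegative count matrix (sliding-window counting).
#' @slot lag counting lag in frames.
#' @slot activeSet original state labels retained (after trimming, these form
#'   one strongly connected component).
#' @slot trimmed logical; TRUE once restricted to the largest SCC.
#' @exportClass CountMatrix
setClass("CountMatrix",
  representation(counts = "matrix", lag = "integer", activeSet = "integer",
                 trimmed = "logical"),
  validity = function(object) {
    if (any(object@counts < 0)) return("counts must be nonnegative")
    if (nrow(object@counts) != ncol(object@counts)) return("counts must be square")
    if (length(object@activeSet) != nrow(object@counts))
      return("activeSet length must match the count matrix dimension")
    TRUE
  })

#' MarkovModel: a discrete-time Markov state model at lag tau
#'
#' @slot T row-stochastic transition matrix on the active set.
#' @slot lag lag in frames.
#' @slot frameInterval time units per frame; tau = lag * frameInterval.
#' @slot pi stationary distribution.
#' @slot eigenvalues eigenvalues sorted by decreasing real part (lambda1 = 1).
#' @slot rightVectors right eigenvectors (columns), pi-orthonormal for
#'   reversible models.
#' @slot leftVectors left eigenvectors (columns).
#' @slot activeSet original state labels of the model states.
#' @slot reversible TRUE if estimated with count symmetrization.
#' @exportClass MarkovModel
setClass("MarkovModel",
  representation(T = "matrix", lag = "integer", frameInterval = "numeric",
                 pi = "numeric", eigenvalues = "numeric",
                 rightVectors = "matrix", leftVectors = "matrix",
                 activeSet = "integer", reversible = "logical"),
  validity = function(object) {
    if (max(abs(rowSums(object@T) - 1)) > 1e-12)
      return("transition matrix rows must sum to 1 within 1e-12")
    if (abs(sum(object@pi) - 1) > 1e-10) return("pi must sum to 1")
    err <- max(abs(drop(object@pi %*% object@T) - object@pi))
    if (err > 1e-10) return("pi must be a fixed point of T within 1e-10")
    TRUE
  })

#' MacroModel: coarse-grained (lumped) kinetic model
#'
#' @slot nMacro number of macrostates.
#' @slot assignment integer micro -> macro map (one entry per model state).
#' @slot populations summed stationary probability per macrostate.
#' @slot eigenvalues microstate eigenvalue sequence used for the gap decision.
#' @slot gapRatios lambda_k / lambda_(k+1) diagnostics.
#' @exportClass MacroModel
setClass("MacroModel",
  representation(nMacro = "integer", assignment = "integer",
                 populations = "numeric", eigenvalues = "numeric",
                 gapRatios = "numeric"),
  validity = function(object) {
    if (abs(sum(object@populations) - 1) > 1e-10)
      return("macrostate populations must sum to 1 within 1e-10")
    if (length(unique(object@assignment)) != object@nMacro)
      return("every macrostate must be nonempty")
    TRUE
  })

#' FluxNetwork: transition-path-theory reactive flux between two state sets
#'
#' Gross flux f_ij = pi_i q-_i T_ij q+_j, net flux f+_ij = max(0, f_ij - f_ji),
#' total flux F = sum of net flux out of the source set. Units: probability
#' flux per lag time tau.
#'
#' @slot A,B source and sink state index sets (model indexing).
#' @slot qplus,qminus forward and backward committors.
#' @slot grossFlux,netFlux flux matrices.
#' @slot totalFlux total reactive flux F.
#' @slot pi stationary distribution of the underlying model.
#' @exportClass FluxNetwork
setClass("FluxNetwork",
  representation(A = "integer", B = "integer", qplus = "numeric",
                 qminus = "numeric", grossFlux = "matrix", netFlux = "matrix",
                 totalFlux = "numeric", pi = "numeric"),
  validity = function(object) {
    q <- object@qplus
    if (any(q < -1e-10 | q > 1 + 1e-10)) return("committor must lie in [0, 1]")
    if (max(abs(q[object@A])) > 1e-10) return("committor must be 0 on A")
    if (max(abs(q[object@B] - 1)) > 1e-10) return("committor must be 1 on B")
    TRUE
  })

#' PathwayDecomposition: bottleneck decomposition of a flux network
#'
#' @slot pathways list of state index sequences from source to sink.
#' @slot fluxes flux carried by each pathway (bottleneck at extraction time).
#' @slot coverage cumulative fraction of total flux covered.
#' @slot totalFlux the decomposed network's total reactive flux.
#' @exportClass PathwayDecomposition
setClass("PathwayDecomposition",
  representation(pathways = "list", fluxes = "numeric", coverage = "numeric",
                 totalFlux = "numeric"),
  validity = function(object) {
    if (length(object@pathways) != length(object@fluxes))
      return("one flux per pathway required")
    if (sum(object@fluxes) > object@totalFlux * (1 + 1e-10))
      return("pathway fluxes cannot exceed the total reactive flux")
    TRUE
  })

#' KinkProfile: per-residue helix kink and wobble angles
#'
#' Angles are measured between axes of cylinders fit to the two windows
#' flanking each residue; the straight/kinked label applies the threshold to
#' the maximum kink angle (strict inequality).
#'
#' @slot residues residue indices at which both windows fit.
#' @slot angles kink angle in degrees at each supported residue.
#' @slot wobbles bend-direction azimuth in degrees (NA where angle ~ 0).
#' @slot maxAngle maximum kink angle.
#' @slot straight TRUE iff no angle exceeds the threshold.
#' @slot threshold classification threshold in degrees (default 35).
#' @slot window cylinder window length in residues.
#' @exportClass KinkProfile
setClass("KinkProfile",
  representation(residues = "integer", angles = "numeric", wobbles = "numeric",
                 maxAngle = "numeric", straight = "logical",
                 threshold = "numeric", window = "integer"),
  validity = function(object) {
    if (any(object@angles < 0 | object@angles >= 180))
      return("kink angles must lie in [0, 180)")
    if (object@straight != (object@maxAngle < object@threshold))
      return("straight flag inconsistent with max angle and threshold")
    TRUE
  })

#' HBondCriterion: geometric hydrogen-bond definition
#'
#' A donor/hydrogen/acceptor triple is bonded when the donor-acceptor
#' distance is strictly below `maxDistance` and the hydrogen deviates
#' strictly less than `maxAngle` from the donor-acceptor line.
#'
#' @slot maxDistance donor-acceptor cutoff in nm (default 0.35).
#' @slot maxAngle hydrogen deviation cutoff in degrees (default 30).
#' @exportClass HBondCriterion
setClass("HBondCriterion",
  representation(maxDistance = "numeric", maxAngle = "numeric"),
  validity = function(object) {
    if (object@maxDistance <= 0 || object@maxAngle <= 0)
      return("criterion thresholds must be strictly positive")
    TRUE
  })

#' GMRQReport: cross-validation scores over a parameter grid
#'
#' @slot scores data.frame with one row per (grid point, split): columns
#'   `name`, `split`, `train`, `test`, `nStatesShared`, `flagged`.
#' @slot summary data.frame of mean train/test score per grid point.
#' @slot best name of the grid point with highest mean test score.
#' @slot m number of eigenvalues scored.
#' @slot nSplits,splitRatio the cross-validation layout.
#' @exportClass GMRQReport
setClass("GMRQReport",
  representation(scores = "data.frame", summary = "data.frame",
                 best = "character", m = "integer", nSplits = "integer",
                 splitRatio = "numeric"))

#' ResidenceReport: residence-probability validation of an MSM
#'
#' @slot states original labels of the tested (most populated) microstates.
#' @slot lagMultiples the propagation multiples tested.
#' @slot model matrix of model-predicted residence probabilities (T^k)_ii.
#' @slot data matrix of trajectory-estimated residence probabilities.
#' @slot lower,upper bootstrap band matrices (simultaneous level used for the
#'   verdict; see `residenceProbabilityTest`).
#' @slot pass logical verdict per tested state.
#' @slot nStarts qualifying start counts per state.
#' @exportClass ResidenceReport
setClass("ResidenceReport",
  representation(states = "integer", lagMultiples = "integer",
                 model = "matrix", data = "matrix", lower = "matrix",
                 upper = "matrix", pass = "logical", nStarts = "integer"))
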