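#' @name msmhelix-accessors
#' @title Accessors for msmhelix model objects
#' @description Slot access for the S4 model classes goes through these
#'   accessors; slots are an implementation detail.
#' @param object a model object.
NULL

#' @describeIn msmhelix-accessors number of model states (or centers).
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @describeIn msmhelix-accessors row-stochastic transition matrix.
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' @describeIn msmhelix-accessors stationary distribution.
#' @export
setGeneric("stationaryDist", function(object) standardGeneric("stationaryDist"))

#' @describeIn msmhelix-accessors implied timescales t_k = -tau / log(lambda_k).
#' @export
setGeneric("impliedTimescales", function(object) standardGeneric("impliedTimescales"))

#' @describeIn msmhelix-accessors original state labels retained in the model.
#' @export
setGeneric("activeSet", function(object) standardGeneric("activeSet"))

#' @describeIn msmhelix-accessors micro-to-macro state assignment.
#' @export
setGeneric("macroAssignment", function(object) standardGeneric("macroAssignment"))

#' @describeIn msmhelix-accessors macrostate populations.
#' @export
setGeneric("populations", function(object) standardGeneric("populations"))

#' @describeIn msmhelix-accessors total reactive flux F.
#' @export
setGeneric("totalFlux", function(object) standardGeneric("totalFlux"))

#' @describeIn msmhelix-accessors forward committor q+.
#' @export
setGeneric("forwardCommittor", function(object) standardGeneric("forwardCommittor"))

#' @describeIn msmhelix-accessors net (positive part) flux matrix.
#' @export
setGeneric("netFlux", function(object) standardGeneric("netFlux"))

#' @describeIn msmhelix-accessors feature values matrix of a trajectory.
#' @export
setGeneric("values", function(object) standardGeneric("values"))

#' @describeIn msmhelix-accessors number of frames.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @describeIn msmhelix-accessors feature labels.
#' @export
setGeneric("featureLabels", function(object) standardGeneric("featureLabels"))

#' @describeIn msmhelix-accessors time between consecutive frames.
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @describeIn msmhelix-accessors tICA/MSM eigenvalues.
#' @export
setGeneric("modelEigenvalues", function(object) standardGeneric("modelEigenvalues"))

#' @describeIn msmhelix-accessors tICA loading matrix (columns = tICs).
#' @export
setGeneric("ticComponents", function(object) standardGeneric("ticComponents"))

#' Evaluate a landscape potential
#'
#' @param landscape a [Landscape-class] object.
#' @param x numeric vector (one point) or matrix (one point per row).
#' @return potential values, in kT units.
#' @export
setGeneric("potential", function(landscape, x) standardGeneric("potential"))

#' Evaluate a landscape potential gradient
#'
#' @inheritParams potential
#' @return gradient vector (or matrix of gradients, one per row of `x`).
#' @export
setGeneric("potentialGradient",
           function(landscape, x) standardGeneric("potentialGradient"))
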