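## Closed-form potential families for the synthetic trajectory generator and
## for quadrature oracles. The compiled integrator evaluates the same closed
## forms (family `code` / `cpar` layout); agreement is tested numerically.

.LANDSCAPE_CODES <- c("flat" = 0L, "harmonic" = 1L, "double-well" = 2L,
                      "tilted-double-well" = 3L, "triple-well-2d" = 4L)

#' Construct an analytic potential-energy landscape
#'
#' Named families, in kT units:
#' \describe{
#'   \item{flat}{U = 0 (free diffusion); any dimension in \{1, 2\}.}
#'   \item{harmonic}{U = kappa/2 |x|^2.}
#'   \item{double-well}{U = h (x^2 - 1)^2, 1D, barrier height h at x = 0.}
#'   \item{tilted-double-well}{U = h (x^2 - 1)^2 + tilt * x, 1D.}
#'   \item{triple-well-2d}{harmonic confinement kappa/2 |x|^2 plus signed
#'     Gaussian terms of common width `sigma`: positive `depths` entries are
#'     wells, negative entries are repulsive hills. The defaults place three
#'     wells of unequal depth (middle deepest) on a bent path around a
#'     central hill, so the landscape has three metastable states connected
#'     along a single unbranching 1 -> 2 -> 3 channel — the topology of a
#'     paused translocation intermediate landscape. The default constants
#'     (kappa = 3, sigma = 0.35, depths 6.2/6.9/6.0 kT, hill 7 kT) are
#'     documented design choices: barriers of 3.5-5 kT separate hopping
#'     (timescales ~ 2-4 time units) from intra-basin relaxation (< 0.3),
#'     and the hill blocks the direct 1 -> 3 corridor.}
#' }
#'
#' @param family family name (see above).
#' @param dimension 1 or 2 (only `flat` and `harmonic` accept both).
#' @param kappa harmonic/confinement spring constant (kT per length^2).
#' @param h double-well barrier height (kT).
#' @param tilt linear tilt (kT per length).
#' @param sigma Gaussian well width (length units).
#' @param depths well depths (kT).
#' @param centers well centers, one row per well.
#' @return a [Landscape-class] object.
#' @examples
#' L <- makeLandscape("double-well", h = 4)
#' potential(L, c(0, 1))   # barrier top and well bottom
#' @export
makeLandscape <- function(family = c("flat", "harmonic", "double-well",
                                     "tilted-double-well", "triple-well-2d"),
                          dimension = NULL, kappa = NULL, h = 4, tilt = 0.5,
                          sigma = 0.35, depths = c(6.2, 6.9, 6.0, -7),
                          centers = rbind(c(-1, 0), c(0, 0.8), c(1, 0),
                                          c(0, -0.2))) {
  family <- match.arg(family)
  code <- .LANDSCAPE_CODES[[family]]
  if (family %in% c("double-well", "tilted-double-well")) {
    if (!is.null(dimension) && dimension != 1L)
      stop("family '", family, "' is one-dimensional")
    dimension <- 1L
  } else if (family == "triple-well-2d") {
    if (!is.null(dimension) && dimension != 2L)
      stop("family 'triple-well-2d' is two-dimensional")
    dimension <- 2L
  } else if (is.null(dimension)) dimension <- 1L
  # confinement default: stiffer for the triple-well so intra-basin modes are
  # much faster than inter-well hopping (documented in the methods vignette)
  if (is.null(kappa)) kappa <- if (family == "triple-well-2d") 3 else 1
  params <- switch(family,
    "flat" = c(),
    "harmonic" = c(kappa = kappa),
    "double-well" = c(h = h),
    "tilted-double-well" = c(h = h, tilt = tilt),
    "triple-well-2d" = {
      centers <- as.matrix(centers)
      stopifnot(nrow(centers) == length(depths), ncol(centers) == 2L)
      p <- c(kappa = kappa, sigma = sigma)
      for (w in seq_along(depths))
        p <- c(p, stats::setNames(c(depths[w], centers[w, ]),
                                  paste0(c("depth", "cx", "cy"), w)))
      p
    })
  cpar <- switch(family,
    "flat" = numeric(0),
    "harmonic" = kappa,
    "double-well" = h,
    "tilted-double-well" = c(h, tilt),
    "triple-well-2d" = unname(params))
  new("Landscape", family = family, dimension = as.integer(dimension),
      params = if (length(params)) params else numeric(0),
      code = code, cpar = as.numeric(cpar))
}

#' @rdname potential
setMethod("potential", "Landscape", function(landscape, x) {
  x <- .as_points(x, landscape@dimension)
  p <- landscape@params
  switch(landscape@family,
    "flat" = rep(0, nrow(x)),
    "harmonic" = 0.5 * p[["kappa"]] * rowSums(x^2),
    "double-well" = p[["h"]] * (x[, 1]^2 - 1)^2,
    "tilted-double-well" = p[["h"]] * (x[, 1]^2 - 1)^2 + p[["tilt"]] * x[, 1],
    "triple-well-2d" = {
      u <- 0.5 * p[["kappa"]] * rowSums(x^2)
      s2 <- p[["sigma"]]^2
      nw <- (length(p) - 2L) %/% 3L
      for (w in seq_len(nw)) {
        dx <- x[, 1] - p[[paste0("cx", w)]]
        dy <- x[, 2] - p[[paste0("cy", w)]]
        u <- u - p[[paste0("depth", w)]] * exp(-(dx^2 + dy^2) / (2 * s2))
      }
      u
    })
})

#' @rdname potentialGradient
setMethod("potentialGradient", "Landscape", function(landscape, x) {
  x <- .as_points(x, landscape@dimension)
  g <- t(apply(x, 1L, function(row)
    cpp_grad(landscape@code, landscape@cpar, as.numeric(row))))
  if (landscape@dimension == 1L) g <- matrix(g, ncol = 1L)
  if (nrow(x) == 1L) drop(g) else g
})

.as_points <- function(x, dimension) {
  if (is.null(dim(x))) {
    if (dimension == 1L) x <- matrix(x, ncol = 1L)
    else x <- matrix(x, ncol = dimension, byrow = TRUE)
  }
  if (ncol(x) != dimension)
    stop("points have dimension ", ncol(x), " but the landscape has ",
         dimension)
  x
}

#' Approximate minima of a landscape
#'
#' Returns the analytic well centers (refined by a local optimizer), one row
#' per minimum, used for basin partitioning and equilibrium start points.
#'
#' @param landscape a [Landscape-class] object.
#' @return matrix with one minimum per row.
#' @export
landscapeMinima <- function(landscape) {
  starts <- switch(landscape@family,
    "flat" = matrix(0, 1L, landscape@dimension),
    "harmonic" = matrix(0, 1L, landscape@dimension),
    "double-well" = matrix(c(-1, 1), 2L, 1L),
    "tilted-double-well" = matrix(c(-1, 1), 2L, 1L),
    "triple-well-2d" = {
      p <- landscape@params
      nw <- (length(p) - 2L) %/% 3L
      wells <- Filter(function(w) p[[paste0("depth", w)]] > 0, seq_len(nw))
      t(vapply(wells, function(w)
        c(p[[paste0("cx", w)]], p[[paste0("cy", w)]]), numeric(2L)))
    })
  if (landscape@family == "flat") return(starts)
  refined <- t(apply(starts, 1L, function(s) {
    stats::optim(s, function(z) potential(landscape, z),
                 method = if (length(s) == 1L) "BFGS" else "Nelder-Mead")$par
  }))
  if (landscape@dimension == 1L) refined <- matrix(refined, ncol = 1L)
  refined
}

#' Boltzmann basin weights by trapezoid quadrature
#'
#' Numerically integrates exp(-U/kT) on a regular grid and partitions the
#' mass over basins defined by nearest landscape minimum. This is the
#' independent equilibrium oracle against which sampled populations are
#' checked.
#'
#' @param landscape a [Landscape-class] object.
#' @param kT temperature factor.
#' @param lower,upper integration box (vectors of length = dimension).
#' @param n grid points per dimension.
#' @return named list: `weights` (per-basin probability, ordered as
#'   [landscapeMinima()]), `Z` (partition function), `minima`.
#' @export
boltzmannWeights <- function(landscape, kT = 1, lower = NULL, upper = NULL,
                             n = 301L) {
  d <- landscape@dimension
  if (is.null(lower)) lower <- rep(-3.5, d)
  if (is.null(upper)) upper <- rep(3.5, d)
  minima <- landscapeMinima(landscape)
  grids <- lapply(seq_len(d), function(j) seq(lower[j], upper[j], length.out = n))
  if (d == 1L) {
    x <- matrix(grids[[1L]], ncol = 1L)
    w <- rep(1, n); w[c(1L, n)] <- 0.5
    cellw <- w * diff(grids[[1L]][1:2])
  } else {
    x <- as.matrix(expand.grid(grids[[1L]], grids[[2L]]))
    w1 <- rep(1, n); w1[c(1L, n)] <- 0.5
    # expand.grid varies its first argument fastest, matching column-major outer()
    cellw <- as.numeric(outer(w1, w1)) *
      diff(grids[[1L]][1:2]) * diff(grids[[2L]][1:2])
  }
  dens <- exp(-potential(landscape, x) / kT) * cellw
  Z <- sum(dens)
  basin <- .nearest_row(x, minima)
  weights <- vapply(seq_len(nrow(minima)), function(b) sum(dens[basin == b]),
                    numeric(1L)) / Z
  list(weights = weights, Z = Z, minima = minima)
}

.nearest_row <- function(x, centers) {
  best <- rep(1L, nrow(x))
  bestd <- rowSums((x - matrix(centers[1L, ], nrow(x), ncol(x), byrow = TRUE))^2)
  for (b in seq_len(nrow(centers))[-1L]) {
    d <- rowSums((x - matrix(centers[b, ], nrow(x), ncol(x), byrow = TRUE))^2)
    hit <- d < bestd
    best[hit] <- b
    bestd[hit] <- d[hit]
  }
  best
}

setMethod("show", "Landscape", function(object) {
  cat("Landscape <", object@family, "> dimension", object@dimension, "\n")
  if (length(object@params))
    cat("  params:", paste(names(object@params), signif(object@params, 4),
                           sep = "=", collapse = ", "), "\n")
})
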