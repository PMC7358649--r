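# Forward model: Abeles matrix reflectivity with Nevot-Croce roughness and
# Gaussian resolution smearing.  Q is in inverse Angstrom throughout.

#' Momentum transfer of a specular reflection
#'
#' Q = 4 pi sin(theta) / lambda.
#'
#' @param theta angle of incidence in degrees.
#' @param lambda neutron wavelength in Angstrom (> 0).
#' @return Q in A^-1.
#' @export
momentum_transfer <- function(theta, lambda) {
  if (any(lambda <= 0)) stop("wavelength must be positive")
  4 * pi * sin(theta * pi / 180) / lambda
}

#' Build a slab stack
#'
#' A stack is a data frame with one row per medium, ordered from the
#' incident (fronting) medium to the backing medium.  `rough` is the rms
#' roughness of the interface to the *previous* medium; the first entry is
#' unused, as are the first and last thicknesses (semi-infinite media).
#'
#' @param thickness,sld,rough equal-length numeric vectors (A, A^-2, A).
#' @param name optional layer labels.
#' @return data frame of class `slab_stack`.
#' @export
slab_stack <- function(thickness, sld, rough, name = NULL) {
  n <- length(sld)
  if (length(thickness) != n || length(rough) != n)
    stop("thickness, sld and rough must have equal length")
  if (n < 2) stop("a stack needs at least fronting and backing media")
  if (any(!is.finite(sld))) stop("non-finite SLD in stack")
  if (any(thickness[-c(1, n)] < 0)) stop("negative layer thickness")
  if (any(rough < 0)) stop("negative roughness")
  structure(data.frame(name = if (is.null(name)) paste0("L", seq_len(n) - 1)
                       else name,
                       thickness = thickness, sld = sld, rough = rough),
            class = c("slab_stack", "data.frame"))
}

#' Specular reflectivity of a slab stack (Abeles matrix method)
#'
#' Exact transfer-matrix reflectivity with Nevot-Croce Gaussian-roughness
#' damping of each Fresnel coefficient.  Results are clipped to at most 1.
#'
#' @param stack a [slab_stack()].
#' @param Q momentum-transfer grid (A^-1, > 0).
#' @return reflectivity in `[0, 1]` at each Q.
#' @export
abeles_reflectivity <- function(stack, Q) {
  if (!is.data.frame(stack) || nrow(stack) < 2)
    stop("a stack needs at least fronting and backing media")
  if (any(!is.finite(stack$sld))) stop("non-finite SLD in stack")
  if (any(Q <= 0)) stop("Q must be positive")
  abeles_c(as.numeric(Q), as.numeric(stack$thickness),
           as.numeric(stack$sld), as.numeric(stack$rough))
}

# Gauss-Hermite nodes/weights by Golub-Welsch; weights normalised so the
# quadrature integrates a Gaussian-weighted constant to exactly 1.
gauss_hermite <- function(n = 17) {
  key <- paste0("gh", n)
  if (is.null(.pkg[[key]])) {
    j <- sqrt(seq_len(n - 1) / 2)
    J <- matrix(0, n, n)
    J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- j
    J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- j
    e <- eigen(J, symmetric = TRUE)
    w <- e$vectors[1, ]^2
    .pkg[[key]] <- list(nodes = e$values, weights = w / sum(w))
  }
  .pkg[[key]]
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Resolution-smear a model reflectivity curve
#'
#' Convolves a model R(Q) with a Gaussian resolution function using
#' fixed-order Gauss-Hermite quadrature (17 points).  The kernel width is
#' either a constant relative resolution dQ/Q (FWHM) or a per-point dQ
#' (FWHM) array.  End points are handled by evaluating the model at the
#' shifted Q values, never by padding.
#'
#' @param fn function taking a Q vector and returning model reflectivity.
#' @param Q evaluation grid (A^-1).
#' @param resolution scalar relative dQ/Q FWHM, or numeric vector of
#'   per-point dQ FWHM values the same length as `Q`.
#' @param n_nodes quadrature order.
#' @return smeared reflectivity at `Q`.
#' @export
smear <- function(fn, Q, resolution, n_nodes = 17) {
  if (is.null(resolution)) return(fn(Q))
  if (length(resolution) == 1) {
    if (resolution < 0) stop("resolution must be non-negative")
    if (resolution < 1e-9) return(fn(Q))
    dq <- resolution * Q
  } else {
    if (length(resolution) != length(Q))
      stop("per-point dQ must match Q in length")
    if (any(resolution <= 0)) stop("per-point dQ must be positive")
    dq <- resolution
  }
  gh <- gauss_hermite(n_nodes)
  sig <- fwhm_to_sigma(dq)
  qe <- outer(sig * sqrt(2), gh$nodes) + Q   # nQ x n_nodes
  qe[qe <= 0] <- 1e-9                        # guard sub-critical overshoot
  r <- fn(as.numeric(qe))
  dim(r) <- dim(qe)
  as.numeric(r %*% gh$weights)
}

#' Smeared reflectivity of a slab stack
#'
#' @inheritParams abeles_reflectivity
#' @inheritParams smear
#' @return reflectivity at `Q`.
#' @export
reflectivity <- function(stack, Q, resolution = NULL) {
  if (is.null(resolution)) return(abeles_reflectivity(stack, Q))
  smear(function(q) abeles_reflectivity(stack, q), Q, resolution)
}

#' A measured (or simulated) reflectivity curve
#'
#' @param Q strictly increasing positive momentum transfer (A^-1).
#' @param R reflectivity, non-negative.
#' @param dR one-sigma uncertainties (> 0), optional.
#' @param dQ per-point resolution FWHM (A^-1), optional.
#' @param contrast contrast label this curve was measured in.
#' @return data frame of class `refl_curve`.
#' @export
reflectivity_curve <- function(Q, R, dR = NULL, dQ = NULL, contrast = NA) {
  n <- length(Q)
  if (length(R) != n) stop("Q and R must have equal length")
  if (any(Q <= 0)) stop("Q must be positive")
  if (any(diff(Q) <= 0)) stop("Q must be strictly increasing")
  if (any(R < 0)) stop("R must be non-negative")
  if (!is.null(dR)) {
    if (length(dR) != n) stop("dR must match Q in length")
    if (any(dR <= 0)) stop("dR must be positive")
  }
  if (!is.null(dQ) && (length(dQ) != n || any(dQ <= 0)))
    stop("dQ must be positive and match Q in length")
  out <- data.frame(Q = Q, R = R)
  if (!is.null(dR)) out$dR <- dR
  if (!is.null(dQ)) out$dQ <- dQ
  structure(out, class = c("refl_curve", "data.frame"),
            contrast = contrast)
}

#' @export
print.refl_curve <- function(x, ...) {
  cat(sprintf("<refl_curve> %d points, Q in [%.4g, %.4g] A^-1, contrast %s\n",
              nrow(x), min(x$Q), max(x$Q), attr(x, "contrast")))
  invisible(x)
}
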