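# Training-free, weight-variable complex RNN generating grid-cell activity.
#
# The four-unit complex activity vector a(x) is updated multiplicatively by
# exp(W_r(phi) r + W_b b), where both generators share the unitary eigenbasis
# U and have purely imaginary eigenvalues i * B %*% (displacement). The update
# is therefore unitary: each eigen-coordinate c_k = (U^H a)_k keeps its
# modulus and only accumulates phase (B %*% dx)_k. The rows of B / b0 are the
# four tetrahedral axes, so the phase pattern is periodic on an FCC lattice
# in 3D and on a hexagonal lattice when restricted to the horizontal plane.

# unrotated tetrahedral basis; rows are unit vectors with pairwise dot -1/3
tetra_basis <- function() {
  matrix(c(2 * sqrt(2) / 3, 0, -1 / 3,
           -sqrt(2) / 3, sqrt(6) / 3, -1 / 3,
           -sqrt(2) / 3, -sqrt(6) / 3, -1 / 3,
           0, 0, 1), 4, 3, byrow = TRUE)
}

#' Network constants of the grid RNN
#'
#' Builds the basis matrix \code{B = b0 * (tetrahedral basis rotated by R0)}
#' and the fixed 4x4 unitary eigenbasis \code{U}. \code{b0} sets the spatial
#' frequency (the activity is periodic with period \code{2*pi/b0} along each
#' basis axis); \code{R0} is a rotation about the vertical axis that breaks
#' alignment between the lattice and the arena walls.
#'
#' @param b0 nonzero scale (default 10).
#' @param rotation_deg rotation of the basis about the vertical axis in
#'   degrees (default 8).
#' @return object of class \code{grid_constants} with fields \code{B} (4x3),
#'   \code{U} (4x4 complex), \code{b0}, \code{R0}, \code{phase0} (initial
#'   eigen-coordinates).
#' @examples
#' k <- grid_constants()
#' rowSums((k$B / k$b0)^2)  # unit rows
#' @export
grid_constants <- function(b0 = 10, rotation_deg = 8) {
  if (!is.finite(b0) || b0 == 0) stop("b0 must be a nonzero finite scale")
  R0 <- rotation_z(rotation_deg)
  B <- tetra_basis() %*% t(R0) * b0
  w <- exp(1i * pi / 3)          # sixth root of unity
  U <- matrix(c(1, 1, 1, 1,
                1, w^-2, w, -1,
                1, w, w^-2, -1,
                1, -1, -1, 1), 4, 4, byrow = TRUE) / 2
  phase0 <- exp(1i * c(0, pi, 0, 3 * pi / 2))
  structure(list(B = B, U = U, b0 = b0, R0 = R0, phase0 = phase0),
            class = "grid_constants")
}

#' Weight-generator matrices of the grid RNN
#'
#' Returns the planar and vertical update generators
#' \code{W_r = U diag(i B M gamma) U^H} and \code{W_b = U diag(i B u) U^H}.
#' Both are skew-Hermitian and commute (they share the eigenbasis U), so
#' finite updates \code{exp(W_r r + W_b b)} are unitary and path integration
#' over closed loops is exact.
#'
#' @param u unit length-3 axis direction.
#' @param gamma length-2 unit planar direction \code{c(cos phi, sin phi)}.
#' @param consts \code{\link{grid_constants}}.
#' @param M optional 3x2 plane mapping (defaults to the one built from u).
#' @return list with complex 4x4 matrices \code{W_r} and \code{W_b}.
#' @export
weight_generators <- function(u, gamma, consts = grid_constants(), M = NULL) {
  stopifnot(length(u) == 3, length(gamma) == 2)
  if (is.null(M)) M <- plane_rotation(u)$M
  U <- consts$U
  W_r <- U %*% diag(1i * drop(consts$B %*% (M %*% gamma))) %*% Conj(t(U))
  W_b <- U %*% diag(1i * drop(consts$B %*% u)) %*% Conj(t(U))
  list(W_r = W_r, W_b = W_b)
}

#' Initial network state
#'
#' Eigen-coordinates start at the unit-modulus phases
#' \code{[1, e^{i pi}, 1, e^{i 3 pi / 2}]}; the activity vector is
#' \code{a = U c}.
#'
#' @param consts \code{\link{grid_constants}}.
#' @return object of class \code{network_state} with complex 4-vectors
#'   \code{a} and \code{c}.
#' @export
network_state <- function(consts = grid_constants()) {
  cc <- consts$phase0
  structure(list(a = drop(consts$U %*% cc), c = cc), class = "network_state")
}

#' Single activity update
#'
#' Advances the network by one displacement. The update is performed in the
#' eigenbasis: \code{c_k <- exp(i (B p)_k) c_k} with
#' \code{p = r * M gamma + b * u} the effective world-frame displacement
#' (mathematically identical to multiplying by the matrix exponential
#' \code{exp(W_r r + W_b b)}, since all generators share U).
#'
#' @param state a \code{\link{network_state}}.
#' @param cd a \code{cyl_disp} (fields r, phi/gamma, b).
#' @param u unit axis used for reconstruction (the perceived axis).
#' @param consts \code{\link{grid_constants}}.
#' @param M optional 3x2 plane mapping (defaults to the one built from u).
#' @return updated \code{network_state}.
#' @export
update_activity <- function(state, cd, u, consts = grid_constants(),
                            M = NULL) {
  if (!all(is.finite(c(cd$r, cd$b)))) stop("non-finite displacement")
  if (is.null(M)) M <- plane_rotation(u)$M
  p <- cd$r * drop(M %*% cd$gamma) + cd$b * u
  cc <- state$c * exp(1i * drop(consts$B %*% p))
  structure(list(a = drop(consts$U %*% cc), c = cc), class = "network_state")
}

# Vectorized phase integration: P is an n x 3 matrix of effective world-frame
# displacements; returns the n x 4 complex activity history (after each step).
integrate_activity <- function(P, consts) {
  phases <- apply(P %*% t(consts$B), 2, cumsum)
  if (is.null(dim(phases))) phases <- matrix(phases, nrow = 1)
  C <- exp(1i * phases) * matrix(consts$phase0, nrow(P), 4, byrow = TRUE)
  C %*% t(consts$U)
}

#' Normalized real activity
#'
#' Per-neuron min-max normalization of the real part of the activity over the
#' whole trial, mapping it to [0, 1] as input to the spiking nonlinearity.
#' A constant trace is degenerate and normalizes to 0.5 with a warning.
#'
#' @param a_history T x 4 complex (or real) matrix of activities.
#' @return T x 4 real matrix in [0, 1].
#' @export
normalized_activity <- function(a_history) {
  x <- Re(as.matrix(a_history))
  stopifnot(nrow(x) >= 1)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  span <- hi - lo
  flat <- span < 1e-12
  if (any(flat)) {
    warning("constant activity trace(s) normalized to 0.5")
    span[flat] <- 1
  }
  out <- sweep(sweep(x, 2, lo, "-"), 2, span, "/")
  out[, flat] <- 0.5
  out
}

#' Spiking parameters of the logistic rate map
#'
#' @param lambda0 ceiling parameter (default 1.1).
#' @param c slope (default 15).
#' @param lambda1 midpoint (default 0.7; above the midpoint of the
#'   normalized-activity range, so only the top of the activity profile
#'   fires appreciably).
#' @return object of class \code{spike_params}.
#' @export
spike_params <- function(lambda0 = 1.1, c = 15, lambda1 = 0.7) {
  structure(list(lambda0 = lambda0, c = c, lambda1 = lambda1),
            class = "spike_params")
}

#' Logistic spike rate
#'
#' \eqn{\lambda = [\lambda_0 + \exp(-c (a' - \lambda_1))]^{-1}}: an S-shaped
#' map from normalized activity to a Poisson rate bounded by
#' \eqn{1/\lambda_0}.
#'
#' @param a_prime normalized activity in [0, 1] (vectorized).
#' @param params \code{\link{spike_params}}.
#' @return spike rate(s) per step.
#' @examples
#' spike_rate(0.7)  # 1 / 2.1
#' @export
spike_rate <- function(a_prime, params = spike_params()) {
  stopifnot(all(is.finite(a_prime)))
  1 / (params$lambda0 + exp(-params$c * (a_prime - params$lambda1)))
}

#' Poisson spike emission
#'
#' @param rate nonnegative rate(s) per step (one step = unit time).
#' @return integer spike count(s).
#' @export
emit_spikes <- function(rate) {
  stopifnot(all(rate >= 0))
  stats::rpois(length(rate), rate)
}
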