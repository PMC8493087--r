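# Screw-axis representation of 6-DoF motion and its plane-referenced
# cylindrical decomposition.
#
# Any rigid motion with nonzero rotation is, by Chasles' theorem, a rotation
# about a single axis u combined with a translation along it (pitch h). A
# displacement is then split into a component on the plane normal to u and an
# elevation along u, giving local cylindrical coordinates (r, phi, b) that
# drive the grid network.

#' Screw-axis representation of 6-DoF motion
#'
#' Converts rotational and translational velocities into the screw-axis form
#' (u, h, q, theta): unit axis direction \code{u = omega / theta}, pitch
#' \code{h = (v . omega) / theta^2} (translation per radian), and a point on
#' the axis \code{q = u x v / theta}.
#'
#' @param omega rotational velocity, length-3 (rad/step).
#' @param v translational velocity, length-3 (length/step).
#' @return object of class \code{screw_axis} with fields \code{u}, \code{h},
#'   \code{q}, \code{theta}.
#' @examples
#' screw_axis(c(0, 0, 2), c(0, 0, 4))  # pure axial translation + spin
#' @export
screw_axis <- function(omega, v) {
  stopifnot(length(omega) == 3, length(v) == 3,
            all(is.finite(omega)), all(is.finite(v)))
  theta <- sqrt(sum(omega^2))
  if (theta == 0)
    stop("no-rotation case (theta = 0): use the translation-only branch")
  u <- omega / theta
  h <- sum(v * omega) / theta^2
  q <- crossprod3(u, v) / theta
  structure(list(u = u, h = h, q = q, theta = theta), class = "screw_axis")
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Reconstruct the translational velocity from a screw axis
#'
#' Inverse of \code{\link{screw_axis}}: \code{v = h theta u + theta (q x u)}.
#' Used as a round-trip oracle for the decomposition.
#'
#' @param sa a \code{screw_axis} object.
#' @return length-3 translational velocity.
#' @export
screw_velocity <- function(sa) {
  sa$h * sa$theta * sa$u + sa$theta * crossprod3(sa$q, sa$u)
}

#' Rotation mapping a reference plane onto the horizontal
#'
#' Builds the rotation \eqn{\hat M^u = 2 z z^T / (z^T z) - I} with
#' \eqn{z = (u + e_z)/2}: a 180-degree rotation about the bisector of u and
#' the vertical, which maps \eqn{e_z} to u. Its first two columns M span the
#' plane normal to u.
#'
#' The construction is undefined for u antiparallel to the vertical. In
#' \code{strict} mode that is an error; otherwise u is nudged by rotating
#' 1e-6 rad toward +e_x, so long trajectories cannot silently produce NaNs.
#'
#' @param u unit length-3 axis direction.
#' @param strict error on the degenerate antiparallel axis (default TRUE).
#' @return object of class \code{plane_rotation}: \code{M_hat} (3x3),
#'   \code{M} (3x2, first two columns), \code{u}.
#' @examples
#' plane_rotation(c(0, 0, 1))$M_hat  # diag(-1, -1, 1)
#' @export
plane_rotation <- function(u, strict = TRUE) {
  stopifnot(length(u) == 3, all(is.finite(u)))
  u <- unit(u)
  z <- (u + c(0, 0, 1)) / 2
  zz <- sum(z^2)
  if (zz < 1e-12) {
    if (strict) stop("degenerate axis: u is antiparallel to the vertical")
    # rotate 1e-6 rad toward +e_x within the x-z plane
    eps <- 1e-6
    u <- unit(c(sin(eps), 0, -cos(eps)))
    z <- (u + c(0, 0, 1)) / 2
    zz <- sum(z^2)
  }
  M_hat <- 2 * tcrossprod(z) / zz - diag(3)
  structure(list(M_hat = M_hat, M = M_hat[, 1:2], u = u),
            class = "plane_rotation")
}

#' Cylindrical decomposition of a displacement
#'
#' Splits a 3D displacement into elevation b along the axis u and a planar
#' component of magnitude r and direction phi, such that
#' \code{r * M \%*\% c(cos(phi), sin(phi)) + b * u} reconstructs the input.
#' When the planar component vanishes, phi is 0 by convention.
#'
#' @param dx length-3 displacement.
#' @param rot a \code{\link{plane_rotation}} built from \code{u} (computed if
#'   missing).
#' @param u unit axis direction.
#' @return object of class \code{cyl_disp}: \code{r}, \code{phi}, \code{b},
#'   \code{gamma} (c(cos phi, sin phi)).
#' @examples
#' decompose_displacement(c(3, 4, 5), u = c(0, 0, 1))
#' @export
decompose_displacement <- function(dx, rot = NULL, u = rot$u) {
  stopifnot(length(dx) == 3, all(is.finite(dx)))
  if (is.null(rot)) rot <- plane_rotation(u)
  u <- rot$u
  b <- sum(dx * u)
  planar <- dx - b * u
  r <- sqrt(sum(planar^2))
  if (r < 1e-12) {
    r <- 0
    phi <- 0
  } else {
    # M columns are orthonormal and span the plane normal to u
    pq <- crossprod(rot$M, planar)  # r * gamma
    phi <- atan2(pq[2], pq[1])
  }
  structure(list(r = r, phi = phi, b = b, gamma = c(cos(phi), sin(phi))),
            class = "cyl_disp")
}

#' Navigation mode descriptor
#'
#' Tags how the cylindrical components reach the grid network:
#' \itemize{
#'   \item \code{planar_2d}: motion represented as intrinsically 2D; the
#'     plane mapping is clamped to the identity and elevation is discarded.
#'   \item \code{projected}: motion projected onto the reference plane;
#'     elevation is discarded, the plane mapping is kept.
#'   \item \code{volumetric}: both components are used (plane-dependent 3D).
#'   \item \code{plane_independent}: the raw displacement is integrated in
#'     the world frame with no plane perception at all.
#' }
#'
#' @param tag one of \code{"planar_2d"}, \code{"projected"},
#'   \code{"volumetric"}, \code{"plane_independent"}.
#' @return object of class \code{navigation_mode}.
#' @export
navigation_mode <- function(tag = c("planar_2d", "projected", "volumetric",
                                    "plane_independent")) {
  tag <- match.arg(tag)
  structure(list(tag = tag,
                 clamp_M_to_identity = tag == "planar_2d",
                 discard_b = tag %in% c("planar_2d", "projected")),
            class = "navigation_mode")
}

#' Apply a navigation mode to a cylindrical displacement
#'
#' Returns the effective displacement components the network integrates:
#' projected modes zero the elevation, the planar mode additionally replaces
#' the plane mapping by the identity, the volumetric mode passes everything
#' through unchanged.
#'
#' @param cd a \code{cyl_disp}.
#' @param rot the \code{plane_rotation} used for reconstruction.
#' @param mode a \code{\link{navigation_mode}}.
#' @return list with the (possibly modified) \code{cd} and the effective
#'   3x2 plane mapping \code{M}.
#' @export
apply_navigation_mode <- function(cd, rot, mode) {
  stopifnot(inherits(mode, "navigation_mode"))
  if (mode$tag == "plane_independent")
    stop("plane-independent navigation bypasses the cylindrical decomposition")
  M <- rot$M
  if (mode$clamp_M_to_identity) M <- diag(3)[, 1:2]
  if (mode$discard_b) cd$b <- 0
  list(cd = cd, M = M)
}
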