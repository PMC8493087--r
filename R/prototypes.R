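# Reference point clouds for calibrating the 3D structure metrics: the two
# densest sphere packings (FCC, HCP), a columnar arrangement (COL: stacked
# hexagonal layers sharing an offset), and uniform random placement (RND).
# Every cloud is a set of lattice vertices inside the unit cube, rotated
# 8 degrees about the vertical to match the simulated fields, then blurred
# with 500 isotropic Gaussian points per vertex.

#' Default lattice spacing
#'
#' Nearest-neighbor spacing commensurate with the grid network scale: the
#' activity period along each basis axis, \code{2 * pi / b0}.
#'
#' @param b0 network scale (default 10).
#' @return spacing (length units of the arena).
#' @export
default_spacing <- function(b0 = 10) 2 * pi / b0

# hexagonal layer of points with nearest-neighbor distance d covering
# [-lim, lim]^2, offset by (ox, oy)
hex_layer <- function(d, lim = 1.6, ox = 0, oy = 0) {
  ny <- ceiling(2 * lim / (d * sqrt(3) / 2)) + 2
  nx <- ceiling(2 * lim / d) + 2
  pts <- list()
  for (j in seq(-ny, ny)) {
    y <- j * d * sqrt(3) / 2 + oy
    xs <- seq(-nx, nx) * d + (j %% 2) * d / 2 + ox
    pts[[length(pts) + 1]] <- cbind(xs, y)
  }
  do.call(rbind, pts)
}

#' FCC or HCP lattice vertices in the unit cube
#'
#' Generates all vertices of the infinite close packing with given
#' nearest-neighbor spacing that fall inside \code{[-1, 1]^3}, then rotates
#' them by \code{rotation_deg} about the vertical axis. Both packings stack
#' hexagonal layers at inter-layer distance \code{spacing * sqrt(2/3)}:
#' FCC repeats offsets A-B-C, HCP repeats A-B.
#'
#' @param kind \code{"FCC"} or \code{"HCP"}.
#' @param spacing nearest-neighbor distance (default
#'   \code{\link{default_spacing}()}).
#' @param rotation_deg rotation about the vertical (default 8).
#' @return K x 3 matrix of vertices.
#' @export
lattice_vertices <- function(kind = c("FCC", "HCP"),
                             spacing = default_spacing(),
                             rotation_deg = 8) {
  kind <- match.arg(kind)
  stopifnot(spacing > 0)
  d <- spacing
  dz <- d * sqrt(2 / 3)
  # in-plane offsets of the B and C stacking positions
  offB <- c(d / 2, d / (2 * sqrt(3)))
  offC <- c(0, d / sqrt(3))
  nz <- ceiling(1 / dz) + 1
  layers <- lapply(seq(-nz, nz), function(k) {
    z <- k * dz
    pos <- if (kind == "FCC") k %% 3 else k %% 2
    off <- switch(pos + 1, c(0, 0), offB, offC)
    L <- hex_layer(d, ox = off[1], oy = off[2])
    cbind(L, z)
  })
  V <- do.call(rbind, layers)
  V <- V[apply(abs(V) <= 1, 1, all), , drop = FALSE]
  if (nrow(V) < 2)
    stop("spacing too large: fewer than 2 lattice vertices in the cube")
  V <- V %*% t(rotation_z(rotation_deg))
  dimnames(V) <- NULL
  V
}

#' Columnar (COL) vertices
#'
#' Hexagonal layers all sharing the same in-plane offset, stacked with
#' one tenth of the FCC/HCP inter-layer distance, so blurred clouds form
#' vertical columns rather than separable spherical clusters.
#'
#' @param hex_spacing in-plane nearest-neighbor distance.
#' @param layer_gap vertical gap between layers (default the FCC inter-layer
#'   distance divided by 10).
#' @param rotation_deg rotation about the vertical (default 8).
#' @return K x 3 matrix of vertices.
#' @export
columnar_vertices <- function(hex_spacing = default_spacing(),
                              layer_gap = default_spacing() * sqrt(2 / 3) / 10,
                              rotation_deg = 8) {
  stopifnot(hex_spacing > 0, layer_gap > 0)
  L <- hex_layer(hex_spacing)
  zs <- seq(-1, 1, by = layer_gap)
  V <- do.call(rbind, lapply(zs, function(z) cbind(L, z)))
  V <- V[apply(abs(V) <= 1, 1, all), , drop = FALSE]
  V <- V %*% t(rotation_z(rotation_deg))
  dimnames(V) <- NULL
  V
}

#' Uniform random (RND) vertices
#'
#' @param n number of vertices (default 100, comparable to the lattice
#'   prototypes).
#' @return n x 3 matrix uniform in the cube.
#' @export
random_vertices <- function(n = 100) {
  matrix(stats::runif(3 * n, -1, 1), n, 3)
}

#' Blur vertices into a prototype point cloud
#'
#' Draws \code{points_per_vertex} points from an isotropic 3D normal
#' distribution around every vertex.
#'
#' @param vertices K x 3 matrix.
#' @param sigma isotropic blur scale (default 0.05, small enough that
#'   clusters stay well separable at the default spacing).
#' @param points_per_vertex points per vertex (default 500).
#' @param label structure label carried along (FCC/HCP/COL/RND).
#' @return object of class \code{prototype_cloud}: \code{points}
#'   ((K * points_per_vertex) x 3), \code{vertices}, \code{sigma},
#'   \code{label}.
#' @export
blur_vertices <- function(vertices, sigma = 0.05, points_per_vertex = 500,
                          label = "proto") {
  stopifnot(sigma > 0, nrow(vertices) >= 1)
  K <- nrow(vertices)
  P <- vertices[rep(seq_len(K), each = points_per_vertex), , drop = FALSE] +
    matrix(stats::rnorm(3 * K * points_per_vertex, sd = sigma),
           K * points_per_vertex, 3)
  structure(list(points = P, vertices = vertices, sigma = sigma,
                 label = label), class = "prototype_cloud")
}

#' Generate a labelled prototype cloud
#'
#' Convenience wrapper: vertices of the requested structure inside the cube,
#' blurred into a cloud.
#'
#' @param kind \code{"FCC"}, \code{"HCP"}, \code{"COL"} or \code{"RND"}.
#' @param spacing lattice spacing (ignored for RND).
#' @param sigma blur scale.
#' @param n_random RND vertex count.
#' @param points_per_vertex points per vertex.
#' @return a \code{prototype_cloud}.
#' @examples
#' pc <- prototype_cloud("FCC", points_per_vertex = 50)
#' nrow(pc$vertices)
#' @export
prototype_cloud <- function(kind = c("FCC", "HCP", "COL", "RND"),
                            spacing = default_spacing(), sigma = 0.05,
                            n_random = 100, points_per_vertex = 500) {
  kind <- match.arg(kind)
  V <- switch(kind,
              FCC = lattice_vertices("FCC", spacing),
              HCP = lattice_vertices("HCP", spacing),
              COL = columnar_vertices(spacing),
              RND = random_vertices(n_random))
  blur_vertices(V, sigma, points_per_vertex, label = kind)
}

#' @export
print.prototype_cloud <- function(x, ...) {
  cat(sprintf("<prototype_cloud> %s: %d vertices, %d points, sigma=%.3f\n",
              x$label, nrow(x$vertices), nrow(x$points), x$sigma))
  invisible(x)
}

#' Write a prototype cloud as columnar text
#'
#' @param cloud a \code{prototype_cloud}.
#' @param file path.
#' @export
write_prototype <- function(cloud, file) {
  df <- data.frame(label = cloud$label, x = cloud$points[, 1],
                   y = cloud$points[, 2], z = cloud$points[, 3])
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
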