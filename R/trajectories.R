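# Trajectory generators: bounded cube random walk, manifold walks with
# analytic surface normals, and the wandering reference-axis process.

#' Bounded random walk in the unit cube
#'
#' At every step the next position is drawn per axis uniformly from
#' \code{[max(x - dx_max, -1), min(x + dx_max, 1)]}, keeping the walk inside
#' \code{[-1, 1]^3} with per-axis step sizes bounded by \code{dx_max}.
#'
#' @param n_steps number of time steps T (default 1e5).
#' @param dx_max per-axis step bound (default 0.08).
#' @param init starting position (default random inside the cube).
#' @param dims number of walking dimensions (3 for volumetric, 2 for planar
#'   navigation; remaining coordinates are 0).
#' @param lower,upper per-axis bounds (defaults -1 and 1).
#' @return object of class \code{trajectory}: list with \code{positions}
#'   (T x 3), \code{dx_max}, \code{n_steps}.
#' @examples
#' tr <- cube_random_walk(1000)
#' range(tr$positions)
#' @export
cube_random_walk <- function(n_steps = 1e5, dx_max = 0.08, init = NULL,
                             dims = 3, lower = rep(-1, 3), upper = rep(1, 3)) {
  stopifnot(n_steps >= 1, dx_max > 0, dx_max < 2, dims %in% 1:3)
  X <- matrix(0, n_steps, 3)
  x <- if (is.null(init)) {
    c(stats::runif(dims, lower[seq_len(dims)], upper[seq_len(dims)]),
      rep(0, 3 - dims))
  } else {
    stopifnot(length(init) == 3)
    init
  }
  X[1, ] <- x
  U <- matrix(stats::runif((n_steps - 1) * dims), n_steps - 1, dims)
  lo <- lower[seq_len(dims)]
  hi <- upper[seq_len(dims)]
  for (t in seq_len(n_steps - 1)) {
    a <- pmax(x[seq_len(dims)] - dx_max, lo)
    b <- pmin(x[seq_len(dims)] + dx_max, hi)
    x[seq_len(dims)] <- a + U[t, ] * (b - a)
    X[t + 1, ] <- x
  }
  structure(list(positions = X, dx_max = dx_max, n_steps = n_steps),
            class = "trajectory")
}

#' Sum-of-Gaussian-bumps surface
#'
#' Height function used for manifold navigation demos: four isotropic
#' Gaussian bumps. Returns a function of (x, y) carrying an analytic
#' gradient as the \code{"gradient"} attribute.
#'
#' @param centers k x 2 matrix of bump centers.
#' @param amp bump amplitudes (recycled).
#' @param sigma bump widths (recycled).
#' @return function (x, y) -> z with a gradient attribute.
#' @export
gaussian_bump_surface <- function(centers = rbind(c(-0.5, -0.5), c(-0.5, 0.5),
                                                  c(0.5, -0.5), c(0.5, 0.5)),
                                  amp = c(0.5, -0.4, -0.45, 0.55),
                                  sigma = 0.3) {
  amp <- rep_len(amp, nrow(centers))
  sigma <- rep_len(sigma, nrow(centers))
  f <- function(x, y) {
    z <- 0
    for (k in seq_len(nrow(centers))) {
      z <- z + amp[k] * exp(-((x - centers[k, 1])^2 +
                              (y - centers[k, 2])^2) / (2 * sigma[k]^2))
    }
    z
  }
  grad <- function(x, y) {
    gx <- 0; gy <- 0
    for (k in seq_len(nrow(centers))) {
      e <- amp[k] * exp(-((x - centers[k, 1])^2 +
                          (y - centers[k, 2])^2) / (2 * sigma[k]^2))
      gx <- gx - e * (x - centers[k, 1]) / sigma[k]^2
      gy <- gy - e * (y - centers[k, 2]) / sigma[k]^2
    }
    cbind(gx, gy)
  }
  attr(f, "gradient") <- grad
  f
}

#' Random walk on a manifold
#'
#' The planar coordinates follow the bounded 2D random walk; the altitude is
#' the surface height at each position. Unit surface normals (from the
#' analytic or finite-difference gradient) are attached for plane-dependent
#' integration.
#'
#' @param n_steps number of steps.
#' @param surface_fn function (x, y) -> z, e.g.
#'   \code{\link{gaussian_bump_surface}}.
#' @param dx_max per-axis planar step bound.
#' @param init optional starting position (x, y used).
#' @return a \code{trajectory} whose positions lie on the surface, with a
#'   \code{normals} field (T x 3 unit vectors).
#' @export
manifold_walk <- function(n_steps = 1e5, surface_fn = gaussian_bump_surface(),
                          dx_max = 0.08, init = NULL) {
  tr <- cube_random_walk(n_steps, dx_max, init = init, dims = 2)
  x <- tr$positions[, 1]
  y <- tr$positions[, 2]
  z <- surface_fn(x, y)
  if (any(abs(z) > 1)) {
    warning("surface heights outside [-1, 1] clipped")
    z <- pmin(1, pmax(-1, z))
  }
  tr$positions[, 3] <- z
  grad <- attr(surface_fn, "gradient")
  g <- if (is.null(grad)) {
    h <- 1e-5
    cbind((surface_fn(x + h, y) - surface_fn(x - h, y)) / (2 * h),
          (surface_fn(x, y + h) - surface_fn(x, y - h)) / (2 * h))
  } else {
    grad(x, y)
  }
  n <- cbind(-g[, 1], -g[, 2], 1)
  tr$normals <- n / sqrt(rowSums(n^2))
  tr$surface_fn <- surface_fn
  class(tr) <- c("manifold_trajectory", "trajectory")
  tr
}

#' Wandering reference-axis process
#'
#' One true axis per refresh epoch: at every refresh the axis is redrawn from
#' vMF(previous axis, \code{kappa_traj}); between refreshes it is constant.
#' With \code{wander = FALSE} every draw is centered on \code{center}
#' instead.
#'
#' @param n_epochs number of refresh epochs.
#' @param kappa_traj concentration of the axis redraw (default 200).
#' @param center initial (and, if \code{wander = FALSE}, fixed) center,
#'   default the vertical.
#' @param wander center each draw on the previous axis (default TRUE).
#' @return n_epochs x 3 matrix of unit axes.
#' @export
trajectory_axes <- function(n_epochs, kappa_traj = 200, center = c(0, 0, 1),
                            wander = TRUE) {
  stopifnot(n_epochs >= 1)
  U <- matrix(0, n_epochs, 3)
  prev <- unit(center)
  for (e in seq_len(n_epochs)) {
    prev <- drop(rvmf(1, if (wander) prev else center, kappa_traj))
    U[e, ] <- prev
  }
  U
}

#' Axis at one step of the wandering process
#'
#' Refresh-interval form of \code{\link{trajectory_axes}}: at multiples of
#' tau the axis is redrawn from vMF(previous, kappa_traj), otherwise it is
#' unchanged.
#'
#' @param t integer step (>= 0).
#' @param previous_u current axis.
#' @param tau refresh interval.
#' @param kappa_traj redraw concentration.
#' @return unit length-3 axis.
#' @export
trajectory_axis <- function(t, previous_u, tau, kappa_traj = 200) {
  stopifnot(tau >= 1)
  if (t %% tau == 0) drop(rvmf(1, previous_u, kappa_traj)) else previous_u
}

#' Write / read a trajectory as columnar text
#'
#' @param tr a \code{trajectory} (or T x 3 matrix).
#' @param file path.
#' @return \code{read_trajectory} returns a \code{trajectory}.
#' @export
write_trajectory <- function(tr, file) {
  X <- if (inherits(tr, "trajectory")) tr$positions else as.matrix(tr)
  df <- data.frame(t = seq_len(nrow(X)), x = X[, 1], y = X[, 2], z = X[, 3])
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  X <- as.matrix(df[, c("x", "y", "z")])
  dimnames(X) <- NULL
  structure(list(positions = X, dx_max = NA_real_, n_steps = nrow(X)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d steps, dx_max = %s, bounds [%.2f, %.2f]\n",
              x$n_steps, format(x$dx_max), min(x$positions),
              max(x$positions)))
  invisible(x)
}
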