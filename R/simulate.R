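# Trial-level simulation engine: trajectory -> perceived plane axes ->
# effective displacements -> unitary phase integration -> Poisson spikes.
#
# All navigation modes reduce to a per-step linear map G applied to the raw
# displacement before it reaches the network:
#   planar_2d          G = P_z                      (intrinsic 2D coordinates)
#   projected          G = M(xi) P_z M(u_true)^T    (planar part, 3D-anchored)
#   manifold           G = P_z M(xi)^T              (tangent-frame coordinates)
#   volumetric         G = M(xi) M(u_true)^T        (full plane-dependent 3D)
#   plane_independent  G = I                        (no plane perception)
# where M(.) is the 180-degree plane rotation and P_z zeroes the vertical.
# The cylindrical components (r, phi, b) are decomposed with respect to the
# true axis (the animal knows its egocentric motion); the allocentric
# reconstruction uses the perceived axis xi, so perception error bends the
# integrated path while accurate perception (kappa = Inf) integrates the true
# displacement exactly.

# apply the symmetric involution M(u) row-wise: y -> 2 z (z.y)/(z.z) - y
apply_plane_rotation_rows <- function(Urows, Y) {
  Z <- Urows
  Z[, 3] <- Z[, 3] + 1
  Z <- Z / 2
  zz <- rowSums(Z^2)
  bad <- zz < 1e-12
  if (any(bad)) {
    # degenerate antiparallel axes: nudge 1e-6 rad toward +e_x
    eps <- 1e-6
    Z[bad, ] <- matrix(c(sin(eps), 0, -cos(eps) + 1) / 2, sum(bad), 3,
                       byrow = TRUE)
    zz[bad] <- rowSums(Z[bad, , drop = FALSE]^2)
  }
  s <- rowSums(Z * Y) / zz
  2 * Z * s - Y
}

#' Simulate one grid-cell trial
#'
#' Runs the plane-dependent grid network along a trajectory under a given
#' navigation mode and perception condition, and emits Poisson spikes from
#' the logistic rate map.
#'
#' @param trajectory a \code{\link{cube_random_walk}} /
#'   \code{\link{manifold_walk}} result or a T x 3 position matrix.
#' @param mode navigation mode: \code{"volumetric"} (plane-dependent 3D,
#'   the sweep condition), \code{"planar"}, \code{"projected"}
#'   (multilayered), \code{"manifold"}, or \code{"plane_independent"}.
#' @param kappa perceptual certainty (\code{Inf} = accurate perception).
#' @param tau refresh interval in steps.
#' @param consts \code{\link{grid_constants}}.
#' @param sparams \code{\link{spike_params}}.
#' @param axes optional per-epoch true axes (n_epochs x 3). Defaults: the
#'   wandering vMF axis process (volumetric), the vertical (projected), or
#'   surface normals at refresh steps (manifold).
#' @param kappa_traj concentration of the wandering-axis redraw (default
#'   200).
#' @param seed optional seed for perception and spiking randomness.
#' @param keep_activity retain the complex activity history (default TRUE).
#' @return object of class \code{grid_trial}: positions (T x 3), spike
#'   counts (T x 4), normalized activity, condition parameters.
#' @examples
#' tr <- cube_random_walk(2000)
#' trial <- simulate_trial(tr, "volumetric", kappa = Inf, tau = 10)
#' summary(trial)
#' @export
simulate_trial <- function(trajectory,
                           mode = c("volumetric", "planar", "projected",
                                    "manifold", "plane_independent"),
                           kappa = Inf, tau = 10,
                           consts = grid_constants(),
                           sparams = spike_params(),
                           axes = NULL, kappa_traj = 200, seed = NULL,
                           keep_activity = TRUE) {
  mode <- match.arg(mode)
  X <- if (inherits(trajectory, "trajectory")) trajectory$positions
       else as.matrix(trajectory)
  n_steps <- nrow(X)
  stopifnot(n_steps >= 2, tau >= 1)
  if (!is.null(seed)) set.seed(seed)
  dX <- diff(X)
  n <- nrow(dX)
  epoch <- (seq_len(n) - 1) %/% tau + 1L
  n_epochs <- max(epoch)

  P <- switch(mode,
    planar = {
      p <- dX
      p[, 3] <- 0
      p
    },
    plane_independent = dX,
    projected = {
      u_true <- axes %||% matrix(c(0, 0, 1), n_epochs, 3, byrow = TRUE)
      xi <- perceive_epochs(u_true, kappa)
      Y <- apply_plane_rotation_rows(u_true[epoch, , drop = FALSE], dX)
      Y[, 3] <- 0
      apply_plane_rotation_rows(xi[epoch, , drop = FALSE], Y)
    },
    manifold = {
      u_true <- axes
      if (is.null(u_true)) {
        normals <- trajectory$normals
        if (is.null(normals)) stop("manifold mode needs surface normals")
        # normal at the first step of each epoch
        u_true <- normals[((seq_len(n_epochs) - 1L) * tau + 1L), ,
                          drop = FALSE]
      }
      xi <- perceive_epochs(u_true, kappa)
      Y <- apply_plane_rotation_rows(xi[epoch, , drop = FALSE], dX)
      Y[, 3] <- 0
      Y
    },
    volumetric = {
      u_true <- axes %||% trajectory_axes(n_epochs, kappa_traj)
      xi <- perceive_epochs(u_true, kappa)
      Y <- apply_plane_rotation_rows(u_true[epoch, , drop = FALSE], dX)
      apply_plane_rotation_rows(xi[epoch, , drop = FALSE], Y)
    })

  A <- rbind(matrix(drop(consts$U %*% consts$phase0), 1, 4),
             integrate_activity(P, consts))
  a_prime <- suppressWarnings(normalized_activity(A))
  rate <- spike_rate(a_prime, sparams)
  counts <- matrix(stats::rpois(length(rate), rate), n_steps, 4)

  structure(list(positions = X, counts = counts, activity = if (keep_activity) A,
                 a_prime = a_prime, mode = mode, kappa = kappa, tau = tau,
                 consts = consts, sparams = sparams, seed = seed),
            class = "grid_trial")
}

#' Spike positions of one neuron
#'
#' @param trial a \code{grid_trial}.
#' @param neuron neuron index 1..4.
#' @return matrix of 3D positions, one row per spike (steps with k spikes
#'   contribute k rows).
#' @export
spike_positions <- function(trial, neuron) {
  stopifnot(inherits(trial, "grid_trial"), neuron %in% 1:4)
  k <- trial$counts[, neuron]
  trial$positions[rep(seq_along(k), k), , drop = FALSE]
}

#' Spike train as a columnar table
#'
#' @param trial a \code{grid_trial}.
#' @return data.frame with columns neuron, t, x, y, z (one row per spike).
#' @export
as_spike_train <- function(trial) {
  stopifnot(inherits(trial, "grid_trial"))
  out <- lapply(1:4, function(j) {
    k <- trial$counts[, j]
    idx <- rep(which(k > 0), k[k > 0])
    if (!length(idx)) return(NULL)
    data.frame(neuron = j, t = idx, x = trial$positions[idx, 1],
               y = trial$positions[idx, 2], z = trial$positions[idx, 3])
  })
  do.call(rbind, out)
}

#' @rdname as_spike_train
#' @param file path for the tab-separated spike table.
#' @export
write_spikes <- function(trial, file) {
  utils::write.table(as_spike_train(trial), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a spike table written by \code{write_spikes}
#'
#' @param file path.
#' @return data.frame with columns neuron, t, x, y, z.
#' @export
read_spikes <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t")
}

#' @export
print.grid_trial <- function(x, ...) {
  cat(sprintf("<grid_trial> mode=%s kappa=%s tau=%d, %d steps\n",
              x$mode, format(x$kappa), x$tau, nrow(x$positions)))
  cat("  spikes per neuron:", paste(colSums(x$counts), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.grid_trial <- function(object, ...) {
  ns <- colSums(object$counts)
  out <- list(mode = object$mode, kappa = object$kappa, tau = object$tau,
              n_steps = nrow(object$positions), n_spikes = ns,
              mean_rate = ns / nrow(object$positions))
  class(out) <- "summary.grid_trial"
  out
}

#' @export
print.summary.grid_trial <- function(x, ...) {
  cat(sprintf("grid trial: mode=%s, kappa=%s, tau=%d, T=%d\n", x$mode,
              format(x$kappa), x$tau, x$n_steps))
  m <- rbind(spikes = x$n_spikes, `rate/step` = round(x$mean_rate, 4))
  colnames(m) <- paste0("neuron", 1:4)
  print(m)
  invisible(x)
}

#' @export
plot.grid_trial <- function(x, neuron = 1, ...) {
  sp <- spike_positions(x, neuron)
  if (!nrow(sp)) {
    warning("no spikes to plot")
    return(invisible(x))
  }
  cols <- grDevices::hcl.colors(10, "viridis")
  zi <- cut(sp[, 3], breaks = seq(-1, 1, length.out = 11),
            include.lowest = TRUE)
  graphics::plot(sp[, 1], sp[, 2], col = cols[as.integer(zi)], pch = 16,
                 cex = 0.4, xlab = "x", ylab = "y",
                 main = sprintf("neuron %d spikes (color = z)", neuron), ...)
  invisible(x)
}
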