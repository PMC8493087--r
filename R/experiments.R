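# Simulation campaigns: the (kappa, tau) sweep over plane-dependent trials
# and single-condition navigation-mode demos.

#' Sweep configuration
#'
#' Defaults reproduce the full simulation campaign: 8 cube random-walk
#' trajectories of 1e5 steps, perceptual certainty kappa in
#' {300, 400, 500, 600, Inf} and refresh interval tau over 11 values from 1
#' to 1e5, 4 neurons per network, i.e. 32 samples per (kappa, tau) cell.
#' Reduced configurations (fewer trajectories, shorter trials, subsets of
#' kappa/tau) keep the same output schema.
#'
#' @param kappas perceptual certainty values.
#' @param taus refresh intervals (steps).
#' @param n_trajectories number of shared trajectories.
#' @param n_steps steps per trajectory.
#' @param b0 grid scale.
#' @param dx_max walk step bound.
#' @param kappa_traj wandering-axis concentration.
#' @param n_shuffles shuffles for Z-scoring.
#' @param n_bins rate-map bins per axis.
#' @param mode navigation mode of the sweep trials.
#' @param seed master seed; every trajectory/condition/stage derives its own
#'   substream via \code{\link{substream_seed}}.
#' @return object of class \code{sweep_config}.
#' @export
sweep_config <- function(kappas = c(300, 400, 500, 600, Inf),
                         taus = c(1, 5, 10, 50, 1e2, 5e2, 1e3, 5e3, 1e4,
                                  5e4, 1e5),
                         n_trajectories = 8, n_steps = 1e5, b0 = 10,
                         dx_max = 0.08, kappa_traj = 200, n_shuffles = 50,
                         n_bins = 20, mode = "volumetric", seed = 1) {
  stopifnot(all(kappas > 0), all(taus >= 1), n_trajectories >= 1,
            n_steps >= 2)
  structure(list(kappas = kappas, taus = taus,
                 n_trajectories = n_trajectories, n_steps = n_steps,
                 b0 = b0, dx_max = dx_max, kappa_traj = kappa_traj,
                 n_shuffles = n_shuffles, n_bins = n_bins, mode = mode,
                 seed = seed),
            class = "sweep_config")
}

#' Run a (kappa, tau) sweep
#'
#' Generates the shared trajectories, then for every trajectory and
#' (kappa, tau) condition simulates the plane-dependent network, emits
#' Poisson spikes, and computes per-neuron metrics: spike count, spatial
#' information and sparsity index with shuffle Z-scores, and (optionally)
#' FCC/HCP/COL structure scores. Fully deterministic given the master seed.
#'
#' @param config a \code{\link{sweep_config}}.
#' @param calibration optional \code{\link{structure_calibration}}; when
#'   supplied, chi scores are computed per trial.
#' @param fields also run field detection and median inter-field distance
#'   per trial (default FALSE; the costliest metric).
#' @param progress print one line per trial (default FALSE).
#' @return data.frame of class \code{grid_sweep}: one row per
#'   (trajectory, kappa, tau, neuron).
#' @export
run_sweep <- function(config = sweep_config(), calibration = NULL,
                      fields = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  consts <- grid_constants(config$b0)
  trajs <- lapply(seq_len(config$n_trajectories), function(i) {
    set.seed(substream_seed(config$seed, 1, i))
    cube_random_walk(config$n_steps, config$dx_max)
  })
  rows <- list()
  for (i in seq_len(config$n_trajectories)) {
    for (ki in seq_along(config$kappas)) {
      for (ti in seq_along(config$taus)) {
        kappa <- config$kappas[ki]
        tau <- config$taus[ti]
        trial <- simulate_trial(trajs[[i]], config$mode, kappa = kappa,
                                tau = tau, consts = consts,
                                kappa_traj = config$kappa_traj,
                                seed = substream_seed(config$seed, 2, i,
                                                      ki, ti),
                                keep_activity = FALSE)
        set.seed(substream_seed(config$seed, 3, i, ki, ti))
        for (j in 1:4) {
          spk <- trial$counts[, j]
          z <- shuffle_zscores(trial$positions, spk,
                               metrics = list(si = spatial_information,
                                              sparsity = sparsity_index),
                               n_shuffles = config$n_shuffles,
                               n_bins = config$n_bins)
          map <- bin_rate_map(trial$positions, spk, config$n_bins)
          row <- data.frame(trajectory = i, kappa = kappa, tau = tau,
                            neuron = j, n_spikes = sum(spk),
                            si = spatial_information(map),
                            z_si = z[["si"]],
                            sparsity = sparsity_index(map),
                            z_sparsity = z[["sparsity"]],
                            chi_fcc = NA_real_, chi_hcp = NA_real_,
                            chi_col = NA_real_, n_fields = NA_integer_,
                            median_ifd = NA_real_)
          if (!is.null(calibration)) {
            ac <- autocorrelogram_3d(spike_positions(trial, j),
                                     n_bins = config$n_bins)
            chi <- structure_scores(ac, calibration)$chi
            row$chi_fcc <- chi[["FCC"]]
            row$chi_hcp <- chi[["HCP"]]
            row$chi_col <- chi[["COL"]]
          }
          if (fields) {
            fs <- suppressWarnings(detect_fields(spike_positions(trial, j)))
            row$n_fields <- nrow(fs$centers)
            ifd <- interfield_distances(fs)
            row$median_ifd <- if (length(ifd)) stats::median(ifd) else
              NA_real_
          }
          rows[[length(rows) + 1]] <- row
        }
        if (progress)
          message(sprintf("trajectory %d kappa %s tau %g done", i,
                          format(kappa), tau))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("grid_sweep", class(out))
  out
}

#' @export
summary.grid_sweep <- function(object, ...) {
  agg <- stats::aggregate(cbind(z_si, z_sparsity) ~ kappa + tau,
                          data = object, FUN = mean)
  agg[order(agg$kappa, agg$tau), ]
}

#' Single-condition navigation-mode demo
#'
#' Simulates one trial in the requested navigation mode and summarizes its
#' firing fields: planar/manifold modes report the hexagonal grid score of
#' the horizontal projection; volumetric and plane-independent modes report
#' field counts and (with a calibration) structure scores.
#'
#' @param mode \code{"planar"}, \code{"manifold"}, \code{"multilayered"},
#'   \code{"volumetric"} or \code{"plane_independent"}.
#' @param kappa,tau perception condition (defaults: accurate perception,
#'   tau = 10).
#' @param n_steps trial length.
#' @param calibration optional \code{\link{structure_calibration}} for chi
#'   scores.
#' @param seed seed.
#' @return list with the \code{grid_trial} and a per-neuron summary
#'   data.frame.
#' @export
run_mode_demo <- function(mode = c("planar", "manifold", "multilayered",
                                   "volumetric", "plane_independent"),
                          kappa = Inf, tau = 10, n_steps = 1e5,
                          calibration = NULL, seed = 1) {
  mode <- match.arg(mode)
  set.seed(substream_seed(seed, 4))
  tr <- switch(mode,
               planar = cube_random_walk(n_steps, dims = 2),
               manifold = manifold_walk(n_steps),
               multilayered = cube_random_walk(n_steps),
               cube_random_walk(n_steps))
  sim_mode <- switch(mode, planar = "planar", manifold = "manifold",
                     multilayered = "projected", volumetric = "volumetric",
                     plane_independent = "plane_independent")
  trial <- simulate_trial(tr, sim_mode, kappa = kappa, tau = tau,
                          seed = substream_seed(seed, 5))
  neurons <- if (sim_mode %in% c("planar", "manifold")) 1:3 else 1:4
  rows <- lapply(neurons, function(j) {
    sp <- spike_positions(trial, j)
    g <- gridness_2d(sp[, 1:2, drop = FALSE])
    row <- data.frame(neuron = j, n_spikes = nrow(sp),
                      hex_2d = g$hex, chi_fcc = NA_real_,
                      chi_hcp = NA_real_, chi_col = NA_real_)
    if (!is.null(calibration) && sim_mode %in% c("volumetric",
                                                 "plane_independent")) {
      chi <- structure_scores(autocorrelogram_3d(sp), calibration)$chi
      row$chi_fcc <- chi[["FCC"]]
      row$chi_hcp <- chi[["HCP"]]
      row$chi_col <- chi[["COL"]]
    }
    row
  })
  list(trial = trial, summary = do.call(rbind, rows))
}
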