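# Mode-switching demonstration: navigation on a half-flat, half-tilted
# arena, alternating Flat -> Slope -> Flat -> Slope. The two regions use
# different navigation planes and unequal grid scales, so re-entering a
# region shifts the grid phase; the "virtual walk" replays the displacement
# from the stored exit state in 100 sub-updates to restore it.

#' Half-flat, half-tilted arena
#'
#' The square arena is split at x = 0: for x < 0 the floor is flat (z = 0),
#' for x >= 0 it rises with the given tilt. Each region runs its own grid
#' scale b0; the flat region is navigated as intrinsically planar, the
#' slope in the tangent frame of its surface normal.
#'
#' @param tilt_deg slope tilt angle (default 30).
#' @param b0_flat,b0_slope per-region grid scales (default 10 and 12.5; the
#'   unequal scales stand in for the differing sensory context).
#' @param min_steps,max_steps visit-duration bounds in steps (durations are
#'   drawn uniformly; default 5000-7000).
#' @param dx_max per-axis step bound of the walk.
#' @return object of class \code{switch_arena}.
#' @export
switch_arena <- function(tilt_deg = 30, b0_flat = 10, b0_slope = 12.5,
                         min_steps = 5000, max_steps = 7000,
                         dx_max = 0.08) {
  if (min_steps < 5000)
    warning("visits shorter than 5000 steps give unstable field estimates")
  structure(list(tilt_deg = tilt_deg, b0_flat = b0_flat,
                 b0_slope = b0_slope, min_steps = min_steps,
                 max_steps = max_steps, dx_max = dx_max,
                 normal_slope = unit(c(-tan(tilt_deg * pi / 180), 0, 1))),
            class = "switch_arena")
}

arena_height <- function(arena, x) {
  ifelse(x < 0, 0, tan(arena$tilt_deg * pi / 180) * x)
}

# tangent-frame planar phase increments for a block of 3D displacements
region_increments <- function(arena, region, dX3, consts) {
  b0 <- if (region == "flat") arena$b0_flat else arena$b0_slope
  B <- consts$B / consts$b0 * b0
  if (region == "flat") {
    P <- dX3
    P[, 3] <- 0
  } else {
    n <- arena$normal_slope
    P <- apply_plane_rotation_rows(matrix(n, nrow(dX3), 3, byrow = TRUE),
                                   dX3)
    P[, 3] <- 0
  }
  P %*% t(B)
}

#' Virtual-walk phase restoration
#'
#' Replays the displacement from a stored exit state in \code{n} equal
#' sub-updates through the region's own basis. Because all sub-updates
#' commute, the result is independent of \code{n}.
#'
#' @param c_state complex 4-vector of eigen-coordinates at the stored exit.
#' @param displacement length-3 displacement from the exit position to the
#'   re-entry position.
#' @param arena a \code{\link{switch_arena}}.
#' @param region \code{"flat"} or \code{"slope"}.
#' @param consts \code{\link{grid_constants}} (scale is replaced by the
#'   region's b0).
#' @param n number of sub-updates (default 100).
#' @return restored complex 4-vector.
#' @export
virtual_walk <- function(c_state, displacement, arena, region,
                         consts = grid_constants(), n = 100) {
  step <- matrix(displacement / n, 1, 3)
  dq <- drop(region_increments(arena, region, step, consts))
  for (i in seq_len(n)) c_state <- c_state * exp(1i * dq)
  c_state
}

#' Run the mode-switching experiment
#'
#' Simulates four visits (Flat, Slope, Flat, Slope) with a continuous
#' bounded walk: within a visit the walk is confined to its half-arena, and
#' at the end of a visit the animal walks to the border and crosses. Grid
#' phases integrate throughout; with \code{restore = TRUE}, re-entering a
#' previously visited region resets the eigen-coordinates to the stored
#' exit state followed by a 100-step virtual walk along the exit-to-entry
#' displacement.
#'
#' @param arena a \code{\link{switch_arena}}.
#' @param restore apply the virtual-walk phase restoration (default TRUE).
#' @param consts \code{\link{grid_constants}} (per-region b0 is substituted).
#' @param sparams \code{\link{spike_params}}.
#' @param seed optional seed.
#' @return object of class \code{switch_experiment}: positions, spike
#'   counts, per-visit table (region, start, end), parameters.
#' @export
run_switch_experiment <- function(arena = switch_arena(), restore = TRUE,
                                  consts = grid_constants(),
                                  sparams = spike_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regions <- c("flat", "slope", "flat", "slope")
  durations <- floor(stats::runif(4, arena$min_steps, arena$max_steps + 1))
  dx_max <- arena$dx_max

  pos_list <- list()
  visit <- data.frame(visit = integer(0), region = character(0),
                      start = integer(0), end = integer(0))
  xy <- c(stats::runif(1, -1, 0), stats::runif(1, -1, 1))  # start on flat
  t_total <- 0L
  for (v in seq_along(regions)) {
    reg <- regions[v]
    xlim <- if (reg == "flat") c(-1, 0) else c(0, 1)
    # nudge the entry point into the region interior
    xy[1] <- min(max(xy[1], xlim[1]), xlim[2])
    steps <- matrix(0, durations[v], 2)
    for (t in seq_len(durations[v])) {
      a <- pmax(xy - dx_max, c(xlim[1], -1))
      b <- pmin(xy + dx_max, c(xlim[2], 1))
      xy <- stats::runif(2, a, b)
      steps[t, ] <- xy
    }
    # transit: walk straight to the border at x = 0 to cross over
    if (v < length(regions)) {
      n_tr <- ceiling(abs(xy[1]) / dx_max)
      if (n_tr > 0) {
        tx <- seq(xy[1], 0, length.out = n_tr + 1)[-1]
        steps <- rbind(steps, cbind(tx, xy[2]))
        xy <- c(0, xy[2])
      }
    }
    pos_list[[v]] <- steps
    visit <- rbind(visit, data.frame(visit = v, region = reg,
                                     start = t_total + 1L,
                                     end = t_total + nrow(steps)))
    t_total <- t_total + nrow(steps)
  }
  XY <- do.call(rbind, pos_list)
  X3 <- cbind(XY, arena_height(arena, XY[, 1]))
  n_steps <- nrow(X3)
  dX3 <- diff(X3)
  # classify steps by midpoint so border-touching steps use the basis of
  # the floor they actually traverse
  mid_x <- (XY[-nrow(XY), 1] + XY[-1, 1]) / 2
  region_of_step <- ifelse(mid_x < 0, "flat", "slope")

  # phase increments per step, per region basis
  Q <- matrix(0, n_steps - 1, 4)
  for (reg in c("flat", "slope")) {
    sel <- region_of_step == reg
    if (any(sel))
      Q[sel, ] <- region_increments(arena, reg, dX3[sel, , drop = FALSE],
                                    consts)
  }

  # integrate phases with optional restoration at re-entries
  phases <- matrix(0, n_steps, 4)
  phases[1, ] <- Arg(consts$phase0)
  stored <- list()  # per region: list(c = phases, pos = exit position)
  cur <- phases[1, ]
  restored_exact <- c()
  for (v in seq_along(regions)) {
    reg <- regions[v]
    i0 <- visit$start[v]
    i1 <- visit$end[v]
    if (restore && !is.null(stored[[reg]])) {
      entry_pos <- X3[i0, ]
      c_new <- virtual_walk(exp(1i * stored[[reg]]$c),
                            entry_pos - stored[[reg]]$pos, arena, reg,
                            consts)
      cur <- Arg(c_new)
      restored_exact <- c(restored_exact, v)
    }
    phases[i0, ] <- cur
    if (i1 > i0) {
      seg <- Q[i0:(i1 - 1), , drop = FALSE]
      phases[(i0 + 1):i1, ] <- matrix(cur, i1 - i0, 4, byrow = TRUE) +
        apply(seg, 2, cumsum)
      cur <- phases[i1, ]
    }
    stored[[reg]] <- list(c = cur, pos = X3[i1, ])
  }

  C <- exp(1i * phases)
  A <- C %*% t(consts$U)
  a_prime <- suppressWarnings(normalized_activity(A))
  counts <- matrix(stats::rpois(length(a_prime),
                                spike_rate(a_prime, sparams)),
                   n_steps, 4)
  structure(list(positions = X3, counts = counts, visits = visit,
                 restore = restore, arena = arena, consts = consts,
                 seed = seed),
            class = "switch_experiment")
}

#' Compare firing fields between the two visits of a region
#'
#' Detects planar firing fields (x, y) per neuron for the first and second
#' visit of a region and matches every second-visit field to its nearest
#' first-visit field. Without phase restoration the matched displacements
#' share a common nonzero translation; with restoration they fall within a
#' field radius of zero.
#'
#' @param exp a \code{\link{run_switch_experiment}} result.
#' @param region \code{"flat"} or \code{"slope"}.
#' @param neurons neurons to analyze (default 1:3; the fourth unit has no
#'   planar wavevector and is excluded).
#' @param bandwidth mean-shift bandwidth (default 0.25).
#' @return data.frame with one row per matched field: neuron, displacement
#'   components, distance, and the first-visit field radius.
#' @export
compare_switch_fields <- function(exp, region = "flat", neurons = 1:3,
                                  bandwidth = 0.25) {
  stopifnot(inherits(exp, "switch_experiment"))
  vv <- exp$visits[exp$visits$region == region, ]
  stopifnot(nrow(vv) >= 2)
  out <- list()
  for (j in neurons) {
    get_fields <- function(v) {
      idx <- vv$start[v]:vv$end[v]
      k <- exp$counts[idx, j]
      pts <- exp$positions[idx, 1:2, drop = FALSE][rep(seq_along(k), k), ,
                                                   drop = FALSE]
      if (nrow(pts) < 30) return(NULL)
      f <- suppressWarnings(detect_fields(pts, bandwidth = bandwidth,
                                          bounds = NULL))
      # drop centers hugging the outer arena walls
      keep <- abs(f$centers[, 1]) < 0.95 & abs(f$centers[, 2]) < 0.95
      f$centers <- f$centers[keep, , drop = FALSE]
      f$radii <- f$radii[keep]
      f
    }
    f1 <- get_fields(1)
    f2 <- get_fields(2)
    if (is.null(f1) || is.null(f2) || nrow(f1$centers) == 0 ||
        nrow(f2$centers) == 0) next
    for (k in seq_len(nrow(f2$centers))) {
      d2 <- rowSums(sweep(f1$centers, 2, f2$centers[k, ], "-")^2)
      i <- which.min(d2)
      out[[length(out) + 1]] <- data.frame(
        neuron = j,
        dx = f2$centers[k, 1] - f1$centers[i, 1],
        dy = f2$centers[k, 2] - f1$centers[i, 2],
        dist = sqrt(d2[i]),
        radius = f1$radii[i])
    }
  }
  do.call(rbind, out) %||% data.frame(neuron = integer(0), dx = numeric(0),
                                      dy = numeric(0), dist = numeric(0),
                                      radius = numeric(0))
}

#' Cross-correlation of repeat-visit rate maps
#'
#' Builds planar (x, y) rate maps of the two visits of a region and
#' cross-correlates them (Pearson, per offset, over overlapping visited
#' bins). The joint peak over neurons gives the common field translation
#' between visits: nonzero without phase restoration, near zero with it.
#'
#' @param exp a \code{\link{run_switch_experiment}} result.
#' @param region \code{"flat"} or \code{"slope"}.
#' @param neurons neurons to pool (default 1:3).
#' @param n_bins bins per axis over [-1, 1].
#' @param max_shift largest offset considered, in bins (default 8).
#' @return list: \code{offset} (length-2, arena units) of the joint
#'   correlation peak, \code{corr_at_peak}, \code{corr_at_zero} (means over
#'   neurons), and the per-neuron correlation at the joint peak.
#' @export
switch_map_correlation <- function(exp, region = "flat", neurons = 1:3,
                                   n_bins = 25, max_shift = 8) {
  stopifnot(inherits(exp, "switch_experiment"))
  vv <- exp$visits[exp$visits$region == region, ]
  stopifnot(nrow(vv) >= 2)
  bw <- 2 / n_bins
  cors <- list()
  for (j in neurons) {
    maps <- lapply(1:2, function(v) {
      idx <- vv$start[v]:vv$end[v]
      xy <- exp$positions[idx, 1:2, drop = FALSE]
      k <- exp$counts[idx, j]
      b <- pmin(pmax(floor((xy + 1) / 2 * n_bins), 0), n_bins - 1)
      flat <- as.integer(b[, 1] + n_bins * b[, 2] + 1)
      occ <- tabulate(flat, nbins = n_bins^2)
      spk <- tabulate(rep(flat, k), nbins = n_bins^2)
      list(rate = array(ifelse(occ > 0, spk / pmax(occ, 1), 0),
                        c(n_bins, n_bins)),
           mask = array(occ > 0, c(n_bins, n_bins)))
    })
    w1 <- maps[[1]]$mask * 1
    w2 <- maps[[2]]$mask * 1
    x1 <- maps[[1]]$rate * w1
    x2 <- maps[[2]]$rate * w2
    n_ov <- round(xcorr3_sums(w1, w2))
    sx <- xcorr3_sums(x1, w2)
    sy <- xcorr3_sums(w1, x2)
    sxx <- xcorr3_sums(x1^2, w2)
    syy <- xcorr3_sums(w1, x2^2)
    sxy <- xcorr3_sums(x1, x2)
    num <- n_ov * sxy - sx * sy
    den2 <- pmax(n_ov * sxx - sx^2, 0) * pmax(n_ov * syy - sy^2, 0)
    cc <- num / sqrt(den2)
    cc[n_ov < 20 | den2 <= 0] <- NA_real_
    cors[[length(cors) + 1]] <- cc
  }
  ctr <- n_bins
  win <- (ctr - max_shift):(ctr + max_shift)
  pooled <- Reduce(`+`, cors) / length(cors)
  sub <- pooled[win, win]
  pk <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
  off_bins <- c(win[pk[1]], win[pk[2]]) - ctr
  per_neuron <- vapply(cors, function(cc)
    cc[win[pk[1]], win[pk[2]]], numeric(1))
  list(offset = off_bins * bw,
       corr_at_peak = max(sub, na.rm = TRUE),
       corr_at_zero = pooled[ctr, ctr],
       per_neuron = per_neuron)
}

#' @export
print.switch_experiment <- function(x, ...) {
  cat(sprintf("<switch_experiment> restore=%s, %d steps\n", x$restore,
              nrow(x$positions)))
  print(x$visits)
  invisible(x)
}
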