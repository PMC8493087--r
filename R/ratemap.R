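# 3D occupancy/rate maps, Skaggs spatial information, sparsity index, and
# shuffle-based Z-scoring.

#' Bin a trial into a 3D rate map
#'
#' Divides \code{[-1, 1]^3} into \code{n_bins^3} voxels and accumulates
#' occupancy (visits per bin) and spike counts. Occupancy probability is
#' p_i = visits_i / T; the firing rate is lambda_i = spikes_i / visits_i on
#' visited bins.
#'
#' @param positions T x 3 matrix (or \code{trajectory}) of positions.
#' @param spikes length-T integer vector of spike counts per step.
#' @param n_bins bins per axis (default 20, i.e. 0.1 bin width).
#' @return object of class \code{rate_map3}: arrays \code{visits},
#'   \code{spikes}, \code{rate} (NA on unvisited bins), \code{p}
#'   (occupancy probability), \code{edges}, and the per-step \code{bin_idx}.
#' @export
bin_rate_map <- function(positions, spikes, n_bins = 20) {
  X <- if (inherits(positions, "trajectory")) positions$positions
       else as.matrix(positions)
  stopifnot(nrow(X) == length(spikes), n_bins >= 2)
  idx <- position_bin_index(X, n_bins)
  nb <- n_bins^3
  visits <- tabulate(idx, nbins = nb)
  if (all(visits == 0)) stop("no visited bins")
  rs <- rowsum(as.numeric(spikes), idx)
  spk_full <- numeric(nb)
  spk_full[as.integer(rownames(rs))] <- rs[, 1]
  rate <- ifelse(visits > 0, spk_full / pmax(visits, 1), NA_real_)
  dims <- c(n_bins, n_bins, n_bins)
  structure(list(visits = array(visits, dims),
                 spikes = array(spk_full, dims),
                 rate = array(rate, dims),
                 p = array(visits / sum(visits), dims),
                 edges = seq(-1, 1, length.out = n_bins + 1),
                 n_bins = n_bins, bin_idx = idx),
            class = "rate_map3")
}

# flat voxel index of positions in [-1,1]^3 on an n^3 grid
position_bin_index <- function(X, n_bins) {
  b <- pmin(pmax(floor((X + 1) / 2 * n_bins), 0), n_bins - 1)
  as.integer(b[, 1] + n_bins * b[, 2] + n_bins^2 * b[, 3] + 1)
}

# SI and sparsity from occupancy probabilities and rates on visited bins
info_from_pr <- function(p, lambda) {
  mean_rate <- sum(p * lambda)
  if (mean_rate <= 0) stop("all-zero rates: spatial measures undefined")
  rel <- lambda / mean_rate
  pos <- rel > 0
  si <- sum(p[pos] * rel[pos] * log2(rel[pos]))
  sparsity <- mean_rate^2 / sum(p * lambda^2)
  c(si = si, sparsity = sparsity)
}

#' Skaggs spatial information (bits/spike)
#'
#' \eqn{\sum_i p_i (\lambda_i/\langle\lambda\rangle)
#' \log_2(\lambda_i/\langle\lambda\rangle)} over visited bins, zero iff the
#' rate is uniform.
#'
#' @param map a \code{\link{bin_rate_map}} result.
#' @return nonnegative scalar, bits per spike.
#' @export
spatial_information <- function(map) {
  v <- map$visits > 0
  unname(info_from_pr(map$p[v], map$rate[v])["si"])
}

#' Sparsity index
#'
#' \eqn{\langle\lambda\rangle^2 / \langle\lambda^2\rangle} over visited
#' bins: 1 for a uniform map, 1/N when a single bin of N is active.
#'
#' @param map a \code{\link{bin_rate_map}} result.
#' @return scalar in (0, 1].
#' @export
sparsity_index <- function(map) {
  v <- map$visits > 0
  unname(info_from_pr(map$p[v], map$rate[v])["sparsity"])
}

#' Shuffle Z-score of a spatial metric
#'
#' Nulls the spike-position relationship by circularly shifting the spike
#' train against the trajectory by a uniform offset in
#' \code{[0.05 T, 0.95 T]} (preserving the spike train's autostructure),
#' recomputes the metric on each shuffle, and returns
#' \code{(observed - mean(shuffles)) / sd(shuffles)}.
#'
#' @param positions T x 3 matrix or \code{trajectory}.
#' @param spikes length-T spike counts.
#' @param metric_fn function of a \code{rate_map3}, e.g.
#'   \code{\link{spatial_information}}.
#' @param n_shuffles number of shuffles (default 50).
#' @param n_bins bins per axis.
#' @return the Z-score (scalar).
#' @export
shuffle_zscore <- function(positions, spikes, metric_fn, n_shuffles = 50,
                           n_bins = 20) {
  stopifnot(n_shuffles >= 2)
  zs <- shuffle_zscores(positions, spikes,
                        metrics = list(m = metric_fn),
                        n_shuffles = n_shuffles, n_bins = n_bins)
  zs[["m"]]
}

# Z-scores of several metrics sharing one set of shuffles (one binning pass
# per shuffle). `metrics` is a named list of functions of a rate_map3.
shuffle_zscores <- function(positions, spikes, metrics, n_shuffles = 50,
                            n_bins = 20) {
  X <- if (inherits(positions, "trajectory")) positions$positions
       else as.matrix(positions)
  n <- nrow(X)
  stopifnot(length(spikes) == n)
  map0 <- bin_rate_map(X, spikes, n_bins)
  obs <- vapply(metrics, function(f) f(map0), numeric(1))
  offs <- floor(stats::runif(n_shuffles, 0.05 * n, 0.95 * n))
  sh <- vapply(offs, function(s) {
    spk <- c(spikes[(s + 1):n], spikes[1:s])
    m <- bin_rate_map(X, spk, n_bins)
    vapply(metrics, function(f) f(m), numeric(1))
  }, numeric(length(metrics)))
  sh <- matrix(sh, nrow = length(metrics))
  mu <- rowMeans(sh)
  sdv <- apply(sh, 1, stats::sd)
  if (any(sdv == 0)) stop("degenerate shuffle distribution (zero SD)")
  z <- (obs - mu) / sdv
  names(z) <- names(metrics)
  z
}
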