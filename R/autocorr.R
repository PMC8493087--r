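# 3D spatial autocorrelograms, oblique-slice grid scores, structure-score
# calibration, and the modified radial autocorrelation.

# linear (non-circular) cross-correlation sums of two equally-sized 2D/3D
# arrays over all integer offsets, returned centered: dimension 2n-1 per
# axis, the zero offset at index n.
xcorr3_sums <- function(a, b) {
  d <- dim(a)
  k <- length(d)
  m <- 2 * d
  ix <- lapply(d, seq_len)
  ap <- array(0, m)
  bp <- array(0, m)
  ap <- do.call(`[<-`, c(list(ap), ix, list(a)))
  bp <- do.call(`[<-`, c(list(bp), ix, list(b)))
  cc <- Re(stats::fft(Conj(stats::fft(ap)) * stats::fft(bp),
                      inverse = TRUE)) / prod(m)
  # offset q along one dim sits at index q+1 (q >= 0) or m+q+1 (q < 0)
  ord <- lapply(seq_len(k), function(i) {
    if (d[i] == 1) 1L else c((m[i] - d[i] + 2):m[i], 1:d[i])
  })
  do.call(`[`, c(list(cc), ord))
}

#' 3D spatial autocorrelogram
#'
#' Pearson-normalized discrete autocorrelation of a 3D map: for every
#' integer offset the correlation is computed over the overlapping valid
#' bins. Offsets with fewer than \code{min_overlap} overlapping bins are
#' masked (NA). The zero-offset value is 1.
#'
#' @param map a \code{rate_map3}, a 3D array (e.g. binned spike counts), or
#'   an n x 3 point matrix (binned internally on \code{n_bins} per axis).
#' @param mask logical array of valid bins (defaults to non-NA entries; for
#'   rate maps, the visited bins).
#' @param min_overlap minimum overlapping bins per offset (default 20).
#' @param n_bins bins per axis when binning a point matrix.
#' @return object of class \code{autocorr3}: array \code{A} of dimension
#'   (2n-1)^3 with attribute \code{center} (index of the zero offset).
#' @export
autocorrelogram_3d <- function(map, mask = NULL, min_overlap = 20,
                               n_bins = 20) {
  x <- if (inherits(map, "rate_map3")) {
    mask <- mask %||% (map$visits > 0)
    map$rate
  } else if (is.array(map) && length(dim(map)) == 3) {
    map
  } else {
    pts <- as.matrix(map)
    stopifnot(ncol(pts) == 3)
    idx <- position_bin_index(pts, n_bins)
    array(tabulate(idx, nbins = n_bins^3), rep(n_bins, 3))
  }
  d <- dim(x)
  stopifnot(all(d >= 2))
  if (is.null(mask)) mask <- !is.na(x)
  w <- mask * 1
  x0 <- ifelse(mask, x, 0)
  n_ov <- xcorr3_sums(w, w)
  sx <- xcorr3_sums(x0, w)
  sy <- xcorr3_sums(w, x0)
  sxx <- xcorr3_sums(x0^2, w)
  syy <- xcorr3_sums(w, x0^2)
  sxy <- xcorr3_sums(x0, x0)
  n_ov <- round(n_ov)
  num <- n_ov * sxy - sx * sy
  den2 <- pmax(n_ov * sxx - sx^2, 0) * pmax(n_ov * syy - sy^2, 0)
  A <- num / sqrt(den2)
  A[n_ov < min_overlap | den2 <= 0] <- NA_real_
  A[is.nan(A)] <- NA_real_
  ctr <- d  # zero offset index per dim
  A[ctr[1], ctr[2], ctr[3]] <- 1
  structure(list(A = A, center = ctr), class = "autocorr3")
}

#' Modified radial autocorrelation
#'
#' Shell-aggregated autocorrelation: offsets are partitioned into unit-width
#' Euclidean annuli (r-1, r], and each shell sum is divided by the square
#' root of the shell size, \eqn{\hat A(r) = N(r)^{-1/2} \sum_{shell} A}.
#' The sub-linear divisor keeps widely spaced repeated patterns from being
#' averaged away, while still damping the quadratic growth of shell size.
#'
#' @param ac an \code{\link{autocorrelogram_3d}} result.
#' @return object of class \code{mra_profile}: \code{r} (1..max_r, half the
#'   autocorrelogram edge), \code{value}, \code{n} (valid offsets per
#'   shell).
#' @export
modified_radial_autocorr <- function(ac) {
  stopifnot(inherits(ac, "autocorr3"))
  A <- ac$A
  d <- dim(A)
  ctr <- ac$center
  max_r <- (d[1] - 1) %/% 2
  ii <- slice.index(A, 1) - ctr[1]
  jj <- slice.index(A, 2) - ctr[2]
  kk <- slice.index(A, 3) - ctr[3]
  rad <- sqrt(ii^2 + jj^2 + kk^2)
  shell <- ceiling(rad)
  ok <- !is.na(A) & shell >= 1 & shell <= max_r
  sums <- rep(0, max_r)
  cnts <- rep(0L, max_r)
  if (any(ok)) {
    agg <- rowsum(A[ok], shell[ok])
    cnt <- rowsum(rep(1L, sum(ok)), shell[ok])
    r_idx <- as.integer(rownames(agg))
    sums[r_idx] <- agg[, 1]
    cnts[r_idx] <- cnt[, 1]
  }
  value <- ifelse(cnts > 0, sums / sqrt(pmax(cnts, 1)), 0)
  structure(list(r = seq_len(max_r), value = value, n = cnts),
            class = "mra_profile")
}

#' @export
plot.mra_profile <- function(x, ...) {
  graphics::plot(x$r, x$value, type = "l", xlab = "shell radius (bins)",
                 ylab = "modified radial autocorrelation", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# --- slice grid scores ------------------------------------------------------

#' Orientation grid over slice normals
#'
#' Azimuth 0..(180 - step) x elevation 0..90 in degrees. Elevation 90 is the
#' vertical normal (horizontal slice).
#'
#' @param step_deg angular resolution (default 3).
#' @return data.frame with columns az, el (degrees) and the unit normals.
#' @export
orientation_grid <- function(step_deg = 3) {
  az <- seq(0, 180 - step_deg, by = step_deg)
  el <- seq(0, 90, by = step_deg)
  g <- expand.grid(az = az, el = el)
  a <- g$az * pi / 180
  e <- g$el * pi / 180
  g$nx <- cos(a) * cos(e)
  g$ny <- sin(a) * cos(e)
  g$nz <- sin(e)
  attr(g, "step_deg") <- step_deg
  g
}

# polar samples of a central oblique slice of the autocorrelogram for a set
# of normals; returns an array [n_orient, n_rho, n_theta]
polar_slice_samples <- function(ac, normals, radii, n_theta = 24) {
  A <- ac$A
  ctr <- ac$center
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  n_or <- nrow(normals)
  e1 <- matrix(0, n_or, 3)
  e2 <- matrix(0, n_or, 3)
  for (i in seq_len(n_or)) {
    n <- normals[i, ]
    ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    b1 <- unit(crossprod3(ref, n))
    e1[i, ] <- b1
    e2[i, ] <- crossprod3(n, b1)
  }
  # all sample points: orientation x rho x theta
  ct <- cos(thetas)
  st <- sin(thetas)
  n_rho <- length(radii)
  or_idx <- rep(seq_len(n_or), times = n_rho * n_theta)
  rho <- rep(rep(radii, each = n_or), times = n_theta)
  th_i <- rep(seq_len(n_theta), each = n_or * n_rho)
  dir <- e1[or_idx, , drop = FALSE] * ct[th_i] +
         e2[or_idx, , drop = FALSE] * st[th_i]
  pts <- dir * rho
  vals <- trilinear(A, pts, orig = -(ctr - 1), step = c(1, 1, 1))
  array(vals, c(n_or, n_rho, n_theta))
}

# hexagonal and square grid scores from a polar field V[n_rho, n_theta]
# sampled at 15-degree steps. The annulus is set from the first trough and
# first ring peak of the radial profile.
gridness_from_polar <- function(V, radii) {
  prof <- rowMeans(V, na.rm = TRUE)
  n <- length(prof)
  if (all(!is.finite(prof))) return(c(hex = NA_real_, square = NA_real_))
  # first local minimum (end of the central peak)
  i_min <- NA_integer_
  for (i in 2:(n - 1)) {
    if (is.finite(prof[i]) && prof[i] <= prof[i - 1] &&
        prof[i] <= prof[i + 1]) {
      i_min <- i
      break
    }
  }
  if (is.na(i_min)) return(c(hex = NA_real_, square = NA_real_))
  i_pk <- NA_integer_
  if (i_min < n - 1) {
    for (i in (i_min + 1):(n - 1)) {
      if (is.finite(prof[i]) && prof[i] >= prof[i - 1] &&
          prof[i] >= prof[i + 1]) {
        i_pk <- i
        break
      }
    }
  }
  if (is.na(i_pk)) return(c(hex = NA_real_, square = NA_real_))
  outer_i <- min(n, i_pk + (i_pk - i_min))
  rows <- i_min:outer_i
  V0 <- V[rows, , drop = FALSE]
  v <- as.vector(V0)
  n_theta <- ncol(V)
  step <- 360 / n_theta
  rot_cor <- function(deg) {
    k <- as.integer(round(deg / step)) %% n_theta
    vr <- as.vector(V0[, c((k + 1):n_theta, seq_len(k))[1:n_theta]])
    ok <- is.finite(v) & is.finite(vr)
    if (sum(ok) < 8) return(NA_real_)
    suppressWarnings(stats::cor(v[ok], vr[ok]))
  }
  hex <- min(rot_cor(60), rot_cor(120)) -
         max(rot_cor(30), rot_cor(90), rot_cor(150))
  sq <- rot_cor(90) - max(rot_cor(45), rot_cor(135))
  c(hex = hex, square = sq)
}

#' Grid scores of oblique slices of a 3D autocorrelogram
#'
#' For each slice-normal orientation the central planar slice is sampled on
#' a polar grid (trilinear interpolation), an annulus around the first ring
#' of peaks is selected from the radial profile, and rotational-correlation
#' grid scores are computed: hexagonal score
#' \code{min(cor at 60, 120) - max(cor at 30, 90, 150)} and square score
#' \code{cor at 90 - max(cor at 45, 135)}. Slices with no detectable ring
#' are NA.
#'
#' @param ac an \code{\link{autocorrelogram_3d}} result.
#' @param orientations an \code{\link{orientation_grid}} (or subset of its
#'   rows).
#' @param rho_step radial sampling step in bins (default 0.5).
#' @param n_theta angular samples (default 24, i.e. 15-degree steps).
#' @return data.frame: orientation columns plus \code{hex} and
#'   \code{square} scores.
#' @export
slice_grid_scores <- function(ac, orientations = orientation_grid(),
                              rho_step = 0.5, n_theta = 24) {
  stopifnot(inherits(ac, "autocorr3"), n_theta %% 24 == 0)
  max_r <- (dim(ac$A)[1] - 1) %/% 2
  radii <- seq(1, max_r * 0.95, by = rho_step)
  normals <- as.matrix(orientations[, c("nx", "ny", "nz")])
  S <- polar_slice_samples(ac, normals, radii, n_theta)
  sc <- t(vapply(seq_len(nrow(normals)),
                 function(i) gridness_from_polar(S[i, , ], radii),
                 numeric(2)))
  out <- cbind(orientations, hex = sc[, 1], square = sc[, 2])
  class(out) <- c("slice_scores", class(out))
  out
}

# local maxima of a score vector laid out on the (az, el) orientation grid;
# azimuth wraps (period 180 degrees). Returns row indices sorted by score.
score_map_maxima <- function(scores, orientations, max_keep = 12) {
  step <- attr(orientations, "step_deg")
  az <- sort(unique(orientations$az))
  el <- sort(unique(orientations$el))
  M <- matrix(NA_real_, length(az), length(el))
  ia <- match(orientations$az, az)
  ie <- match(orientations$el, el)
  M[cbind(ia, ie)] <- scores
  na <- nrow(M)
  ne <- ncol(M)
  is_max <- matrix(FALSE, na, ne)
  for (i in seq_len(na)) {
    for (j in seq_len(ne)) {
      v <- M[i, j]
      if (!is.finite(v) || v <= 0) next
      nb <- c()
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          jj <- j + dj
          if (jj < 1 || jj > ne) next
          ii <- ((i - 1 + di) %% na) + 1  # azimuth wraps
          nb <- c(nb, M[ii, jj])
        }
      }
      nb <- nb[is.finite(nb)]
      if (length(nb) && all(v >= nb)) is_max[i, j] <- TRUE
    }
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(integer(0))
  rows <- match(paste(az[idx[, 1]], el[idx[, 2]]),
                paste(orientations$az, orientations$el))
  ord <- order(scores[rows], decreasing = TRUE)
  utils::head(rows[ord], max_keep)
}

#' Calibrate the structure scores on prototype clouds
#'
#' Generates FCC, HCP and COL prototype clouds, computes their slice
#' grid-score maps, and records (a) the orientations of the local maxima of
#' each structure's hexagonal and square score maps and (b) the reference
#' chi value of each structure on its own cloud
#' (\code{median(hex at hex maxima) + median(square at square maxima)}).
#'
#' @param spacing prototype lattice spacing.
#' @param sigma blur scale.
#' @param n_bins bins per axis for the spike-count maps.
#' @param step_deg orientation-grid resolution (default 3 degrees).
#' @param points_per_vertex blur points per vertex.
#' @param seed seed for the prototype generation.
#' @return object of class \code{structure_calibration}: per-structure
#'   maxima orientations, reference scores, and parameters.
#' @export
structure_calibration <- function(spacing = default_spacing(), sigma = 0.05,
                                  n_bins = 20, step_deg = 3,
                                  points_per_vertex = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  og <- orientation_grid(step_deg)
  structures <- c("FCC", "HCP", "COL")
  maxima <- list()
  reference <- c(FCC = NA_real_, HCP = NA_real_, COL = NA_real_)
  for (s in structures) {
    cloud <- prototype_cloud(s, spacing = spacing, sigma = sigma,
                             points_per_vertex = points_per_vertex)
    ac <- autocorrelogram_3d(cloud$points, n_bins = n_bins)
    sc <- slice_grid_scores(ac, og)
    hx <- score_map_maxima(sc$hex, og)
    sq <- score_map_maxima(sc$square, og)
    if (!length(hx) || !length(sq))
      stop("no score-map maxima found for ", s)
    maxima[[s]] <- list(hex = og[hx, , drop = FALSE],
                        square = og[sq, , drop = FALSE],
                        hex_scores = sc$hex[hx],
                        square_scores = sc$square[sq])
    reference[s] <- stats::median(sc$hex[hx], na.rm = TRUE) +
      stats::median(sc$square[sq], na.rm = TRUE)
  }
  structure(list(maxima = maxima, reference = reference,
                 spacing = spacing, sigma = sigma, n_bins = n_bins,
                 step_deg = step_deg),
            class = "structure_calibration")
}

.gf3_cache <- new.env(parent = emptyenv())

#' Memoized default structure calibration
#'
#' Returns the calibration for the default prototype parameters, computing
#' it on first use and caching it for the session (it is deterministic
#' given the seed, and moderately expensive).
#'
#' @param seed prototype-generation seed (default 42).
#' @param step_deg orientation-grid resolution.
#' @return a \code{\link{structure_calibration}}.
#' @export
default_calibration <- function(seed = 42, step_deg = 3) {
  key <- paste0("cal_", seed, "_", step_deg)
  if (!exists(key, envir = .gf3_cache)) {
    assign(key, structure_calibration(seed = seed, step_deg = step_deg),
           envir = .gf3_cache)
  }
  get(key, envir = .gf3_cache)
}

#' Structure scores of a 3D autocorrelogram
#'
#' Evaluates the sample's hexagonal and square slice grid scores at the
#' calibrated maxima orientations of each prototype structure and returns
#' \code{chi = median(hex scores) + median(square scores)} per structure.
#'
#' @param ac an \code{\link{autocorrelogram_3d}} result.
#' @param calibration a \code{\link{structure_calibration}}.
#' @return object of class \code{structure_scores}: \code{chi} (named
#'   vector FCC/HCP/COL) and the calibration \code{reference}.
#' @export
structure_scores <- function(ac, calibration) {
  if (missing(calibration) || !inherits(calibration, "structure_calibration"))
    stop("a structure_calibration is required")
  chi <- vapply(names(calibration$maxima), function(s) {
    m <- calibration$maxima[[s]]
    ors <- rbind(m$hex, m$square)
    sc <- slice_grid_scores(ac, ors)
    nh <- nrow(m$hex)
    stats::median(sc$hex[seq_len(nh)], na.rm = TRUE) +
      stats::median(sc$square[nh + seq_len(nrow(m$square))], na.rm = TRUE)
  }, numeric(1))
  structure(list(chi = chi, reference = calibration$reference),
            class = "structure_scores")
}

#' @export
print.structure_scores <- function(x, ...) {
  cat("structure scores (chi):\n")
  print(round(x$chi, 3))
  cat("prototype references:\n")
  print(round(x$reference, 3))
  invisible(x)
}

# --- planar gridness --------------------------------------------------------

#' 2D autocorrelogram and hexagonal grid score
#'
#' Bins planar points (or accepts a 2D array), computes the
#' Pearson-normalized 2D autocorrelogram, and scores hexagonal symmetry by
#' rotational correlation over the annulus around the inner ring of peaks.
#'
#' @param xy n x 2 point matrix or a 2D numeric array.
#' @param n_bins bins per axis (default 40 over [-1, 1]).
#' @param n_theta angular samples (default 24).
#' @return list with the autocorrelation array \code{A} and scores
#'   \code{hex}, \code{square}.
#' @export
gridness_2d <- function(xy, n_bins = 40, n_theta = 24) {
  x <- if (is.matrix(xy) && ncol(xy) == 2 && !is.null(dim(xy))) {
    b1 <- pmin(pmax(floor((xy[, 1] + 1) / 2 * n_bins), 0), n_bins - 1)
    b2 <- pmin(pmax(floor((xy[, 2] + 1) / 2 * n_bins), 0), n_bins - 1)
    array(tabulate(as.integer(b1 + n_bins * b2 + 1), nbins = n_bins^2),
          c(n_bins, n_bins))
  } else {
    as.array(xy)
  }
  # embed the 2D problem in the 3D machinery: three identical slabs, so the
  # central-plane interpolation is well defined; the in-plane correlation is
  # unchanged by the duplication
  x3 <- array(rep(x, 3), c(dim(x), 3))
  ac <- autocorrelogram_3d(x3, min_overlap = 20)
  A3 <- ac$A[, , ac$center[3]]
  max_r <- (dim(A3)[1] - 1) %/% 2
  radii <- seq(1, max_r * 0.95, by = 0.5)
  S <- polar_slice_samples(ac, matrix(c(0, 0, 1), 1), radii, n_theta)
  sc <- gridness_from_polar(S[1, , ], radii)
  list(A = A3, hex = unname(sc["hex"]), square = unname(sc["square"]))
}
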