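# Firing-field detection by flat-kernel mean-shift clustering and
# inter-field distances.
#
# The algorithm mirrors the scikit-learn MeanShift procedure: seeds are
# centers of occupied bins of width = bandwidth (kept if they hold at least
# min_bin_freq points), each seed ascends to the mean of the points within
# one bandwidth until convergence, modes closer than the bandwidth are
# merged (highest support wins), and points farther than one bandwidth from
# every mode stay unassigned (noise; cluster_all = FALSE semantics).

mean_shift_modes <- function(P, bandwidth, min_bin_freq, max_iter = 300,
                             tol = 1e-3) {
  d <- ncol(P)
  # bin seeding
  key <- floor(sweep(P, 2, bandwidth, "/"))
  kstr <- apply(key, 1, paste, collapse = ",")
  tab <- table(kstr)
  keep <- names(tab)[tab >= min_bin_freq]
  if (!length(keep)) return(NULL)
  seeds <- do.call(rbind, lapply(strsplit(keep, ","), as.numeric))
  seeds <- (seeds + 0.5) * bandwidth
  centers <- seeds
  active <- rep(TRUE, nrow(centers))
  support <- integer(nrow(centers))
  bw2 <- bandwidth^2
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    ca <- centers[active, , drop = FALSE]
    # squared distances seeds x points
    d2 <- outer(rowSums(ca^2), rowSums(P^2), "+") - 2 * ca %*% t(P)
    within <- d2 <= bw2
    cnt <- rowSums(within)
    newc <- (within %*% P) / pmax(cnt, 1)
    newc[cnt == 0, ] <- ca[cnt == 0, ]
    shift <- sqrt(rowSums((newc - ca)^2))
    centers[active, ] <- newc
    support[active] <- cnt
    conv <- shift < tol * bandwidth
    idx <- which(active)
    active[idx[conv]] <- FALSE
  }
  ord <- order(support, decreasing = TRUE)
  centers <- centers[ord, , drop = FALSE]
  support <- support[ord]
  # merge modes within one bandwidth of a stronger mode
  kept <- logical(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    if (i == 1) {
      kept[1] <- TRUE
      next
    }
    prev <- centers[kept, , drop = FALSE]
    dd <- rowSums(sweep(prev, 2, centers[i, ], "-")^2)
    kept[i] <- all(dd > bw2)
  }
  list(centers = centers[kept, , drop = FALSE], support = support[kept])
}

#' Detect firing fields with mean-shift clustering
#'
#' Clusters spike positions with a flat kernel of the given bandwidth.
#' Noise rejection: points beyond one bandwidth of every mode are
#' unassigned, clusters smaller than \code{min_cluster} are removed, and
#' clusters whose centers lie within \code{margin} of a cube face are
#' removed (their visible portion does not estimate the true center).
#'
#' @param spike_positions n x 3 (or n x 2) matrix of spike locations.
#' @param bandwidth flat-kernel radius (default 0.25).
#' @param min_bin_freq minimum points per seeding bin (default 25).
#' @param min_cluster minimum retained cluster size (default 30).
#' @param margin minimum center distance from the boundary (default 0.05).
#' @param bounds arena half-width per axis (default 1; set NULL to skip the
#'   boundary rule).
#' @return object of class \code{field_set}: \code{centers} (M x d),
#'   \code{sizes}, \code{radii} (per-field RMS point distance),
#'   \code{assignment} (cluster id per spike, NA = noise),
#'   \code{n_rejected}.
#' @examples
#' pts <- rbind(matrix(rnorm(300, 0, 0.05), 100, 3),
#'              matrix(rnorm(300, 0.8, 0.05), 100, 3))
#' detect_fields(pts)$centers
#' @export
detect_fields <- function(spike_positions, bandwidth = 0.25,
                          min_bin_freq = 25, min_cluster = 30,
                          margin = 0.05, bounds = 1) {
  P <- as.matrix(spike_positions)
  stopifnot(nrow(P) >= min_cluster)
  ms <- mean_shift_modes(P, bandwidth, min_bin_freq)
  empty <- structure(list(centers = matrix(numeric(0), 0, ncol(P)),
                          sizes = integer(0), radii = numeric(0),
                          assignment = rep(NA_integer_, nrow(P)),
                          n_rejected = nrow(P)),
                     class = "field_set")
  if (is.null(ms) || nrow(ms$centers) == 0) {
    warning("no clusters found")
    return(empty)
  }
  C <- ms$centers
  d2 <- outer(rowSums(P^2), rowSums(C^2), "+") - 2 * P %*% t(C)
  nearest <- max.col(-d2)
  nd2 <- d2[cbind(seq_len(nrow(P)), nearest)]
  assign <- ifelse(nd2 <= bandwidth^2, nearest, NA_integer_)
  sizes <- tabulate(assign, nbins = nrow(C))
  keep <- sizes >= min_cluster
  if (!is.null(bounds)) {
    inside <- apply(abs(C) <= (bounds - margin), 1, all)
    keep <- keep & inside
  }
  if (!any(keep)) {
    warning("no clusters survive the size/boundary rules")
    return(empty)
  }
  new_id <- cumsum(keep)
  assign <- ifelse(!is.na(assign) & keep[assign], new_id[assign],
                   NA_integer_)
  C <- C[keep, , drop = FALSE]
  sizes <- sizes[keep]
  radii <- vapply(seq_len(nrow(C)), function(k) {
    pts <- P[which(assign == k), , drop = FALSE]
    sqrt(mean(rowSums(sweep(pts, 2, C[k, ], "-")^2)))
  }, numeric(1))
  structure(list(centers = C, sizes = sizes, radii = radii,
                 assignment = assign,
                 n_rejected = sum(is.na(assign))),
            class = "field_set")
}

#' @export
print.field_set <- function(x, ...) {
  cat(sprintf("<field_set> %d fields (sizes %s), %d noise spikes\n",
              nrow(x$centers), paste(x$sizes, collapse = "/"),
              x$n_rejected))
  invisible(x)
}

#' Inter-field distances
#'
#' Nearest-neighbor distance per field center (the default, concentrating
#' at the lattice constant for regular structures), or all pairwise
#' distances.
#'
#' @param fields a \code{\link{detect_fields}} result (or M x d center
#'   matrix).
#' @param pairwise return all pairwise distances instead (default FALSE).
#' @return numeric vector of distances (empty if fewer than 2 fields).
#' @export
interfield_distances <- function(fields, pairwise = FALSE) {
  C <- if (inherits(fields, "field_set")) fields$centers else as.matrix(fields)
  if (nrow(C) < 2) return(numeric(0))
  D <- as.matrix(stats::dist(C))
  if (pairwise) return(D[upper.tri(D)])
  diag(D) <- Inf
  unname(apply(D, 1, min))
}
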