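# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with a vector of small integers (condition
#' indices, trajectory ids, stage codes) into a seed below 2^31, so that every
#' stage of a simulation campaign draws from an independent, reproducible
#' stream.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the substream.
#' @return a single integer seed in [1, 2^31 - 2].
#' @export
substream_seed <- function(master, ...) {
  idx <- as.numeric(c(...))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (k in idx) {
    # affine hash step; multipliers are arbitrary odd constants
    h <- (h * 48271 + (k + 1) * 16807) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize the zero vector")
  v / n
}

#' Rotation about the vertical axis
#'
#' @param deg rotation angle in degrees.
#' @return 3x3 rotation matrix about e_z.
#' @export
rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), 3, 3)
}

# Trilinear interpolation into a 3D array `A` whose voxel (i, j, k) is centered
# at coordinates `orig + (c(i, j, k) - 1) * step`. `pts` is an n x 3 matrix.
# Values outside the grid, or touching an NA voxel, come back NA.
trilinear <- function(A, pts, orig, step) {
  d <- dim(A)
  g <- sweep(pts, 2, orig, "-") / step  # 0-based continuous index
  i0 <- floor(g)
  f <- g - i0
  out <- rep(NA_real_, nrow(pts))
  ok <- i0[, 1] >= 0 & i0[, 1] <= d[1] - 2 &
        i0[, 2] >= 0 & i0[, 2] <= d[2] - 2 &
        i0[, 3] >= 0 & i0[, 3] <= d[3] - 2
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE] + 1L  # 1-based corner
  f <- f[ok, , drop = FALSE]
  idx <- function(a, b, cc) {
    A[cbind(i0[, 1] + a, i0[, 2] + b, i0[, 3] + cc)]
  }
  v <- idx(0L, 0L, 0L) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
       idx(1L, 0L, 0L) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
       idx(0L, 1L, 0L) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
       idx(0L, 0L, 1L) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
       idx(1L, 1L, 0L) * f[, 1] * f[, 2] * (1 - f[, 3]) +
       idx(1L, 0L, 1L) * f[, 1] * (1 - f[, 2]) * f[, 3] +
       idx(0L, 1L, 1L) * (1 - f[, 1]) * f[, 2] * f[, 3] +
       idx(1L, 1L, 1L) * f[, 1] * f[, 2] * f[, 3]
  out[ok] <- v
  out
}
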