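# Uncertain, periodically refreshed perception of the reference-plane axis.
#
# The perceived axis xi follows a 3D von Mises-Fisher distribution centered
# on the true axis with concentration kappa ("perceptual certainty"); it is
# redrawn only every tau steps (the "refresh interval"). kappa = Inf is the
# accurate-perception sentinel: xi equals the true axis exactly.

#' Sample from the 3D von Mises-Fisher distribution
#'
#' Exact, rejection-free sampler: the cosine of the angle to the mean
#' direction has density proportional to exp(kappa * w) on [-1, 1], whose
#' CDF inverts in closed form; the azimuth about the mean is uniform.
#' \code{kappa = Inf} returns \code{mu} exactly.
#'
#' @param n number of samples.
#' @param mu unit length-3 mean direction.
#' @param kappa concentration (> 0, or \code{Inf}).
#' @return n x 3 matrix of unit vectors.
#' @examples
#' x <- rvmf(1000, c(0, 0, 1), 200)
#' mean(x[, 3])  # ~ coth(200) - 1/200
#' @export
rvmf <- function(n, mu, kappa) {
  stopifnot(length(mu) == 3, n >= 0)
  mu <- unit(mu)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  if (is.infinite(kappa)) {
    if (kappa <= 0) stop("kappa must be positive")
    return(matrix(mu, n, 3, byrow = TRUE))
  }
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be positive")
  u <- stats::runif(n)
  # W ~ density C * exp(kappa w) on [-1, 1]; inverse CDF, written to stay
  # accurate for large kappa
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  w <- pmin(1, pmax(-1, w))
  a <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  # orthonormal frame around mu
  ref <- if (abs(mu[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(crossprod3(ref, mu))
  e2 <- crossprod3(mu, e1)
  cbind(w * mu[1] + s * (cos(a) * e1[1] + sin(a) * e2[1]),
        w * mu[2] + s * (cos(a) * e1[2] + sin(a) * e2[2]),
        w * mu[3] + s * (cos(a) * e1[3] + sin(a) * e2[3]))
}

#' Mean resultant length of the 3D von Mises-Fisher distribution
#'
#' Closed form \eqn{A(\kappa) = \coth\kappa - 1/\kappa}, the expected cosine
#' of the angle between a sample and the mean direction.
#'
#' @param kappa concentration parameter.
#' @return expected resultant length in [0, 1).
#' @export
vmf_mean_resultant <- function(kappa) {
  if (is.infinite(kappa)) return(1)
  # coth(k) - 1/k, stable for large k
  1 / tanh(kappa) - 1 / kappa
}

#' Perception parameters
#'
#' @param kappa perceptual certainty (> 0 or \code{Inf} for accurate
#'   perception).
#' @param tau refresh interval in steps (>= 1): the perceived axis is redrawn
#'   whenever the step index is a multiple of tau.
#' @return object of class \code{perception_params}.
#' @export
perception_params <- function(kappa = Inf, tau = 10) {
  stopifnot(kappa > 0, tau >= 1)
  structure(list(kappa = kappa, tau = as.integer(tau)),
            class = "perception_params")
}

#' Refresh the perceived axis
#'
#' At step t the perceived axis is resampled from vMF(u_true, kappa) if t is
#' a multiple of tau or the state is uninitialized; otherwise the previous
#' percept is kept. The very first step (t = 0) counts as a refresh.
#'
#' @param t integer step (>= 0).
#' @param u_true unit length-3 true axis.
#' @param params a \code{\link{perception_params}}.
#' @param state previous state (list with \code{xi}) or NULL.
#' @return list with fields \code{xi} (unit 3-vector) and
#'   \code{last_refresh}.
#' @export
refresh_perception <- function(t, u_true, params, state = NULL) {
  stopifnot(t >= 0)
  if (is.null(state) || t %% params$tau == 0) {
    xi <- drop(rvmf(1, u_true, params$kappa))
    list(xi = xi, last_refresh = t)
  } else {
    state
  }
}

# Perceived axis per refresh epoch for a trial of n_steps steps: epoch e
# covers steps [ (e-1)*tau + 1, e*tau ]. u_true is an n_epochs x 3 matrix of
# true axes (recycled if a single row). Returns n_epochs x 3 matrix.
perceive_epochs <- function(u_true, kappa) {
  if (is.infinite(kappa)) return(u_true)
  t(apply(u_true, 1, function(u) drop(rvmf(1, u, kappa))))
}
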