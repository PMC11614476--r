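#' Center coordinates at the origin
#'
#' Subtracts the centroid so the coordinate set lies in the zero-centered
#' linear subspace on which the diffusion's Gaussians are defined; this is
#' what makes the whole process translation invariant. Idempotent.
#'
#' @param x numeric matrix, tokens x 3.
#' @return matrix of the same shape with zero column means.
#' @export
center <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need at least one token")
  sweep(x, 2L, colMeans(x))
}

is_centered <- function(x, tol = 1e-6) all(abs(colMeans(x)) < tol)

#' Draw Gaussian noise in the zero-centered subspace
#'
#' Samples i.i.d. standard normals and removes the centroid, giving a draw
#' from the standard Gaussian restricted to the subspace of zero-centroid
#' coordinate sets.
#'
#' @param n number of tokens.
#' @return n x 3 matrix with zero column means.
#' @export
centered_noise <- function(n) {
  center(matrix(stats::rnorm(n * 3L), n, 3L))
}

#' Forward diffusion sample q(z_t | x)
#'
#' \eqn{z_t = \alpha_t x + \sigma_t \epsilon} with \eqn{\epsilon} drawn from
#' the zero-centered-subspace standard Gaussian.
#'
#' @param x centered coordinates, tokens x 3.
#' @param t diffusion time in [0, 1].
#' @param sched a [make_schedule()] object.
#' @param seed optional integer; when given, the draw is reproducible.
#' @param auto_center center \code{x} instead of erroring when its centroid
#'   is off origin.
#' @return list with \code{z} (latent coordinates), \code{t}, and \code{eps}
#'   (the noise actually used, needed as the regression target in training).
#' @export
forward_sample <- function(x, t, sched, seed = NULL, auto_center = FALSE) {
  x <- as.matrix(x)
  if (!is_centered(x)) {
    if (auto_center) x <- center(x) else stop("x must be centered (or set auto_center = TRUE)")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  eps <- centered_noise(nrow(x))
  z <- sched$alpha(t) * x + sched$sigma(t) * eps
  list(z = z, t = t, eps = eps)
}

#' Gaussian posterior q(z_s | z_t, x)
#'
#' The Bayes posterior of the forward transitions: mean
#' \eqn{\mu_{t \to s} = \frac{\alpha_{t|s}\sigma_s^2}{\sigma_t^2} z_t +
#' \frac{\alpha_s \sigma^2_{t|s}}{\sigma_t^2} x} and scalar variance
#' \eqn{\sigma^2_{t \to s} = \sigma^2_{t|s}\sigma_s^2 / \sigma_t^2}.
#'
#' @param z_t latent coordinates at time t (tokens x 3).
#' @param x (estimated) clean coordinates, same shape.
#' @param s,t times with \code{s < t}.
#' @param sched a [make_schedule()] object.
#' @return list with \code{mean} (tokens x 3, zero centroid if inputs are
#'   centered) and scalar \code{var}.
#' @export
posterior_params <- function(z_t, x, s, t, sched) {
  if (s >= t) stop("posterior requires s < t")
  a_ts <- sched$alpha_ts(t, s)
  s2_ts <- sched$sigma2_ts(t, s)
  s2_s <- sched$sigma(s)^2
  s2_t <- sched$sigma(t)^2
  mean <- (a_ts * s2_s / s2_t) * z_t + (sched$alpha(s) * s2_ts / s2_t) * x
  list(mean = mean, var = s2_ts * s2_s / s2_t)
}

#' Denoised estimate of the clean coordinates
#'
#' Inverts the forward map using the predicted noise:
#' \eqn{\hat{x} = (z_t - \sigma_t \hat\epsilon) / \alpha_t}.
#'
#' @param z_t latent coordinates.
#' @param eps_hat predicted noise, same shape.
#' @param t time; \eqn{\alpha_t} must exceed 1e-8.
#' @param sched a [make_schedule()] object.
#' @return tokens x 3 matrix of estimated clean coordinates.
#' @export
denoised_estimate <- function(z_t, eps_hat, t, sched) {
  a <- sched$alpha(t)
  if (a < 1e-8) stop("alpha(t) too small to invert the forward map")
  (z_t - sched$sigma(t) * eps_hat) / a
}

#' One ancestral reverse step z_t -> z_s
#'
#' Uses the noise-prediction form of the reverse transition mean,
#' \eqn{z_s = z_t/\alpha_{t|s} - (\sigma^2_{t|s}/(\alpha_{t|s}\sigma_t))
#' \hat\epsilon + \sigma_{t \to s}\,\epsilon'}, with \eqn{\epsilon'} a fresh
#' zero-centered-subspace Gaussian. This is algebraically the posterior
#' [posterior_params()] with the denoised estimate substituted for x.
#'
#' @param z_t latent coordinates at time t.
#' @param eps_hat predicted noise.
#' @param s,t times with \code{s < t}.
#' @param sched a [make_schedule()] object.
#' @param seed optional integer for the fresh noise.
#' @param noise logical; FALSE suppresses the stochastic term (mean step).
#' @return list with \code{z} (latent at time s) and \code{t = s}.
#' @export
reverse_step <- function(z_t, eps_hat, s, t, sched, seed = NULL, noise = TRUE) {
  if (s >= t) stop("reverse step requires s < t")
  a_ts <- sched$alpha_ts(t, s)
  s2_ts <- sched$sigma2_ts(t, s)
  mean <- z_t / a_ts - (s2_ts / (a_ts * sched$sigma(t))) * eps_hat
  if (noise) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    sd_ts <- sqrt(s2_ts * sched$sigma(s)^2 / sched$sigma(t)^2)
    z <- mean + sd_ts * centered_noise(nrow(z_t))
  } else {
    z <- mean
  }
  if (any(!is.finite(z))) stop("non-finite latent after reverse step")
  list(z = z, t = s)
}
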