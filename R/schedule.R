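#' Variance-preserving noise schedules
#'
#' Construct a noise schedule for the diffusion process on complex
#' coordinates. The schedule supplies the signal scale \eqn{\alpha_t} and
#' noise scale \eqn{\sigma_t} on continuous time \eqn{t \in [0, 1]}, subject
#' to the variance-preserving identity \eqn{\alpha_t^2 + \sigma_t^2 = 1}.
#' \eqn{\alpha} decreases monotonically from approximately 1 at \eqn{t = 0}
#' (the latent is essentially the data) to approximately 0 at \eqn{t = 1}
#' (the latent is essentially noise).
#'
#' Two schedule kinds are registered:
#' \describe{
#'   \item{\code{"cosine"}}{\eqn{\alpha_t = \cos(\pi/2 (\epsilon_0 + t(1 -
#'     2\epsilon_0)))} with a small endpoint shift \eqn{\epsilon_0} so that
#'     \eqn{\alpha} never reaches 0 or 1 exactly (keeps every reverse-step
#'     ratio finite).}
#'   \item{\code{"linear_logsnr"}}{log signal-to-noise ratio
#'     \eqn{\lambda(t) = \log(\alpha_t^2/\sigma_t^2)} linear in \eqn{t}
#'     between \code{logsnr_max} and \code{logsnr_min};
#'     \eqn{\alpha_t^2 = \mathrm{sigmoid}(\lambda(t))}.}
#' }
#'
#' @param T integer number of discrete generative steps; the sampling grid is
#'   \eqn{s(i) = (i-1)/T}, \eqn{t(i) = i/T}.
#' @param kind schedule family, one of \code{"cosine"},
#'   \code{"linear_logsnr"}.
#' @param eps0 endpoint shift of the cosine schedule.
#' @param logsnr_max,logsnr_min endpoints of the linear log-SNR schedule.
#'
#' @return an object of class \code{noise_schedule} with functions
#'   \code{alpha(t)}, \code{sigma(t)}, \code{alpha_ts(t, s)},
#'   \code{sigma2_ts(t, s)} and the step count \code{T}.
#' @export
make_schedule <- function(T, kind = c("cosine", "linear_logsnr"),
                          eps0 = 0.005, logsnr_max = 10, logsnr_min = -10) {
  if (!is.numeric(T) || length(T) != 1L || T < 1 || T != round(T))
    stop("T must be a positive integer")
  kind <- match.arg(kind)
  alpha <- switch(kind,
    cosine = function(t) cos(pi / 2 * (eps0 + t * (1 - 2 * eps0))),
    linear_logsnr = function(t) {
      lam <- logsnr_max + t * (logsnr_min - logsnr_max)
      sqrt(stats::plogis(lam))
    }
  )
  sigma <- function(t) sqrt(pmax(0, 1 - alpha(t)^2))
  sched <- list(
    T = as.integer(T),
    kind = kind,
    alpha = alpha,
    sigma = sigma,
    # transition scale alpha_{t|s} = alpha_t / alpha_s for s <= t
    alpha_ts = function(t, s) alpha(t) / alpha(s),
    # transition variance sigma^2_{t|s} = sigma_t^2 - alpha_{t|s}^2 sigma_s^2
    sigma2_ts = function(t, s) {
      pmax(0, sigma(t)^2 - (alpha(t) / alpha(s))^2 * sigma(s)^2)
    }
  )
  class(sched) <- "noise_schedule"
  sched
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf(
    "<noise_schedule: kind=%s T=%d alpha(0)=%.6f alpha(1)=%.6f>\n",
    x$kind, x$T, x$alpha(0), x$alpha(1)
  ))
  invisible(x)
}

#' Registered schedule kinds
#' @return character vector of valid \code{kind} values for
#'   [make_schedule()].
#' @export
schedule_kinds <- function() c("cosine", "linear_logsnr")

#' Literal reading of the signal/noise relation (diagnostic only)
#'
#' Returns \eqn{\alpha = 1 - \sigma^2} for a given noise scale. This linear
#' relation is sometimes written as shorthand for the variance-preserving
#' identity \eqn{\alpha^2 = 1 - \sigma^2}; taken literally it cannot satisfy
#' \eqn{\alpha^2 + \sigma^2 = 1} except at \eqn{\sigma \in \{0, 1\}}, so it is
#' provided for comparison only and is not a registered schedule kind.
#'
#' @param sigma noise scale(s) in [0, 1].
#' @return \eqn{1 - \sigma^2}.
#' @export
literal_alpha_from_sigma <- function(sigma) 1 - sigma^2
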