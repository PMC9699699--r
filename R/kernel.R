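#' Calcium transient kernel
#'
#' Unit-peak event waveform used throughout the simulator: an
#' instantaneous-onset saturating rise, an optional plateau, and an
#' exponential decay,
#' \deqn{g(t) = (1 - e^{-t/\tau_r})\, e^{-\max(0, t - p)/\tau_d},}
#' rescaled so that \eqn{\max_t g(t) = 1}. The \code{amplitude} argument is
#' therefore the peak dF/F0 the event contributes.
#'
#' @param t numeric vector of times (s) relative to event onset; values
#'   before onset contribute 0.
#' @param amplitude peak dF/F0 of the event.
#' @param rise_tau rise time constant (s), > 0.
#' @param decay_tau decay time constant (s), > 0.
#' @param plateau_s plateau duration (s) inserted between rise and decay;
#'   0 for ordinary transients.
#' @return numeric vector, same length as \code{t}.
#' @export
ca_kernel <- function(t, amplitude = 1, rise_tau, decay_tau, plateau_s = 0) {
  stopifnot(rise_tau > 0, decay_tau > 0, plateau_s >= 0)
  g <- ifelse(t < 0, 0,
              (1 - exp(-t / rise_tau)) * exp(-pmax(0, t - plateau_s) / decay_tau))
  amplitude * g / .kernel_peak(rise_tau, decay_tau, plateau_s)
}

# peak of the unnormalised kernel; closed form at plateau end when plateau>0,
# else at t* = rise*log(1 + decay/rise)
.kernel_peak <- function(rise_tau, decay_tau, plateau_s = 0) {
  tstar <- rise_tau * log1p(decay_tau / rise_tau)
  if (plateau_s >= tstar) return(1 - exp(-plateau_s / rise_tau))
  (1 - exp(-tstar / rise_tau)) * exp(-max(0, tstar - plateau_s) / decay_tau)
}

#' Full width at half maximum of the event kernel
#'
#' Computed numerically on a dense time grid with linear interpolation at
#' the two half-maximum crossings.
#'
#' @inheritParams ca_kernel
#' @param dt grid step (s) for the numerical evaluation.
#' @return FWHM in seconds.
#' @export
kernel_fwhm <- function(rise_tau, decay_tau, plateau_s = 0, dt = 1e-3) {
  tmax <- plateau_s + rise_tau * 10 + decay_tau * 15
  t <- seq(0, tmax, by = dt)
  y <- ca_kernel(t, 1, rise_tau, decay_tau, plateau_s)
  half <- max(y) / 2
  above <- which(y >= half)
  i1 <- above[1]; i2 <- above[length(above)]
  t_up <- if (i1 == 1) t[1] else {
    t[i1 - 1] + dt * (half - y[i1 - 1]) / (y[i1] - y[i1 - 1])
  }
  t_dn <- t[i2] + if (i2 < length(y)) dt * (y[i2] - half) / (y[i2] - y[i2 + 1]) else 0
  t_dn - t_up
}
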