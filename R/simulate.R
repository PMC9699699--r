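#' Simulate a field of view of spontaneous activity
#'
#' Generates raw fluorescence traces for \code{n_cells} cells sharing one
#' network drive. Event times are the union of a network-shared Poisson
#' train (rate \code{event_rate * shared_fraction}, identical across cells)
#' and a per-cell private Poisson train (rate
#' \code{event_rate * (1 - shared_fraction)}). Each event adds a unit-peak
#' kernel (\code{\link{ca_kernel}}) scaled by an amplitude drawn from
#' N(amplitude_mean, amplitude_sd) (truncated below at a quarter of the
#' mean) in dF/F0 space. The raw trace is
#' \deqn{F(t) = F_{bg} + F_{base}\,(1 + \sum_i g_i(t)) + \epsilon(t),}
#' with \eqn{\epsilon \sim N(0, (F_{base}\,\sigma)^2)} white noise.
#'
#' One RNG stream seeds the shared train; each cell then gets its own
#' stream derived from \code{seed} and the cell index, so per-cell output
#' is reproducible when \code{n_cells} changes.
#'
#' @param preset a \code{\link{stage_preset}}.
#' @param n_cells number of cells (>= 1).
#' @param duration_s recording duration (s).
#' @param fs sampling rate (Hz).
#' @param seed integer seed; identical (preset, seed) give bit-identical
#'   output.
#' @return object of class \code{synthetic_view}: list with \code{traces}
#'   (cells x time matrix of raw fluorescence), \code{fs}, \code{t},
#'   \code{preset}, \code{seed}, \code{truth_events} (per-cell data.frames
#'   of time/amplitude) and \code{truth_shared_times}.
#' @export
simulate_view <- function(preset, n_cells, duration_s, fs, seed) {
  stopifnot(inherits(preset, "stage_preset"), n_cells >= 1)
  if (fs <= 0 || duration_s <= 0) stop("fs and duration_s must be positive")
  n <- round(duration_s * fs)
  if (n < 10) stop("duration_s * fs must give at least 10 samples")
  tgrid <- (seq_len(n) - 1) / fs

  set.seed(seed %% .Machine$integer.max)
  sh_rate <- preset$event_rate * preset$shared_fraction
  n_sh <- stats::rpois(1, sh_rate * duration_s)
  shared_times <- sort(stats::runif(n_sh, 0, duration_s))

  traces <- matrix(0, nrow = n_cells, ncol = n)
  truth <- vector("list", n_cells)
  pv_rate <- preset$event_rate * (1 - preset$shared_fraction)
  for (i in seq_len(n_cells)) {
    set.seed((seed + i * 131071L) %% .Machine$integer.max)
    n_pv <- stats::rpois(1, pv_rate * duration_s)
    ev_t <- sort(c(shared_times, stats::runif(n_pv, 0, duration_s)))
    amp <- pmax(stats::rnorm(length(ev_t), preset$amplitude_mean,
                             preset$amplitude_sd),
                0.25 * preset$amplitude_mean)
    dff <- .sum_kernels(tgrid, ev_t, amp, preset)
    noise <- stats::rnorm(n, 0, 1) * preset$baseline_F * preset$noise_sd
    traces[i, ] <- preset$background_F +
      preset$baseline_F * (1 + dff) + noise
    truth[[i]] <- data.frame(time = ev_t, amplitude = amp)
  }
  rownames(traces) <- paste0("cell", seq_len(n_cells))
  structure(list(traces = traces, fs = fs, t = tgrid,
                 duration_s = duration_s, preset = preset, seed = seed,
                 truth_events = truth, truth_shared_times = shared_times),
            class = "synthetic_view")
}

# add each event kernel only over its own support window
.sum_kernels <- function(tgrid, ev_t, amp, preset) {
  n <- length(tgrid); fs <- 1 / (tgrid[2] - tgrid[1])
  dff <- numeric(n)
  span <- preset$plateau_s + preset$rise_tau * 12 + preset$decay_tau * 30
  for (j in seq_along(ev_t)) {
    i0 <- max(1L, floor(ev_t[j] * fs) + 1L)
    i1 <- min(n, ceiling((ev_t[j] + span) * fs) + 1L)
    if (i0 > n) next
    idx <- i0:i1
    dff[idx] <- dff[idx] + ca_kernel(tgrid[idx] - ev_t[j], amp[j],
                                     preset$rise_tau, preset$decay_tau,
                                     preset$plateau_s)
  }
  dff
}

#' @export
print.synthetic_view <- function(x, ...) {
  cat(sprintf("<synthetic_view %s:%s>  %d cells x %d samples (%.0f s @ %g Hz), seed %d\n",
              x$preset$stage_label, x$preset$condition, nrow(x$traces),
              ncol(x$traces), x$duration_s, x$fs, x$seed))
  invisible(x)
}

#' Simulate stimulus-aligned trials
#'
#' Each trial is a raw-fluorescence segment with a pre-onset baseline of at
#' least 1 s. With probability \code{response_prob} a stimulus-locked
#' kernel of peak amplitude \code{response_amp} is injected at the onset;
#' the injections are recorded as ground-truth response flags.
#'
#' @inheritParams simulate_view
#' @param n_trials number of trials.
#' @param response_prob probability a trial responds, in [0,1].
#' @param response_amp peak dF/F0 of the evoked response.
#' @param pre_s,post_s seconds before/after stimulus onset (pre_s >= 1).
#' @param stim_dur_s stimulus duration (s), carried in the result for
#'   response-window conventions.
#' @return object of class \code{trial_set}: list with \code{trials} (list
#'   of numeric raw traces), \code{onset_index}, \code{fs},
#'   \code{truth_response_flags}, \code{preset}, \code{stim_dur_s}.
#' @export
simulate_trials <- function(preset, n_trials, response_prob, response_amp,
                            fs, seed, pre_s = 2, post_s = 6, stim_dur_s = 1) {
  stopifnot(inherits(preset, "stage_preset"),
            response_prob >= 0, response_prob <= 1, n_trials >= 1)
  if (pre_s < 1) stop("trials need at least 1 s of pre-onset baseline")
  n_pre <- round(pre_s * fs)
  if (n_pre < fs) stop("fs too low to give 1 s of pre-onset baseline samples")
  n <- round((pre_s + post_s) * fs)
  onset <- n_pre + 1L
  tgrid <- (seq_len(n) - 1) / fs
  t_on <- tgrid[onset]

  set.seed(seed %% .Machine$integer.max)
  flags <- stats::runif(n_trials) < response_prob
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    dff <- numeric(n)
    if (flags[k]) {
      dff <- ca_kernel(tgrid - t_on, response_amp, preset$rise_tau,
                       preset$decay_tau, preset$plateau_s)
    }
    noise <- stats::rnorm(n, 0, 1) * preset$baseline_F * preset$noise_sd
    trials[[k]] <- preset$background_F + preset$baseline_F * (1 + dff) + noise
  }
  structure(list(trials = trials, onset_index = onset, fs = fs,
                 truth_response_flags = flags, preset = preset,
                 pre_s = pre_s, post_s = post_s, stim_dur_s = stim_dur_s,
                 seed = seed),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set>  %d trials, onset at sample %d (%g Hz), %d flagged responders\n",
              length(x$trials), x$onset_index, x$fs,
              sum(x$truth_response_flags)))
  invisible(x)
}
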