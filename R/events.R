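#' Detect spontaneous calcium events (three-standard-deviations rule)
#'
#' Events are local maxima of the dF/F0 trace exceeding
#' \code{median + k * SD}, where the SD is a robust estimate of the noise:
#' the scaled median absolute deviation of the first difference divided by
#' \eqn{\sqrt{2}} (\code{sd_mode = "noise"}, default) or the plain SD of
#' the whole trace (\code{sd_mode = "raw"}). Four deterministic refinements
#' make the rule robust at realistic sampling rates:
#' \enumerate{
#'   \item a candidate peak must be corroborated on a lightly smoothed copy
#'     of the trace (centred boxcar of \code{smooth_window} samples, whose
#'     noise SD is \code{SD/sqrt(w)}), suppressing single-sample noise
#'     spikes that the bare threshold admits;
#'   \item separation at half maximum: two candidates are distinct events
#'     only if the trace dips below half of the smaller peak height (above
#'     baseline) between them, otherwise they merge into the higher peak —
#'     this keeps long plateaued transients intact;
#'   \item each event must rise at least \code{k * SD} above the deeper of
#'     the valleys separating it from its neighbouring events (prominence),
#'     suppressing threshold-level bumps riding on slow decay tails;
#'   \item peaks closer than \code{min_separation} keep only the higher.
#' }
#'
#' @param dff a \code{\link{dff_trace}} (or numeric vector with \code{fs}).
#' @param k threshold multiple of the noise SD (default 3).
#' @param min_separation minimum event separation in seconds (default
#'   \code{2/fs}).
#' @param smooth_window boxcar width (samples) for the corroboration trace
#'   (default 3; 1 disables).
#' @param sd_mode noise-based (default) or raw-trace SD.
#' @param fs sampling rate, required for bare vectors.
#' @return an \code{event_table}: data.frame with columns \code{index},
#'   \code{t_peak} (s), \code{amplitude} (peak minus baseline median),
#'   plus columns \code{t_on50}, \code{t_off50}, \code{fwhm} filled by
#'   \code{\link{waveform_metrics}}; attributes \code{duration_s},
#'   \code{threshold}, \code{noise_sd}, \code{baseline}, \code{fs}.
#' @export
detect_events <- function(dff, k = 3, min_separation = NULL,
                          smooth_window = 3,
                          sd_mode = c("noise", "raw"), fs = NULL) {
  sd_mode <- match.arg(sd_mode)
  if (inherits(dff, "dff_trace")) { x <- dff$values; fs <- dff$fs }
  else { x <- as.numeric(dff); if (is.null(fs)) stop("fs required") }
  n <- length(x)
  if (n < 10) stop("trace needs at least 10 samples")
  if (is.null(min_separation)) min_separation <- 2 / fs
  w <- smooth_window

  sdn <- if (sd_mode == "noise") {
    stats::mad(diff(x)) / sqrt(2)
  } else stats::sd(x)
  base <- stats::median(x)
  th <- base + k * sdn
  if (sdn == 0 && stats::var(x) == 0) {
    warning("zero-variance trace; no events")
    return(.event_table(integer(0), numeric(0), x, fs, th, sdn, base))
  }

  xs <- .moving_average(x, w)
  th_s <- stats::median(xs) + k * sdn / sqrt(max(1, w))

  pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  pk <- pk[x[pk] > th & xs[pk] > th_s]

  # separation at half maximum (hysteresis merge, keep higher peak)
  if (length(pk) > 1) {
    acc <- pk[1]
    for (j in pk[-1]) {
      prev <- acc[length(acc)]
      valley <- min(x[prev:j])
      lo <- min(x[prev], x[j])
      if (valley < base + 0.5 * (lo - base)) acc <- c(acc, j)
      else if (x[j] > x[prev]) acc[length(acc)] <- j
    }
    pk <- acc
  }

  # prominence vs adjacent-event valleys
  if (length(pk) > 1) {
    m <- length(pk); keep <- logical(m)
    for (i in seq_len(m)) {
      vl <- min(x[(if (i == 1) 1L else pk[i - 1]):pk[i]])
      vr <- min(x[pk[i]:(if (i == m) n else pk[i + 1])])
      keep[i] <- (x[pk[i]] - max(vl, vr)) >= k * sdn
    }
    pk <- pk[keep]
  }

  # minimum separation, higher peak wins
  if (length(pk) > 1) {
    ord <- order(x[pk], decreasing = TRUE)
    keep <- logical(length(pk))
    for (j in ord) {
      if (!any(abs(pk[keep] - pk[j]) < min_separation * fs)) keep[j] <- TRUE
    }
    pk <- sort(pk[keep])
  }

  .event_table(pk, x[pk] - base, x, fs, th, sdn, base)
}

.event_table <- function(idx, amp, x, fs, th, sdn, base) {
  m <- length(idx)
  tab <- data.frame(index = as.integer(idx),
                    t_peak = (as.integer(idx) - 1) / fs,
                    amplitude = as.numeric(amp),
                    t_on50 = rep(NA_real_, m), t_off50 = rep(NA_real_, m),
                    fwhm = rep(NA_real_, m))
  structure(tab, class = c("event_table", "data.frame"),
            duration_s = length(x) / fs, threshold = th,
            noise_sd = sdn, baseline = base, fs = fs)
}

#' Event frequency in mHz
#'
#' \code{1000 * number of events / recording duration}.
#'
#' @param table an \code{event_table} from \code{\link{detect_events}}.
#' @return frequency in mHz.
#' @export
event_frequency_mHz <- function(table) {
  dur <- attr(table, "duration_s")
  if (is.null(dur) || dur <= 0) stop("event table lacks a positive duration")
  1000 * nrow(table) / dur
}

#' Waveform metrics: FWHM and 50% rise/decay times
#'
#' For each detected event the half-maximum level is half the peak height
#' above the local baseline; crossing times are linearly interpolated
#' between bracketing samples. Overlapping events are split at the
#' inter-event minimum; the local baseline on each side is the larger of
#' the global baseline median and the flanking minimum, so a transient
#' riding on a neighbour's tail is measured against its own pedestal.
#' \code{fwhm} is the time between the upward and downward half-maximum
#' crossings, \code{t_on50} the time from the upward crossing to the peak,
#' \code{t_off50} the time from the peak to the downward crossing. Events
#' truncated by the trace edge (no crossing inside their segment) keep
#' \code{NA} metrics.
#'
#' @param dff the \code{\link{dff_trace}} the events were detected on.
#' @param table the \code{event_table} from \code{\link{detect_events}}.
#' @return the event table with \code{t_on50}, \code{t_off50}, \code{fwhm}
#'   filled (seconds).
#' @export
waveform_metrics <- function(dff, table) {
  stopifnot(inherits(dff, "dff_trace"))
  x <- dff$values; fs <- dff$fs; n <- length(x)
  pk <- table$index
  if (!length(pk)) return(table)
  med <- stats::median(x)
  bnds <- if (length(pk) > 1) {
    vapply(seq_len(length(pk) - 1),
           function(i) pk[i] - 1L + which.min(x[pk[i]:pk[i + 1]]),
           numeric(1))
  } else numeric(0)
  bnds <- c(1, bnds, n)
  for (i in seq_along(pk)) {
    b1 <- bnds[i]; b2 <- bnds[i + 1]; p <- pk[i]
    # the pedestal of a riding event is the larger flanking minimum, but a
    # flank only counts when a neighbouring event sits on that side --
    # otherwise (trace edges) the baseline median is the reference
    left_min <- if (i > 1) min(x[b1:p]) else med
    right_min <- if (i < length(pk)) min(x[p:b2]) else med
    base <- max(med, left_min, right_min)
    half <- base + (x[p] - base) / 2
    up <- .cross_left(x, p, b1, half)
    dn <- .cross_right(x, p, b2, half)
    if (is.na(up) || is.na(dn)) next
    table$t_on50[i] <- (p - 1) / fs - up / fs
    table$t_off50[i] <- dn / fs - (p - 1) / fs
    table$fwhm[i] <- (dn - up) / fs
  }
  table
}

# interpolated crossing (0-based sample units) walking left from peak
.cross_left <- function(x, p, b1, half) {
  j <- p
  while (j > b1 && x[j - 1] >= half) j <- j - 1
  if (j == b1 && x[b1] >= half) return(NA_real_)  # truncated
  (j - 1) - (x[j] - half) / (x[j] - x[j - 1])
}

.cross_right <- function(x, p, b2, half) {
  j <- p
  while (j < b2 && x[j + 1] >= half) j <- j + 1
  if (j == b2 && x[b2] >= half) return(NA_real_)
  (j - 1) + (x[j] - half) / (x[j] - x[j + 1])
}

#' Trial success rate
#'
#' A trial succeeds when its post-onset maximum exceeds the pre-onset
#' baseline mean plus \code{k} baseline SDs. The response window is
#' [onset, onset + stimulus duration + 1 s]; the baseline window is the
#' 1 s right before the onset. The criterion is applied to the raw trial
#' segments directly (it is invariant to the affine dF/F0 transform).
#'
#' @param trials a \code{\link{simulate_trials}} result, or a list with
#'   elements \code{trials}, \code{onset_index}, \code{fs},
#'   \code{stim_dur_s}.
#' @param k baseline SD multiple (default 3).
#' @return fraction of successful trials in [0,1].
#' @export
trial_success_rate <- function(trials, k = 3) {
  fs <- trials$fs; onset <- trials$onset_index
  nb <- round(fs)
  if (onset - nb < 1) stop("trials need >= 1 s of pre-onset baseline")
  stim <- if (!is.null(trials$stim_dur_s)) trials$stim_dur_s else 1
  succ <- vapply(trials$trials, function(x) {
    n <- length(x)
    base <- x[(onset - nb):(onset - 1)]
    resp_end <- min(n, onset + round((stim + 1) * fs))
    max(x[onset:resp_end]) > mean(base) + k * stats::sd(base)
  }, logical(1))
  mean(succ)
}
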