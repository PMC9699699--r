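#' Raw fluorescence trace
#'
#' Lightweight container for a sampled fluorescence signal in arbitrary
#' units.
#'
#' @param values numeric vector of fluorescence samples (length >= 10,
#'   finite).
#' @param fs sampling rate, Hz.
#' @param meta optional named list of identifiers (cell, view, ...).
#' @return object of class \code{raw_trace}.
#' @export
raw_trace <- function(values, fs, meta = list()) {
  values <- as.numeric(values)
  if (length(values) < 10) stop("trace needs at least 10 samples")
  if (!all(is.finite(values))) stop("trace values must be finite")
  if (fs <= 0) stop("fs must be positive")
  structure(list(values = values, fs = fs, meta = meta), class = "raw_trace")
}

#' dF/F0 trace
#'
#' @param values numeric vector of dF/F0 samples.
#' @param f0 baseline fluorescence used for normalisation (> 0).
#' @param fs sampling rate, Hz.
#' @return object of class \code{dff_trace}.
#' @export
dff_trace <- function(values, f0, fs) {
  if (f0 <= 0) stop("f0 must be positive")
  if (fs <= 0) stop("fs must be positive")
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("dF/F0 values must be finite")
  structure(list(values = values, f0 = f0, fs = fs), class = "dff_trace")
}

.trace_values <- function(x) {
  if (inherits(x, c("raw_trace", "dff_trace"))) x$values else as.numeric(x)
}

#' Baseline fluorescence F0
#'
#' F0 is the average of \code{n_rest} data points at rest. "At rest" is
#' operationalised as the contiguous \code{n_rest}-sample window with the
#' minimal mean over the whole trace (\code{method = "rest_window"},
#' default), which deterministically avoids transients; alternatively the
#' first \code{n_rest} samples can be used (\code{method = "first_n"}).
#'
#' @param trace a \code{raw_trace} or numeric vector (background-subtracted
#'   fluorescence).
#' @param n_rest number of rest samples averaged (default 5).
#' @param method rest-window search (default) or first-n samples.
#' @return baseline fluorescence, same units as the input.
#' @export
compute_f0 <- function(trace, n_rest = 5,
                       method = c("rest_window", "first_n")) {
  method <- match.arg(method)
  x <- .trace_values(trace)
  n <- length(x)
  if (n < n_rest) stop("trace shorter than n_rest")
  f0 <- if (method == "first_n") {
    mean(x[seq_len(n_rest)])
  } else {
    cs <- cumsum(c(0, x))
    means <- (cs[(n_rest + 1):(n + 1)] - cs[1:(n - n_rest + 1)]) / n_rest
    min(means)
  }
  if (f0 <= 0) warning("non-positive F0; dF/F0 conversion will fail")
  f0
}

#' Convert raw fluorescence to dF/F0
#'
#' Background is subtracted first, then
#' \eqn{\Delta F/F_0 = ((F - F_{bg}) - F_0)/F_0} sample-wise. \code{f0}
#' must have been computed on background-subtracted values.
#'
#' @param trace a \code{raw_trace} or numeric vector.
#' @param background scalar background fluorescence (same units as F).
#' @param f0 baseline fluorescence from \code{\link{compute_f0}}; if
#'   missing it is computed from the background-subtracted trace.
#' @param fs sampling rate, required when \code{trace} is a bare vector.
#' @return a \code{\link{dff_trace}}.
#' @export
to_dff <- function(trace, background = 0, f0 = NULL, fs = NULL) {
  x <- .trace_values(trace) - background
  if (is.null(fs)) {
    if (!inherits(trace, "raw_trace")) stop("fs required for bare vectors")
    fs <- trace$fs
  }
  if (is.null(f0)) f0 <- compute_f0(x)
  if (f0 <= 0) stop("f0 must be positive")
  dff_trace((x - f0) / f0, f0 = f0, fs = fs)
}

#' Neuropil correction
#'
#' \eqn{F_{cell}(t) = F_{measured}(t) - r\,F_{neuropil}(t)} with the
#' conventional contamination ratio r = 0.7.
#'
#' @param measured \code{raw_trace} (or numeric) from the cell ROI.
#' @param neuropil \code{raw_trace} (or numeric) from the surrounding
#'   neuropil annulus, same length and sampling.
#' @param r contamination ratio (default 0.7).
#' @return corrected \code{raw_trace} (or numeric vector if both inputs
#'   were bare vectors).
#' @export
neuropil_correct <- function(measured, neuropil, r = 0.7) {
  xm <- .trace_values(measured); xn <- .trace_values(neuropil)
  if (length(xm) != length(xn)) stop("measured and neuropil lengths differ")
  if (inherits(measured, "raw_trace") && inherits(neuropil, "raw_trace") &&
      measured$fs != neuropil$fs) stop("sampling rates differ")
  out <- xm - r * xn
  if (inherits(measured, "raw_trace")) {
    raw_trace(out, measured$fs, measured$meta)
  } else out
}

#' Stimulus-evoked signal-to-noise ratio
#'
#' Ratio of the post-onset dF/F0 maximum to the standard deviation of the
#' moving-average-filtered dF/F0 over the 1 s window right before the
#' stimulus.
#'
#' @param dff a \code{\link{dff_trace}}.
#' @param onset_index sample index of stimulus onset (1-based).
#' @param smooth_window centred moving-average width in samples for the
#'   baseline filter (default 3; 1 disables filtering).
#' @param stim_dur_s stimulus duration (s); the response window is
#'   [onset, onset + stim_dur_s + 1 s].
#' @return SNR (dimensionless); \code{Inf} with a warning for a
#'   zero-variance baseline.
#' @export
stimulus_snr <- function(dff, onset_index, smooth_window = 3,
                         stim_dur_s = 1) {
  stopifnot(inherits(dff, "dff_trace"))
  x <- dff$values; fs <- dff$fs; n <- length(x)
  nb <- round(fs)  # 1 s of baseline samples
  if (onset_index - nb < 1) stop("need >= 1 s of samples before onset")
  # filter the pre-onset segment only, so the response cannot bleed into
  # the baseline through the smoothing window
  pre <- x[seq_len(onset_index - 1)]
  xf <- if (smooth_window > 1) {
    as.numeric(stats::filter(pre, rep(1 / smooth_window, smooth_window),
                             sides = 2))
  } else pre
  base <- utils::tail(xf, nb)
  resp_end <- min(n, onset_index + round((stim_dur_s + 1) * fs))
  num <- max(x[onset_index:resp_end])
  den <- stats::sd(base, na.rm = TRUE)
  if (is.na(den) || den == 0) {
    warning("zero-variance pre-onset baseline; SNR is infinite")
    return(Inf)
  }
  num / den
}

# centred boxcar; edges fall back to the raw samples
.moving_average <- function(x, w) {
  if (w <= 1) return(x)
  xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  nas <- is.na(xs)
  xs[nas] <- x[nas]
  xs
}
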