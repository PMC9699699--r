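#' Network synchrony per field of view
#'
#' Spearman rank correlation for every unordered pair of traces
#' (average-rank tie handling); the view synchrony is the mean over the
#' strict upper triangle. A constant trace has no defined rank correlation:
#' its pairs are flagged missing and excluded from the mean with a warning.
#'
#' @param traces a cells x time numeric matrix, a list of
#'   \code{\link{dff_trace}}, or a \code{synthetic_view}.
#' @return object of class \code{synchrony_result}: list with
#'   \code{pair_matrix} (symmetric, unit diagonal), \code{mean_coefficient}
#'   and \code{n_cells}.
#' @export
view_synchrony <- function(traces) {
  mat <- .as_trace_matrix(traces)
  if (nrow(mat) < 2) stop("need at least 2 traces")
  cm <- suppressWarnings(stats::cor(t(mat), method = "spearman"))
  diag(cm) <- 1
  up <- cm[upper.tri(cm)]
  if (anyNA(up)) warning("constant trace(s): undefined pairs excluded from the mean")
  structure(list(pair_matrix = cm,
                 mean_coefficient = mean(up, na.rm = TRUE),
                 n_cells = nrow(mat)),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("<synchrony_result>  %d cells, mean pairwise Spearman %.3f\n",
              x$n_cells, x$mean_coefficient))
  invisible(x)
}

.as_trace_matrix <- function(traces) {
  if (inherits(traces, "synthetic_view")) return(traces$traces)
  if (is.matrix(traces)) return(traces)
  if (is.list(traces)) {
    return(do.call(rbind, lapply(traces, .trace_values)))
  }
  stop("unsupported trace container")
}

#' One-sided FFT amplitude spectrum
#'
#' The mean is removed, the discrete Fourier transform taken, and each bin
#' reported as \code{2 * sqrt(Re^2 + Im^2) / n} for frequencies strictly
#' between 0 and the Nyquist frequency (the DC bin and, for even n, the
#' Nyquist bin are not doubled). The frequency grid is \code{k * fs / n}.
#'
#' @param dff a \code{\link{dff_trace}} or numeric vector.
#' @param fs sampling rate, required for bare vectors.
#' @return object of class \code{spectral_decomposition}: list with
#'   \code{freqs} (Hz, ascending from 0 to Nyquist), \code{amplitude},
#'   \code{re}, \code{im}, \code{n}, \code{fs}.
#' @export
amplitude_spectrum <- function(dff, fs = NULL) {
  if (inherits(dff, "dff_trace")) { x <- dff$values; fs <- dff$fs }
  else { x <- as.numeric(dff); if (is.null(fs)) stop("fs required") }
  n <- length(x)
  if (n < 16) stop("need at least 16 samples")
  ft <- stats::fft(x - mean(x))
  nb <- floor(n / 2) + 1L           # bins k = 0 .. floor(n/2)
  scale <- rep(2, nb)
  scale[1] <- 1                     # DC
  if (n %% 2 == 0) scale[nb] <- 1   # Nyquist (even n only)
  amp <- scale * Mod(ft[seq_len(nb)]) / n
  structure(list(freqs = (seq_len(nb) - 1) * fs / n,
                 amplitude = amp,
                 re = Re(ft[seq_len(nb)]), im = Im(ft[seq_len(nb)]),
                 n = n, fs = fs),
            class = "spectral_decomposition")
}

#' Oscillation band fractions
#'
#' Integrates the amplitude spectrum over the ultra-slow (< 10 mHz), slow
#' (10-100 mHz) and fast (100-300 mHz) bands by trapezoidal rule on the
#' bin grid (with linear interpolation at the band edges) and reports each
#' integral as a percentage of the three-band total. Energy above the fast
#' band is returned separately in the \code{"above_band"} attribute, not
#' in the percentages.
#'
#' @param spec a \code{spectral_decomposition}.
#' @param edges_mHz band edges in mHz (default \code{c(0, 10, 100, 300)}).
#' @return named numeric vector (percent) for the three bands, summing to
#'   100; attributes \code{integrals} and \code{above_band}.
#' @export
band_fractions <- function(spec, edges_mHz = c(0, 10, 100, 300)) {
  stopifnot(inherits(spec, "spectral_decomposition"),
            length(edges_mHz) == 4, !is.unsorted(edges_mHz))
  f <- spec$freqs * 1000  # mHz
  a <- spec$amplitude
  if (max(f) < edges_mHz[4]) {
    warning("spectrum does not reach ", edges_mHz[4],
            " mHz; fast band unavailable")
  }
  ints <- vapply(seq_len(3), function(b) {
    .trapz_band(f, a, edges_mHz[b], edges_mHz[b + 1])
  }, numeric(1))
  for (b in seq_len(3)) {
    if (!any(f > edges_mHz[b] & f < edges_mHz[b + 1])) {
      warning("no spectral bin strictly inside band ", b,
              " [", edges_mHz[b], ", ", edges_mHz[b + 1], ") mHz")
    }
  }
  total <- sum(ints)
  pct <- if (total > 0) 100 * ints / total else rep(0, 3)
  names(pct) <- c(
    sprintf("ultra_slow_lt%gmHz", edges_mHz[2]),
    sprintf("slow_%g_%gmHz", edges_mHz[2], edges_mHz[3]),
    sprintf("fast_%g_%gmHz", edges_mHz[3], edges_mHz[4]))
  attr(pct, "integrals") <- ints
  attr(pct, "above_band") <- .trapz_band(f, a, edges_mHz[4], max(f, edges_mHz[4]))
  pct
}

# trapezoid of piecewise-linear (f, a) restricted to [lo, hi]
.trapz_band <- function(f, a, lo, hi) {
  if (hi <= lo) return(0)
  lo <- max(lo, min(f)); hi <- min(hi, max(f))
  if (hi <= lo) return(0)
  inside <- f > lo & f < hi
  fg <- c(lo, f[inside], hi)
  ag <- c(stats::approx(f, a, xout = lo)$y, a[inside],
          stats::approx(f, a, xout = hi)$y)
  sum(diff(fg) * (utils::head(ag, -1) + utils::tail(ag, -1)) / 2)
}

#' Per-view spectrum and band fractions
#'
#' Computes the amplitude spectrum of every cell in a view and averages
#' per-bin (\code{mode = "per_cell"}, default), or computes one spectrum of
#' the view-mean trace (\code{mode = "view_mean"}).
#'
#' @param traces matrix, list of traces, or \code{synthetic_view}.
#' @param fs sampling rate, required for bare matrices.
#' @param mode averaging convention.
#' @return a \code{spectral_decomposition} (re/im are NA for the averaged
#'   per-cell mode).
#' @export
view_spectrum <- function(traces, fs = NULL, mode = c("per_cell", "view_mean")) {
  mode <- match.arg(mode)
  mat <- .as_trace_matrix(traces)
  if (inherits(traces, "synthetic_view")) fs <- traces$fs
  if (is.null(fs)) stop("fs required")
  if (mode == "view_mean") return(amplitude_spectrum(colMeans(mat), fs))
  specs <- lapply(seq_len(nrow(mat)), function(i) amplitude_spectrum(mat[i, ], fs))
  amp <- Reduce(`+`, lapply(specs, `[[`, "amplitude")) / length(specs)
  structure(list(freqs = specs[[1]]$freqs, amplitude = amp,
                 re = NA_real_, im = NA_real_,
                 n = specs[[1]]$n, fs = fs),
            class = "spectral_decomposition")
}
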