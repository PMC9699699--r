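# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-implementations (plain loops, closed forms) kept
# separate from the package code paths they check.

# Exhaustive event-detection oracle: scans every sample against the
# documented rule set (noise SD, threshold, corroboration, half-maximum
# separation, prominence, minimum separation), with no shared code.
oracle_detect <- function(x, fs, k = 3, w = 3, min_sep_s = 2 / fs) {
  n <- length(x)
  d <- diff(x)
  sdn <- stats::median(abs(d - stats::median(d))) * 1.4826 / sqrt(2)
  xs <- x
  if (w > 1) {
    xs <- vapply(seq_len(n), function(i) {
      lo <- i - (w %/% 2); hi <- i + (w %/% 2)
      if (lo < 1 || hi > n) x[i] else mean(x[lo:hi])
    }, numeric(1))
  }
  base <- stats::median(x)
  th <- base + k * sdn
  th_s <- stats::median(xs) + k * sdn / sqrt(w)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1] &&
        x[i] > th && xs[i] > th_s) cand <- c(cand, i)
  }
  # separation at half maximum
  acc <- integer(0)
  for (j in cand) {
    if (!length(acc)) { acc <- j; next }
    prev <- acc[length(acc)]
    valley <- min(x[prev:j])
    lo <- min(x[prev], x[j])
    if (valley < base + 0.5 * (lo - base)) acc <- c(acc, j)
    else if (x[j] > x[prev]) acc[length(acc)] <- j
  }
  # prominence
  if (length(acc) > 1) {
    keep <- logical(length(acc))
    for (i in seq_along(acc)) {
      left <- if (i == 1) 1 else acc[i - 1]
      right <- if (i == length(acc)) n else acc[i + 1]
      prom <- x[acc[i]] - max(min(x[left:acc[i]]), min(x[acc[i]:right]))
      keep[i] <- prom >= k * sdn
    }
    acc <- acc[keep]
  }
  # minimum separation, higher first
  if (length(acc) > 1) {
    kept <- integer(0)
    for (j in acc[order(x[acc], decreasing = TRUE)]) {
      if (!length(kept) || all(abs(kept - j) >= min_sep_s * fs)) {
        kept <- c(kept, j)
      }
    }
    acc <- sort(kept)
  }
  acc
}

# rank-then-Pearson Spearman oracle with average ranks
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# brute-force per-stage mean/SEM
oracle_groupby <- function(div, value) {
  divs <- sort(unique(div))
  data.frame(
    div = divs,
    mean = vapply(divs, function(d) mean(value[div == d]), numeric(1)),
    sem = vapply(divs, function(d) {
      v <- value[div == d]
      stats::sd(v) / sqrt(length(v))
    }, numeric(1)))
}

# pooled-variance two-sample t oracle
oracle_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), na + nb - 2)
  list(t = t, p = p, df = na + nb - 2)
}

# dense-grid half-width of the event kernel (root-solved independently of
# kernel_fwhm's interpolation)
oracle_kernel_fwhm <- function(rise, decay, plateau = 0, dt = 1e-5) {
  t <- seq(0, plateau + rise * 10 + decay * 15, by = dt)
  y <- (1 - exp(-t / rise)) * exp(-pmax(0, t - plateau) / decay)
  half <- max(y) / 2
  idx <- range(which(y >= half))
  t[idx[2]] - t[idx[1]]
}

# exact circle / polyline-segment intersection points for the Sholl oracle
oracle_circle_crossing_points <- function(polylines, center, r_px) {
  pts <- matrix(numeric(0), ncol = 2)
  for (pl in polylines) {
    for (s in seq_len(nrow(pl) - 1)) {
      p0 <- pl[s, ] - center; p1 <- pl[s + 1, ] - center
      dvec <- p1 - p0
      a <- sum(dvec^2)
      b <- 2 * sum(p0 * dvec)
      cc <- sum(p0^2) - r_px^2
      disc <- b^2 - 4 * a * cc
      if (disc <= 0 || a == 0) next
      for (tt in (-b + c(-1, 1) * sqrt(disc)) / (2 * a)) {
        if (tt >= 0 && tt < 1) pts <- rbind(pts, p0 + tt * dvec + center)
      }
    }
  }
  pts
}

oracle_circle_crossings <- function(polylines, center, r_px) {
  nrow(oracle_circle_crossing_points(polylines, center, r_px))
}

# standard-normal helpers for the binomial / Poisson 3-SE checks
se_binom <- function(p, n) sqrt(p * (1 - p) / n)

# standard error (mHz) of the view-mean event frequency for a shared +
# private Poisson design: the shared train moves every cell together
se_view_freq_mHz <- function(rate, shared_fraction, duration_s, n_cells) {
  var_events <- shared_fraction * rate * duration_s +
    (1 - shared_fraction) * rate * duration_s / n_cells
  1000 * sqrt(var_events) / duration_s
}
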