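test_that("synchrony of identical, opposite and independent traces", {
  set.seed(5)
  a <- cumsum(rnorm(300))
  s1 <- view_synchrony(rbind(a, a))
  expect_equal(s1$mean_coefficient, 1.0)
  s2 <- view_synchrony(rbind(a, -a))
  expect_equal(s2$mean_coefficient, -1.0)
  mat <- matrix(rnorm(10 * 1000), nrow = 10)
  s3 <- view_synchrony(mat)
  # pairwise null SD for Spearman is ~1/sqrt(n-1); mean over 45 pairs
  expect_lt(abs(s3$mean_coefficient), 3 / sqrt(999) / sqrt(45) * 3)
  expect_true(isSymmetric(s3$pair_matrix))
  expect_equal(diag(s3$pair_matrix), rep(1, 10))
})

test_that("every pair equals the rank-then-Pearson oracle", {
  set.seed(6)
  mat <- matrix(rnorm(5 * 400), nrow = 5)
  mat[2, ] <- round(mat[2, ], 1)            # force ties
  s <- view_synchrony(mat)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(s$pair_matrix[i, j], oracle_spearman(mat[i, ], mat[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("synchrony is invariant under strictly monotone transforms", {
  set.seed(7)
  mat <- matrix(abs(rnorm(3 * 200)) + 0.1, nrow = 3)
  ref <- view_synchrony(mat)$mean_coefficient
  mat2 <- mat; mat2[1, ] <- log(mat2[1, ]); mat2[2, ] <- mat2[2, ]^3
  expect_equal(view_synchrony(mat2)$mean_coefficient, ref, tolerance = 1e-12)
})

test_that("constant traces are flagged and excluded from the mean", {
  set.seed(8)
  mat <- rbind(rnorm(50), rnorm(50), rep(1, 50))
  expect_warning(s <- view_synchrony(mat), "constant")
  expect_equal(s$mean_coefficient,
               oracle_spearman(mat[1, ], mat[2, ]), tolerance = 1e-12)
})

test_that("synchrony rises with the generator's shared fraction", {
  pr <- build_stage_presets()
  p0 <- get_preset(pr, "DIV14", "healthy")
  # with zero noise and equal amplitudes a fully shared drive makes the
  # traces identical, so the rank correlation is exactly 1
  res <- vapply(c(0, 0.5, 1), function(sf) {
    p <- stage_preset("DIV14", "healthy", 0.08, shared_fraction = sf,
                      p0$amplitude_mean, amplitude_sd = 0, p0$rise_tau,
                      p0$decay_tau, noise_sd = 0)
    v <- simulate_view(p, 6, 300, 5, seed = 11)
    view_synchrony(v)$mean_coefficient
  }, numeric(1))
  expect_true(all(diff(res) > 0))
  expect_lt(abs(res[1]), 0.1)
  expect_equal(res[3], 1.0, tolerance = 1e-9)
})

test_that("a pure tone has its amplitude at its bin and nothing elsewhere", {
  fs <- 5; n <- 1000                        # 50 mHz = bin 10 exactly
  t <- (0:(n - 1)) / fs
  x <- 2.0 * sin(2 * pi * 0.05 * t)
  sp <- amplitude_spectrum(x, fs = fs)
  i50 <- which.min(abs(sp$freqs - 0.05))
  expect_equal(sp$freqs[i50], 0.05)
  expect_equal(sp$amplitude[i50], 2.0, tolerance = 1e-9)
  expect_lt(max(sp$amplitude[-i50]), 1e-9)
  expect_equal(amplitude_spectrum(rep(3, 64), fs = 5)$amplitude,
               rep(0, 33))
})

test_that("one-sided amplitudes satisfy Parseval within 1 percent", {
  set.seed(9)
  for (n in c(1000, 1001)) {               # even and odd lengths
    x <- rnorm(n)
    sp <- amplitude_spectrum(x, fs = 5)
    # per-bin one-sided power: amp^2/2 for doubled bins, amp^2 otherwise
    pw <- sp$amplitude^2 / 2
    pw[1] <- sp$amplitude[1]^2
    if (n %% 2 == 0) pw[length(pw)] <- sp$amplitude[length(pw)]^2
    expect_equal(sum(pw), mean((x - mean(x))^2), tolerance = 0.01)
  }
})

test_that("spectrum is scale-equivariant and the grid is one-sided", {
  set.seed(10)
  x <- rnorm(256)
  s1 <- amplitude_spectrum(x, fs = 2)
  s3 <- amplitude_spectrum(3 * x, fs = 2)
  expect_equal(s3$amplitude, 3 * s1$amplitude, tolerance = 1e-12)
  expect_true(!is.unsorted(s1$freqs))
  expect_lte(max(s1$freqs), 1)             # Nyquist
  expect_error(amplitude_spectrum(rnorm(8), fs = 5), "16")
})

test_that("band fractions put tones in the right bands and sum to 100", {
  fs <- 5; n <- 2000
  t <- (0:(n - 1)) / fs
  tone <- function(f) sin(2 * pi * f * t)
  bf1 <- band_fractions(amplitude_spectrum(tone(0.05), fs))
  expect_equal(as.numeric(bf1), c(0, 100, 0), tolerance = 1e-6)
  bf2 <- band_fractions(amplitude_spectrum(tone(0.005) + tone(0.05), fs))
  expect_equal(as.numeric(bf2), c(50, 50, 0), tolerance = 0.5)
  set.seed(11)
  bf3 <- suppressWarnings(band_fractions(amplitude_spectrum(rnorm(500), fs)))
  expect_equal(sum(bf3), 100, tolerance = 1e-12)
})

test_that("the slow-band share dominates ultra-slow and grows with maturation", {
  # a Poisson train filtered by second-scale kernels is spectrally broad,
  # so the 200-mHz-wide fast band keeps a large share; the maturation trend
  # (slow share rising as events widen and slow down) is the recoverable
  # signature
  pr <- build_stage_presets()
  slow_share <- vapply(c("DIV10", "DIV28"), function(st) {
    v <- simulate_view(get_preset(pr, st, "healthy"), 8, 600, 5, seed = 12)
    dffs <- lapply(seq_len(8), function(i) {
      dff_trace((v$traces[i, ] - 20) / 100 - 1, 100, 5)
    })
    bf <- band_fractions(view_spectrum(dffs, fs = 5))
    bf[[2]]
  }, numeric(1))
  expect_gt(slow_share[2], slow_share[1])
  v <- simulate_view(get_preset(pr, "DIV17", "healthy"), 8, 600, 5, seed = 12)
  dffs <- lapply(seq_len(8), function(i) {
    dff_trace((v$traces[i, ] - 20) / 100 - 1, 100, 5)
  })
  bf <- band_fractions(view_spectrum(dffs, fs = 5))
  expect_gt(bf[[2]], bf[[1]])               # slow >> ultra-slow
})

test_that("a spectrum that cannot reach 300 mHz warns", {
  set.seed(12)
  sp <- amplitude_spectrum(rnorm(100), fs = 0.4)   # Nyquist 200 mHz
  expect_warning(band_fractions(sp), "300")
})
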