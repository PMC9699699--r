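pr <- build_stage_presets()

test_that("identical preset and seed give bit-identical views", {
  p <- get_preset(pr, "DIV14", "healthy")
  v1 <- simulate_view(p, 4, 60, 5, seed = 42)
  v2 <- simulate_view(p, 4, 60, 5, seed = 42)
  expect_identical(v1$traces, v2$traces)
  expect_identical(v1$truth_events, v2$truth_events)
  v3 <- simulate_view(p, 4, 60, 5, seed = 43)
  expect_false(identical(v1$traces, v3$traces))
})

test_that("per-cell streams survive a change in n_cells", {
  p <- get_preset(pr, "DIV14", "healthy")
  v4 <- simulate_view(p, 4, 60, 5, seed = 7)
  v6 <- simulate_view(p, 6, 60, 5, seed = 7)
  expect_identical(v4$traces[1:4, ], v6$traces[1:4, ])
})

test_that("truth event counts match the Poisson law across seeds", {
  p <- get_preset(pr, "DIV3", "healthy")
  counts <- unlist(lapply(1:20, function(s) {
    v <- simulate_view(p, 3, 200, 5, seed = 100 + s)
    vapply(v$truth_events, nrow, integer(1))
  }))
  lambda <- p$event_rate * 200
  n <- length(counts)
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / n) + 3 * sqrt(lambda) * sqrt(2 / n))
  # variance consistent with Poisson (chi-square-ish 3-SE bound)
  expect_lt(abs(var(counts) - lambda), 3 * lambda * sqrt(2 / n))
})

test_that("fully shared drive gives identical truth times across cells", {
  p0 <- get_preset(pr, "DIV14", "healthy")
  p <- stage_preset("DIV14", "healthy", p0$event_rate, shared_fraction = 1,
                    p0$amplitude_mean, amplitude_sd = 0, p0$rise_tau,
                    p0$decay_tau, noise_sd = 0)
  v <- simulate_view(p, 5, 120, 5, seed = 3)
  for (i in 2:5) {
    expect_equal(v$truth_events[[i]]$time, v$truth_events[[1]]$time)
  }
  expect_equal(v$truth_events[[1]]$time, v$truth_shared_times)
})

test_that("noise-free trace equals the summed closed-form kernels", {
  p0 <- get_preset(pr, "DIV10", "healthy")
  p <- stage_preset("DIV10", "healthy", 0.03, shared_fraction = 0,
                    p0$amplitude_mean, amplitude_sd = 0.1, p0$rise_tau,
                    p0$decay_tau, noise_sd = 0)
  v <- simulate_view(p, 2, 120, 5, seed = 9)
  for (i in 1:2) {
    ev <- v$truth_events[[i]]
    expected <- rep(0, length(v$t))
    for (j in seq_len(nrow(ev))) {
      expected <- expected + ca_kernel(v$t - ev$time[j], ev$amplitude[j],
                                       p$rise_tau, p$decay_tau, p$plateau_s)
    }
    # dF/F0 consistency: (raw - background)/baseline - 1 == summed kernels
    recovered <- (v$traces[i, ] - p$background_F) / p$baseline_F - 1
    expect_equal(recovered, unname(expected), tolerance = 1e-9)
  }
})

test_that("single noise-free event reproduces the kernel at every sample", {
  p <- stage_preset("DIV14", "healthy", event_rate = 1 / 600,
                    shared_fraction = 1, amplitude_mean = 1.5,
                    amplitude_sd = 0, rise_tau = 0.3, decay_tau = 1,
                    plateau_s = 0, noise_sd = 0)
  v <- simulate_view(p, 1, 600, 5, seed = 4)
  ev <- v$truth_events[[1]]
  expect_equal(nrow(ev), 1)  # this seed's Poisson draw gives one event
  dff <- (v$traces[1, ] - p$background_F) / p$baseline_F - 1
  expect_equal(unname(dff),
               ca_kernel(v$t - ev$time, 1.5, 0.3, 1, 0), tolerance = 1e-9)
  # unit-peak normalisation: the continuous kernel tops out at the drawn
  # amplitude (the sampling grid sits just off the peak)
  expect_equal(max(ca_kernel(seq(0, 20, 1e-4), 1.5, 0.3, 1, 0)), 1.5,
               tolerance = 1e-6)
  expect_lte(max(dff), 1.5 + 1e-9)
  expect_gt(max(dff), 1.5 * 0.999)
})

test_that("simulate_view validates its inputs", {
  p <- get_preset(pr, "DIV3", "healthy")
  expect_error(simulate_view(p, 2, 1, 5, seed = 1), "10 samples")
  expect_error(simulate_view(p, 2, 60, -5, seed = 1), "positive")
})

test_that("trial injections follow the binomial law and the flags", {
  p <- get_preset(pr, "DIV14", "healthy")
  ts <- simulate_trials(p, 1000, 0.7, 1.5, fs = 5, seed = 2)
  frac <- mean(ts$truth_response_flags)
  expect_lt(abs(frac - 0.7), 3 * se_binom(0.7, 1000))
  ts0 <- simulate_trials(p, 20, 0, 1.5, fs = 5, seed = 2)
  expect_false(any(ts0$truth_response_flags))
  # noise-free responders: post-onset max exceeds the pre-onset max
  pq <- stage_preset("DIV14", "healthy", p$event_rate, p$shared_fraction,
                     p$amplitude_mean, p$amplitude_sd, p$rise_tau,
                     p$decay_tau, noise_sd = 0)
  ts1 <- simulate_trials(pq, 10, 1, 1.5, fs = 5, seed = 4)
  expect_true(all(ts1$truth_response_flags))
  for (tr in ts1$trials) {
    on <- ts1$onset_index
    expect_gt(max(tr[on:length(tr)]), max(tr[1:(on - 1)]))
  }
})

test_that("trials refuse a sub-second baseline", {
  p <- get_preset(pr, "DIV14", "healthy")
  expect_error(simulate_trials(p, 5, 0.5, 1, fs = 5, seed = 1, pre_s = 0.5),
               "baseline")
})
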