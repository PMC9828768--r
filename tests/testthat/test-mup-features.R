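test_that("template building reproduces clean and noisy instances", {
  w <- toy_waveform()
  # identical instances: template equals any instance exactly
  tr <- toy_train(matrix(rep(w, 5), 5, byrow = TRUE))
  tmpl <- build_template(tr)
  expect_equal(tmpl$samples, w, tolerance = 1e-12)

  # averaging oracle: clean + zero-mean noise, n = 200
  set.seed(42)
  sigma <- 10
  n <- 200
  inst <- matrix(rep(w, n), n, byrow = TRUE) +
    matrix(rnorm(n * length(w), 0, sigma), n)
  tmpl <- build_template(toy_train(inst), max_shift_ms = 0)
  expect_lt(max(abs(tmpl$samples - w)), 3 * sigma / sqrt(n) * 1.5)
  expect_equal(tmpl$noise_rms_uV, sigma, tolerance = 0.15)

  # alignment oracle: known integer shifts are recovered exactly
  shifts <- c(0, 3, -2, 5, -4)
  inst <- t(vapply(shifts, function(s) {
    v <- numeric(length(w))
    idx <- seq_along(w) + s
    ok <- idx >= 1 & idx <= length(w)
    v[idx[ok]] <- w[ok]
    v
  }, numeric(length(w))))
  tmpl <- build_template(toy_train(inst), max_shift_ms = 1)
  expect_equal(tmpl$shifts - tmpl$shifts[1], shifts - shifts[1])

  expect_error(build_template(toy_train(matrix(numeric(0), 0, 10))))
})

test_that("marker placement matches analytic crossings", {
  fs <- 40000
  # Gaussian pulse of amplitude A over noise sigma_n: the 3*sigma_n crossing
  # sits at t = w * sqrt(2 log(A / (3 sigma_n)))
  A <- 200
  w_ms <- 0.5
  sigma_n <- 5
  n <- 1200
  t_ms <- (seq_len(n) - 1) / fs * 1000
  centre <- t_ms[n / 2]
  pulse <- A * exp(-(t_ms - centre)^2 / (2 * w_ms^2))
  tmpl <- structure(list(samples = pulse, fs_hz = fs, noise_rms_uV = sigma_n,
                         n_averaged = 1, shifts = 0L), class = "mup_template")
  mk <- place_markers(tmpl, k_onset = 3)
  half_width_ms <- w_ms * sqrt(2 * log(A / (3 * sigma_n)))
  expect_equal(mup_duration(mk, fs), 2 * half_width_ms,
               tolerance = 2 * 1000 / fs / (2 * half_width_ms))

  # symmetric triphasic pulse: onset < peaks < end, symmetric about centre
  v <- toy_waveform(n = 800, amp = 100)
  tmpl <- structure(list(samples = v, fs_hz = fs, noise_rms_uV = 1,
                         n_averaged = 1, shifts = 0L), class = "mup_template")
  mk <- place_markers(tmpl)
  expect_true(mk$onset_idx < mk$neg_peak_idx)
  expect_true(mk$pos_peak_idx < mk$end_idx)
  expect_lt(abs((mk$onset_idx + mk$end_idx - 1) / 2 - 400.5), 1.5)

  # flat template: marker failure
  flat <- structure(list(samples = numeric(500), fs_hz = fs,
                         noise_rms_uV = 0, n_averaged = 1, shifts = 0L),
                    class = "mup_template")
  expect_error(place_markers(flat), class = "nfemg_marker_failure")
})

test_that("duration is index arithmetic at the sampling rate", {
  mk <- structure(list(onset_idx = 100, end_idx = 500, pos_peak_idx = 200,
                       neg_peak_idx = 300), class = "marker_set")
  expect_equal(mup_duration(mk, 40000), 10)
  # one sample period at 40 kHz
  mk1 <- structure(list(onset_idx = 10, end_idx = 11, pos_peak_idx = 10,
                        neg_peak_idx = 10), class = "marker_set")
  expect_equal(mup_duration(mk1, 40000), 0.025)
  # halving fs doubles the reported ms
  expect_equal(mup_duration(mk, 20000), 20)
})

test_that("area matches closed-form integrals and scales linearly", {
  fs <- 40000
  mk <- function(a, b) structure(list(onset_idx = a, end_idx = b,
                                      pos_peak_idx = a, neg_peak_idx = a),
                                 class = "marker_set")
  tmpl_of <- function(v) structure(list(samples = v, fs_hz = fs,
                                        noise_rms_uV = 0, n_averaged = 1,
                                        shifts = 0L), class = "mup_template")
  # zero signal
  expect_equal(mup_area(tmpl_of(numeric(100)), mk(1, 101)), 0)
  # rectangular pulse 100 uV x 2 ms = 200 uV*ms
  n2ms <- 2 / 1000 * fs
  v <- c(numeric(10), rep(100, n2ms), numeric(10))
  expect_equal(mup_area(tmpl_of(v), mk(11, 11 + n2ms)), 200)
  # linearity in amplitude
  expect_equal(mup_area(tmpl_of(3 * v), mk(11, 11 + n2ms)), 600)
})

test_that("turns counting obeys the excursion threshold", {
  # monotone ramp: no turns
  expect_equal(count_turns(seq(0, 100, length.out = 50)), 0L)
  # alternating +/-30 uV: every reversal counted; +/-8 uV: none
  alt <- rep(c(30, -30), 10)
  expect_equal(count_turns(alt), length(alt) - 2L)
  expect_equal(count_turns(alt * 8 / 30), 0L)
  # scaled up, counts never decrease (threshold fixed)
  set.seed(7)
  for (i in 1:50) {
    v <- cumsum(sample(-30:30, 40, replace = TRUE))
    expect_gte(count_turns(2 * v), count_turns(v))
  }
})

test_that("turns counts agree exactly with the brute-force oracle", {
  set.seed(123)
  for (i in 1:1000) {
    v <- cumsum(sample(-25:25, 50, replace = TRUE))
    expect_identical(count_turns(v), oracle_turns(v, 20))
  }
})

test_that("SNR behaves as peak-to-peak over noise RMS", {
  w <- toy_waveform(amp = 150)  # peak-to-peak = 150 * (1 + 2 * exp(-1.5))
  set.seed(1)
  sigma <- 10
  inst <- matrix(rep(w, 100), 100, byrow = TRUE) +
    matrix(rnorm(100 * length(w), 0, sigma), 100)
  tr <- toy_train(inst)
  snr <- compute_snr(tr, max_shift_ms = 0)
  expect_equal(snr, diff(range(w)) / sigma, tolerance = 0.1)

  # doubling the signal doubles the SNR at fixed noise
  tr2 <- toy_train(inst + matrix(rep(w, 100), 100, byrow = TRUE))
  expect_equal(compute_snr(tr2, max_shift_ms = 0) / snr, 2, tolerance = 0.1)

  # a pure-noise train scores far below the inclusion threshold
  noise_tr <- toy_train(matrix(rnorm(200 * 400, 0, sigma), 200))
  expect_lt(compute_snr(noise_tr), 5)
})

test_that("IDI mean averages consecutive differences with outlier guard", {
  expect_equal(idi_mean(c(0, 100, 200, 300)), 100)
  expect_equal(idi_mean(c(0, 100, 205, 295)), mean(c(100, 105, 90)))
  # one missed discharge creates a double-length gap; the guard drops it
  tt <- cumsum(c(rep(100, 20), 200, rep(100, 20)))
  expect_equal(idi_mean(tt), 100, tolerance = 0.02)
  expect_error(idi_mean(50), class = "nfemg_insufficient_data")
})

test_that("duration and area are invariant to a pure time shift", {
  w <- toy_waveform(n = 1000)
  sh <- 40
  w2 <- c(numeric(sh), w[1:(length(w) - sh)])
  fs <- 40000
  t_of <- function(v) structure(list(samples = v, fs_hz = fs,
                                     noise_rms_uV = 1, n_averaged = 1,
                                     shifts = 0L), class = "mup_template")
  m1 <- place_markers(t_of(w))
  m2 <- place_markers(t_of(w2))
  expect_equal(mup_duration(m1, fs), mup_duration(m2, fs))
  expect_equal(mup_area(t_of(w), m1), mup_area(t_of(w2), m2))
})

test_that("noiseless simulator output reproduces the summed-MFP template", {
  mu <- motor_unit_model(list(
    fibre_model(0.06, mean_latency_ms = 2, jitter_sd_us = 0),
    fibre_model(0.12, mean_latency_ms = 4, jitter_sd_us = 0)), label = "gt")
  cfg <- sim_config(seed = 8, noise_rms_uV = 0)
  tr <- simulate_mup_train(mu, cfg)
  tmpl <- build_template(tr)
  # ground truth: sum of the two MFPs at their mean latencies
  n <- ncol(tr$instances)
  t_rel <- (seq_len(n) - 1) / cfg$fs_hz * 1000 - cfg$window_pre_ms
  truth <- numeric(n)
  for (fb in mu$fibres) {
    u2 <- ((t_rel - fb$mean_latency_ms) / fb$mfp_width_ms)^2
    truth <- truth + fb$mfp_amplitude_uV * (1 - u2) * exp(-u2 / 2)
  }
  expect_equal(tmpl$samples, truth, tolerance = 1e-12)
})
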