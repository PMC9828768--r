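test_that("NF filter rejects constant and linear inputs exactly", {
  fs <- 40000
  n <- 600
  for (x in list(rep(7, n), 3 + 0.5 * seq_len(n), -2 - 0.01 * seq_len(n))) {
    y <- nf_filter(x, fs)
    expect_lt(max(abs(y)), 1e-9 * max(abs(x)))
  }
  expect_error(nf_filter(numeric(5), fs), "kernel")
})

test_that("sinusoid attenuation matches the kernel transfer function", {
  fs <- 40000
  n <- 4000
  k <- nf_kernel(fs)
  t <- (seq_len(n) - 1) / fs
  h <- (length(k) - 1) %/% 2
  interior <- (h + 200):(n - h - 200)
  amp_out <- vapply(c(100, 2000), function(f) {
    y <- nf_filter(sin(2 * pi * f * t), fs)
    sine_amplitude(y[interior], f, fs, t0_samples = interior[1] - 1)
  }, numeric(1))
  measured_ratio <- amp_out[2] / amp_out[1]
  expected_ratio <- kernel_gain(k, 2000, fs) / kernel_gain(k, 100, fs)
  expect_equal(measured_ratio, expected_ratio, tolerance = 0.01)
  # it is a differentiator: high frequencies pass, low are suppressed
  expect_gt(measured_ratio, 100)
})

test_that("NF filtering sharpens the near-fibre/distant-fibre contrast", {
  fs <- 40000
  near <- simulate_mfp_waveform(fibre_model(0.05), fs, 25)
  far <- simulate_mfp_waveform(fibre_model(1), fs, 25)
  raw_ratio <- max(abs(near)) / max(abs(far))
  nf_ratio <- max(abs(nf_filter(near, fs))) / max(abs(nf_filter(far, fs)))
  expect_gt(nf_ratio, raw_ratio)
})

test_that("contribution detection counts distinct near fibres", {
  cfg <- sim_config(seed = 2, noise_rms_uV = 0.5)
  # single fibre, low noise
  tr1 <- simulate_mup_train(single_fibre_mu(20), cfg)
  d1 <- detect_contributions(nf_transform(tr1))
  expect_equal(d1$nf_count, 1L)

  # two near fibres 2 ms apart: two contributions, duration spans them
  mu2 <- motor_unit_model(list(
    fibre_model(0.06, mean_latency_ms = 2, jitter_sd_us = 20),
    fibre_model(0.06, mean_latency_ms = 4, jitter_sd_us = 20)), label = "two")
  nf2 <- nf_transform(simulate_mup_train(mu2, cfg))
  d2 <- detect_contributions(nf2)
  expect_equal(d2$nf_count, 2L)
  margin_ms <- (length(nf2$kernel) - 1) / 2 / cfg$fs_hz * 1000
  expect_equal(d2$nf_duration_ms, 2 + 2 * margin_ms, tolerance = 0.15)
  expect_equal(nrow(d2$segment_windows), 2L)

  # flat NF template: zero contributions (train then fails NF QC)
  flat <- toy_nf_train(matrix(0, 3, 200), numeric(200))
  expect_equal(detect_contributions(flat)$nf_count, 0L)
})

test_that("nf_count grows with the number of fibres near the electrode", {
  # Spearman association between near-fibre density and detected count
  densities <- rep(1:5, each = 20)
  counts <- vapply(seq_along(densities), function(i) {
    nf <- densities[i]
    fibres <- lapply(seq_len(nf), function(j)
      fibre_model(0.07, mean_latency_ms = 1 + 1.7 * j, jitter_sd_us = 20))
    mu <- motor_unit_model(fibres, label = sprintf("d%d_%d", nf, i))
    tr <- simulate_mup_train(mu, sim_config(seed = 1000 + i,
                                            contraction_duration_s = 5))
    detect_contributions(nf_transform(tr))$nf_count
  }, numeric(1))
  ct <- suppressWarnings(stats::cor.test(densities, counts,
                                         method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("jiggle matches its closed form on constructed instances", {
  # identical consecutive instances: exactly zero
  w <- toy_waveform(n = 200)
  same <- toy_nf_train(matrix(rep(w, 4), 4, byrow = TRUE), w)
  expect_equal(jiggle(same), 0)

  # alternating template / 1.1 * template: every consecutive difference is
  # 0.1 * sum|w|; the normaliser is the mean rectified area 1.05 * sum|w|
  alt <- toy_nf_train(rbind(w, 1.1 * w, w, 1.1 * w), w)
  expect_equal(jiggle(alt), 100 * 0.1 / 1.05, tolerance = 1e-10)

  # scale invariance: multiplying all instances by a constant cancels
  sc <- toy_nf_train(rbind(w, 1.1 * w, w, 1.1 * w) * 7.3, w * 7.3)
  expect_equal(jiggle(sc), jiggle(alt), tolerance = 1e-10)

  expect_error(jiggle(toy_nf_train(matrix(w, 1), w)),
               class = "nfemg_insufficient_data")
})

test_that("blocking raises jiggle monotonically in simulation", {
  med <- vapply(c(0, 0.15), function(bp) {
    js <- vapply(1:12, function(s) {
      mu <- single_fibre_mu(25, label = sprintf("b%g", bp),
                            blocking_prob = bp, amplitude_cv = 0.05)
      tr <- simulate_mup_train(mu, sim_config(seed = s,
                                              contraction_duration_s = 8))
      jiggle(nf_transform(tr))
    }, numeric(1))
    median(js)
  }, numeric(1))
  expect_gt(med[2], med[1])
})

test_that("segment jitter resolves deterministic sub-sample latencies", {
  fs <- 40000
  n <- 800
  t_ms <- (seq_len(n) - 1) / fs * 1000
  mk_inst <- function(lat_ms) {
    u2 <- ((t_ms - 10 - lat_ms) / 0.2)^2
    200 * (1 - u2) * exp(-u2 / 2)
  }
  # deterministic alternating latency +/-10 us: every consecutive
  # difference is 20 us
  lats <- rep(c(0.01, -0.01), 20)
  inst <- t(vapply(lats, mk_inst, numeric(n)))
  tr <- mup_train(fs, seq_along(lats) * 100, inst)
  nf <- nf_transform(tr)
  expect_equal(segment_jitter(nf), 20, tolerance = 0.05)

  # zero injected jitter, no noise: under 1 us of interpolation error
  inst0 <- t(vapply(rep(0, 10), mk_inst, numeric(n)))
  nf0 <- nf_transform(mup_train(fs, 1:10 * 100, inst0))
  expect_lt(segment_jitter(nf0), 1)

  # invariance to a common latency shift of every occurrence
  instS <- t(vapply(lats + 0.1, mk_inst, numeric(n)))
  nfS <- nf_transform(mup_train(fs, seq_along(lats) * 100, instS))
  expect_equal(segment_jitter(nfS), segment_jitter(nf), tolerance = 0.01)
})

test_that("segment jitter recovers injected NMJ jitter at 2 sigma / sqrt(pi)", {
  sigma <- 25
  est <- vapply(1:10, function(s) {
    tr <- simulate_mup_train(single_fibre_mu(sigma),
                             sim_config(seed = s, noise_rms_uV = 0))
    segment_jitter(nf_transform(tr))
  }, numeric(1))
  expect_equal(mean(est), 2 * sigma / sqrt(pi), tolerance = 0.1)
})

test_that("nf_features assembles the full NF metric set", {
  tr <- simulate_mup_train(single_fibre_mu(20), sim_config(seed = 3))
  f <- nf_features(tr)
  expect_named(f, c("nf_duration_ms", "nf_count", "jiggle_pct",
                    "segment_jitter_us", "n_occurrences"))
  expect_gte(f$nf_count, 1)
  expect_gte(f$jiggle_pct, 0)
  expect_gte(f$segment_jitter_us, 0)
})
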