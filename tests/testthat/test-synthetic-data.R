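test_that("MFP waveforms follow the distance-attenuation law", {
  fs <- 40000
  near <- fibre_model(0.05)
  far <- fibre_model(0.35)
  w_near <- simulate_mfp_waveform(near, fs, 25)
  w_far <- simulate_mfp_waveform(far, fs, 25)
  expect_gt(max(abs(w_near)), max(abs(w_far)))
  # width: time above half of the (positive) peak grows with distance
  width_of <- function(w) sum(w > max(w) / 2)
  expect_lt(width_of(w_near), width_of(w_far))

  # amplitude ratio between r and 2r equals the attenuation law evaluated
  # directly (power law, default exponent -1.5)
  r <- 0.1
  f1 <- fibre_model(r)
  f2 <- fibre_model(2 * r)
  ratio <- max(abs(simulate_mfp_waveform(f1, fs, 25))) /
    max(abs(simulate_mfp_waveform(f2, fs, 25)))
  expect_equal(ratio, mfp_amplitude_at(r) / mfp_amplitude_at(2 * r),
               tolerance = 1e-10)
  expect_equal(ratio, 2^1.5, tolerance = 1e-10)

  # linearity: doubling the amplitude parameter doubles every sample
  fa <- fibre_model(0.1)
  fb <- fibre_model(0.1, mfp_amplitude_uV = 2 * fa$mfp_amplitude_uV)
  expect_equal(simulate_mfp_waveform(fb, fs, 25),
               2 * simulate_mfp_waveform(fa, fs, 25))

  expect_error(fibre_model(0.1, mfp_amplitude_uV = 0), "amplitude")
  expect_error(simulate_mfp_waveform(fa, -1, 25), "fs_hz")
})

test_that("MFP peak amplitude is strictly decreasing in radial distance", {
  r <- seq(0.05, 1, length.out = 20)
  amps <- mfp_amplitude_at(r)
  expect_true(all(diff(amps) < 0))
})

test_that("simulated trains honour their stochastic parameters", {
  # no stochastic terms: every instance row is identical
  mu0 <- single_fibre_mu(0, label = "det")
  tr0 <- simulate_mup_train(mu0, sim_config(seed = 5, noise_rms_uV = 0))
  expect_true(all(tr0$instances == rep(tr0$instances[1, ],
                                       each = nrow(tr0$instances))))

  # occurrence count oracle: duration / IDI in expectation, +/- 3 SD
  counts <- vapply(1:20, function(s) {
    tr <- simulate_mup_train(single_fibre_mu(20), sim_config(seed = s))
    nrow(tr$instances)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 200), 3 * sd(counts) / sqrt(20) + 3)
  # a 20-s contraction at physiological rates comfortably passes the
  # 35-occurrence train-length requirement
  expect_true(all(counts > 35))

  # realized IDI within 2% of the model mean (average over seeds)
  idis <- vapply(1:50, function(s) {
    tr <- simulate_mup_train(single_fibre_mu(20), sim_config(seed = s))
    mean(diff(tr$occurrence_times_ms))
  }, numeric(1))
  expect_lt(abs(mean(idis) / 100 - 1), 0.02)
})

test_that("generators are bit-identical under identical seeds", {
  mu <- single_fibre_mu(25, blocking_prob = 0.1, amplitude_cv = 0.1)
  cfg <- sim_config(seed = 11)
  expect_identical(simulate_mup_train(mu, cfg), simulate_mup_train(mu, cfg))
  expect_identical(simulate_cohort_features(seed = 11),
                   simulate_cohort_features(seed = 11))
  gs <- toy_gene_sets()
  expect_identical(simulate_ranked_list(gs, "set1", 2, seed = 11),
                   simulate_ranked_list(gs, "set1", 2, seed = 11))
  # different seeds give different draws
  expect_false(identical(simulate_mup_train(mu, sim_config(seed = 12)),
                         simulate_mup_train(mu, cfg)))
})

test_that("hierarchical seeding isolates per-fibre streams", {
  f1 <- fibre_model(0.08, mean_latency_ms = 2, jitter_sd_us = 20)
  f2 <- fibre_model(0.5, mean_latency_ms = 8, jitter_sd_us = 20)
  cfg <- sim_config(seed = 3, noise_rms_uV = 0)
  one <- simulate_mup_train(motor_unit_model(list(f1), label = "m"), cfg)
  two <- simulate_mup_train(motor_unit_model(list(f1, f2), label = "m"), cfg)
  # fibre 1's contribution is unchanged by adding fibre 2: subtracting the
  # second fibre's share leaves exactly the single-fibre train
  expect_identical(one$occurrence_times_ms, two$occurrence_times_ms)
  # where fibre 2's MFP is negligible (first 100 samples), signals agree
  expect_equal(two$instances[, 1:100], one$instances[, 1:100],
               tolerance = 1e-8)
})

test_that("cohort feature tables carry the planted time effects", {
  # null case: all multipliers 1 -> group means agree
  null_tab <- simulate_cohort_features(c(LS0 = 1, LS10 = 1, AR21 = 1),
                                       n_subjects = 30, n_mus_per_cell = 50,
                                       seed = 4)
  m <- tapply(null_tab$value, null_tab$time_point, mean)
  expect_lt(max(abs(m / m[1] - 1)), 0.05)

  # moment oracle: gamma/identity multiplier 1.2 -> mean ratio about 1.2
  tab <- simulate_cohort_features(c(LS0 = 1, LS10 = 1.2, AR21 = 1),
                                  n_subjects = 40, n_mus_per_cell = 100,
                                  family = "gamma", link = "identity",
                                  seed = 4)
  m <- tapply(tab$value, tab$time_point, mean)
  expect_equal(unname(m["LS10"] / m["LS0"]), 1.2, tolerance = 0.03)

  # defaults mirror the cohort design: 11 subjects, positive outcomes
  d <- simulate_cohort_features(seed = 1)
  expect_equal(nlevels(d$subject_id), 11)
  expect_true(all(d$value > 0))
  expect_error(simulate_cohort_features(c(LS0 = 1, LS10 = -1)), "positive|> 0")
})

test_that("ranked-list simulation plants enrichment as requested", {
  gs <- toy_gene_sets(set_size = 30)
  # large planted effect pushes every planted gene into the top |set| ranks
  rk <- simulate_ranked_list(gs, "set1", planted_effect = 5, seed = 9)
  expect_true(all(gs$set1 %in% rk$gene[seq_len(30)]))
  # output is a two-column name/score table sorted descending
  expect_named(rk, c("gene", "score"))
  expect_true(all(diff(rk$score) <= 0))

  # null effect: planted set ranks indistinguishable from uniform
  ranks <- unlist(lapply(1:10, function(s) {
    r <- simulate_ranked_list(gs, "set1", planted_effect = 0, seed = s)
    match(gs$set1, r$gene) / nrow(r)
  }))
  expect_gt(suppressWarnings(stats::ks.test(ranks, "punif"))$p.value, 0.01)

  expect_error(simulate_ranked_list(gs, "nope", 1), "not found")
})

test_that("RNK round-trips through disk", {
  gs <- toy_gene_sets()
  rk <- simulate_ranked_list(gs, "set1", 2, seed = 2)
  path <- tempfile(fileext = ".rnk")
  write_rnk(rk, path)
  back <- read_rnk(path)
  expect_equal(back$gene, rk$gene)
  expect_equal(back$score, rk$score, tolerance = 1e-12)
})
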