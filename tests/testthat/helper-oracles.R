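# Independent oracles and small fixture builders shared across tests.

# Brute-force turns oracle: compress plateaus (keeping one sample per run),
# enumerate strict local extrema of the compressed series, then greedily
# count extrema whose amplitude differs from the previously counted turning
# point (initially the first sample) by at least the threshold.
oracle_turns <- function(v, threshold) {
  w <- v[c(TRUE, diff(v) != 0)]
  n <- length(w)
  if (n < 3) return(0L)
  is_ext <- c(FALSE, (w[2:(n - 1)] - w[1:(n - 2)]) *
                (w[3:n] - w[2:(n - 1)]) < 0, FALSE)
  ext <- w[is_ext]
  count <- 0L
  ref <- w[1]
  for (e in ext) {
    if (abs(e - ref) >= threshold) {
      count <- count + 1L
      ref <- e
    }
  }
  count
}

# Brute-force weighted KS enrichment score: full running-sum walk over every
# position in the ranking, tracking the maximum deviation from zero.
oracle_es <- function(scores, hit, weight_exponent) {
  w <- abs(scores)^weight_exponent
  if (sum(w[hit]) == 0) w[hit] <- 1
  nh <- sum(w[hit])
  nm <- sum(!hit)
  run <- 0
  best <- 0
  for (i in seq_along(scores)) {
    run <- run + if (hit[i]) w[i] / nh else -1 / nm
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Magnitude of the NF kernel transfer function at frequency f_hz.
kernel_gain <- function(kernel, f_hz, fs_hz) {
  j <- seq_along(kernel) - 1
  Mod(sum(kernel * exp(-2i * pi * f_hz * j / fs_hz)))
}

# Amplitude of a sinusoid in a measured segment, by least-squares projection
# onto the sin/cos pair.
sine_amplitude <- function(y, f_hz, fs_hz, t0_samples = 0) {
  t <- (t0_samples + seq_along(y) - 1) / fs_hz
  X <- cbind(sin(2 * pi * f_hz * t), cos(2 * pi * f_hz * t))
  b <- stats::coef(stats::lm.fit(X, y))
  sqrt(sum(b^2))
}

# A clean triphasic test waveform with a flat baseline, plus helpers to wrap
# raw instances into the package's containers.
toy_waveform <- function(n = 400, fs_hz = 40000, amp = 100, width_ms = 0.3,
                         centre_frac = 0.5) {
  t_ms <- (seq_len(n) - 1) / fs_hz * 1000
  c_ms <- centre_frac * n / fs_hz * 1000
  u2 <- ((t_ms - c_ms) / width_ms)^2
  amp * (1 - u2) * exp(-u2 / 2)
}

toy_train <- function(instances, fs_hz = 40000, idi_ms = 100) {
  n <- nrow(instances)
  mup_train(fs_hz = fs_hz, occurrence_times_ms = seq_len(n) * idi_ms,
            instances = instances, meta = list(label = "toy"))
}

# Wrap precomputed NF pieces into an nf_mup_train (for closed-form tests).
toy_nf_train <- function(nf_instances, nf_template, fs_hz = 40000,
                         noise_rms_nf = 0, onset = 1,
                         end = ncol(nf_instances) + 1) {
  structure(list(fs_hz = fs_hz, nf_instances = nf_instances,
                 nf_template = nf_template, nf_onset_idx = onset,
                 nf_end_idx = end, noise_rms_nf = noise_rms_nf,
                 kernel = nf_kernel(fs_hz),
                 occurrence_times_ms = seq_len(nrow(nf_instances)) * 100,
                 meta = list(label = "toy_nf")),
            class = "nf_mup_train")
}

# Single-fibre motor unit at a given NMJ jitter, used by several tests.
single_fibre_mu <- function(jitter_sd_us, label = "sf",
                            blocking_prob = 0, amplitude_cv = 0) {
  motor_unit_model(list(fibre_model(0.08, mean_latency_ms = 2,
                                    jitter_sd_us = jitter_sd_us,
                                    blocking_prob = blocking_prob,
                                    amplitude_cv = amplitude_cv)),
                   idi_mean_ms = 100, idi_cv = 0.15, label = label)
}

# Small gene-set universe for enrichment tests.
toy_gene_sets <- function(set_size = 30, n_sets = 2) {
  sets <- lapply(seq_len(n_sets), function(i)
    sprintf("SET%d_G%03d", i, seq_len(set_size)))
  names(sets) <- paste0("set", seq_len(n_sets))
  sets
}
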