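#' Muscle-fibre potential amplitude at a given radial distance
#'
#' Extracellular muscle-fibre potential (MFP) amplitude falls off sharply with
#' electrode-to-fibre distance; fibres beyond a few hundred micrometres
#' contribute only low-amplitude, low-frequency components to the motor unit
#' potential. The simulator uses a power-law attenuation
#' \eqn{A(r) = A_{ref} (r / r_{ref})^{exponent}} with a negative exponent.
#'
#' @param radial_distance_mm electrode-to-fibre distance in mm (> 0).
#' @param amp_ref_uV amplitude at the reference distance, in microvolts.
#' @param r_ref_mm reference distance in mm.
#' @param exponent power-law exponent (negative; default -1.5).
#' @return peak amplitude in microvolts.
#' @export
mfp_amplitude_at <- function(radial_distance_mm, amp_ref_uV = 150,
                             r_ref_mm = 0.1, exponent = -1.5) {
  stopifnot(all(radial_distance_mm > 0), amp_ref_uV > 0, r_ref_mm > 0,
            exponent < 0)
  amp_ref_uV * (radial_distance_mm / r_ref_mm)^exponent
}

#' Muscle-fibre potential width at a given radial distance
#'
#' Tissue filtering broadens the MFP with distance; the simulator grows the
#' characteristic width linearly: \eqn{w(r) = w_0 + s \cdot r}.
#'
#' @param radial_distance_mm electrode-to-fibre distance in mm (> 0).
#' @param width0_ms width at zero distance, ms.
#' @param slope_ms_per_mm width growth per mm.
#' @return characteristic width in ms.
#' @export
mfp_width_at <- function(radial_distance_mm, width0_ms = 0.15,
                         slope_ms_per_mm = 0.45) {
  stopifnot(all(radial_distance_mm > 0), width0_ms > 0, slope_ms_per_mm >= 0)
  width0_ms + slope_ms_per_mm * radial_distance_mm
}

#' Describe one muscle fibre of a simulated motor unit
#'
#' A fibre is characterised by its geometry relative to the needle electrode
#' (radial distance, which sets MFP amplitude and width unless overridden) and
#' by its neuromuscular-junction transmission behaviour: latency jitter SD,
#' per-discharge blocking probability and multiplicative amplitude
#' variability.
#'
#' @param radial_distance_mm electrode-to-fibre distance, mm (> 0).
#' @param mean_latency_ms mean arrival offset of this fibre's MFP within the
#'   motor unit potential, ms from the discharge trigger.
#' @param jitter_sd_us SD of per-discharge latency jitter at the NMJ, in
#'   microseconds (>= 0).
#' @param blocking_prob per-discharge probability that transmission fails and
#'   the fibre does not fire, in `[0, 1]`.
#' @param amplitude_cv coefficient of variation of the per-discharge
#'   multiplicative amplitude factor (>= 0; factors are log-normal, mean 1).
#' @param mfp_amplitude_uV peak MFP amplitude at the electrode; defaults to
#'   [mfp_amplitude_at()] evaluated at `radial_distance_mm`.
#' @param mfp_width_ms characteristic MFP width; defaults to [mfp_width_at()].
#' @return an object of class `fibre_model`.
#' @export
#' @examples
#' near <- fibre_model(0.05)
#' far  <- fibre_model(0.35)
#' near$mfp_amplitude_uV > far$mfp_amplitude_uV  # closer fibre is larger
fibre_model <- function(radial_distance_mm, mean_latency_ms = 0,
                        jitter_sd_us = 25, blocking_prob = 0,
                        amplitude_cv = 0,
                        mfp_amplitude_uV = mfp_amplitude_at(radial_distance_mm),
                        mfp_width_ms = mfp_width_at(radial_distance_mm)) {
  stopifnot(is.numeric(radial_distance_mm), radial_distance_mm > 0)
  if (!(blocking_prob >= 0 && blocking_prob <= 1))
    stop("blocking_prob must lie in [0, 1]", call. = FALSE)
  if (jitter_sd_us < 0) stop("jitter_sd_us must be >= 0", call. = FALSE)
  if (amplitude_cv < 0) stop("amplitude_cv must be >= 0", call. = FALSE)
  if (mfp_amplitude_uV <= 0) stop("mfp_amplitude_uV must be > 0", call. = FALSE)
  if (mfp_width_ms <= 0) stop("mfp_width_ms must be > 0", call. = FALSE)
  structure(list(radial_distance_mm = radial_distance_mm,
                 mfp_amplitude_uV = mfp_amplitude_uV,
                 mfp_width_ms = mfp_width_ms,
                 jitter_sd_us = jitter_sd_us,
                 blocking_prob = blocking_prob,
                 amplitude_cv = amplitude_cv,
                 mean_latency_ms = mean_latency_ms),
            class = "fibre_model")
}

#' Generative model of one motor unit
#'
#' @param fibres list of [fibre_model()] objects (at least one).
#' @param idi_mean_ms mean inter-discharge interval, ms (> 0).
#' @param idi_cv coefficient of variation of the inter-discharge interval
#'   (>= 0); discharge intervals are Gaussian truncated at zero.
#' @param label identifier used in outputs and for seed derivation.
#' @return an object of class `motor_unit_model`.
#' @export
motor_unit_model <- function(fibres, idi_mean_ms = 100, idi_cv = 0.15,
                             label = "mu1") {
  if (inherits(fibres, "fibre_model")) fibres <- list(fibres)
  if (length(fibres) < 1) stop("at least one fibre is required", call. = FALSE)
  if (!all(vapply(fibres, inherits, logical(1), "fibre_model")))
    stop("fibres must be fibre_model objects", call. = FALSE)
  stopifnot(idi_mean_ms > 0, idi_cv >= 0)
  structure(list(fibres = fibres, idi_mean_ms = idi_mean_ms,
                 idi_cv = idi_cv, label = as.character(label)),
            class = "motor_unit_model")
}

#' Simulation configuration
#'
#' Defaults mirror the recording protocol the package targets: 20-s voluntary
#' contractions sampled at 40 kHz with a concentric needle electrode.
#'
#' @param contraction_duration_s contraction length, s.
#' @param fs_hz sampling rate, Hz.
#' @param noise_rms_uV RMS of additive white Gaussian baseline noise, uV.
#' @param window_pre_ms window extent before each detected discharge, ms.
#' @param window_post_ms window extent after each detected discharge, ms.
#' @param seed integer seed; together with the motor-unit label it fully
#'   determines the simulated train.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(contraction_duration_s = 20, fs_hz = 40000,
                       noise_rms_uV = 2, window_pre_ms = 5,
                       window_post_ms = 20, seed = 1) {
  stopifnot(contraction_duration_s > 0, fs_hz > 0, noise_rms_uV >= 0,
            window_pre_ms >= 0, window_post_ms > 0)
  structure(list(contraction_duration_s = contraction_duration_s,
                 fs_hz = fs_hz, noise_rms_uV = noise_rms_uV,
                 window_pre_ms = window_pre_ms,
                 window_post_ms = window_post_ms,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Triphasic MFP kernel: second derivative of a Gaussian ("Mexican hat"),
# unit peak amplitude at t = 0, characteristic width w (ms).
mfp_kernel <- function(t_ms, width_ms) {
  u2 <- (t_ms / width_ms)^2
  (1 - u2) * exp(-u2 / 2)
}

#' Simulate a single muscle-fibre potential waveform
#'
#' Returns the deterministic (noise-free, jitter-free) MFP of one fibre,
#' sampled at `fs_hz` over a window of `window_ms` centred on the fibre's
#' arrival time. The shape is an analytic triphasic kernel (second derivative
#' of a Gaussian); amplitude and width follow the fibre's distance-dependent
#' parameters, so nearer fibres are sharper and larger.
#'
#' @param fibre a [fibre_model()].
#' @param fs_hz sampling rate, Hz (> 0).
#' @param window_ms window length, ms (> 0); must cover the MFP support.
#' @param centred if `TRUE` (default) the MFP peak sits at the window centre;
#'   otherwise at `mean_latency_ms` from the window start.
#' @return numeric vector of microvolt samples, length `round(window_ms/1000*fs_hz)`.
#' @export
simulate_mfp_waveform <- function(fibre, fs_hz, window_ms, centred = TRUE) {
  stopifnot(inherits(fibre, "fibre_model"))
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be > 0", call. = FALSE)
  if (!is.numeric(window_ms) || window_ms <= 0)
    stop("window_ms must be > 0", call. = FALSE)
  n <- round(window_ms / 1000 * fs_hz)
  if (n < 2) stop("window too short for the sampling rate", call. = FALSE)
  t_ms <- (seq_len(n) - 1) / fs_hz * 1000
  centre <- if (centred) window_ms / 2 else fibre$mean_latency_ms
  fibre$mfp_amplitude_uV * mfp_kernel(t_ms - centre, fibre$mfp_width_ms)
}

# Strictly increasing discharge times (ms) over the contraction, IDIs drawn
# from a Gaussian truncated at zero.
draw_discharge_times <- function(idi_mean_ms, idi_cv, duration_ms) {
  n_max <- ceiling(duration_ms / idi_mean_ms * (1 + 6 * idi_cv)) + 10
  idis <- rnorm(n_max, idi_mean_ms, idi_cv * idi_mean_ms)
  bad <- which(idis <= 0)
  while (length(bad)) {
    idis[bad] <- rnorm(length(bad), idi_mean_ms, idi_cv * idi_mean_ms)
    bad <- bad[idis[bad] <= 0]
  }
  tt <- cumsum(idis)
  tt[tt <= duration_ms]
}

#' Simulate a decomposed MUP train
#'
#' Generates the per-occurrence waveform windows of one motor unit as a
#' decomposition program would present them: each window is time-locked to
#' the discharge trigger, and each fibre contributes its MFP shifted by its
#' mean latency plus Gaussian NMJ jitter, scaled by a log-normal amplitude
#' factor with the configured CV, and omitted altogether with probability
#' `blocking_prob`. White Gaussian baseline noise is added. Draws are split
#' into per-component streams (see [derive_seed()]), so the output is fully
#' reproducible from `config$seed` and unaffected by unrelated components.
#'
#' @param mu a [motor_unit_model()].
#' @param config a [sim_config()].
#' @return an object of class `mup_train` with elements `fs_hz`,
#'   `occurrence_times_ms`, `instances` (occurrences x samples matrix, uV),
#'   `noise_rms_uV` (the generating value), and `meta`.
#' @export
simulate_mup_train <- function(mu, config = sim_config()) {
  stopifnot(inherits(mu, "motor_unit_model"), inherits(config, "sim_config"))
  fs <- config$fs_hz
  duration_ms <- config$contraction_duration_s * 1000
  times <- with_seed(derive_seed(config$seed, mu$label, "idi"),
                     draw_discharge_times(mu$idi_mean_ms, mu$idi_cv, duration_ms))
  n_occ <- length(times)
  if (n_occ < 1) stop("contraction too short: no discharges drawn", call. = FALSE)
  n_samp <- round((config$window_pre_ms + config$window_post_ms) / 1000 * fs)
  # time axis of each window relative to the discharge trigger, ms
  t_rel <- (seq_len(n_samp) - 1) / fs * 1000 - config$window_pre_ms
  inst <- matrix(0, n_occ, n_samp)
  for (i in seq_along(mu$fibres)) {
    fb <- mu$fibres[[i]]
    draws <- with_seed(derive_seed(config$seed, mu$label, "fibre", i), {
      lat <- fb$mean_latency_ms + rnorm(n_occ, 0, fb$jitter_sd_us / 1000)
      fire <- runif(n_occ) >= fb$blocking_prob
      amp <- if (fb$amplitude_cv > 0) {
        s <- sqrt(log(1 + fb$amplitude_cv^2))
        exp(rnorm(n_occ, -s^2 / 2, s))
      } else rep(1, n_occ)
      list(lat = lat, fire = fire, amp = amp)
    })
    scale <- fb$mfp_amplitude_uV * draws$amp * draws$fire
    # occurrence i sees the kernel centred at its jittered latency
    dt <- outer(-draws$lat, t_rel, `+`)  # t_rel - lat[i]
    inst <- inst + scale * mfp_kernel(dt, fb$mfp_width_ms)
  }
  if (config$noise_rms_uV > 0) {
    inst <- inst + with_seed(derive_seed(config$seed, mu$label, "noise"),
                             matrix(rnorm(n_occ * n_samp, 0, config$noise_rms_uV),
                                    n_occ, n_samp))
  }
  mup_train(fs_hz = fs, occurrence_times_ms = times, instances = inst,
            noise_rms_uV = config$noise_rms_uV,
            meta = list(label = mu$label, window_pre_ms = config$window_pre_ms,
                        window_post_ms = config$window_post_ms,
                        seed = config$seed))
}

#' Construct a MUP train object
#'
#' The central container all EMG stages consume: occurrence times plus one
#' aligned waveform window per discharge.
#'
#' @param fs_hz sampling rate, Hz.
#' @param occurrence_times_ms strictly increasing discharge times, ms.
#' @param instances numeric matrix, one row per occurrence, uV.
#' @param noise_rms_uV baseline noise RMS if known (else `NA`).
#' @param meta named list of labels (subject, time point, contraction level, ...).
#' @return an object of class `mup_train`.
#' @export
mup_train <- function(fs_hz, occurrence_times_ms, instances,
                      noise_rms_uV = NA_real_, meta = list()) {
  instances <- as.matrix(instances)
  if (fs_hz <= 0) stop("fs_hz must be > 0", call. = FALSE)
  if (nrow(instances) != length(occurrence_times_ms))
    stop("instances must have one row per occurrence", call. = FALSE)
  if (length(occurrence_times_ms) > 1 && any(diff(occurrence_times_ms) <= 0))
    stop("occurrence times must be strictly increasing", call. = FALSE)
  structure(list(fs_hz = fs_hz,
                 occurrence_times_ms = as.numeric(occurrence_times_ms),
                 instances = instances,
                 noise_rms_uV = noise_rms_uV,
                 meta = meta),
            class = "mup_train")
}

#' @export
print.mup_train <- function(x, ...) {
  cat(sprintf("<mup_train> %s: %d occurrences x %d samples @ %g kHz\n",
              x$meta$label %||% "?", nrow(x$instances), ncol(x$instances),
              x$fs_hz / 1000))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
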