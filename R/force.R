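#' Construct a force trace
#'
#' @param samples force samples in newtons.
#' @param fs_hz sampling rate, Hz (default 1000).
#' @param trial_id identifier.
#' @return an object of class `force_trace`.
#' @export
force_trace <- function(samples, fs_hz = 1000, trial_id = "trial") {
  if (fs_hz <= 0) stop("fs_hz must be > 0", call. = FALSE)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  structure(list(samples = samples, fs_hz = fs_hz, trial_id = trial_id),
            class = "force_trace")
}

#' Maximum voluntary contraction force
#'
#' The maximum force value reached across all recorded trials.
#'
#' @param trials a `force_trace` or list of them.
#' @return MVC in newtons.
#' @export
compute_mvc <- function(trials) {
  if (inherits(trials, "force_trace")) trials <- list(trials)
  if (!length(trials)) stop("at least one trial is required", call. = FALSE)
  stopifnot(all(vapply(trials, inherits, logical(1), "force_trace")))
  max(vapply(trials, function(tr) max(tr$samples), numeric(1)))
}

#' Time to reach 63 percent of MVC
#'
#' The rapid-force-production time constant: time from contraction onset to
#' the first crossing of `0.63 * mvc_N`, linearly interpolated between
#' samples. Onset is the last sample at or below the baseline mean plus
#' `k_onset` baseline SDs before the first sustained (`min_run_ms`)
#' supra-threshold excursion, the baseline being the first `baseline_ms` of
#' the trace; the run requirement keeps isolated noise spikes from
#' triggering a false onset (an onset rule standing in for operator
#' placement).
#'
#' @param trace a [force_trace()].
#' @param mvc_N MVC reference in newtons.
#' @param baseline_ms pre-contraction baseline window, ms.
#' @param k_onset onset threshold in baseline SDs.
#' @param min_run_ms minimum supra-threshold run defining the onset.
#' @return time in ms.
#' @export
compute_ttp63 <- function(trace, mvc_N, baseline_ms = 200, k_onset = 3,
                          min_run_ms = 10) {
  stopifnot(inherits(trace, "force_trace"), mvc_N > 0)
  v <- trace$samples
  fs <- trace$fs_hz
  nb <- max(2L, min(length(v) - 1L, round(baseline_ms / 1000 * fs)))
  thr_onset <- mean(v[1:nb]) + k_onset * stats::sd(v[1:nb])
  run <- max(1L, round(min_run_ms / 1000 * fs))
  r <- rle(v > thr_onset)
  ends <- cumsum(r$lengths)
  ok <- r$values & r$lengths >= run
  first_exceed <- if (any(ok)) (ends - r$lengths + 1L)[ok][1] else NA_integer_
  onset <- if (is.na(first_exceed)) 1L else max(1L, first_exceed - 1L)
  target <- 0.63 * mvc_N
  above <- which(v >= target)
  above <- above[above >= onset]
  if (!length(above))
    stop(structure(class = c("nfemg_not_reached", "error", "condition"),
                   list(message = "trace never reaches 63% of MVC",
                        call = sys.call())))
  j <- above[1]
  frac <- if (j == onset || v[j] == v[j - 1]) 0
          else (target - v[j - 1]) / (v[j] - v[j - 1])
  # crossing sits between samples j-1 and j, i.e. at position (j-2) + frac
  ((j - 2 + frac) - (onset - 1)) / fs * 1000
}

#' Specific force
#'
#' MVC normalised by muscle cross-sectional area.
#'
#' @param mvc_N MVC in newtons.
#' @param csa_cm2 cross-sectional area in cm^2 (> 0).
#' @return specific force in N/cm^2.
#' @export
specific_force <- function(mvc_N, csa_cm2) {
  if (!is.numeric(csa_cm2) || csa_cm2 <= 0)
    stop("csa_cm2 must be > 0", call. = FALSE)
  mvc_N / csa_cm2
}

#' Simulate an exponential-rise force trace
#'
#' \eqn{f(t) = MVC (1 - e^{-t/\tau})} after a quiet baseline, with optional
#' Gaussian noise; a convenient ground-truth input for [compute_ttp63()].
#'
#' @param mvc_N plateau force, N.
#' @param tau_ms rise time constant, ms.
#' @param duration_ms total trace length, ms.
#' @param baseline_ms quiet pre-contraction period, ms.
#' @param fs_hz sampling rate, Hz.
#' @param noise_sd_N additive noise SD, N.
#' @param seed integer seed.
#' @return a [force_trace()].
#' @export
simulate_force_trace <- function(mvc_N = 600, tau_ms = 150, duration_ms = 3000,
                                 baseline_ms = 500, fs_hz = 1000,
                                 noise_sd_N = 0, seed = 1) {
  t_ms <- (seq_len(round(duration_ms / 1000 * fs_hz)) - 1) / fs_hz * 1000
  f <- ifelse(t_ms < baseline_ms, 0,
              mvc_N * (1 - exp(-(t_ms - baseline_ms) / tau_ms)))
  if (noise_sd_N > 0)
    f <- f + with_seed(derive_seed(seed, "force"),
                       rnorm(length(f), 0, noise_sd_N))
  force_trace(f, fs_hz, trial_id = sprintf("sim_tau%g", tau_ms))
}
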