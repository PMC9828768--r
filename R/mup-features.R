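#' Build the MUP template of a train
#'
#' Instances are aligned by integer-sample cross-correlation against a running
#' reference (the first instance, then the mean of the instances aligned so
#' far), then averaged sample-wise; a second pass re-aligns every instance to
#' the first-pass mean. Baseline noise RMS is estimated from the pre-onset
#' part of the window (the first `baseline_frac` of samples), as the RMS of
#' the mean-removed baseline across instances.
#'
#' @param train a [mup_train()].
#' @param max_shift_ms largest alignment shift searched, ms.
#' @param baseline_frac fraction of the window (from the start) treated as
#'   pre-onset baseline for noise estimation.
#' @param estimator `"mean"` (default) or `"median"` sample-wise average.
#' @return an object of class `mup_template`: `samples` (uV), `fs_hz`,
#'   `noise_rms_uV`, `n_averaged`, `shifts` (per-instance integer shifts).
#' @export
build_template <- function(train, max_shift_ms = 1, baseline_frac = 0.2,
                           estimator = c("mean", "median")) {
  stopifnot(inherits(train, "mup_train"))
  estimator <- match.arg(estimator)
  inst <- train$instances
  if (nrow(inst) < 1) stop("train has no instances", call. = FALSE)
  max_lag <- max(0L, round(max_shift_ms / 1000 * train$fs_hz))
  n <- nrow(inst)

  shifts <- integer(n)
  if (n > 1 && max_lag > 0) {
    ref <- inst[1, ]
    acc <- inst[1, ]
    for (i in 2:n) {
      shifts[i] <- best_lag(ref, inst[i, ], max_lag)
      acc <- acc + shift_vec(inst[i, ], -shifts[i])
      ref <- acc / i
    }
    # second pass against the converged mean
    for (i in seq_len(n)) shifts[i] <- best_lag(ref, inst[i, ], max_lag)
  }
  aligned <- inst
  for (i in seq_len(n)) if (shifts[i] != 0L)
    aligned[i, ] <- shift_vec(inst[i, ], -shifts[i])
  tmpl <- if (estimator == "mean") colMeans(aligned)
          else apply(aligned, 2, stats::median)

  nb <- max(4L, floor(baseline_frac * ncol(inst)))
  base <- aligned[, seq_len(nb), drop = FALSE]
  base <- base - rowMeans(base)
  noise_rms <- sqrt(mean(base^2) * nb / max(1, nb - 1))

  structure(list(samples = tmpl, fs_hz = train$fs_hz,
                 noise_rms_uV = noise_rms, n_averaged = n, shifts = shifts),
            class = "mup_template")
}

# lag (in samples) maximising cross-correlation of y against ref;
# positive lag means y is delayed relative to ref. FFT-based.
best_lag <- function(ref, y, max_lag) {
  n <- length(ref)
  # circular cross-correlation c[l] = sum_t ref[t] * y[t + l], l = 0..n-1
  cc <- Re(stats::fft(Conj(stats::fft(ref)) * stats::fft(y), inverse = TRUE))
  lags <- -max_lag:max_lag
  vals <- cc[(lags %% n) + 1L]
  lags[which.max(vals)]
}

# shift right by k samples (zero-padded); negative k shifts left
shift_vec <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  out <- numeric(n)
  if (k > 0) out[(k + 1):n] <- x[1:(n - k)]
  else out[1:(n + k)] <- x[(1 - k):n]
  out
}

#' Place onset/end/peak markers on a MUP template
#'
#' Onset is the first sample of the first run where `|signal|` exceeds
#' `k_onset * noise_rms` for at least `min_run_ms`; the end marker is one past
#' the last sample of the last such run (half-open window). Positive and
#' negative peak markers are the extrema inside the window.
#'
#' @param template a [mup_template()].
#' @param k_onset threshold multiple of the baseline noise RMS.
#' @param min_run_ms minimum supra-threshold run length, ms.
#' @return an object of class `marker_set` with 1-based sample indices
#'   `onset_idx`, `end_idx` (exclusive), `pos_peak_idx`, `neg_peak_idx`.
#' @export
place_markers <- function(template, k_onset = 3, min_run_ms = 0.1) {
  stopifnot(inherits(template, "mup_template"))
  v <- template$samples
  thr <- k_onset * template$noise_rms_uV
  if (!is.finite(thr) || thr <= 0) thr <- 1e-9 * max(1, max(abs(v)))
  min_run <- max(1L, round(min_run_ms / 1000 * template$fs_hz))
  active <- abs(v) >= thr
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= min_run
  if (!any(ok))
    stop(structure(class = c("nfemg_marker_failure", "error", "condition"),
                   list(message = "no supra-threshold activity: cannot place markers",
                        call = sys.call())))
  onset <- starts[ok][1]
  end <- ends[ok][sum(ok)] + 1L
  win <- onset:(end - 1L)
  structure(list(onset_idx = onset, end_idx = end,
                 pos_peak_idx = win[which.max(v[win])],
                 neg_peak_idx = win[which.min(v[win])]),
            class = "marker_set")
}

#' MUP duration from markers
#'
#' The time between the onset and end markers.
#'
#' @param markers a [place_markers()] result.
#' @param fs_hz sampling rate, Hz.
#' @return duration in ms.
#' @export
mup_duration <- function(markers, fs_hz) {
  stopifnot(inherits(markers, "marker_set"), fs_hz > 0)
  (markers$end_idx - markers$onset_idx) / fs_hz * 1000
}

#' Rectified MUP area within the duration window
#'
#' @param template a [mup_template()].
#' @param markers a [place_markers()] result.
#' @return area in uV*ms.
#' @export
mup_area <- function(template, markers) {
  stopifnot(inherits(template, "mup_template"), inherits(markers, "marker_set"))
  win <- markers$onset_idx:(markers$end_idx - 1L)
  sum(abs(template$samples[win])) * 1000 / template$fs_hz
}

#' Count MUP turns
#'
#' A turn is a change in MUP direction of at least `threshold_uV`. The
#' waveform inside the marker window is walked through its local extrema
#' (plateaus contribute their last sample); an extremum is counted as a turn
#' when its amplitude differs from the previously counted turning point
#' (initially the onset sample) by at least the threshold, and the reference
#' resets to each counted turn.
#'
#' @param template a [mup_template()] or numeric vector (uV).
#' @param markers optional [place_markers()] result restricting the window;
#'   when `NULL` the whole vector is used.
#' @param threshold_uV minimum amplitude excursion for a turn (default 20 uV).
#' @return integer turn count.
#' @export
count_turns <- function(template, markers = NULL, threshold_uV = 20) {
  v <- if (inherits(template, "mup_template")) template$samples else as.numeric(template)
  if (!is.null(markers)) {
    stopifnot(inherits(markers, "marker_set"))
    v <- v[markers$onset_idx:(markers$end_idx - 1L)]
  }
  n <- length(v)
  if (n < 3) return(0L)
  count <- 0L
  ref <- v[1]          # last counted turning point (onset sample to start)
  dir <- 0L            # current direction of travel: -1, 0, +1
  extreme <- v[1]      # running extreme in the current direction
  for (j in 2:n) {
    d <- sign(v[j] - v[j - 1])
    if (d == 0) next                      # plateau: wait for the last sample
    if (dir == 0L) {
      dir <- d
      extreme <- v[j]
    } else if (d == dir) {
      extreme <- v[j]                     # still travelling: extend extreme
    } else {
      # direction reversal: previous running extreme is a candidate turn
      if (abs(extreme - ref) >= threshold_uV) {
        count <- count + 1L
        ref <- extreme
      }
      dir <- d
      extreme <- v[j]
    }
  }
  count
}

#' Signal-to-noise ratio of a MUP train
#'
#' Defined as the template peak-to-peak amplitude divided by the baseline
#' noise RMS estimated from the pre-onset window.
#'
#' @param train a [mup_train()].
#' @param template optionally a precomputed [build_template()] result.
#' @param ... passed to [build_template()] when `template` is `NULL`.
#' @return SNR (dimensionless); `Inf` when the noise estimate is zero.
#' @export
compute_snr <- function(train, template = NULL, ...) {
  stopifnot(inherits(train, "mup_train"))
  if (is.null(template)) template <- build_template(train, ...)
  p2p <- diff(range(template$samples))
  if (template$noise_rms_uV <= 0) return(Inf)
  p2p / template$noise_rms_uV
}

#' Mean inter-discharge interval of a firing pattern
#'
#' Consecutive differences of the occurrence times, with a guard against
#' missed or merged discharges: intervals outside `[0.5, 1.75]` times the
#' median interval are discarded before averaging.
#'
#' @param occurrence_times_ms strictly increasing discharge times, ms.
#' @param outlier_band lower/upper multiples of the median interval kept.
#' @return mean inter-discharge interval, ms.
#' @export
idi_mean <- function(occurrence_times_ms, outlier_band = c(0.5, 1.75)) {
  tt <- as.numeric(occurrence_times_ms)
  if (length(tt) < 2)
    stop(structure(class = c("nfemg_insufficient_data", "error", "condition"),
                   list(message = "need at least 2 occurrences for IDI",
                        call = sys.call())))
  idis <- diff(tt)
  med <- stats::median(idis)
  keep <- idis >= outlier_band[1] * med & idis <= outlier_band[2] * med
  if (!any(keep)) keep <- rep(TRUE, length(idis))
  mean(idis[keep])
}

#' Compute the full MUP feature set of a train
#'
#' @param train a [mup_train()].
#' @param threshold_uV turns threshold, uV.
#' @param ... passed to [build_template()].
#' @return a one-row data.frame with `duration_ms`, `area_uVms`, `turns`,
#'   `snr`, `idi_mean_ms`, `n_occurrences`.
#' @export
mup_features <- function(train, threshold_uV = 20, ...) {
  tmpl <- build_template(train, ...)
  mk <- place_markers(tmpl)
  data.frame(
    duration_ms = mup_duration(mk, train$fs_hz),
    area_uVms = mup_area(tmpl, mk),
    turns = count_turns(tmpl, mk, threshold_uV),
    snr = compute_snr(train, template = tmpl),
    idi_mean_ms = if (length(train$occurrence_times_ms) >= 2)
      idi_mean(train$occurrence_times_ms) else NA_real_,
    n_occurrences = nrow(train$instances)
  )
}
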