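#' Second-order low-pass differentiator kernel
#'
#' The near-fibre transform uses a smoothed second-difference FIR kernel: the
#' second derivative of a Gaussian with time constant `sigma_us`, sampled
#' symmetrically and mean-corrected so that its response to constant and
#' linear-in-time inputs is exactly zero. The kernel is normalised to unit
#' energy; all downstream near-fibre statistics are invariant to this scale.
#'
#' @param fs_hz sampling rate, Hz.
#' @param sigma_us Gaussian time constant, microseconds (default 60).
#' @param half_support_sigmas kernel half-support in units of sigma.
#' @return numeric kernel of odd length.
#' @export
nf_kernel <- function(fs_hz, sigma_us = 60, half_support_sigmas = 4) {
  stopifnot(fs_hz > 0, sigma_us > 0)
  sig <- sigma_us * 1e-6 * fs_hz               # sigma in samples
  h <- max(2L, ceiling(half_support_sigmas * sig))
  t <- (-h):h
  u2 <- (t / sig)^2
  k <- (u2 - 1) * exp(-u2 / 2)                 # +d2/dt2 of a Gaussian
  k <- k - mean(k)                             # exact DC rejection
  k / sqrt(sum(k^2))
}

#' Apply the near-fibre filter
#'
#' Zero-phase convolution with the [nf_kernel()]. Distant fibres contribute
#' low-amplitude, low-frequency components to a MUP; the second-order
#' differentiator suppresses them relative to the sharp potentials of fibres
#' close to the electrode. Only the valid (full-overlap) region is retained;
#' the half-kernel margin at each edge is set to zero, so constant and linear
#' inputs map to an identically zero output.
#'
#' @param x numeric vector, or matrix with one waveform per row (uV).
#' @param fs_hz sampling rate, Hz.
#' @param sigma_us kernel time constant, microseconds.
#' @param kernel optionally a precomputed kernel (overrides `sigma_us`).
#' @return filtered object of the same shape as `x`.
#' @export
nf_filter <- function(x, fs_hz, sigma_us = 60, kernel = NULL) {
  if (is.null(kernel)) kernel <- nf_kernel(fs_hz, sigma_us)
  h <- (length(kernel) - 1L) %/% 2L
  if (is.matrix(x)) {
    if (ncol(x) < length(kernel))
      stop("window shorter than the filter kernel", call. = FALSE)
    n <- ncol(x)
    out <- matrix(0, nrow(x), n)
    valid <- (h + 1):(n - h)
    # accumulate one shifted block per tap; vectorised across rows
    for (j in seq_along(kernel))
      out[, valid] <- out[, valid] +
        kernel[j] * x[, valid + (j - 1L) - h, drop = FALSE]
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (length(x) < length(kernel))
    stop("window shorter than the filter kernel", call. = FALSE)
  n <- length(x)
  out <- numeric(n)
  out[(h + 1):(n - h)] <- stats::convolve(x, kernel, type = "filter")
  out
}

#' Near-fibre transform of a MUP train
#'
#' Filters every instance with the second-order low-pass differentiator,
#' derives the NF template by filtering the aligned MUP template, estimates
#' the filtered baseline noise, and places the NF duration window with the
#' same sustained-threshold rule used for MUP markers.
#'
#' @param train a [mup_train()].
#' @param sigma_us filter time constant, microseconds.
#' @param k_window threshold multiple of filtered noise RMS for the NF window.
#' @param baseline_frac fraction of the window used as noise baseline.
#' @param ... passed to [build_template()].
#' @return an object of class `nf_mup_train`: `fs_hz`, `nf_instances`,
#'   `nf_template`, `nf_onset_idx`, `nf_end_idx`, `noise_rms_nf`, `kernel`,
#'   `occurrence_times_ms`.
#' @export
nf_transform <- function(train, sigma_us = 60, k_window = 3,
                         baseline_frac = 0.2, ...) {
  stopifnot(inherits(train, "mup_train"))
  kernel <- nf_kernel(train$fs_hz, sigma_us)
  tmpl <- build_template(train, baseline_frac = baseline_frac, ...)
  nf_tmpl <- nf_filter(tmpl$samples, train$fs_hz, kernel = kernel)
  nf_inst <- nf_filter(train$instances, train$fs_hz, kernel = kernel)

  nb <- max(4L, floor(baseline_frac * ncol(nf_inst)))
  h <- (length(kernel) - 1L) %/% 2L
  bcols <- (h + 1):max(h + 2, nb)              # skip the zeroed margin
  base <- nf_inst[, bcols, drop = FALSE]
  base <- base - rowMeans(base)
  noise_rms_nf <- sqrt(mean(base^2))

  thr <- k_window * noise_rms_nf
  if (!is.finite(thr) || thr <= 0) thr <- 1e-9 * max(1, max(abs(nf_tmpl)))
  active <- abs(nf_tmpl) >= thr
  if (any(active)) {
    onset <- which(active)[1]
    endx <- which(active)[sum(active)] + 1L
  } else {
    onset <- 1L; endx <- length(nf_tmpl) + 1L   # degenerate: whole window
  }
  structure(list(fs_hz = train$fs_hz, nf_instances = nf_inst,
                 nf_template = nf_tmpl, nf_onset_idx = onset,
                 nf_end_idx = endx, noise_rms_nf = noise_rms_nf,
                 kernel = kernel,
                 occurrence_times_ms = train$occurrence_times_ms,
                 meta = train$meta),
            class = "nf_mup_train")
}

#' Detect fibre contributions in an NF MUP
#'
#' Contributions are significant peaks of the rectified NF template: local
#' maxima of `|template|` exceeding `k_detect` times the filtered noise RMS
#' (with a relative floor of 10 percent of the template maximum, which keeps
#' the count meaningful on noise-free input). Peaks closer than
#' `min_separation_ms` are merged into the largest one, since one fibre's
#' filtered MFP is an oscillatory wavelet with several lobes. The NF duration
#' runs from the first to the last accepted contribution plus the kernel
#' support margin, and each contribution receives a segment window for jitter
#' estimation.
#'
#' @param nf_train an [nf_transform()] result.
#' @param k_detect threshold multiple of the filtered noise RMS.
#' @param min_separation_ms minimum peak separation treated as two fibres.
#' @param segment_halfwidth_ms half-width of each jitter segment window.
#' @param rel_floor relative amplitude floor for accepted peaks.
#' @return list with `nf_count`, `nf_duration_ms`, and `segment_windows`
#'   (data.frame `peak_idx`, `start_idx`, `end_idx`).
#' @export
detect_contributions <- function(nf_train, k_detect = 5,
                                 min_separation_ms = 0.8,
                                 segment_halfwidth_ms = 0.5,
                                 rel_floor = 0.1) {
  stopifnot(inherits(nf_train, "nf_mup_train"))
  v <- abs(nf_train$nf_template)
  n <- length(v)
  thr <- max(k_detect * nf_train$noise_rms_nf, rel_floor * max(v))
  if (max(v) == 0 || thr <= 0) {
    return(list(nf_count = 0L, nf_duration_ms = 0,
                segment_windows = data.frame(peak_idx = integer(),
                                             start_idx = integer(),
                                             end_idx = integer())))
  }
  # local maxima of the rectified template
  cand <- which(v >= thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[v[cand] >= v[cand - 1] & v[cand] >= v[cand + 1]]
  if (!length(cand)) {
    return(list(nf_count = 0L, nf_duration_ms = 0,
                segment_windows = data.frame(peak_idx = integer(),
                                             start_idx = integer(),
                                             end_idx = integer())))
  }
  min_sep <- round(min_separation_ms / 1000 * nf_train$fs_hz)
  accepted <- integer()
  for (p in cand[order(v[cand], decreasing = TRUE)]) {
    if (!length(accepted) || all(abs(accepted - p) >= min_sep))
      accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)
  h <- (length(nf_train$kernel) - 1L) %/% 2L
  margin_ms <- h / nf_train$fs_hz * 1000
  dur <- (max(accepted) - min(accepted)) / nf_train$fs_hz * 1000 + 2 * margin_ms
  sh <- round(segment_halfwidth_ms / 1000 * nf_train$fs_hz)
  segs <- data.frame(peak_idx = accepted,
                     start_idx = pmax(1L, accepted - sh),
                     end_idx = pmin(n, accepted + sh))
  list(nf_count = length(accepted), nf_duration_ms = dur,
       segment_windows = segs)
}

#' NF MUP jiggle
#'
#' Normalised shape variability of consecutive NF MUPs: each filtered
#' instance is aligned to the NF template by integer-sample
#' cross-correlation, the mean absolute sample-wise difference between
#' consecutive occurrences is accumulated over the NF duration window, and
#' the result is normalised by the mean rectified NF-window area across
#' instances, expressed in percent. An index of neuromuscular-junction
#' transmission instability: blocking and amplitude variability at single
#' fibres inflate it, while a perfectly repeating NF MUP scores zero.
#'
#' @param nf_train an [nf_transform()] result.
#' @param max_shift_ms alignment search range, ms.
#' @return jiggle in percent.
#' @export
jiggle <- function(nf_train, max_shift_ms = 0.5) {
  stopifnot(inherits(nf_train, "nf_mup_train"))
  inst <- nf_train$nf_instances
  if (nrow(inst) < 2)
    stop(structure(class = c("nfemg_insufficient_data", "error", "condition"),
                   list(message = "jiggle needs at least 2 occurrences",
                        call = sys.call())))
  win <- nf_train$nf_onset_idx:(nf_train$nf_end_idx - 1L)
  max_lag <- max(0L, round(max_shift_ms / 1000 * nf_train$fs_hz))
  tmpl <- nf_train$nf_template
  aligned <- inst
  if (max_lag > 0) {
    for (i in seq_len(nrow(inst))) {
      l <- best_lag(tmpl, inst[i, ], max_lag)
      if (l != 0L) aligned[i, ] <- shift_vec(inst[i, ], -l)
    }
  }
  w <- aligned[, win, drop = FALSE]
  d <- abs(w[-1, , drop = FALSE] - w[-nrow(w), , drop = FALSE])
  mean_abs_diff <- mean(rowSums(d))
  norm <- mean(rowSums(abs(w)))
  if (norm == 0) return(0)
  100 * mean_abs_diff / norm
}

#' NF MUP segment jitter
#'
#' Temporal variability of consecutive NF MUPs: for every detected fibre
#' contribution (segment), the latency of each occurrence is estimated by
#' cross-correlating the filtered instance against the NF template restricted
#' to the segment window, with parabolic interpolation of the correlation
#' peak for sub-sample resolution. The segment statistic is the mean absolute
#' consecutive difference (MCD) of those latencies; segments whose normalised
#' correlation falls below `min_corr` in an occurrence drop that occurrence,
#' and segments left with fewer than two usable consecutive pairs are
#' dropped. The result averages the per-segment MCDs, in microseconds. For
#' i.i.d. Gaussian latency jitter with SD sigma the expected value is
#' \eqn{2\sigma/\sqrt{\pi}}.
#'
#' @param nf_train an [nf_transform()] result.
#' @param segment_windows from [detect_contributions()]; computed when `NULL`.
#' @param max_lag_ms cross-correlation search range, ms.
#' @param min_corr minimum normalised correlation for a usable occurrence.
#' @return segment jitter in microseconds.
#' @export
segment_jitter <- function(nf_train, segment_windows = NULL,
                           max_lag_ms = 0.5, min_corr = 0.5) {
  stopifnot(inherits(nf_train, "nf_mup_train"))
  if (is.null(segment_windows))
    segment_windows <- detect_contributions(nf_train)$segment_windows
  inst <- nf_train$nf_instances
  if (nrow(inst) < 2 || nrow(segment_windows) < 1)
    stop(structure(class = c("nfemg_insufficient_data", "error", "condition"),
                   list(message = "segment jitter needs >=2 occurrences and >=1 segment",
                        call = sys.call())))
  fs <- nf_train$fs_hz
  max_lag <- max(1L, round(max_lag_ms / 1000 * fs))
  dt_us <- 1e6 / fs
  per_segment <- numeric(0)
  for (s in seq_len(nrow(segment_windows))) {
    a <- segment_windows$start_idx[s]
    b <- segment_windows$end_idx[s]
    ts <- nf_train$nf_template[a:b]
    ts_energy <- sqrt(sum(ts^2))
    if (ts_energy == 0) next
    lat <- segment_latencies(inst, ts, a, b, max_lag, ts_energy, min_corr) *
      dt_us
    dd <- abs(diff(lat))
    dd <- dd[!is.na(dd)]
    if (length(dd) >= 2) per_segment <- c(per_segment, mean(dd))
  }
  if (!length(per_segment))
    stop(structure(class = c("nfemg_insufficient_data", "error", "condition"),
                   list(message = "all segments dropped (contaminated or too short)",
                        call = sys.call())))
  mean(per_segment)
}

# Per-occurrence latencies (in samples, sub-sample resolution) of the
# segment template `ts` within each row of `inst`, searched over +/- max_lag
# around [a, b]. Occurrences whose normalised correlation at the peak falls
# below min_corr return NA. Vectorised across occurrences.
segment_latencies <- function(inst, ts, a, b, max_lag, ts_energy, min_corr) {
  n <- ncol(inst)
  m <- length(ts)
  lags <- (-max_lag):max_lag
  ok <- (a + lags) >= 1 & (a + lags + m - 1) <= n
  lags <- lags[ok]
  if (!length(lags)) return(rep(NA_real_, nrow(inst)))
  # cc[i, j]: correlation of occurrence i with the template at lag j
  cc <- vapply(lags, function(l)
    as.numeric(inst[, (a + l):(a + l + m - 1), drop = FALSE] %*% ts),
    numeric(nrow(inst)))
  cc <- matrix(cc, nrow = nrow(inst))
  jbest <- max.col(cc, ties.method = "first")
  idx <- cbind(seq_len(nrow(inst)), jbest)
  peak <- cc[idx]
  # parabolic interpolation around the correlation peak
  inner <- jbest > 1 & jbest < length(lags)
  delta <- numeric(nrow(inst))
  if (any(inner)) {
    cm <- cc[cbind(which(inner), jbest[inner] - 1L)]
    cp <- cc[cbind(which(inner), jbest[inner] + 1L)]
    denom <- cm - 2 * peak[inner] + cp
    d <- ifelse(denom < 0, 0.5 * (cm - cp) / denom, 0)
    delta[inner] <- ifelse(abs(d) <= 1, d, 0)
  }
  lat <- lags[jbest] + delta
  # normalised correlation at the integer peak, for contamination filtering
  x_energy <- sqrt(vapply(seq_len(nrow(inst)), function(i) {
    aa <- a + lags[jbest[i]]
    sum(inst[i, aa:(aa + m - 1)]^2)
  }, numeric(1)))
  corr <- ifelse(x_energy > 0, peak / (x_energy * ts_energy), 0)
  ifelse(corr >= min_corr, lat, NA_real_)
}

#' Compute the full NF feature set of a train
#'
#' @param train a [mup_train()] (transformed internally) or an
#'   [nf_transform()] result.
#' @param ... passed to [nf_transform()] when `train` is a raw MUP train.
#' @return one-row data.frame with `nf_duration_ms`, `nf_count`,
#'   `jiggle_pct`, `segment_jitter_us`, `n_occurrences`.
#' @export
nf_features <- function(train, ...) {
  nf <- if (inherits(train, "nf_mup_train")) train else nf_transform(train, ...)
  det <- detect_contributions(nf)
  jig <- if (nrow(nf$nf_instances) >= 2) jiggle(nf) else NA_real_
  sj <- if (nrow(nf$nf_instances) >= 2 && det$nf_count >= 1)
    tryCatch(segment_jitter(nf, det$segment_windows),
             nfemg_insufficient_data = function(e) NA_real_)
  else NA_real_
  data.frame(nf_duration_ms = det$nf_duration_ms, nf_count = det$nf_count,
             jiggle_pct = jig, segment_jitter_us = sj,
             n_occurrences = nrow(nf$nf_instances))
}
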