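#' Draw a random motor-unit model for a cohort cell
#'
#' Samples a physiologically plausible motor unit: fibre count, radial
#' distances (log-uniform between 0.05 and 1 mm, so a subset falls within
#' the near-fibre radius), arrival latencies, NMJ jitter, blocking and
#' amplitude variability, and firing statistics.
#'
#' @param label motor-unit label.
#' @param seed integer seed.
#' @param n_fibres number of fibres; drawn in 2..5 when `NULL`.
#' @param jitter_sd_us,blocking_prob,amplitude_cv NMJ parameter ranges
#'   (length-2 vectors) sampled uniformly per fibre.
#' @return a [motor_unit_model()].
#' @export
random_motor_unit <- function(label, seed, n_fibres = NULL,
                              jitter_sd_us = c(15, 35),
                              blocking_prob = c(0, 0.05),
                              amplitude_cv = c(0.02, 0.08)) {
  with_seed(derive_seed(seed, "model", label), {
    if (is.null(n_fibres)) n_fibres <- sample(2:5, 1)
    fibres <- lapply(seq_len(n_fibres), function(i)
      fibre_model(radial_distance_mm = exp(runif(1, log(0.05), log(1))),
                  mean_latency_ms = runif(1, 1, 9),
                  jitter_sd_us = runif(1, jitter_sd_us[1], jitter_sd_us[2]),
                  blocking_prob = runif(1, blocking_prob[1], blocking_prob[2]),
                  amplitude_cv = runif(1, amplitude_cv[1], amplitude_cv[2])))
    motor_unit_model(fibres, idi_mean_ms = runif(1, 80, 120),
                     idi_cv = runif(1, 0.12, 0.18), label = label)
  })
}

#' Run the full iEMG analysis pipeline on simulated data
#'
#' End-to-end orchestration: simulates MUP trains for every subject, time
#' point and contraction level, computes MUP and NF features, applies both
#' QC stages, and writes three deterministic TSV tables to `out_dir`
#' (`mup_features.tsv`, `nf_features.tsv`, `qc_report.tsv`). The run is a
#' pure function of `seed`: repeating it produces byte-identical files.
#'
#' @param out_dir output directory.
#' @param seed integer seed driving every stochastic component.
#' @param n_subjects subjects per cohort.
#' @param n_mus_per_cell motor units per subject, time point and level.
#' @param time_points time-point labels.
#' @param contraction_levels contraction levels (percent MVC).
#' @param config a [sim_config()]; its `seed` is overridden by `seed`.
#' @return invisibly, a list with the three tables and file paths.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_subjects = 2,
                         n_mus_per_cell = 2,
                         time_points = c("LS0", "LS10", "AR21"),
                         contraction_levels = c(10, 25),
                         config = sim_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- as.integer(seed)
  cells <- expand.grid(subject = seq_len(n_subjects),
                       time_point = time_points,
                       level = contraction_levels, mu = seq_len(n_mus_per_cell),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mup_rows <- list(); nf_rows <- list(); qc_rows <- list()
  for (r in seq_len(nrow(cells))) {
    lab <- sprintf("S%02d_%s_%d_MU%02d", cells$subject[r], cells$time_point[r],
                   cells$level[r], cells$mu[r])
    mu <- random_motor_unit(lab, seed)
    train <- simulate_mup_train(mu, config)
    train$meta$subject <- cells$subject[r]
    train$meta$time_point <- cells$time_point[r]
    train$meta$contraction_level <- cells$level[r]
    feats <- mup_features(train)
    qc1 <- qc_mup_train(train, feats, train_id = lab)
    nf <- nf_transform(train)
    nfeats <- nf_features(nf)
    qc2 <- qc_nf_train(nf, nfeats, snr = feats$snr, train_id = lab)
    id_cols <- data.frame(train_id = lab, subject_id = cells$subject[r],
                          time_point = cells$time_point[r],
                          contraction_level = cells$level[r])
    mup_rows[[r]] <- cbind(id_cols, feats)
    nf_rows[[r]] <- cbind(id_cols, nfeats)
    qc_rows[[r]] <- data.frame(
      train_id = lab, mup_passed = qc1$passed,
      mup_reasons = paste(qc1$reasons, collapse = ";"),
      nf_passed = qc2$passed,
      nf_reasons = paste(qc2$reasons, collapse = ";"))
  }
  mup_tab <- do.call(rbind, mup_rows)
  nf_tab <- do.call(rbind, nf_rows)
  qc_tab <- do.call(rbind, qc_rows)
  paths <- c(mup = file.path(out_dir, "mup_features.tsv"),
             nf = file.path(out_dir, "nf_features.tsv"),
             qc = file.path(out_dir, "qc_report.tsv"))
  write_feature_table(mup_tab, paths["mup"])
  write_feature_table(nf_tab, paths["nf"])
  write_feature_table(qc_tab, paths["qc"])
  invisible(list(mup_features = mup_tab, nf_features = nf_tab,
                 qc_report = qc_tab, paths = paths))
}
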