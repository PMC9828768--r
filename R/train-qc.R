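#' Quality control of a MUP train
#'
#' Applies the inclusion rules for decomposed MUP trains: at least 35
#' occurrences (trains with fewer are excluded), signal-to-noise ratio of at
#' least 15 (trains with SNR < 15 are excluded), and optionally a
#' shape-plausibility heuristic standing in for operator review of
#' non-physiological shapes (flagging durations over `max_duration_ms`, more
#' than `max_turns` turns, or a peak-to-peak amplitude under three times the
#' noise). The heuristic is off by default.
#'
#' @param train a [mup_train()].
#' @param features a one-row data.frame from [mup_features()]; computed when
#'   `NULL`.
#' @param min_occurrences minimum occurrence count (inclusive).
#' @param min_snr minimum SNR (inclusive).
#' @param shape_check apply the shape-plausibility heuristic?
#' @param max_duration_ms,max_turns shape heuristic limits.
#' @param train_id identifier copied into the report.
#' @return an object of class `qc_report`: `train_id`, `passed`, `reasons`
#'   (character vector of failed rule identifiers, empty iff passed), and
#'   `metrics`.
#' @export
qc_mup_train <- function(train, features = NULL, min_occurrences = 35,
                         min_snr = 15, shape_check = FALSE,
                         max_duration_ms = 40, max_turns = 25,
                         train_id = train$meta$label %||% "train") {
  stopifnot(inherits(train, "mup_train"))
  if (is.null(features)) features <- mup_features(train)
  reasons <- character()
  if (features$n_occurrences < min_occurrences)
    reasons <- c(reasons, "min-occurrences")
  if (features$snr < min_snr) reasons <- c(reasons, "snr")
  if (shape_check &&
      (features$duration_ms > max_duration_ms || features$turns > max_turns))
    reasons <- c(reasons, "shape")
  qc_report(train_id, reasons, features)
}

#' Quality control of an NF MUP train
#'
#' Inclusion requires SNR strictly greater than 15, strictly more than 34 NF
#' MUPs, and an NF count of at least 1. Boundary semantics are strict as
#' printed: SNR exactly 15 and exactly 34 occurrences are both excluded,
#' while NF count 1 is included.
#'
#' @param nf_train an [nf_transform()] result (or any object; only used for
#'   its label when `train_id` is missing).
#' @param nf_features one-row data.frame from [nf_features()].
#' @param snr SNR of the source train (template peak-to-peak over noise RMS).
#' @param min_snr exclusive SNR threshold.
#' @param min_occurrences exclusive occurrence threshold.
#' @param min_nf_count inclusive NF count threshold.
#' @param train_id identifier copied into the report.
#' @return a `qc_report`.
#' @export
qc_nf_train <- function(nf_train, nf_features, snr,
                        min_snr = 15, min_occurrences = 34, min_nf_count = 1,
                        train_id = nf_train$meta$label %||% "train") {
  reasons <- character()
  if (!(snr > min_snr)) reasons <- c(reasons, "snr")
  if (!(nf_features$n_occurrences > min_occurrences))
    reasons <- c(reasons, "min-occurrences")
  if (!(nf_features$nf_count >= min_nf_count))
    reasons <- c(reasons, "nf-count")
  qc_report(train_id, reasons, cbind(nf_features, snr = snr))
}

qc_report <- function(train_id, reasons, metrics) {
  structure(list(train_id = train_id, passed = length(reasons) == 0,
                 reasons = reasons, metrics = metrics),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %s%s\n", x$train_id,
              if (x$passed) "PASS" else "FAIL",
              if (x$passed) "" else paste0(" [", paste(x$reasons, collapse = ", "), "]")))
  invisible(x)
}

#' Summarise a batch of QC reports
#'
#' Counts inputs, passes, and per-rule exclusions with first-failing-rule
#' attribution (each excluded train is attributed to the first rule in its
#' `reasons`, so `n_input = n_passed + sum(excluded_by)`; all failing rules
#' remain listed in each report).
#'
#' @param reports list of `qc_report` objects.
#' @return list with `n_input`, `n_passed`, `excluded_by` (named integer
#'   vector), and a per-train data.frame `table`.
#' @export
qc_summarise <- function(reports) {
  stopifnot(all(vapply(reports, inherits, logical(1), "qc_report")))
  first_fail <- vapply(reports, function(r)
    if (r$passed) NA_character_ else r$reasons[1], character(1))
  excl <- table(first_fail[!is.na(first_fail)])
  list(n_input = length(reports),
       n_passed = sum(vapply(reports, `[[`, logical(1), "passed")),
       excluded_by = stats::setNames(as.integer(excl), names(excl)),
       table = data.frame(
         train_id = vapply(reports, `[[`, character(1), "train_id"),
         passed = vapply(reports, `[[`, logical(1), "passed"),
         reasons = vapply(reports, function(r)
           paste(r$reasons, collapse = ";"), character(1))))
}
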