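#' Write MUP trains to a plain-text container
#'
#' One group of files per motor unit under `dir`: `<label>_times.tsv`
#' (occurrence times, ms), `<label>_instances.tsv` (one row per occurrence,
#' uV), and `<label>_meta.json` (sampling rate, noise RMS and metadata).
#' An optional JSON sidecar `ground_truth.json` records simulation ground
#' truth when supplied.
#'
#' @param trains named list of [mup_train()] objects (names become labels).
#' @param dir output directory (created if needed).
#' @param ground_truth optional list serialised to `ground_truth.json`.
#' @return `dir`, invisibly.
#' @export
write_mup_trains <- function(trains, dir, ground_truth = NULL) {
  if (inherits(trains, "mup_train")) trains <- list(trains)
  if (is.null(names(trains)) || any(!nzchar(names(trains))))
    names(trains) <- vapply(seq_along(trains), function(i)
      trains[[i]]$meta$label %||% sprintf("mu%03d", i), character(1))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(trains)) {
    tr <- trains[[nm]]
    stopifnot(inherits(tr, "mup_train"))
    utils::write.table(data.frame(time_ms = tr$occurrence_times_ms),
                       file.path(dir, paste0(nm, "_times.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format(tr$instances, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       file.path(dir, paste0(nm, "_instances.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(c(list(fs_hz = tr$fs_hz,
                                noise_rms_uV = tr$noise_rms_uV), tr$meta),
                         file.path(dir, paste0(nm, "_meta.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(ground_truth))
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read MUP trains written by [write_mup_trains()]
#'
#' @param dir directory containing the per-MU files.
#' @return named list of [mup_train()] objects.
#' @export
read_mup_trains <- function(dir) {
  metas <- list.files(dir, pattern = "_meta\\.json$", full.names = TRUE)
  labels <- sub("_meta\\.json$", "", basename(metas))
  out <- lapply(seq_along(metas), function(i) {
    meta <- jsonlite::read_json(metas[i], simplifyVector = TRUE)
    times <- utils::read.table(file.path(dir, paste0(labels[i], "_times.tsv")),
                               header = TRUE, sep = "\t")$time_ms
    inst <- as.matrix(utils::read.table(
      file.path(dir, paste0(labels[i], "_instances.tsv")), sep = "\t"))
    dimnames(inst) <- NULL
    mup_train(fs_hz = meta$fs_hz, occurrence_times_ms = times,
              instances = inst, noise_rms_uV = meta$noise_rms_uV,
              meta = meta[setdiff(names(meta), c("fs_hz", "noise_rms_uV"))])
  })
  stats::setNames(out, labels)
}

#' Write a feature or QC table as TSV
#'
#' Deterministic plain-text serialisation (fixed 15-digit formatting), so
#' identical inputs produce byte-identical files.
#'
#' @param table a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], function(x)
    format(x, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
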