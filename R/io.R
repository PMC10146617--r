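#' Write a subject's epochs as a delimited matrix plus JSON sidecar
#'
#' The matrix stacks trials as blocks of channel rows (trial 1 channels,
#' trial 2 channels, ...); the sidecar records channels, sampling rate,
#' pulse sample, trial count and cohort metadata.
#'
#' @param epochs an `epoch_set`.
#' @param dir output directory.
#' @return invisibly, the two file paths.
#' @export
write_subject <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), d[1] * d[2], d[3])
  base <- file.path(dir, epochs$subject_id)
  data_path <- paste0(base, "_eeg.csv")
  meta_path <- paste0(base, "_eeg.json")
  data.table::fwrite(data.table::as.data.table(flat), data_path, col.names = FALSE)
  jsonlite::write_json(list(subject_id = epochs$subject_id, group = epochs$group,
                            site = epochs$site, channels = epochs$channel_labels,
                            fs_hz = epochs$fs_hz, pulse_sample = epochs$pulse_sample,
                            n_trials = d[1]),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data = data_path, meta = meta_path))
}

#' Read a subject written by [write_subject()]
#'
#' @param data_path path to the `_eeg.csv` matrix (the `_eeg.json` sidecar is
#'   expected alongside).
#' @return an `epoch_set`.
#' @export
read_subject <- function(data_path) {
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", data_path), simplifyVector = TRUE)
  flat <- as.matrix(data.table::fread(data_path, header = FALSE))
  n_ch <- length(meta$channels)
  arr <- aperm(array(flat, dim = c(n_ch, meta$n_trials, ncol(flat))), c(2L, 1L, 3L))
  epoch_set(arr, meta$fs_hz, meta$pulse_sample, meta$channels,
            subject_id = meta$subject_id, group = meta$group, site = meta$site)
}

#' Write a cohort: per-subject matrices, manifest and ground-truth sidecar
#'
#' @param cohort result of [synthesize_cohort()].
#' @param dir output directory.
#' @return invisibly, the manifest with file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(cohort$subjects, function(s) write_subject(s, dir)[["data"]],
                  character(1))
  manifest <- cohort$manifest
  manifest$file <- basename(files)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- cohort$truth
  gt <- list(planted_network = truth$planted_network,
             planted_delta_j = truth$planted_delta_j, seed = truth$seed,
             models = lapply(truth$models, function(g) lapply(g, function(cond)
               lapply(cond, function(m) list(h = m$h, J = m$J)))))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write an ROI activation table as tidy CSV
#'
#' One row per (subject, roi, sample), mirroring the pipeline's CSV handoff
#' between source localization and the landscape stage.
#'
#' @param roi_series_list list of `roi_series`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_roi_table <- function(roi_series_list, path) {
  dt <- data.table::rbindlist(lapply(roi_series_list, function(rs) {
    data.table::data.table(subject_id = rs$subject_id, group = rs$group,
                           site = rs$site, roi = rep(rownames(rs$values),
                                                     ncol(rs$values)),
                           sample = rep(seq_len(ncol(rs$values)),
                                        each = nrow(rs$values)),
                           value = as.vector(rs$values))
  }))
  data.table::fwrite(dt, path)
  invisible(path)
}
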