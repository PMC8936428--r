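# Plain-text EEG and result I/O: channel x sample CSV matrices with a YAML
# sidecar, and tidy CSV writers for coherence profiles and reports.

#' Read an EEG recording from CSV plus YAML sidecar
#'
#' The CSV holds one row per channel: first column the channel label, the
#' remaining columns the samples in microvolts.  The sidecar (same path with
#' `.yaml`, or given explicitly) supplies `subject_id`, `fs` and
#' `lesion_side`.
#'
#' @param path CSV path.
#' @param sidecar YAML sidecar path; default replaces the CSV extension with
#'   `.yaml`.
#' @return An [eeg_recording()].
#' @export
read_eeg_csv <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".yaml", path)
  if (!file.exists(sidecar)) {
    abort(paste0("Sidecar not found: ", sidecar))
  }
  meta <- yaml::read_yaml(sidecar)
  for (field in c("subject_id", "fs", "lesion_side")) {
    if (is.null(meta[[field]])) {
      abort(paste0("Sidecar is missing field `", field, "`."))
    }
  }
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  channels <- as.character(raw[[1]])
  data <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(data) <- "double"
  eeg_recording(meta$subject_id, data, channels, meta$fs, meta$lesion_side)
}

#' Write an EEG recording as CSV plus YAML sidecar
#'
#' @param recording An [eeg_recording()].
#' @param dir Output directory (created if needed).
#' @param digits Significant digits kept in the CSV (default 6).
#' @return Invisibly, the CSV path.
#' @export
write_eeg_csv <- function(recording, dir, digits = 6) {
  stopifnot(inherits(recording, "eeg_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(recording$subject_id, "_eeg.csv"))
  side <- file.path(dir, paste0(recording$subject_id, "_eeg.yaml"))
  m <- signif(recording$data, digits)
  utils::write.table(
    cbind(recording$channels, as.data.frame(m)), csv,
    sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  yaml::write_yaml(
    list(subject_id = recording$subject_id, fs = recording$fs,
         lesion_side = recording$lesion_side),
    side
  )
  invisible(csv)
}

#' Write tidy coherence outputs
#'
#' Pair-level profiles go to `<stem>_pairs.csv` (subject, frame, band,
#' electrodes, coherence); network summaries to `<stem>_networks.csv`.
#'
#' @param profile Profile tibble ([coherence_profile()] /
#'   [canonicalize_lesion()]).
#' @param networks Network tibble ([network_aggregate()]), optional.
#' @param stem Output path stem.
#' @return Invisibly, the paths written.
#' @export
write_coherence_csv <- function(profile, networks = NULL, stem) {
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  paths <- paste0(stem, "_pairs.csv")
  readr::write_csv(profile, paths[1])
  if (!is.null(networks)) {
    paths <- c(paths, paste0(stem, "_networks.csv"))
    readr::write_csv(networks, paths[2])
  }
  invisible(paths)
}
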