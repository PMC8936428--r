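# Montage constants: the eight sensorimotor electrodes, frequency bands,
# pair bookkeeping, lesion-frame flipping and the five network definitions.

# Fixed display/ordering convention for the analysis electrodes.  Pair labels
# ("C4-FC3", "FC4-CP3", ...) order their members by this vector, which matches
# how pairs are conventionally written for this montage.
.ELECTRODE_ORDER <- c("C3", "C4", "FC3", "FC4", "CP3", "CP4", "FCz", "Cz")

.BAND_LEVELS <- c("delta", "theta", "alpha", "beta")

# Midline flip used to map a left-lesion recording into the canonical frame.
.FLIP_MAP <- c(
  C3 = "C4", C4 = "C3", FC3 = "FC4", FC4 = "FC3",
  CP3 = "CP4", CP4 = "CP3", FCz = "FCz", Cz = "Cz"
)

#' Electrodes entering the coherence analysis
#'
#' The eight 10-20 electrodes over the sensorimotor strip used for pairwise
#' coherence: primary motor (C3/C4), premotor (FC3/FC4), somatosensory
#' (CP3/CP4), supplementary motor area (Cz) and FCz.
#'
#' @return Character vector of eight 10-20 labels in canonical order.
#' @export
#' @examples
#' analysis_electrodes()
analysis_electrodes <- function() .ELECTRODE_ORDER

#' Default frequency-band definitions
#'
#' Half-open bands `[lo, hi)` in Hz: delta 1-4, theta 4-8, alpha 8-14,
#' beta 14-30.  The half-open convention keeps the shared edges (4, 8, 14 Hz)
#' from being counted in two bands on the Welch frequency grid.
#'
#' @return A tibble with columns `band` (factor delta < theta < alpha < beta),
#'   `lo`, `hi` in Hz.
#' @export
#' @examples
#' coh_bands()
coh_bands <- function() {
  tibble(
    band = band_factor(.BAND_LEVELS),
    lo = c(1, 4, 8, 14),
    hi = c(4, 8, 14, 30)
  )
}

#' @rdname coh_bands
#' @param x Character vector of band names.
#' @export
band_factor <- function(x) factor(x, levels = .BAND_LEVELS)

#' Canonical label for an electrode pair
#'
#' Orders the two electrodes by the montage convention (see
#' [analysis_electrodes()]) so that `(a, b)` and `(b, a)` map to the same
#' label, e.g. `pair_label("FC3", "C4")` is `"C4-FC3"`.
#'
#' @param a,b Electrode labels (vectorized).
#' @return Character vector of pair labels.
#' @export
pair_label <- function(a, b) {
  ia <- match(a, .ELECTRODE_ORDER)
  ib <- match(b, .ELECTRODE_ORDER)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(a[is.na(ia)], b[is.na(ib)]))
    abort(paste0("Unknown electrode label(s): ", paste(bad, collapse = ", ")))
  }
  ifelse(ia <= ib, paste0(a, "-", b), paste0(b, "-", a))
}

# Split "C4-FC3" back into ordered members.
.pair_members <- function(label) strsplit(label, "-", fixed = TRUE)

#' All unordered electrode pairs of the analysis montage
#'
#' @return Tibble with `electrode_a`, `electrode_b`, `pair` (28 rows),
#'   members ordered by the montage convention.
#' @export
electrode_pairs <- function() {
  cmb <- combn(.ELECTRODE_ORDER, 2)
  tibble(
    electrode_a = cmb[1, ],
    electrode_b = cmb[2, ],
    pair = pair_label(cmb[1, ], cmb[2, ])
  )
}

#' The five coherence-network definitions
#'
#' Groups 21 of the 28 electrode pairs into five networks: interhemispheric
#' (`InterHemi`, 9 pairs), ipsilesional local (`IpsiLHemi`), contralesional
#' local (`ContraLHemi`), ipsilesional-to-SMA (`IpsiL-SMA`) and
#' contralesional-to-SMA (`ContraL-SMA`), 3 pairs each.  Pairs involving FCz
#' belong to no network.
#'
#' Definitions are expressed in the canonical lesion frame.  With the default
#' `ipsi_side = "right"` the ipsilesional hemisphere occupies C4/FC4/CP4 (so
#' contralesional structures carry C3-side labels); `ipsi_side = "left"`
#' mirrors the membership for the opposite convention.
#'
#' @param ipsi_side Which hemisphere the canonical frame treats as
#'   ipsilesional, `"right"` (default) or `"left"`.
#' @return Tibble with `network`, `electrode_a`, `electrode_b`, `pair`
#'   (21 rows).
#' @export
#' @examples
#' dplyr::count(network_pairs(), network)
network_pairs <- function(ipsi_side = c("right", "left")) {
  ipsi_side <- match.arg(ipsi_side)
  inter <- expand.grid(
    a = c("C3", "FC3", "CP3"), b = c("C4", "FC4", "CP4"),
    stringsAsFactors = FALSE
  )
  local_left <- data.frame(
    a = c("C3", "C3", "FC3"), b = c("FC3", "CP3", "CP3")
  )
  local_right <- data.frame(
    a = c("C4", "C4", "FC4"), b = c("CP4", "FC4", "CP4")
  )
  sma_left <- data.frame(a = c("C3", "FC3", "CP3"), b = "Cz")
  sma_right <- data.frame(a = c("C4", "FC4", "CP4"), b = "Cz")

  if (ipsi_side == "right") {
    ipsi_local <- local_right; contra_local <- local_left
    ipsi_sma <- sma_right; contra_sma <- sma_left
  } else {
    ipsi_local <- local_left; contra_local <- local_right
    ipsi_sma <- sma_left; contra_sma <- sma_right
  }

  out <- rbind(
    cbind(network = "InterHemi", inter),
    cbind(network = "IpsiLHemi", ipsi_local),
    cbind(network = "ContraLHemi", contra_local),
    cbind(network = "IpsiL-SMA", ipsi_sma),
    cbind(network = "ContraL-SMA", contra_sma)
  )
  lab <- pair_label(out$a, out$b)
  members <- do.call(rbind, .pair_members(lab))
  tibble(
    network = factor(out$network, levels = c(
      "InterHemi", "IpsiLHemi", "ContraLHemi", "IpsiL-SMA", "ContraL-SMA"
    )),
    electrode_a = members[, 1],
    electrode_b = members[, 2],
    pair = lab
  ) %>% arrange(.data$network, .data$pair)
}

#' Construct an EEG recording object
#'
#' Light container for one participant's multichannel resting EEG: a
#' channels-by-samples matrix in microvolts plus montage labels, sampling
#' rate and lesion side.
#'
#' @param subject_id Participant identifier.
#' @param data Numeric matrix, channels x samples.
#' @param channels Character vector of 10-20 labels, one per row of `data`.
#'   Must contain each of the eight analysis electrodes exactly once.
#' @param fs Sampling rate in Hz (positive).
#' @param lesion_side `"left"` or `"right"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, data, channels, fs,
                          lesion_side = c("right", "left")) {
  lesion_side <- match.arg(lesion_side)
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("`data` must be a numeric matrix.")
  if (length(channels) != nrow(data)) {
    abort("`channels` must have one label per row of `data`.")
  }
  need <- .ELECTRODE_ORDER
  counts <- table(factor(channels, levels = unique(channels)))
  missing <- setdiff(need, channels)
  if (length(missing) > 0) {
    abort(paste0(
      "Recording is missing required channel(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  dup <- intersect(need, names(counts)[counts > 1])
  if (length(dup) > 0) {
    abort(paste0("Duplicated channel label(s): ", paste(dup, collapse = ", ")))
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive sampling rate in Hz.")
  }
  rownames(data) <- channels
  structure(
    list(
      subject_id = as.character(subject_id),
      channels = as.character(channels),
      data = data,
      fs = as.numeric(fs),
      lesion_side = lesion_side
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s), lesion %s\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs, x$lesion_side
  ))
  invisible(x)
}
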