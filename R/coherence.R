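# Welch magnitude-squared coherence and the per-subject coherence profile.

# Segment layout for a Welch estimate. Errors when fewer than `min_segments`
# fit, because coherence from a single segment is identically 1.
.welch_segments_layout <- function(n, fs, seg_sec, overlap, min_segments = 2) {
  L <- round(seg_sec * fs)
  step <- max(1L, round(L * (1 - overlap)))
  if (L < 8) abort("Welch segments are too short; increase `seg_sec`.")
  if (n < L + step) {
    abort(paste0(
      "Signal too short for Welch coherence: need at least 2 segments of ",
      seg_sec, " s at ", 100 * overlap, "% overlap (", L + step,
      " samples), got ", n, "."
    ))
  }
  starts <- seq(1L, n - L + 1L, by = step)
  if (length(starts) < min_segments) {
    abort("Fewer than 2 Welch segments available.")
  }
  list(L = L, starts = starts)
}

.welch_window <- function(L, window) {
  switch(window,
    hann = 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L),
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / L),
    rect = rep(1, L),
    abort(paste0("Unknown taper `", window, "`; use hann, hamming or rect."))
  )
}

# Per-segment windowed FFTs for a channels x samples matrix.
# Returns nf x nchan x nseg complex array plus the frequency grid.
.welch_fft <- function(data, fs, seg_sec = 2, overlap = 0.5,
                       window = "hann", detrend = "linear") {
  lay <- .welch_segments_layout(ncol(data), fs, seg_sec, overlap)
  L <- lay$L
  w <- .welch_window(L, window)
  nf <- L %/% 2 + 1
  tt <- seq_len(L)
  # orthonormal basis of the (intercept, slope) space for fast detrending
  Q <- qr.Q(qr(cbind(1, tt)))
  nseg <- length(lay$starts)
  out <- array(0i, dim = c(nf, nrow(data), nseg))
  for (k in seq_len(nseg)) {
    seg <- data[, lay$starts[k]:(lay$starts[k] + L - 1), drop = FALSE]
    seg <- switch(detrend,
      linear = seg - (seg %*% Q) %*% t(Q),
      mean = seg - rowMeans(seg),
      none = seg,
      abort("`detrend` must be one of linear, mean, none.")
    )
    segw <- sweep(seg, 2, w, `*`)
    Fk <- stats::mvfft(t(segw))[1:nf, , drop = FALSE]
    out[, , k] <- Fk
  }
  list(fft = out, freq = (0:(nf - 1)) * fs / L, nseg = nseg)
}

# Coherence spectrum from the stacked segment FFTs of two channels.
.msc_from_fft <- function(Fa, Fb) {
  Saa <- rowSums(Mod(Fa)^2)
  Sbb <- rowSums(Mod(Fb)^2)
  Sab <- rowSums(Fa * Conj(Fb))
  coh <- Mod(Sab)^2 / (Saa * Sbb)
  coh[Saa == 0 | Sbb == 0] <- NA_real_
  pmin(pmax(coh, 0), 1)
}

#' Welch magnitude-squared coherence spectrum
#'
#' Estimates the magnitude-squared coherence
#' \eqn{|S_{xy}(f)|^2 / (S_{xx}(f) S_{yy}(f))} between two equally long
#' signals from Welch-averaged cross- and auto-spectra: the signals are cut
#' into overlapping tapered segments (linearly detrended by default), the
#' per-segment FFT cross products are averaged, and the ratio is formed on
#' the segment frequency grid.  Values lie in `[0, 1]`; bins where either
#' signal has zero power are `NA` (coherence is undefined there).
#'
#' At least two segments must fit: a single-segment estimate is identically
#' one and is rejected.
#'
#' @param x,y Numeric vectors of equal length.
#' @param fs Sampling rate in Hz.
#' @param seg_sec Segment length in seconds (default 2, i.e. 0.5 Hz
#'   resolution).
#' @param overlap Fractional segment overlap in `[0, 1)` (default 0.5).
#' @param window Taper: `"hann"` (default), `"hamming"` or `"rect"`.
#' @param detrend Per-segment detrending: `"linear"` (default), `"mean"` or
#'   `"none"`.
#' @return Tibble with columns `freq` (Hz) and `coherence`.
#' @export
#' @examples
#' x <- bandlimited_noise(2048, fs = 256, lo = 8, hi = 14, seed = 1)
#' msc <- msc_spectrum(x, x, fs = 256)
#' all(msc$coherence[msc$freq >= 8 & msc$freq < 14] > 0.999)
msc_spectrum <- function(x, y, fs, seg_sec = 2, overlap = 0.5,
                         window = "hann", detrend = "linear") {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ff <- .welch_fft(rbind(x, y), fs, seg_sec, overlap, window, detrend)
  tibble(
    freq = ff$freq,
    coherence = .msc_from_fft(ff$fft[, 1, , drop = FALSE][, 1, ],
                              ff$fft[, 2, , drop = FALSE][, 1, ])
  )
}

#' Band-average a coherence spectrum
#'
#' Arithmetic mean of the coherence values whose frequencies fall in the
#' half-open band `[lo, hi)`.
#'
#' @param spectrum Tibble from [msc_spectrum()] (columns `freq`,
#'   `coherence`).
#' @param lo,hi Band edges in Hz.
#' @return Single coherence value in `[0, 1]`.
#' @export
band_average <- function(spectrum, lo, hi) {
  stopifnot(lo < hi)
  sel <- spectrum$freq >= lo & spectrum$freq < hi
  if (!any(sel)) {
    abort(paste0(
      "No frequency bins fall in [", lo, ", ", hi, ") Hz; the Welch grid is ",
      "too coarse -- lengthen `seg_sec`."
    ))
  }
  mean(spectrum$coherence[sel], na.rm = TRUE)
}

#' Per-subject band-by-pair coherence profile
#'
#' Computes band-averaged Welch coherence for all 28 unordered pairs of the
#' eight analysis electrodes.  Segment FFTs are computed once per channel and
#' reused across pairs.
#'
#' @param recording An [eeg_recording()], normally after [eeg_preprocess()].
#' @param bands Band definition tibble, see [coh_bands()].
#' @inheritParams msc_spectrum
#' @return Tibble with columns `subject_id`, `lesion_side`,
#'   `frame` (`"raw"`), `band`, `electrode_a`, `electrode_b`, `pair`,
#'   `coherence` (28 pairs x `nrow(bands)` rows).
#' @export
coherence_profile <- function(recording, bands = coh_bands(), seg_sec = 2,
                              overlap = 0.5, window = "hann",
                              detrend = "linear") {
  stopifnot(inherits(recording, "eeg_recording"))
  chans <- analysis_electrodes()
  ff <- .welch_fft(recording$data[chans, , drop = FALSE], recording$fs,
                   seg_sec, overlap, window, detrend)
  pairs <- electrode_pairs()
  per_pair <- purrr::pmap(pairs, function(electrode_a, electrode_b, pair) {
    ia <- match(electrode_a, chans)
    ib <- match(electrode_b, chans)
    coh <- .msc_from_fft(ff$fft[, ia, , drop = FALSE][, 1, ],
                         ff$fft[, ib, , drop = FALSE][, 1, ])
    spec <- tibble(freq = ff$freq, coherence = coh)
    tibble(
      electrode_a = electrode_a, electrode_b = electrode_b, pair = pair,
      band = bands$band,
      coherence = purrr::map2_dbl(bands$lo, bands$hi,
                                  ~ band_average(spec, .x, .y))
    )
  })
  bind_rows(per_pair) %>%
    mutate(
      subject_id = recording$subject_id,
      lesion_side = recording$lesion_side,
      frame = "raw",
      .before = 1
    ) %>%
    arrange(.data$band, .data$pair)
}

#' Map a coherence profile into the canonical lesion frame
#'
#' Relabels electrodes so the ipsilesional hemisphere always occupies the
#' same side of the montage.  With the default convention (ipsilesional =
#' right, the frame used by the five-network definitions), right-lesion
#' profiles pass through unchanged and left-lesion profiles have their labels
#' swapped across the midline (C3<->C4, FC3<->FC4, CP3<->CP4; Cz and FCz
#' fixed).  Applying the flip mapping twice is the identity, and the multiset
#' of coherence values is preserved -- only labels move.
#'
#' @param profile Profile tibble from [coherence_profile()] (may hold several
#'   subjects).  Must be in the `"raw"` frame.
#' @param lesion_side Optional override; by default the profile's own
#'   `lesion_side` column is used.
#' @param ipsi_side Which side the canonical frame assigns to the
#'   ipsilesional hemisphere (default `"right"`).
#' @return The profile with `frame = "canonical"` and relabeled pairs.
#' @export
canonicalize_lesion <- function(profile, lesion_side = NULL,
                                ipsi_side = c("right", "left")) {
  ipsi_side <- match.arg(ipsi_side)
  if (!all(profile$frame == "raw")) {
    abort("`profile` must be in the raw frame (not already canonicalized).")
  }
  if (!is.null(lesion_side)) {
    lesion_side <- match.arg(lesion_side, c("left", "right"))
    profile$lesion_side <- lesion_side
  }
  if (!all(profile$lesion_side %in% c("left", "right"))) {
    abort("Unknown lesion side; must be \"left\" or \"right\".")
  }
  flip <- profile$lesion_side != ipsi_side
  out <- profile
  out$electrode_a <- ifelse(flip, .FLIP_MAP[profile$electrode_a],
                            profile$electrode_a)
  out$electrode_b <- ifelse(flip, .FLIP_MAP[profile$electrode_b],
                            profile$electrode_b)
  # restore canonical member order inside each pair
  swap <- match(out$electrode_a, .ELECTRODE_ORDER) >
    match(out$electrode_b, .ELECTRODE_ORDER)
  tmp <- out$electrode_a[swap]
  out$electrode_a[swap] <- out$electrode_b[swap]
  out$electrode_b[swap] <- tmp
  out$pair <- pair_label(out$electrode_a, out$electrode_b)
  out$frame <- "canonical"
  arrange(out, .data$subject_id, .data$band, .data$pair)
}

#' Five-network coherence summaries
#'
#' Averages the member pairs of each of the five networks (InterHemi,
#' IpsiLHemi, ContraLHemi, IpsiL-SMA, ContraL-SMA) per band and subject.
#' Requires a canonical-frame profile; FCz pairs are carried in the profile
#' but belong to no network.
#'
#' @param profile Canonical-frame profile from [canonicalize_lesion()].
#' @param networks Network membership tibble, see [network_pairs()].
#' @return Tibble with `subject_id`, `band`, `network`, `value`.
#' @export
network_aggregate <- function(profile, networks = network_pairs()) {
  if (!all(profile$frame == "canonical")) {
    abort("`profile` must be canonicalized first (see canonicalize_lesion).")
  }
  joined <- left_join(
    networks %>% select("network", "pair"),
    profile %>% select("subject_id", "band", "pair", "coherence"),
    by = "pair", relationship = "many-to-many"
  )
  missing <- joined %>% filter(is.na(.data$coherence))
  if (nrow(missing) > 0) {
    abort(paste0(
      "Profile is missing network member pair(s): ",
      paste(unique(missing$pair), collapse = ", ")
    ))
  }
  joined %>%
    group_by(.data$subject_id, .data$band, .data$network) %>%
    summarise(value = mean(.data$coherence), .groups = "drop") %>%
    arrange(.data$subject_id, .data$band, .data$network)
}
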