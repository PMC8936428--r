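# Shared fixtures built in code.

# A raw-frame profile with given (or random) coherence values for one subject.
make_profile <- function(values = NULL, subject_id = "p1",
                         lesion_side = "right", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::crossing(coh_bands()["band"], electrode_pairs())
  grid$coherence <- if (is.null(values)) runif(nrow(grid)) else values
  dplyr::mutate(grid, subject_id = subject_id, lesion_side = lesion_side,
                frame = "raw", .before = 1)
}

# Sinusoid recording helper for filter tests.
make_sine_recording <- function(freq, fs = 256, duration = 8, amp = 50) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t)
  data <- matrix(rep(x, each = 8), nrow = 8)
  eeg_recording("sine", data, analysis_electrodes(), fs, "right")
}

# RMS of the central portion (avoids filtfilt edge transients).
central_rms <- function(x, trim = 0.2) {
  n <- length(x)
  i <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  sqrt(mean(x[i]^2))
}
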