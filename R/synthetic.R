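# Synthetic EEG with controlled pairwise coherence and synthetic cohorts
# with a known coherence-to-outcome model.  The shared-source mixing model
# makes the generator its own oracle: a pair built as
#   x = sqrt(gamma) s + sqrt(1 - gamma) n_x
#   y = sqrt(gamma) s + sqrt(1 - gamma) n_y
# with independent unit-variance band-limited s, n_x, n_y has band coherence
# exactly gamma^2.

# round-half-away-from-zero (FMA scores are integers)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Band-limited Gaussian noise
#'
#' Zero-mean, unit-variance noise whose power lies entirely in the half-open
#' band `[lo, hi)`: white Gaussian noise is transformed to the frequency
#' domain, out-of-band bins are zeroed, and the inverse transform is
#' standardized.  Spectral masking (rather than FIR filtering) puts 100% of
#' the power in-band, which keeps the shared-source coherence target exact.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz; `hi` must not exceed the Nyquist frequency.
#' @param seed Optional integer seed (reproducible for a given `n`).
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' x <- bandlimited_noise(4096, 256, 8, 14, seed = 1)
#' c(mean(x), sd(x))
bandlimited_noise <- function(n, fs, lo, hi, seed = NULL) {
  stopifnot(n > 8, lo >= 0, lo < hi)
  if (hi > fs / 2) {
    abort(paste0("Band edge ", hi, " Hz is above the Nyquist frequency ",
                 fs / 2, " Hz."))
  }
  .with_seed_or_not(seed, {
    w <- rnorm(n)
    W <- fft(w)
    f <- (0:(n - 1)) * fs / n
    f <- pmin(f, fs - f) # fold to two-sided frequencies
    W[!(f >= lo & f < hi)] <- 0
    x <- Re(fft(W, inverse = TRUE)) / n
    (x - mean(x)) / sd(x)
  })
}

#' Specify target pairwise coherences for a synthetic recording
#'
#' Each row requests one electrode pair and band to share a band-limited
#' source with shared power fraction `gamma`; the measured band coherence of
#' that pair is then `gamma^2` in expectation.  Within one band a channel may
#' appear in at most one requested pair (otherwise the closed form no longer
#' holds and the spec is rejected at generation time).  Unlisted pairs share
#' no source and sit at the independence floor.
#'
#' @param electrode_a,electrode_b Electrode labels.
#' @param band Band name (delta/theta/alpha/beta).
#' @param gamma Shared power fraction in `[0, 1]`.
#' @return Tibble of class spec rows; zero rows by default.
#' @export
#' @examples
#' coherence_spec("C3", "C4", "alpha", gamma = sqrt(0.5)) # coherence 0.5
coherence_spec <- function(electrode_a = character(),
                           electrode_b = character(),
                           band = character(), gamma = numeric()) {
  out <- tibble(
    electrode_a = as.character(electrode_a),
    electrode_b = as.character(electrode_b),
    band = as.character(band),
    gamma = as.numeric(gamma)
  )
  if (nrow(out) > 0) {
    stopifnot(all(out$gamma >= 0 & out$gamma <= 1),
              all(out$band %in% levels(band_factor("delta"))))
    pair_label(out$electrode_a, out$electrode_b) # validates labels
  }
  out
}

#' Generate a synthetic resting EEG recording
#'
#' Builds a recording over the analysis montage as a sum of per-band
#' components.  For every [coherence_spec()] row the two requested channels
#' mix a shared band-limited source with fraction `gamma` of their in-band
#' power; every other channel-band component is private noise.  Defaults
#' match the acquisition emulated throughout the package: 3 minutes at
#' 256 Hz.
#'
#' @param subject_id Identifier for the recording.
#' @param spec A [coherence_spec()] tibble.
#' @param duration Recording length in seconds (default 180).
#' @param fs Sampling rate in Hz (default 256).
#' @param lesion_side Lesion side stored on the recording (default
#'   `"right"`).
#' @param bands Band definitions used for the per-band components.
#' @param edge_guard Spectral margin in Hz at the band edges (default 1).
#'   A finite-window spectral estimate integrates roughly +/- 1 Hz around
#'   each frequency bin, so a boundary bin of the measured band sees both
#'   sides of the band edge.  To keep the gamma^2 target exact across the
#'   whole measured band, the shared-pair components are synthesized
#'   `edge_guard` Hz beyond each band edge (every measured bin then carries
#'   the shared structure), while the independent components of all other
#'   channels are kept `edge_guard` Hz inside their band (their power never
#'   reaches a measured bin of a neighbouring band).  Real rhythms are not
#'   brick-wall confined to the analysis bands either.
#' @param amplitude Per-channel standard deviation in microvolts (cosmetic;
#'   coherence is amplitude-invariant).
#' @param seed Optional integer seed.
#' @return An [eeg_recording()].
#' @export
#' @examples
#' spec <- coherence_spec("C3", "C4", "delta", gamma = sqrt(0.5))
#' rec <- generate_recording("s1", spec, duration = 20, seed = 2)
generate_recording <- function(subject_id = "sim", spec = coherence_spec(),
                               duration = 180, fs = 256,
                               lesion_side = "right", bands = coh_bands(),
                               edge_guard = 1, amplitude = 10,
                               seed = NULL) {
  chans <- analysis_electrodes()
  if (nrow(spec) > 0) {
    touched <- c(paste(spec$band, spec$electrode_a),
                 paste(spec$band, spec$electrode_b))
    if (anyDuplicated(touched)) {
      abort(paste0(
        "Conflicting coherence spec: a channel may appear in at most one ",
        "requested pair per band (",
        paste(unique(touched[duplicated(touched)]), collapse = ", "), ")."
      ))
    }
    bad <- setdiff(c(spec$electrode_a, spec$electrode_b), chans)
    if (length(bad) > 0) {
      abort(paste0("Spec uses unknown channel(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  n <- round(duration * fs)
  .with_seed_or_not(seed, {
    data <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
    for (bi in seq_len(nrow(bands))) {
      bname <- as.character(bands$band[bi])
      # shared components reach past the edges; private ones stay inside
      lo_sh <- max(bands$lo[bi] - edge_guard, 0.25)
      hi_sh <- min(bands$hi[bi] + edge_guard, fs / 2)
      lo_pr <- bands$lo[bi] + edge_guard
      hi_pr <- bands$hi[bi] - edge_guard
      comp <- matrix(0, length(chans), n)
      rows <- spec[spec$band == bname, , drop = FALSE]
      shared_chans <- c(rows$electrode_a, rows$electrode_b)
      for (ri in seq_len(nrow(rows))) {
        g <- rows$gamma[ri]
        s <- bandlimited_noise(n, fs, lo_sh, hi_sh)
        for (ch in c(rows$electrode_a[ri], rows$electrode_b[ri])) {
          comp[match(ch, chans), ] <-
            sqrt(g) * s + sqrt(1 - g) * bandlimited_noise(n, fs, lo_sh, hi_sh)
        }
      }
      for (ch in setdiff(chans, shared_chans)) {
        comp[match(ch, chans), ] <- bandlimited_noise(n, fs, lo_pr, hi_pr)
      }
      data <- data + comp
    }
    data <- data / sqrt(nrow(bands)) * amplitude
    eeg_recording(subject_id, data, chans, fs, lesion_side)
  })
}

#' Generate a synthetic cohort with a known coherence-to-outcome model
#'
#' Draws a subjects-by-features table of coherence-like predictors uniform
#' on `[0, 1]` and realizes intervention gains from the linear model
#' `delta = beta0 + sum_k beta_k f_k + eps`, with the informative features
#' placed at seeded random positions.  Gains are rounded
#' half-away-from-zero to integer FMA points and clipped so scores stay in
#' `[0, 66]`; recovery labels follow the MCID rule.  The ground truth
#' (coefficients, informative positions, noise realizations, pre-rounding
#' gains) is returned for recovery tests.
#'
#' @param n_subjects Cohort size (default 12).
#' @param n_features Number of predictors (default 20).
#' @param beta Coefficients of the informative features (default
#'   `c(12, -10, 8)`, i.e. 3 informative features whose combined signal
#'   spans a clinically plausible gain range).
#' @param beta0 Intercept in FMA points (default 2).
#' @param noise_frac Noise SD as a fraction of the signal SD (default 0.25);
#'   ignored when `sigma` is given.
#' @param sigma Absolute noise SD in FMA points (optional).
#' @param fma_t0_range Integer range to draw baseline scores from (default
#'   13-41, the span of the packaged cohort).
#' @param mcid MCID used for the recovery labels (default 4).
#' @param round_scores Round gains to integer FMA points (default `TRUE`);
#'   `FALSE` keeps the continuous linear model exactly.
#' @param informative_cols Optional fixed column indices for the informative
#'   features (default: seeded random positions).  Fixing them aligns
#'   predictors across replicate cohorts, e.g. for rank aggregation.
#' @param group Group label stored on the records.
#' @param seed Integer seed (required: cohorts are always reproducible).
#' @return List with `features` (tibble, `subject_id` + `f01`...),
#'   `clinical` (tibble with FMA scores, deltas, `recovery`), and `truth`
#'   (list: `beta0`, `beta`, `informative`, `sigma`, `eps`, `delta_raw`).
#' @export
#' @examples
#' coh <- generate_cohort(n_subjects = 12, seed = 1)
#' dplyr::count(coh$clinical, recovery)
generate_cohort <- function(n_subjects = 12, n_features = 20,
                            beta = c(12, -10, 8), beta0 = 2,
                            noise_frac = 0.25, sigma = NULL,
                            fma_t0_range = c(13, 41), mcid = 4,
                            round_scores = TRUE, informative_cols = NULL,
                            group = "NG-AO", seed) {
  stopifnot(n_features >= length(beta), n_subjects >= 4)
  if (fma_t0_range[1] < 0 || fma_t0_range[2] > 66) {
    abort("`fma_t0_range` must lie within the 0-66 FMA-UE scale.")
  }
  withr::with_seed(seed, {
    p <- n_features
    Fm <- matrix(runif(n_subjects * p), n_subjects, p)
    colnames(Fm) <- sprintf("f%02d", seq_len(p))
    pos <- if (is.null(informative_cols)) {
      sort(sample(p, length(beta)))
    } else {
      stopifnot(length(informative_cols) == length(beta),
                all(informative_cols >= 1 & informative_cols <= p))
      sort(as.integer(informative_cols))
    }
    signal <- drop(Fm[, pos, drop = FALSE] %*% beta)
    if (is.null(sigma)) sigma <- noise_frac * sd(signal)
    eps <- rnorm(n_subjects, 0, sigma)
    delta_raw <- beta0 + signal + eps
    t0 <- sample(seq(fma_t0_range[1], fma_t0_range[2]), n_subjects,
                 replace = TRUE)
    delta <- if (round_scores) .round_half_away(delta_raw) else delta_raw
    tpost <- pmin(66, pmax(0, t0 + delta))
    t6m_jitter <- rnorm(n_subjects, 0, 1)
    if (round_scores) t6m_jitter <- .round_half_away(t6m_jitter)
    t6m <- pmin(66, pmax(0, tpost + t6m_jitter))
    ids <- sprintf("sim%02d", seq_len(n_subjects))
    clinical <- tibble(
      subject_id = ids,
      group = group,
      lesion_side = sample(c("left", "right"), n_subjects, replace = TRUE),
      fma_t0 = t0, fma_tpost = tpost, fma_t6m = t6m,
      training_intensity = 1500L
    ) %>% classify_recovery(mcid = mcid)
    list(
      features = as_tibble(cbind(tibble(subject_id = ids), as.data.frame(Fm))),
      clinical = clinical,
      truth = list(
        beta0 = beta0, beta = beta, informative = colnames(Fm)[pos],
        sigma = sigma, eps = eps, delta_raw = delta_raw
      )
    )
  })
}

#' Generate a full synthetic two-arm study
#'
#' Emulates the statistical structure the pipeline consumes end-to-end: each
#' subject's six lateral electrodes (C3/FC3/CP3/C4/FC4/CP4) share one
#' delta-band source with subject-specific power fraction `gamma`, so every
#' lateral pair -- in particular the nine interhemispheric delta pairs --
#' has true coherence `gamma^2`.  In the intervention arm the gain follows
#' `delta = beta0 + beta1 * gamma^2 + eps` (negative `beta1` by default:
#' higher pre-training interhemispheric coupling, smaller gain); the default
#' intercept puts the MCID near the middle of the `gamma^2` range so both
#' recovery classes are populated, as in the cohort the generator emulates.
#' In the control arm the gain is noise around the MCID
#' (`delta = control_mean + eps_c`), emulating an arm with no
#' coherence-outcome relation and a roughly even good/poor split.
#'
#' @param n_ngao,n_nng Arm sizes (defaults 12 and 10).
#' @param duration,fs Recording length (s) and sampling rate (Hz).
#' @param beta0,beta1 Intervention-arm outcome model in FMA points (defaults
#'   7.5 and -10).
#' @param sigma Intervention-arm outcome noise SD in FMA points (default 1).
#' @param control_mean,control_sigma Control-arm gain distribution (defaults
#'   3.5 and 2).
#' @param gamma_range Range the subject `gamma` is drawn from.
#' @param seed Integer seed.
#' @return List with `recordings` (list of [eeg_recording()]), `clinical`
#'   (tibble) and `truth` (tibble with each subject's `gamma`, `gamma_sq`
#'   and pre-rounding gain).
#' @export
generate_study <- function(n_ngao = 12, n_nng = 10, duration = 180, fs = 256,
                           beta0 = 7.5, beta1 = -10, sigma = 1,
                           control_mean = 3.5, control_sigma = 2,
                           gamma_range = c(0.2, 0.95), edge_guard = 1,
                           seed = 1) {
  chans <- analysis_electrodes()
  lateral <- c("C3", "FC3", "CP3", "C4", "FC4", "CP4")
  bands <- coh_bands()
  n <- round(duration * fs)
  withr::with_seed(seed, {
    n_tot <- n_ngao + n_nng
    grp <- rep(c("NG-AO", "nNG-text"), c(n_ngao, n_nng))
    gamma <- runif(n_tot, gamma_range[1], gamma_range[2])
    eps <- ifelse(grp == "NG-AO", rnorm(n_tot, 0, sigma),
                  rnorm(n_tot, 0, control_sigma))
    delta_raw <- ifelse(
      grp == "NG-AO",
      beta0 + beta1 * gamma^2 + eps,
      control_mean + eps
    )
    side <- sample(c("left", "right"), n_tot, replace = TRUE)
    t0 <- sample(13:41, n_tot, replace = TRUE)
    delta <- .round_half_away(delta_raw)
    tpost <- pmin(66, pmax(0, t0 + delta))
    t6m <- pmin(66, pmax(0, tpost + .round_half_away(rnorm(n_tot, 0, 1))))
    ids <- sprintf("sim%02d", seq_len(n_tot))

    recordings <- purrr::map(seq_len(n_tot), function(i) {
      data <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
      for (bi in seq_len(nrow(bands))) {
        bname <- as.character(bands$band[bi])
        lo_sh <- max(bands$lo[bi] - edge_guard, 0.25)
        hi_sh <- min(bands$hi[bi] + edge_guard, fs / 2)
        lo_pr <- bands$lo[bi] + edge_guard
        hi_pr <- bands$hi[bi] - edge_guard
        comp <- matrix(0, length(chans), n)
        if (bname == "delta") {
          s <- bandlimited_noise(n, fs, lo_sh, hi_sh)
          for (ch in lateral) {
            comp[match(ch, chans), ] <- sqrt(gamma[i]) * s +
              sqrt(1 - gamma[i]) * bandlimited_noise(n, fs, lo_sh, hi_sh)
          }
          for (ch in setdiff(chans, lateral)) {
            comp[match(ch, chans), ] <- bandlimited_noise(n, fs, lo_pr, hi_pr)
          }
        } else {
          for (ch in chans) {
            comp[match(ch, chans), ] <- bandlimited_noise(n, fs, lo_pr, hi_pr)
          }
        }
        data <- data + comp
      }
      eeg_recording(ids[i], data / sqrt(nrow(bands)) * 10, chans, fs, side[i])
    })

    clinical <- tibble(
      subject_id = ids, group = grp, lesion_side = side,
      fma_t0 = t0, fma_tpost = tpost, fma_t6m = t6m,
      training_intensity = 1500L
    ) %>% classify_recovery()

    list(
      recordings = recordings,
      clinical = clinical,
      truth = tibble(subject_id = ids, group = grp, gamma = gamma,
                     gamma_sq = gamma^2, delta_raw = delta_raw)
    )
  })
}
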