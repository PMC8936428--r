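# Coherence estimation, preprocessing, lesion canonicalization and network
# aggregation.

test_that("preprocessing suppresses the notch band and passes the mu band", {
  rec50 <- make_sine_recording(50)
  out50 <- suppressMessages(eeg_preprocess(rec50))
  atten_db <- 20 * log10(central_rms(rec50$data[1, ]) /
                           central_rms(out50$data[1, ]))
  expect_gt(atten_db, 20)

  rec10 <- make_sine_recording(10)
  out10 <- suppressMessages(eeg_preprocess(rec10))
  pass_db <- 20 * log10(central_rms(rec10$data[1, ]) /
                          central_rms(out10$data[1, ]))
  expect_lt(abs(pass_db), 1)
})

test_that("preprocessing is linear in zero and rejects low sampling rates", {
  zeros <- eeg_recording("z", matrix(0, 8, 2048), analysis_electrodes(),
                         256, "right")
  expect_equal(suppressMessages(eeg_preprocess(zeros))$data,
               zeros$data, ignore_attr = TRUE)
  low <- eeg_recording("low", matrix(rnorm(8 * 1024), 8, 1024),
                       analysis_electrodes(), 100, "right")
  expect_error(eeg_preprocess(low), "Nyquist")
})

test_that("self-coherence is 1 wherever power exists", {
  x <- rnorm(256 * 20)
  msc <- msc_spectrum(x, x, fs = 256)
  expect_true(all(abs(msc$coherence - 1) < 1e-10, na.rm = TRUE))
})

test_that("msc is symmetric, bounded and rejects single segments", {
  set.seed(42)
  x <- rnorm(256 * 10)
  y <- rnorm(256 * 10)
  m1 <- msc_spectrum(x, y, fs = 256)
  m2 <- msc_spectrum(y, x, fs = 256)
  expect_equal(m1$coherence, m2$coherence, tolerance = 1e-12)
  expect_true(all(m1$coherence >= 0 & m1$coherence <= 1, na.rm = TRUE))
  expect_error(msc_spectrum(rnorm(512), rnorm(512), fs = 256), "segments")
})

test_that("independent white noise sits near the 1/nseg coherence floor", {
  set.seed(7)
  x <- rnorm(256 * 60)
  y <- rnorm(256 * 60)
  msc <- msc_spectrum(x, y, fs = 256)
  for (b in seq_len(nrow(coh_bands()))) {
    expect_lt(band_average(msc, coh_bands()$lo[b], coh_bands()$hi[b]), 0.15)
  }
})

test_that("band averaging follows the half-open bin convention", {
  spec <- tibble::tibble(freq = seq(0, 30, by = 0.5), coherence = 0.4)
  expect_equal(band_average(spec, 1, 4), 0.4)
  # half the in-band bins at 1, half at 0
  spec2 <- tibble::tibble(
    freq = seq(8, 13.5, by = 0.5),
    coherence = rep(c(1, 0), 6)
  )
  expect_equal(band_average(spec2, 8, 14), 0.5)
  # delta on a 0.5 Hz grid: bins 1.0 .. 3.5 included, 4.0 excluded
  spec3 <- tibble::tibble(freq = seq(0, 30, by = 0.5), coherence = 0)
  spec3$coherence[spec3$freq == 4] <- 1
  expect_equal(band_average(spec3, 1, 4), 0)
  spec3$coherence <- as.numeric(spec3$freq >= 1 & spec3$freq <= 3.5)
  expect_equal(band_average(spec3, 1, 4), 1)
  expect_error(band_average(spec3, 4.1, 4.4), "grid")
})

test_that("shared-source pairs recover the gamma^2 closed form", {
  spec <- coherence_spec("C3", "C4", "alpha", gamma = sqrt(0.5))
  rec <- generate_recording("g", spec, duration = 180, seed = 31)
  msc <- msc_spectrum(rec$data["C3", ], rec$data["C4", ], fs = rec$fs)
  expect_lt(abs(band_average(msc, 8, 14) - 0.5), 0.05)
})

test_that("left-lesion profiles flip across the midline, right pass through", {
  prof <- make_profile(seed = 1, lesion_side = "left")
  v <- prof$coherence[prof$pair == "C3-Cz" & prof$band == "alpha"]
  canon <- canonicalize_lesion(prof)
  expect_true(all(canon$frame == "canonical"))
  expect_equal(canon$coherence[canon$pair == "C4-Cz" & canon$band == "alpha"],
               v)
  prof_r <- make_profile(seed = 2, lesion_side = "right")
  canon_r <- canonicalize_lesion(prof_r)
  expect_equal(canon_r$coherence, prof_r$coherence)
  expect_equal(canon_r$pair, prof_r$pair)
  expect_error(canonicalize_lesion(canon_r), "raw frame")
})

test_that("the flip is an involution and preserves the value multiset", {
  for (s in 1:5) {
    prof <- make_profile(seed = s, lesion_side = "left")
    once <- canonicalize_lesion(prof)
    # flipping the canonical output again (as a raw left profile) restores it
    twice <- canonicalize_lesion(dplyr::mutate(once, frame = "raw"))
    orig <- dplyr::arrange(prof, band, pair)
    expect_equal(
      dplyr::arrange(twice, band, pair)$coherence,
      orig$coherence
    )
    expect_equal(sort(once$coherence), sort(prof$coherence))
  }
})

test_that("network aggregation averages exactly its member pairs", {
  prof <- canonicalize_lesion(make_profile(values = 0.3))
  nets <- network_aggregate(prof)
  expect_equal(nrow(nets), 20) # 5 networks x 4 bands
  expect_true(all(abs(nets$value - 0.3) < 1e-12))

  # InterHemi pairs 0.1..0.9 -> mean 0.5
  inter <- network_pairs()$pair[network_pairs()$network == "InterHemi"]
  prof2 <- make_profile(values = 0)
  idx <- prof2$band == "delta" & prof2$pair %in% inter
  prof2$coherence[idx] <- seq(0.1, 0.9, by = 0.1)
  nets2 <- network_aggregate(canonicalize_lesion(prof2))
  expect_equal(
    nets2$value[nets2$band == "delta" & nets2$network == "InterHemi"], 0.5
  )
})

test_that("network values are bounded by member pairs and order-invariant", {
  member <- network_pairs()
  for (s in 1:5) {
    prof <- canonicalize_lesion(make_profile(seed = s))
    nets <- network_aggregate(prof)
    shuffled <- network_aggregate(prof[sample(nrow(prof)), ])
    expect_equal(nets, shuffled)
    joined <- dplyr::inner_join(prof, member, by = "pair",
                                relationship = "many-to-many")
    rng <- dplyr::summarise(
      dplyr::group_by(joined, band, network),
      lo = min(coherence), hi = max(coherence), .groups = "drop"
    )
    chk <- dplyr::inner_join(nets, rng, by = c("band", "network"))
    expect_true(all(chk$value >= chk$lo - 1e-12 & chk$value <= chk$hi + 1e-12))
  }
})

test_that("network aggregation rejects raw frames and missing members", {
  prof <- make_profile(seed = 3)
  expect_error(network_aggregate(prof), "canonicalized")
  canon <- canonicalize_lesion(prof)
  expect_error(network_aggregate(canon[canon$pair != "C3-C4", ]),
               "C3-C4")
})

test_that("network definitions have the documented sizes and mirror cleanly", {
  np <- network_pairs()
  expect_equal(as.integer(table(np$network)), c(9L, 3L, 3L, 3L, 3L))
  flipped <- network_pairs("left")
  expect_setequal(
    np$pair[np$network == "IpsiLHemi"],
    flipped$pair[flipped$network == "ContraLHemi"]
  )
  expect_setequal(np$pair, flipped$pair)
  # pair labels are orientation-free
  expect_equal(pair_label("FC3", "C4"), "C4-FC3")
  expect_equal(pair_label("C4", "FC3"), "C4-FC3")
})
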