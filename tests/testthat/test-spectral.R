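# Epoch spectra, Parseval scaling, band powers, outlier rejection.

test_that("on-bin sinusoids land their full power A^2/2 in one bin", {
  A <- 12
  rec <- tone_recording(cbind(10, A), duration = 2)
  sp <- epoch_spectra(segment_epochs(rec))
  expect_equal(sp$df, 2)
  expect_identical(sp$freqs[6], 10)
  for (e in 1:4) {
    expect_equal(sp$power[e, 1, 6], A^2 / 2, tolerance = 1e-6)
    expect_lt(sum(sp$power[e, 1, -6]), 1e-12 * A^2)
  }

  ms <- mean_spectrum(sp)
  expect_equal(unname(band_power(ms, 8, 12)), A^2 / 2, tolerance = 1e-6)
  expect_lt(unname(band_power(ms, 12, 30)), 1e-12)
  expect_lt(unname(band_power(ms, 30, 45)), 1e-12)
})

test_that("mixed on-bin tones give closed-form band powers", {
  rec <- tone_recording(rbind(c(10, 10), c(20, 5)), duration = 2)
  ms <- mean_spectrum(epoch_spectra(segment_epochs(rec)))
  expect_equal(unname(band_power(ms, 8, 12)), 50, tolerance = 1e-6)
  expect_equal(unname(band_power(ms, 12, 30)), 12.5, tolerance = 1e-6)
})

test_that("bin powers satisfy Parseval's identity per epoch and channel", {
  ep <- noise_epochs(10, n_channels = 3, seed = 61)
  sp <- epoch_spectra(ep)
  for (e in 1:10) {
    for (ch in 1:3) {
      v <- mean(ep$epochs[e, ch, ]^2)
      expect_equal(sum(sp$power[e, ch, ]), v, tolerance = 1e-6)
    }
  }
  # with a Hann taper the identity refers to the tapered signal
  sph <- epoch_spectra(ep, window = "hann")
  w <- 0.5 * (1 - cos(2 * pi * (0:499) / 500))
  v <- mean((ep$epochs[1, 1, ] * w)^2)
  expect_equal(sum(sph$power[1, 1, ]), v, tolerance = 1e-6)
})

test_that("off-bin tones concentrate power in the two flanking bins", {
  rec <- tone_recording(cbind(9, 10), duration = 3)
  sp <- epoch_spectra(segment_epochs(rec))
  # brute-force DFT oracle for the first epoch
  x <- rec$samples[1, 1:500] - mean(rec$samples[1, 1:500])
  p_oracle <- Mod(fft(x)[1:251])^2 / 500^2 * c(1, rep(2, 249), 1)
  expect_equal(sp$power[1, 1, ], p_oracle, tolerance = 1e-9)
  # the Fejer kernel puts 2*(2/pi)^2 ~ 81% of a half-bin-offset tone into
  # the two flanking bins; with demeaning the observed share is ~82.6%
  frac <- sum(sp$power[1, 1, c(5, 6)]) / sum(sp$power[1, 1, ])
  expect_gt(frac, 0.80)
})

test_that("band extraction follows half-open edges and never counts DC", {
  # hand-built spectrum: bins 0,2,...,20 with power = bin index
  pw <- array(0, dim = c(1, 1, 11))
  pw[1, 1, ] <- 0:10
  ms <- mean_spectrum(make_spectrum_set(pw))
  # [8,12) sums bins 8 and 10 -> indices 5,6 -> powers 4+5
  expect_equal(unname(band_power(ms, 8, 12)), 9)
  # DC bin excluded even when the band starts at 0
  expect_equal(unname(band_power(ms, 0, 4)), 1)
  expect_hb_error(band_power(ms, 30, 45), "hoofbeat_band_error")
  expect_hb_error(band_power(ms, 12, 8), "hoofbeat_band_error")
  # disjoint band additivity
  expect_equal(band_power(ms, 2, 10) + band_power(ms, 10, 20),
               band_power(ms, 2, 20))
})

test_that("averaging spectra matches the brute-force mean", {
  pw <- array(runif(5 * 2 * 11), dim = c(5, 2, 11))
  ss <- make_spectrum_set(pw)
  ms <- mean_spectrum(ss)
  expect_equal(ms$power, apply(pw, c(2, 3), mean), ignore_attr = TRUE)
  one <- make_spectrum_set(pw[1, , , drop = FALSE])
  expect_equal(mean_spectrum(one)$power, pw[1, , ], ignore_attr = TRUE)
  # two epochs p and 3p average to 2p
  pw2 <- array(c(pw[1, , ], 3 * pw[1, , ]), dim = c(2, 2, 11))
  pw2[1, , ] <- pw[1, , ]; pw2[2, , ] <- 3 * pw[1, , ]
  expect_equal(mean_spectrum(make_spectrum_set(pw2))$power, 2 * pw[1, , ],
               ignore_attr = TRUE)
})

test_that("identical or wildly tolerant screening rejects nothing", {
  pw <- array(rep(runif(251), each = 12), dim = c(12, 1, 251))
  ss <- make_spectrum_set(pw) # spectrally identical epochs, SD = 0
  res <- reject_outlier_epochs(ss)
  expect_identical(res$report$kept_epoch_ids, 1:12)
  expect_identical(nrow(res$report$triggers), 0L)

  css <- contaminated_spectra(seed = 3)
  res2 <- reject_outlier_epochs(css, k = 1e9) # k -> infinity limit
  expect_length(res2$report$rejected_epoch_ids, 0L)

  expect_hb_error(reject_outlier_epochs(make_spectrum_set(pw[1:2, , , drop = FALSE])),
                  "hoofbeat_validation_error")
})

test_that("epochs contaminated at a single frequency are screened out", {
  ss <- contaminated_spectra(n_clean = 100, contam_ids = 1:5,
                             contam_freq = 20, factor = 10, seed = 7)
  res <- reject_outlier_epochs(ss)
  expect_true(all(1:5 %in% res$report$rejected_epoch_ids))
  clean_rejected <- setdiff(res$report$rejected_epoch_ids, 1:5)
  expect_lte(length(clean_rejected), 10)
  for (e in 1:5) { # each contaminated epoch was caught at the tampered bin
    expect_true(any(res$report$triggers$epoch == e &
                      res$report$triggers$freq_hz == 20))
  }
  expect_identical(sort(c(res$report$kept_epoch_ids,
                          res$report$rejected_epoch_ids)), 1:105)
})

test_that("rejection is invariant under epoch permutation", {
  ss <- contaminated_spectra(n_clean = 40, contam_ids = 1:3, seed = 9)
  res <- reject_outlier_epochs(ss)
  perm <- withr::with_seed(1, sample(43))
  ssp <- ss
  ssp$power <- ss$power[perm, , , drop = FALSE]
  resp <- reject_outlier_epochs(ssp)
  # rejected positions map through the permutation
  expect_setequal(perm[resp$report$rejected_epoch_ids],
                  res$report$rejected_epoch_ids)
})

test_that("screening every epoch as an outlier raises a degenerate error", {
  # 12 epochs, each carrying a x1000 excursion at its own frequency bin
  pw <- array(runif(12 * 1 * 251, 0.9, 1.1), dim = c(12, 1, 251))
  for (e in 1:12) pw[e, 1, e + 1] <- 1000
  expect_hb_error(reject_outlier_epochs(make_spectrum_set(pw)),
                  "hoofbeat_rejection_error")
})

test_that("clean band-noise epochs mostly survive default screening", {
  # regression guard against mass rejection by multiplicity: with the
  # default restricted scan and pooled log-power statistic the
  # false-rejection rate stays below 15% on stationary multi-band noise
  rates <- vapply(1:12, function(i) {
    rec <- synthesize_recording(sim_config(duration = 45, artifacts = NULL,
                                           seed = 700 + i))
    sp <- epoch_spectra(segment_epochs(rec))
    res <- reject_outlier_epochs(sp)
    length(res$report$rejected_epoch_ids) / n_epochs(sp)
  }, numeric(1))
  expect_lt(mean(rates), 0.15)
  # the raw per-channel variant scans 4x as many statistics and is far
  # more aggressive; the restricted default must stay well below it
  rec <- synthesize_recording(sim_config(duration = 45, artifacts = NULL,
                                         seed = 799))
  sp <- epoch_spectra(segment_epochs(rec))
  raw_rate <- length(reject_outlier_epochs(
    sp, pool_channels = FALSE, log_power = FALSE
  )$report$rejected_epoch_ids) / n_epochs(sp)
  def_rate <- length(reject_outlier_epochs(sp)$report$rejected_epoch_ids) /
    n_epochs(sp)
  expect_lt(def_rate, raw_rate)
})
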