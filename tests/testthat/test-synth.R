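# Synthetic band-noise generator, artifact injection, cohort calibration.

test_that("band noise hits its target RMS and keeps its power in band", {
  b <- band_spec("alpha", 8, 12, target_rms = 15)

  expect_identical(make_band_noise(band_spec("alpha", 8, 12, 0), 2, 1000, 1),
                   numeric(2000))

  x <- make_band_noise(b, duration = 60, fs = 1000, seed = 11)
  rms <- sqrt(mean(x^2))
  expect_gte(rms, 14.7)
  expect_lte(rms, 15.3)
  expect_lt(abs(mean(x)), 1e-9)

  # brute-force periodogram oracle on the generated signal
  p <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) / 60
  f_fold <- pmin(f, 1000 - f)
  in_band <- sum(p[f_fold >= 8 & f_fold < 12]) / sum(p)
  expect_gte(in_band, 0.90)

  # same for the flat (non bin-aligned) pass-band
  xf <- make_band_noise(b, 60, 1000, seed = 11, grid_df = NULL)
  pf <- Mod(fft(xf))^2
  expect_gte(sum(pf[f_fold >= 8 & f_fold < 12]) / sum(pf), 0.90)

  expect_identical(x, make_band_noise(b, 60, 1000, seed = 11))
  expect_false(identical(x, make_band_noise(b, 60, 1000, seed = 12)))

  expect_hb_error(make_band_noise(band_spec("hf", 400, 600, 5), 2, 1000, 1),
                  "hoofbeat_band_error")
  expect_hb_error(band_spec("bad", 12, 8, 5), "hoofbeat_band_error")
})

test_that("synthesized recordings are additive in power, labelled and reproducible", {
  cfg <- sim_config(duration = 60, artifacts = NULL, seed = 21)
  rec <- synthesize_recording(cfg)
  expect_s3_class(rec, "eeg_recording")
  expect_identical(rec$channel_labels, c("RO", "RF", "LO", "LF"))
  expect_equal(rec_duration(rec), 60)

  # variance of the sum of independent components ~ sum of band variances
  total_var <- mean(rec$samples[1, ]^2)
  band_var <- sum(vapply(cfg$bands, function(b) b$target_rms^2, numeric(1)))
  expect_lt(abs(total_var - band_var) / band_var, 0.05)

  expect_identical(rec$samples, synthesize_recording(cfg)$samples)

  silent <- sim_config(duration = 2, artifacts = NULL, seed = 1,
                       bands = relaxed_horse_bands(0, 0, 0, 0, 0))
  expect_true(all(synthesize_recording(silent)$samples == 0))
})

test_that("artifact injection adds seeded, annotated, high-amplitude events", {
  rec <- synthesize_recording(sim_config(duration = 60, artifacts = NULL,
                                         seed = 31))
  spec <- artifact_spec(rate = 6, duration_range = c(0.2, 0.6),
                        amplitude_range = c(200, 500))

  none <- inject_artifacts(rec, artifact_spec(rate = 0), seed = 5)
  expect_identical(none$samples, rec$samples)
  expect_identical(nrow(none$annotations), 0L)

  out <- inject_artifacts(rec, spec, seed = 5)
  out2 <- inject_artifacts(rec, spec, seed = 5)
  expect_identical(out$samples, out2$samples)
  expect_identical(out$annotations, out2$annotations)
  # the annotation count equals the seeded Poisson draw
  n_expected <- withr::with_seed(5, rpois(1, 6 * 60 / 60))
  expect_identical(nrow(out$annotations), as.integer(n_expected))
  expect_gt(nrow(out$annotations), 0L)

  # each event interval reaches well into the configured amplitude range
  for (i in seq_len(nrow(out$annotations))) {
    a <- out$annotations[i, ]
    idx <- (floor(a$onset * 1000) + 1):min(ceiling((a$onset + a$duration) * 1000), 60000)
    expect_gte(max(abs(out$samples[, idx])), 150)
  }
  # input untouched
  expect_identical(nrow(rec$annotations), 0L)
})

test_that("degenerate and infeasible cohort dispersion targets are handled", {
  cfg0 <- cohort_config(between_cv = c(alpha = 0, beta = 0, gamma = 0),
                        within_cv = c(alpha = 0, beta = 0, gamma = 0),
                        seed = 1)
  d <- cohort_design(cfg0)
  for (b in c("alpha", "beta", "gamma")) {
    expect_equal(d$truth[[b]], rep(cfg0$mean_profile[[b]], 10))
  }

  expect_hb_error(
    cohort_config(between_cv = c(alpha = 5, beta = 5, gamma = 5),
                  within_cv = c(alpha = 6, beta = 5, gamma = 5)),
    "hoofbeat_config_error")

  one <- simulate_cohort(cohort_config(n_individuals = 1, seed = 2),
                         synthesize = FALSE)
  expect_hb_error(stability_report(one$truth),
                  "hoofbeat_insufficient_data_error")
})

test_that("cohort dispersion matches its analytic calibration over replicates", {
  # Monte-Carlo over replicate cohorts, on the TRUE profiles (no signals).
  # Sample CVs are biased low by the c4 small-sample SD factor: c4(5) = 0.940
  # for the 5-horse inter CV, c4(2) = 0.798 for the 2-session intra CV.
  inter <- matrix(0, 20, 3)
  intra <- matrix(0, 20, 3)
  realized <- NULL
  for (i in 1:20) {
    sim <- simulate_cohort(cohort_config(seed = 100 + i), synthesize = FALSE)
    st <- stability_report(sim$truth)
    inter[i, ] <- st$inter_cv
    intra[i, ] <- st$intra_cv
    realized <- sim$realized_cv
  }
  expect_equal(unname(realized$intra_cv), c(6, 5, 9), tolerance = 1e-6)
  # realized inter targets are 12/6/12 inflated slightly by the PSD repair
  expect_equal(unname(realized$inter_cv), c(12, 6, 12), tolerance = 0.15)

  exp_inter <- 0.9400 * realized$inter_cv
  exp_intra <- 0.7979 * realized$intra_cv
  expect_true(all(abs(colMeans(inter) - exp_inter) < 1.5))
  expect_true(all(abs(colMeans(intra) - exp_intra) < 1.5))
  # the band-wise ordering of the reference study holds on average
  expect_true(all(colMeans(inter) > colMeans(intra)))

  # true profiles always sum to one exactly
  sums <- rowSums(simulate_cohort(cohort_config(seed = 7), synthesize = FALSE
                                  )$truth[, c("alpha", "beta", "gamma")])
  expect_equal(sums, rep(1, 10), tolerance = 1e-9)
})

test_that("cohort recordings realize their true profiles through band RMS", {
  cfg <- cohort_config(n_individuals = 2, n_sessions = 1, seed = 9,
                       base = sim_config(duration = 10, artifacts = NULL))
  sim <- simulate_cohort(cfg)
  expect_length(sim$recordings, 2)
  for (r in seq_along(sim$recordings)) {
    rec <- sim$recordings[[r]]
    tru <- sim$truth[r, ]
    expect_equal(unname(rec$meta$true_profile),
                 c(tru$alpha, tru$beta, tru$gamma))
    # per-band RMS realizes proportion * fixed total power
    expect_equal(unname(rec$meta$band_rms[c("alpha", "beta", "gamma")]^2),
                 c(tru$alpha, tru$beta, tru$gamma) * 509, tolerance = 1e-8)
  }
})
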