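# Band-profile normalization, CV statistics, stability, hemispheres.

test_that("profiles normalise the three-band powers and nothing else", {
  p <- compute_profile(c(alpha = 2, beta = 1, gamma = 1))
  expect_equal(unname(p$proportions), c(0.5, 0.25, 0.25))
  expect_equal(sum(p$proportions), 1, tolerance = 1e-12)

  p3 <- compute_profile(c(alpha = 1, beta = 1, gamma = 1))
  expect_equal(unname(p3$proportions), rep(1 / 3, 3))

  # slow bands ride along but stay out of the denominator
  p5 <- compute_profile(c(delta = 100, theta = 50, alpha = 2, beta = 1,
                          gamma = 1))
  expect_equal(unname(p5$proportions), c(0.5, 0.25, 0.25))
  expect_equal(unname(p5$power[["delta"]]), 100)

  # channels pooled by averaging power before normalizing
  m <- rbind(c(alpha = 4, beta = 2, gamma = 2),
             c(alpha = 0, beta = 2, gamma = 0))
  pm <- compute_profile(m)
  expect_equal(unname(pm$proportions), c(2, 2, 1) / 5)

  expect_hb_error(compute_profile(c(alpha = 0, beta = 0, gamma = 0)),
                  "hoofbeat_profile_error")
  expect_hb_error(compute_profile(c(alpha = 1, beta = 1)),
                  "hoofbeat_validation_error")
})

test_that("profiles are scale invariant and always sum to one", {
  for (s in 1:25) {
    pw <- withr::with_seed(s, runif(3, 0.01, 50))
    names(pw) <- c("alpha", "beta", "gamma")
    p1 <- compute_profile(pw)
    p2 <- compute_profile(pw * 37.5)
    expect_equal(p1$proportions, p2$proportions, tolerance = 1e-12)
    expect_lt(abs(sum(p1$proportions) - 1), 1e-10)
  }
})

test_that("coefficients of variation follow the sample-SD convention", {
  expect_equal(cv_percent(c(5, 5, 5)), 0)
  expect_equal(cv_percent(c(1, 2, 3)), 50) # mean 2, sample SD 1
  expect_equal(cv_percent(c(1, 2, 3) * 1e4), 50) # scale invariance
  expect_hb_error(cv_percent(3), "hoofbeat_insufficient_data_error")
  expect_hb_error(cv_percent(c(-1, 1)), "hoofbeat_cv_error")

  expect_equal(summary_cv_percent(34.38, 2.19), 100 * 2.19 / 34.38)
  expect_equal(summary_cv_percent(27.99, 1.97), 100 * 1.97 / 27.99)
  expect_equal(summary_cv_percent(42, 0), 0)
  expect_hb_error(summary_cv_percent(0, 1), "hoofbeat_cv_error")
})

test_that("stability report reproduces hand-computed CVs on a 2x2 table", {
  tab <- data.frame(
    individual = c("h1", "h1", "h2", "h2"),
    session = c("S1", "S2", "S1", "S2"),
    alpha = c(40, 44, 36, 38) / 100,
    beta = c(30, 30, 30, 30) / 100,
    gamma = c(30, 26, 34, 32) / 100
  )
  st <- stability_report(tab)
  # inter: mean over sessions of the across-individual CV
  expect_equal(unname(st$inter_cv[["alpha"]]),
               mean(c(100 * sd(c(40, 36)) / 38, 100 * sd(c(44, 38)) / 41)))
  expect_equal(unname(st$inter_cv[["alpha"]]), 8.8955, tolerance = 1e-4)
  # intra: mean over individuals of the across-session CV
  expect_equal(unname(st$intra_cv[["alpha"]]),
               mean(c(100 * sd(c(40, 44)) / 42, 100 * sd(c(36, 38)) / 37)))
  expect_equal(unname(st$inter_cv[["beta"]]), 0)

  same <- tab
  same[, c("alpha", "beta", "gamma")] <- rep(c(0.4, 0.35, 0.25), each = 4)
  st0 <- stability_report(same)
  expect_equal(unname(st0$inter_cv), c(0, 0, 0))
  expect_equal(unname(st0$intra_cv), c(0, 0, 0))

  expect_error(stability_report(tab[tab$session == "S1", ]),
               "session", class = "hoofbeat_insufficient_data_error")
  expect_error(stability_report(tab[tab$individual == "h1", ]),
               "individual", class = "hoofbeat_insufficient_data_error")
})

test_that("published day-wise summaries reproduce the published inter CVs", {
  cv <- summary_inter_cv(reference_profiles())
  # frozen from the closed-form arithmetic 100*sd/mean averaged over days
  expect_equal(unname(cv["alpha"]), 12.297, tolerance = 1e-3)
  expect_equal(unname(cv["beta"]), 5.586, tolerance = 1e-3)
  expect_equal(unname(cv["gamma"]), 12.058, tolerance = 1e-3)

  d1 <- reference_profiles()
  expect_equal(sum(d1$mean_pct[d1$day == "D1"]), 100.00, tolerance = 1e-9)
})

test_that("hemisphere comparison reports differences and a pooling verdict", {
  l <- compute_profile(c(alpha = 40, beta = 35, gamma = 25))
  expect_true(hemisphere_comparison(l, l)$pool)
  expect_equal(unname(hemisphere_comparison(l, l)$diff_pp), c(0, 0, 0))

  r <- compute_profile(c(alpha = 30, beta = 40, gamma = 30))
  h <- hemisphere_comparison(l, r, tol = 5)
  expect_equal(h$max_abs_diff, 10)
  expect_false(h$pool)
})

test_that("independent same-spec hemispheres pool in nearly all runs", {
  pools <- vapply(1:10, function(i) {
    rec <- check_montage(synthesize_recording(
      sim_config(duration = 45, artifacts = NULL, seed = 510 + i)))
    ms <- mean_spectrum(reject_outlier_epochs(
      epoch_spectra(segment_epochs(rec)))$kept)
    b <- analysis_bands(include_slow = TRUE)
    hemi <- rec$meta$hemisphere
    left <- profile_from_spectrum(ms, b, channels = names(hemi)[hemi == "left"])
    right <- profile_from_spectrum(ms, b, channels = names(hemi)[hemi == "right"])
    hemisphere_comparison(left, right)$pool
  }, logical(1))
  expect_gte(mean(pools), 0.9)
})

test_that("cohort tables validate their identifiers", {
  p <- compute_profile(c(alpha = 1, beta = 1, gamma = 1))
  expect_hb_error(cohort_table(c("a", "a"), c("S1", "S1"), list(p, p)),
                  "hoofbeat_validation_error")
  tab <- cohort_table(c("a", "a", "b", "b"), c("S1", "S2", "S1", "S2"),
                      list(p, p, p, p))
  expect_identical(nrow(tab), 4L)
  expect_equal(tab$alpha, rep(1 / 3, 4))
})
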