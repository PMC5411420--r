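# Multi-horse, multi-session cohort simulation with calibrated
# between-individual and within-individual dispersion of the band profile.
#
# Because the three profile proportions sum to one, their deviations are
# constrained to a zero-sum plane, and per-band CV targets cannot be chosen
# independently: three zero-sum deviations with SDs (s1, s2, s3) exist iff
# the SDs satisfy the triangle inequality (think of three plane vectors of
# those lengths summing to zero). The generator therefore draws profile
# deviations from degenerate ("zero-row-sum") Gaussian covariances built by
# that triangle construction, so simulated profiles sum to one EXACTLY and
# per-band dispersions hit the targets as closely as the constraints allow:
#   - session-level (within-individual) deviations: triangle covariance at
#     the within-CV targets -> intra CVs are matched exactly;
#   - individual-level deviations: the difference between the triangle
#     covariance at the between-CV targets and the session-level covariance,
#     projected to the nearest positive-semidefinite matrix (negative
#     eigenvalues clipped). The clipping slightly inflates bands whose
#     between/within gap is small; `cohort_design()` reports the analytic
#     realized CVs so the discrepancy is visible.

#' Cohort simulation configuration
#'
#' @param n_individuals number of horses (default 5).
#' @param n_sessions recording sessions per horse (default 2).
#' @param mean_profile named alpha/beta/gamma proportions of the population
#'   mean profile; positive, summing to 1. The default is the day-1 group
#'   mean profile of the reference study ([reference_profiles()]).
#' @param between_cv per-band targets (percent) for the inter-individual CV
#'   of the proportions observed within a session.
#' @param within_cv per-band targets (percent) for the intra-individual CV
#'   across sessions. Must not exceed `between_cv` band-wise (the implied
#'   individual-level variance would be negative).
#' @param base a [sim_config()] used for every synthesized recording; its
#'   alpha/beta/gamma RMS values set the total profile-band power budget,
#'   which is held fixed across recordings so the proportions are the only
#'   varying quantity.
#' @param seed master integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 5, n_sessions = 2,
                          mean_profile = c(alpha = 0.3763, beta = 0.3438,
                                           gamma = 0.2799),
                          between_cv = c(alpha = 12, beta = 6, gamma = 12),
                          within_cv = c(alpha = 6, beta = 5, gamma = 9),
                          base = sim_config(), seed = 1L) {
  bands <- c("alpha", "beta", "gamma")
  grab <- function(x, what) {
    if (is.null(names(x))) names(x) <- bands
    if (!all(bands %in% names(x))) {
      hb_stop(paste0(what, " must be named alpha/beta/gamma"),
              "hoofbeat_validation_error")
    }
    x[bands]
  }
  mean_profile <- grab(mean_profile, "mean_profile")
  between_cv <- grab(between_cv, "between_cv")
  within_cv <- grab(within_cv, "within_cv")
  if (any(mean_profile <= 0) || abs(sum(mean_profile) - 1) > 1e-8) {
    hb_stop("mean_profile entries must be positive and sum to 1",
            "hoofbeat_validation_error")
  }
  if (any(between_cv < 0) || any(within_cv < 0)) {
    hb_stop("CV targets must be non-negative", "hoofbeat_validation_error")
  }
  if (any(within_cv > between_cv)) {
    hb_stop(paste0(
      "infeasible CV targets: within_cv exceeds between_cv for band(s) ",
      paste(bands[within_cv > between_cv], collapse = ", "),
      " (implied between-individual variance is negative)"),
      "hoofbeat_config_error")
  }
  if (n_individuals < 1 || n_sessions < 1) {
    hb_stop("cohort needs at least 1 individual and 1 session",
            "hoofbeat_validation_error")
  }
  stopifnot(inherits(base, "sim_config"))
  structure(list(n_individuals = as.integer(n_individuals),
                 n_sessions = as.integer(n_sessions),
                 mean_profile = mean_profile, between_cv = between_cv,
                 within_cv = within_cv, base = base, seed = as.integer(seed)),
            class = "cohort_config")
}

# Zero-row-sum covariance with prescribed standard deviations (triangle
# construction). SDs violating the triangle inequality are clipped to the
# nearest feasible value, with a warning.
cov_zero_sum <- function(s) {
  stopifnot(length(s) == 3L, all(s >= 0))
  for (i in 1:3) {
    lim <- sum(s[-i])
    if (s[i] > lim) {
      warning(sprintf(
        "dispersion target for band %d (%.3g) exceeds the sum of the others; clipped to %.3g",
        i, s[i], lim), call. = FALSE)
      s[i] <- lim
    }
  }
  s2 <- s^2
  C <- diag(s2)
  for (i in 1:3) {
    for (j in 1:3) {
      if (i != j) C[i, j] <- (s2[6 - i - j] - s2[i] - s2[j]) / 2
    }
  }
  C
}

# Nearest PSD matrix by clipping negative eigenvalues. Preserves zero row
# sums when the input has them (the all-ones vector stays in the null space).
clip_psd <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  lam[lam < max(lam, 0) * 1e-12] <- 0 # kill numerical-noise modes
  C2 <- e$vectors %*% diag(lam, nrow = length(lam)) %*% t(e$vectors)
  (C2 + t(C2)) / 2
}

# Draw n samples from N(0, C) with possibly singular C. Numerical-noise
# eigenvalues are zeroed so degenerate directions (the all-ones vector of a
# zero-row-sum covariance) stay exactly degenerate.
rmvn_singular <- function(n, C) {
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  lam[lam < max(lam, 0) * 1e-12] <- 0
  L <- e$vectors %*% diag(sqrt(lam), nrow = nrow(C))
  t(L %*% matrix(rnorm(3L * n), nrow = 3L))
}

#' Draw a cohort design: true profiles and per-recording band amplitudes
#'
#' Samples the true (generator-level) profile of every (individual, session)
#' recording and the band RMS amplitudes that realize it, without
#' synthesizing any signal. Band power is taken proportional to the target
#' proportion with the total alpha+beta+gamma power held fixed (at the value
#' implied by `config$base`), so `rms = sqrt(proportion * total_power)`.
#'
#' @param config a [cohort_config()].
#' @return A list with `truth` (tibble: individual, session, alpha, beta,
#'   gamma true proportions, per-band `rms_*` in uV), `realized_cv`
#'   (analytic inter/intra CVs implied by the calibrated covariances, for
#'   comparison against the targets) and the covariances themselves.
#' @export
cohort_design <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  p <- config$mean_profile
  C_eps <- cov_zero_sum(p * config$within_cv / 100)
  C_tot <- cov_zero_sum(p * config$between_cv / 100)
  C_ind <- clip_psd(C_tot - C_eps)
  realized <- list(
    inter_cv = 100 * sqrt(pmax(diag(C_ind + C_eps), 0)) / p,
    intra_cv = 100 * sqrt(pmax(diag(C_eps), 0)) / p
  )

  base_rms <- vapply(config$base$bands, function(b) b$target_rms, numeric(1))
  names(base_rms) <- vapply(config$base$bands, function(b) b$name, character(1))
  total_power <- sum(base_rms[PROFILE_BANDS]^2)

  rows <- list()
  for (i in seq_len(config$n_individuals)) {
    d_i <- with_seed(derive_seed(config$seed, 10L, i),
                     drop(rmvn_singular(1L, C_ind)))
    for (j in seq_len(config$n_sessions)) {
      e_ij <- with_seed(derive_seed(config$seed, 20L, i, j),
                        drop(rmvn_singular(1L, C_eps)))
      prof <- p + d_i + e_ij
      if (any(prof <= 0)) { # extreme draws only; keep proportions valid
        prof <- pmax(prof, 0.01)
        prof <- prof / sum(prof)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        individual = sprintf("horse%02d", i), session = sprintf("S%d", j),
        alpha = prof[["alpha"]], beta = prof[["beta"]], gamma = prof[["gamma"]],
        rms_alpha = sqrt(prof[["alpha"]] * total_power),
        rms_beta = sqrt(prof[["beta"]] * total_power),
        rms_gamma = sqrt(prof[["gamma"]] * total_power)
      )
    }
  }
  list(truth = do.call(rbind, rows), realized_cv = realized,
       cov_individual = C_ind, cov_session = C_eps,
       total_power = total_power, base_rms = base_rms)
}

#' Simulate a multi-horse, multi-session cohort
#'
#' Draws a cohort design with [cohort_design()] and synthesizes one
#' recording per (individual, session), each realizing its true profile
#' through the per-band RMS amplitudes, with the artifact and noise settings
#' of `config$base`.
#'
#' @param config a [cohort_config()].
#' @param synthesize if `FALSE`, return only the design (true profiles);
#'   useful for calibration studies where no signal is needed.
#' @return A list with `truth` (see [cohort_design()]), `recordings` (a list
#'   of [recording()] objects, `NULL` if `synthesize = FALSE`, each with
#'   `meta$individual` / `meta$session` / `meta$true_profile` set) and
#'   `realized_cv`.
#' @export
simulate_cohort <- function(config, synthesize = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  design <- cohort_design(config)
  recordings <- NULL
  if (synthesize) {
    recordings <- vector("list", nrow(design$truth))
    for (r in seq_len(nrow(design$truth))) {
      row <- design$truth[r, ]
      bands <- lapply(config$base$bands, function(b) {
        if (b$name %in% PROFILE_BANDS) {
          b$target_rms <- row[[paste0("rms_", b$name)]]
        }
        b
      })
      cfg <- config$base
      cfg$bands <- bands
      cfg$seed <- derive_seed(config$seed, 30L, r)
      rec <- synthesize_recording(cfg)
      rec$meta$individual <- row$individual
      rec$meta$session <- row$session
      rec$meta$true_profile <- c(alpha = row$alpha, beta = row$beta,
                                 gamma = row$gamma)
      recordings[[r]] <- rec
    }
  }
  list(truth = design$truth, recordings = recordings,
       realized_cv = design$realized_cv)
}
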