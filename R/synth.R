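# Synthetic ambulatory horse EEG.
#
# Recordings are built as sums of independent band-limited Gaussian noise
# components, one per classical EEG band, each rescaled to an exact target
# RMS amplitude, plus optional 50 Hz mains contamination and transient
# high-amplitude movement artifacts. Every random stream is derived from a
# single master seed so any channel/band component is reproducible on its own.

#' Specification of one band-limited noise component
#'
#' @param name band label (conventionally one of delta, theta, alpha, beta,
#'   gamma, but any unique label is accepted).
#' @param f_lo,f_hi band edges in Hz, half-open `[f_lo, f_hi)`.
#' @param target_rms target root-mean-square amplitude in microvolts.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("alpha", 8, 12, target_rms = 14)
#' @export
band_spec <- function(name, f_lo, f_hi, target_rms) {
  if (!is_scalar_number(f_lo) || !is_scalar_number(f_hi) ||
      f_lo < 0 || f_hi <= f_lo) {
    hb_stop("band edges must satisfy 0 <= f_lo < f_hi", "hoofbeat_band_error")
  }
  if (!is_scalar_number(target_rms) || target_rms < 0) {
    hb_stop("target_rms must be a non-negative number", "hoofbeat_band_error")
  }
  structure(list(name = as.character(name), f_lo = f_lo, f_hi = f_hi,
                 target_rms = target_rms),
            class = "band_spec")
}

#' Default band composition of a relaxed standing horse
#'
#' Five bands with the amplitudes the simulator takes as its reference
#' state: low-amplitude delta (0.5-4 Hz) and theta (4-8 Hz) background under
#' 10 uV RMS, and dominant alpha (8-12 Hz), beta (12-30 Hz) and gamma
#' (30-45 Hz) components. The gamma synthesis range stops at 45 Hz to stay
#' clear of 50 Hz mains.
#'
#' @param alpha,beta,gamma,delta,theta per-band RMS amplitudes in microvolts.
#' @return A list of [band_spec()] objects.
#' @export
relaxed_horse_bands <- function(alpha = 14, beta = 13, gamma = 12,
                                delta = 4, theta = 5) {
  list(band_spec("delta", 0.5, 4, delta),
       band_spec("theta", 4, 8, theta),
       band_spec("alpha", 8, 12, alpha),
       band_spec("beta", 12, 30, beta),
       band_spec("gamma", 30, 45, gamma))
}

#' Band-limited Gaussian noise at an exact RMS amplitude
#'
#' White Gaussian noise is band-pass filtered with a zero-phase brick-wall
#' filter in the frequency domain and rescaled so the empirical RMS equals
#' `target_rms` exactly. All spectral power of the result lies inside
#' `[f_lo, f_hi)`.
#'
#' By default the pass-band is *bin aligned*: the union of lines of width
#' `line_frac * grid_df` centred on the multiples of `grid_df` (the
#' frequency grid of the downstream 500 ms epoch analysis, 2 Hz) that fall
#' inside the band, clipped to the band edges. Power placed this way is
#' recovered almost losslessly by short-epoch periodograms, so the
#' generator's band fractions are an unbiased target for pipeline-recovery
#' tests. With `grid_df = NULL` the pass-band is the full flat interval
#' `[f_lo, f_hi)`; short epochs of such a signal lose a substantial,
#' width-dependent share of each band's power to neighbouring bins through
#' spectral leakage (see the package vignette).
#'
#' @param band a [band_spec()].
#' @param duration signal length in seconds.
#' @param fs sampling rate in Hz; `f_hi` must not exceed the Nyquist
#'   frequency `fs / 2`.
#' @param seed integer seed for the noise stream.
#' @param grid_df analysis frequency-grid spacing in Hz (default 2, the
#'   resolution of 500 ms epochs), or `NULL` for a flat pass-band.
#' @param line_frac width of each spectral line as a fraction of `grid_df`.
#' @return Numeric vector of `duration * fs` samples in microvolts.
#' @examples
#' x <- make_band_noise(band_spec("alpha", 8, 12, 15), duration = 2,
#'                      fs = 1000, seed = 1)
#' sqrt(mean(x^2)) # == 15
#' @export
make_band_noise <- function(band, duration, fs, seed, grid_df = 2,
                            line_frac = 0.5) {
  stopifnot(inherits(band, "band_spec"))
  if (band$f_hi > fs / 2 + 1e-9) {
    hb_stop(sprintf("band upper edge %g Hz exceeds Nyquist %g Hz",
                    band$f_hi, fs / 2), "hoofbeat_band_error")
  }
  n <- round(duration * fs)
  if (n < 2L) hb_stop("duration too short", "hoofbeat_validation_error")
  if (band$target_rms == 0) return(numeric(n))
  with_seed(seed, {
    z <- fft(rnorm(n))
    f_pos <- (seq_len(n) - 1L) / duration        # 0, 1/T, ..., (n-1)/T
    f_alias <- pmin(f_pos, n / duration - f_pos) # folded frequency of each bin
    keep <- f_alias >= band$f_lo & f_alias < band$f_hi
    if (!is.null(grid_df)) {
      centres <- seq(ceiling(band$f_lo / grid_df),
                     ceiling(band$f_hi / grid_df) - 1L) * grid_df
      centres <- centres[centres > 0]
      if (length(centres) > 0L) {
        half <- line_frac * grid_df / 2
        near <- Reduce(`|`, lapply(centres, function(fc) abs(f_alias - fc) < half))
        keep <- keep & near
      } # else: no grid point in band, fall back to the flat pass-band
    }
    z[!keep] <- 0
    x <- Re(fft(z, inverse = TRUE)) / n
    rms <- sqrt(mean(x^2))
    if (rms == 0) {
      hb_stop(sprintf("band [%g, %g) Hz contains no frequency bin at this duration",
                      band$f_lo, band$f_hi), "hoofbeat_band_error")
    }
    x * band$target_rms / rms
  })
}

#' Specification of transient movement artifacts
#'
#' Models the large transients that body, head and ear movements stamp onto
#' ambulatory recordings: events arrive at a Poisson rate and each adds the
#' same high-amplitude waveform to every channel.
#'
#' @param rate expected events per minute.
#' @param duration_range ordered pair, event duration bounds in seconds.
#' @param amplitude_range ordered pair, peak amplitude bounds in microvolts.
#' @param shape waveform: `"burst"` (raised cosine, default), `"step"`, or
#'   `"ramp"`.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(rate = 5, duration_range = c(0.2, 0.8),
                          amplitude_range = c(200, 500),
                          shape = c("burst", "step", "ramp")) {
  shape <- match.arg(shape)
  ok_pair <- function(p) length(p) == 2L && all(is.finite(p)) && all(p > 0) && p[1] <= p[2]
  if (!is_scalar_number(rate) || rate < 0) {
    hb_stop("artifact rate must be >= 0", "hoofbeat_validation_error")
  }
  if (!ok_pair(duration_range) || !ok_pair(amplitude_range)) {
    hb_stop("duration_range and amplitude_range must be positive ordered pairs",
            "hoofbeat_validation_error")
  }
  structure(list(rate = rate, duration_range = duration_range,
                 amplitude_range = amplitude_range, shape = shape),
            class = "artifact_spec")
}

#' Simulation configuration for a single recording
#'
#' @param fs sampling rate in Hz (1000 by default, matching the telemetric
#'   acquisition the simulator emulates).
#' @param duration recording length in seconds. The 50 s default is sized so
#'   that, after artifact masking at the default artifact rate, a session
#'   yields on the order of 86 usable 500 ms epochs.
#' @param n_channels number of channels.
#' @param channel_labels channel labels; default `RO, RF, LO, LF`.
#' @param bands list of [band_spec()] components, default
#'   [relaxed_horse_bands()].
#' @param artifacts an [artifact_spec()], or `NULL` for a clean recording.
#' @param line_noise_rms RMS amplitude in microvolts of an additive 50 Hz
#'   mains sinusoid (0 = none).
#' @param seed master integer seed; fixing it makes the output bit-for-bit
#'   reproducible.
#' @param grid_df,line_frac band-noise synthesis grid, see
#'   [make_band_noise()]; set `grid_df = NULL` for flat pass-bands.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs = 1000, duration = 50, n_channels = 4,
                       channel_labels = c("RO", "RF", "LO", "LF"),
                       bands = relaxed_horse_bands(),
                       artifacts = artifact_spec(),
                       line_noise_rms = 0, seed = 1L,
                       grid_df = 2, line_frac = 0.5) {
  if (!is_scalar_number(duration) || duration <= 0) {
    hb_stop("duration must be positive", "hoofbeat_validation_error")
  }
  if (length(channel_labels) != n_channels) {
    channel_labels <- if (n_channels <= 4) {
      c("RO", "RF", "LO", "LF")[seq_len(n_channels)]
    } else {
      paste0("ch", seq_len(n_channels))
    }
  }
  nm <- vapply(bands, function(b) b$name, character(1))
  if (anyDuplicated(nm)) {
    hb_stop("band names must be unique within a configuration",
            "hoofbeat_validation_error")
  }
  f_hi_max <- max(vapply(bands, function(b) b$f_hi, numeric(1)))
  if (fs <= 2 * f_hi_max - 1e-9) {
    hb_stop(sprintf("fs = %g Hz cannot represent bands up to %g Hz", fs, f_hi_max),
            "hoofbeat_validation_error")
  }
  if (!is.null(artifacts)) stopifnot(inherits(artifacts, "artifact_spec"))
  structure(list(fs = fs, duration = duration, n_channels = n_channels,
                 channel_labels = channel_labels, bands = bands,
                 artifacts = artifacts, line_noise_rms = line_noise_rms,
                 seed = as.integer(seed), grid_df = grid_df,
                 line_frac = line_frac),
            class = "sim_config")
}

#' Synthesize a multi-channel EEG recording
#'
#' Each channel is the sum of independent band-noise components (one RNG
#' stream per channel x band, derived from the master seed), an optional
#' 50 Hz mains sinusoid, and - if `config$artifacts` is set - injected
#' movement artifacts with their intervals annotated.
#'
#' @param config a [sim_config()].
#' @return An [recording()] object; `meta$band_rms` records the per-band RMS
#'   targets used.
#' @export
synthesize_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- round(config$duration * config$fs)
  samples <- matrix(0, nrow = config$n_channels, ncol = n)
  for (ch in seq_len(config$n_channels)) {
    x <- numeric(n)
    for (bi in seq_along(config$bands)) {
      b <- config$bands[[bi]]
      if (b$target_rms > 0) {
        x <- x + make_band_noise(b, config$duration, config$fs,
                                 seed = derive_seed(config$seed, 1L, ch, bi),
                                 grid_df = config$grid_df,
                                 line_frac = config$line_frac)
      }
    }
    if (config$line_noise_rms > 0) {
      phase <- with_seed(derive_seed(config$seed, 2L, ch), runif(1, 0, 2 * pi))
      tt <- (seq_len(n) - 1L) / config$fs
      x <- x + config$line_noise_rms * sqrt(2) * sin(2 * pi * 50 * tt + phase)
    }
    samples[ch, ] <- x
  }
  rms <- vapply(config$bands, function(b) b$target_rms, numeric(1))
  names(rms) <- vapply(config$bands, function(b) b$name, character(1))
  rec <- recording(samples, fs = config$fs,
                   channel_labels = config$channel_labels,
                   meta = list(band_rms = rms, seed = config$seed))
  if (!is.null(config$artifacts) && config$artifacts$rate > 0) {
    rec <- inject_artifacts(rec, config$artifacts,
                            seed = derive_seed(config$seed, 3L))
  }
  rec
}

#' Inject transient movement artifacts into a recording
#'
#' Adds seeded high-amplitude transients to all channels and appends one
#' annotation per event. The number of events is a Poisson draw with mean
#' `rate * duration / 60`.
#'
#' @inheritParams rec_duration
#' @param spec an [artifact_spec()].
#' @param seed integer seed for the event stream.
#' @return A modified copy of `rec`; the input is left untouched.
#' @export
inject_artifacts <- function(rec, spec, seed) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "artifact_spec"))
  dur <- rec_duration(rec)
  if (spec$rate == 0) return(rec)
  with_seed(seed, {
    n_ev <- rpois(1L, spec$rate * dur / 60)
    if (n_ev == 0L) return(rec)
    ev_dur <- runif(n_ev, spec$duration_range[1], spec$duration_range[2])
    ev_dur <- pmin(ev_dur, dur)
    onset <- runif(n_ev, 0, pmax(dur - ev_dur, 0))
    amp <- runif(n_ev, spec$amplitude_range[1], spec$amplitude_range[2])
    sign <- sample(c(-1, 1), n_ev, replace = TRUE)
    out <- rec
    for (e in seq_len(n_ev)) {
      i0 <- floor(onset[e] * rec$fs) + 1L
      len <- max(round(ev_dur[e] * rec$fs), 2L)
      i1 <- min(i0 + len - 1L, ncol(rec$samples))
      u <- seq(0, 1, length.out = i1 - i0 + 1L)
      wave <- switch(spec$shape,
        burst = 0.5 * (1 - cos(2 * pi * u)),
        step = rep(1, length(u)),
        ramp = u
      )
      out$samples[, i0:i1] <- out$samples[, i0:i1] +
        rep(sign[e] * amp[e] * wave, each = nrow(out$samples))
    }
    out$annotations <- rbind(
      out$annotations,
      data.frame(onset = onset, duration = ev_dur, label = "artifact",
                 stringsAsFactors = FALSE)
    )
    out$annotations <- out$annotations[order(out$annotations$onset), , drop = FALSE]
    rownames(out$annotations) <- NULL
    out
  })
}
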