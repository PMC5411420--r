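# Shared fixture builders. Everything is generated in code; no binary files.

# A recording holding pure sinusoids: one per row of `tones`
# (columns: freq_hz, amplitude_uv), identical on every channel.
tone_recording <- function(tones, duration = 2, fs = 1000, n_channels = 1,
                           labels = c("RO", "RF", "LO", "LF")[seq_len(n_channels)]) {
  tt <- (seq_len(duration * fs) - 1) / fs
  x <- rowSums(vapply(seq_len(nrow(tones)),
                      function(i) tones[i, 2] * sin(2 * pi * tones[i, 1] * tt),
                      numeric(length(tt))))
  recording(matrix(rep(x, each = n_channels), nrow = n_channels),
            fs = fs, channel_labels = labels)
}

# Epochs of white noise with a given per-channel SD.
noise_epochs <- function(n_epochs, n_channels = 1, spe = 500, fs = 1000,
                         sd = 10, seed = 1) {
  withr::with_seed(seed, {
    arr <- array(rnorm(n_epochs * n_channels * spe, sd = sd),
                 dim = c(n_epochs, n_channels, spe))
  })
  for (e in seq_len(n_epochs)) {
    for (ch in seq_len(n_channels)) {
      arr[e, ch, ] <- arr[e, ch, ] - mean(arr[e, ch, ])
    }
  }
  structure(list(epochs = arr, epoch_len = spe / fs,
                 start_times = (seq_len(n_epochs) - 1) * spe / fs, fs = fs,
                 channel_labels = paste0("ch", seq_len(n_channels))),
            class = "epoch_set")
}

# Hand-built spectrum_set with given power array (epochs x channels x bins).
make_spectrum_set <- function(power, df = 2) {
  structure(list(power = power,
                 freqs = (seq_len(dim(power)[3]) - 1) * df,
                 df = df, fs = 2 * df * (dim(power)[3] - 1),
                 window = "rectangular",
                 channel_labels = paste0("ch", seq_len(dim(power)[2]))),
            class = "spectrum_set")
}

# Clean spectra with bounded multiplicative variability plus `contam_ids`
# epochs whose power at `contam_bin` is multiplied by `factor` on all
# channels: the scenario the outlier-rejection rule must resolve.
contaminated_spectra <- function(n_clean = 100, contam_ids = 1:5,
                                 n_channels = 4, n_bins = 251,
                                 contam_freq = 20, factor = 10, seed = 1) {
  n <- n_clean + length(contam_ids)
  base <- 50 / (1 + (seq_len(n_bins) - 1)) # smooth 1/f-like base spectrum
  withr::with_seed(seed, {
    power <- array(rep(base, each = n * n_channels) *
                     runif(n * n_channels * n_bins, 0.8, 1.2),
                   dim = c(n, n_channels, n_bins))
  })
  bin <- contam_freq / 2 + 1
  power[contam_ids, , bin] <- power[contam_ids, , bin] * factor
  make_spectrum_set(power)
}

# Band RMS targets realizing given alpha/beta/gamma power fractions at a
# fixed total profile-band power (uV^2).
rms_for_fractions <- function(fractions, total_power = 509) {
  sqrt(fractions * total_power)
}

expect_hb_error <- function(expr, class) {
  expect_error(expr, class = class)
}
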