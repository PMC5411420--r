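# Artifact masking and segmentation into fixed-length epochs.
#
# Visual artifact screening is replaced by a reproducible automated
# surrogate: samples whose amplitude or sample-to-sample gradient exceeds a
# threshold on any channel are masked, the flagged intervals are padded and
# merged, and epochs are tiled over the remaining clean runs.

#' Detect high-amplitude / high-gradient artifact intervals
#'
#' Flags every sample where `|x| > amp_thresh` or `|x[t] - x[t-1]| >
#' grad_thresh` on any channel, pads each flagged run by `pad` seconds on
#' both sides, and merges overlapping intervals.
#'
#' @inheritParams rec_duration
#' @param amp_thresh amplitude threshold in microvolts.
#' @param grad_thresh gradient threshold in microvolts per sample.
#' @param pad padding added to each side of a flagged interval, in seconds.
#' @return An object of class `artifact_mask`: a list with `intervals`
#'   (two-column matrix of half-open `[start, end)` times in seconds) and
#'   `source = "amplitude+gradient"`.
#' @export
detect_artifacts <- function(rec, amp_thresh = 100, grad_thresh = 50,
                             pad = 0.25) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (amp_thresh <= 0 || grad_thresh <= 0 || pad < 0) {
    hb_stop("thresholds must be positive and pad non-negative",
            "hoofbeat_validation_error")
  }
  x <- rec$samples
  bad <- colSums(abs(x) > amp_thresh) > 0
  if (ncol(x) > 1L) {
    grad_bad <- colSums(abs(x[, -1L, drop = FALSE] -
                            x[, -ncol(x), drop = FALSE]) > grad_thresh) > 0
    bad[-1L] <- bad[-1L] | grad_bad
  }
  iv <- runs_to_intervals(bad, rec$fs)
  iv <- merge_intervals(iv, pad = pad, lo = 0, hi = rec_duration(rec))
  structure(list(intervals = iv, source = "amplitude+gradient",
                 amp_thresh = amp_thresh, grad_thresh = grad_thresh, pad = pad),
            class = "artifact_mask")
}

#' Build an artifact mask from a recording's annotations
#'
#' Uses annotated intervals (e.g. the ground-truth artifact events written by
#' the simulator, or manual markings imported from an EDF+ file) instead of
#' thresholding.
#'
#' @inheritParams detect_artifacts
#' @param labels annotation labels to mask; default `"artifact"`.
#' @return An `artifact_mask` with `source = "annotation"`.
#' @export
mask_from_annotations <- function(rec, labels = "artifact", pad = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  ann <- rec$annotations[rec$annotations$label %in% labels, , drop = FALSE]
  iv <- merge_intervals(cbind(ann$onset, ann$onset + ann$duration),
                        pad = pad, lo = 0, hi = rec_duration(rec))
  structure(list(intervals = iv, source = "annotation", pad = pad),
            class = "artifact_mask")
}

# boolean sample flags -> half-open [start, end) second intervals; a flagged
# sample i occupies [i/fs, (i+1)/fs) with 0-based i
runs_to_intervals <- function(flag, fs) {
  if (!any(flag)) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = (starts[keep] - 1L) / fs, end = ends[keep] / fs)
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d interval(s), source: %s\n",
              nrow(x$intervals), x$source))
  invisible(x)
}

#' Export an artifact mask as a plain-text interval table
#'
#' @param mask an `artifact_mask`.
#' @param path output path; the file is tab-separated with `start` and `end`
#'   columns in seconds.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "artifact_mask"))
  df <- as.data.frame(mask$intervals)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Segment a recording into fixed-length epochs
#'
#' Tiles consecutive, non-overlapping epochs over every unmasked run of the
#' recording; partial tail segments are discarded, so the epoch count equals
#' `sum(floor(run_length / epoch_len))` over clean runs. The per-channel mean
#' (DC offset) is removed from each epoch.
#'
#' @inheritParams rec_duration
#' @param mask an `artifact_mask`, or `NULL` to use the whole recording.
#' @param epoch_len epoch length in seconds (default 0.5); `epoch_len * fs`
#'   must be an integer.
#' @return An object of class `epoch_set`: epochs as an
#'   `n_epochs x channels x samples_per_epoch` array in microvolts, plus
#'   `start_times` (seconds), `fs`, `epoch_len` and `channel_labels`.
#' @export
segment_epochs <- function(rec, mask = NULL, epoch_len = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- epoch_len * rec$fs
  if (abs(spe - round(spe)) > 1e-9) {
    hb_stop("epoch_len * fs must be an integer number of samples",
            "hoofbeat_validation_error")
  }
  spe <- as.integer(round(spe))
  n <- ncol(rec$samples)

  masked <- rep(FALSE, n)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "artifact_mask"))
    if (nrow(mask$intervals) > 0L) {
      for (i in seq_len(nrow(mask$intervals))) {
        a <- max(floor(mask$intervals[i, 1] * rec$fs) + 1L, 1L)
        b <- min(ceiling(mask$intervals[i, 2] * rec$fs), n)
        if (b >= a) masked[a:b] <- TRUE
      }
    }
  }

  r <- rle(masked)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  starts <- integer(0)
  for (k in which(!r$values)) {
    n_ep <- (run_end[k] - run_start[k] + 1L) %/% spe
    if (n_ep > 0L) {
      starts <- c(starts, run_start[k] + (seq_len(n_ep) - 1L) * spe)
    }
  }
  if (length(starts) == 0L) {
    hb_stop("no unmasked run is at least one epoch long", "hoofbeat_empty_error")
  }

  nch <- n_channels(rec)
  epochs <- array(0, dim = c(length(starts), nch, spe))
  for (e in seq_along(starts)) {
    seg <- rec$samples[, starts[e]:(starts[e] + spe - 1L), drop = FALSE]
    epochs[e, , ] <- seg - rowMeans(seg)
  }
  structure(list(epochs = epochs, epoch_len = epoch_len,
                 start_times = (starts - 1L) / rec$fs, fs = rec$fs,
                 channel_labels = rec$channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epoch(s) x %d channel(s) x %d samples (%.3g s @ %g Hz)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$epoch_len, x$fs))
  invisible(x)
}

#' Number of epochs in an epoch set or spectrum set
#' @param x an `epoch_set` or `spectrum_set`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(x) {
  if (inherits(x, "epoch_set")) return(dim(x$epochs)[1])
  if (inherits(x, "spectrum_set")) return(dim(x$power)[1])
  hb_stop("n_epochs() expects an epoch_set or spectrum_set",
          "hoofbeat_validation_error")
}
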