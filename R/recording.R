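#' Multi-channel EEG recording
#'
#' The central container of the package: a channels-by-time matrix of EEG
#' samples in microvolts, with a sampling rate, ordered channel labels,
#' annotated intervals (e.g. movement artifacts) and free-form metadata
#' (subject and session identifiers, simulation ground truth, ...).
#'
#' Time is measured in seconds from recording start; annotated intervals are
#' half-open, `[onset, onset + duration)`.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `samples`.
#'   Defaults to `rownames(samples)`.
#' @param annotations data frame with columns `onset`, `duration` (seconds)
#'   and `label`, or `NULL` for none.
#' @param meta named list of free-form metadata.
#'
#' @return An object of class `eeg_recording`.
#' @examples
#' x <- matrix(rnorm(2000), nrow = 2,
#'             dimnames = list(c("RO", "LO"), NULL))
#' rec <- recording(x, fs = 1000)
#' rec_duration(rec)
#' @export
recording <- function(samples, fs, channel_labels = rownames(samples),
                      annotations = NULL, meta = list()) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    hb_stop("`samples` must be a numeric channels x time matrix", "hoofbeat_validation_error")
  }
  if (!all(is.finite(samples))) {
    hb_stop("recording samples must all be finite", "hoofbeat_validation_error")
  }
  if (!is_scalar_number(fs) || fs <= 0) {
    hb_stop("`fs` must be a single positive number (Hz)", "hoofbeat_validation_error")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples)) {
    hb_stop("number of channel labels must equal the number of channels",
            "hoofbeat_validation_error")
  }
  annotations <- as_annotations(annotations)
  dur <- ncol(samples) / fs
  if (nrow(annotations) > 0L) {
    if (any(annotations$onset < 0) || any(annotations$duration < 0) ||
        any(annotations$onset + annotations$duration > dur + 1e-9)) {
      hb_stop("annotation intervals must lie within [0, duration]",
              "hoofbeat_validation_error")
    }
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         annotations = annotations, meta = meta),
    class = "eeg_recording"
  )
}

as_annotations <- function(x) {
  if (is.null(x)) {
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  if (!is.data.frame(x) || !all(c("onset", "duration", "label") %in% names(x))) {
    hb_stop("`annotations` must be a data frame with onset, duration, label",
            "hoofbeat_validation_error")
  }
  data.frame(onset = as.numeric(x$onset), duration = as.numeric(x$duration),
             label = as.character(x$label), stringsAsFactors = FALSE)
}

#' Recording duration in seconds
#' @param rec an [recording()] object.
#' @return Length of the recording in seconds.
#' @export
rec_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$samples) / rec$fs
}

#' Number of channels in a recording
#' @inheritParams rec_duration
#' @return Integer channel count.
#' @export
n_channels <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  nrow(rec$samples)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) [%s], %.3f s @ %g Hz, %d annotation(s)\n",
              n_channels(x), paste(x$channel_labels, collapse = ", "),
              rec_duration(x), x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Electrode montage
#'
#' Describes the electrode set the pipeline expects and the hemisphere each
#' electrode records from. The default montage is the four-channel equine
#' forehead layout: right occipital (RO), right frontal (RF), left occipital
#' (LO) and left frontal (LF).
#'
#' @param required_labels ordered character vector of electrode labels.
#' @param hemisphere_map named character vector mapping each required label
#'   to `"left"` or `"right"`.
#' @return An object of class `eeg_montage`.
#' @examples
#' default_montage()
#' @export
montage <- function(required_labels = c("RO", "RF", "LO", "LF"),
                    hemisphere_map = c(RO = "right", RF = "right",
                                       LO = "left", LF = "left")) {
  required_labels <- as.character(required_labels)
  if (anyDuplicated(required_labels)) {
    hb_stop("montage labels must be unique", "hoofbeat_validation_error")
  }
  if (!all(required_labels %in% names(hemisphere_map))) {
    hb_stop("every required label must be mapped to a hemisphere",
            "hoofbeat_validation_error")
  }
  if (!all(hemisphere_map %in% c("left", "right"))) {
    hb_stop("hemispheres must be 'left' or 'right'", "hoofbeat_validation_error")
  }
  structure(list(required_labels = required_labels,
                 hemisphere_map = hemisphere_map[required_labels]),
            class = "eeg_montage")
}

#' @rdname montage
#' @export
default_montage <- function() montage()

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage>", paste(sprintf("%s(%s)", x$required_labels,
                                     substr(x$hemisphere_map, 1, 1)),
                             collapse = " "), "\n")
  invisible(x)
}

#' Check a recording against a montage and reorder its channels
#'
#' Verifies that every montage electrode is present, reorders the channels to
#' montage order, drops channels outside the montage (with a notice), and
#' attaches the hemisphere assignment used downstream for hemisphere
#' comparison and pooling.
#'
#' @inheritParams rec_duration
#' @param mont an [montage()] object.
#' @return The recording restricted to montage channels, in montage order,
#'   with `meta$hemisphere` set to the per-channel hemisphere vector.
#' @export
check_montage <- function(rec, mont = default_montage()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(mont, "eeg_montage"))
  missing <- setdiff(mont$required_labels, rec$channel_labels)
  if (length(missing) > 0L) {
    hb_stop(paste0("recording is missing required montage channel(s): ",
                   paste(missing, collapse = ", ")),
            "hoofbeat_montage_error")
  }
  extra <- setdiff(rec$channel_labels, mont$required_labels)
  if (length(extra) > 0L) {
    message("check_montage: dropping non-montage channel(s): ",
            paste(extra, collapse = ", "))
  }
  idx <- match(mont$required_labels, rec$channel_labels)
  out <- rec
  out$samples <- rec$samples[idx, , drop = FALSE]
  out$channel_labels <- mont$required_labels
  out$meta$hemisphere <- unname(mont$hemisphere_map)
  names(out$meta$hemisphere) <- mont$required_labels
  out
}
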