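# EDF/EDF+ input and output.
#
# The whole pipeline operates in microvolts; these functions convert between
# physical microvolt values and the 16-bit digital samples EDF stores, using
# the header's physical/digital range fields. Annotations travel on a
# standard "EDF Annotations" channel (EDF+C, continuous layout), encoded as
# time-stamped annotation lists (TALs).

EDF_ANN_LABEL <- "EDF Annotations"

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) {
    hb_stop(sprintf("EDF header field too wide (%d > %d): '%s'",
                    nchar(x, type = "bytes"), width, x),
            "hoofbeat_io_error")
  }
  formatC(x, width = width, flag = "-")
}

fmt_num <- function(x, width = 8) {
  for (digits in 7:1) {
    s <- formatC(x, digits = digits, format = "g", width = 1)
    if (nchar(s) <= width) return(s)
  }
  hb_stop(sprintf("cannot format %g into %d EDF header bytes", x, width),
          "hoofbeat_io_error")
}

#' Write a recording to an EDF+ file
#'
#' Writes a standards-conformant continuous EDF+ (EDF+C) file with the
#' physical dimension set to microvolts and any annotations carried on an
#' `EDF Annotations` channel. Samples are quantised to 16 bits over a
#' symmetric physical range; the worst-case round-trip error is
#' `phys_range / 32767`.
#'
#' @inheritParams rec_duration
#' @param path output file path.
#' @param phys_range symmetric physical range in microvolts (samples must lie
#'   in `[-phys_range, phys_range]`). The default chooses the smallest range
#'   covering the observed amplitudes. Samples exceeding an explicit range
#'   raise a range error rather than being clipped.
#' @param record_duration EDF data-record length in seconds; the recording
#'   duration must be an integer multiple of it.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path, phys_range = NULL, record_duration = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_samp <- ncol(rec$samples)
  if (n_samp == 0L) {
    hb_stop("cannot write a zero-length recording", "hoofbeat_validation_error")
  }
  spr <- rec$fs * record_duration # samples per data record
  if (abs(spr - round(spr)) > 1e-9) {
    hb_stop("fs * record_duration must be an integer", "hoofbeat_validation_error")
  }
  spr <- as.integer(round(spr))
  n_rec <- n_samp / spr
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    hb_stop(sprintf(
      "recording length (%d samples) is not a whole number of %g s data records",
      n_samp, record_duration), "hoofbeat_validation_error")
  }
  n_rec <- as.integer(round(n_rec))

  max_abs <- max(abs(rec$samples))
  if (is.null(phys_range)) {
    phys_range <- max(ceiling(max_abs * 1.01), 1)
  } else if (max_abs > phys_range) {
    hb_stop(sprintf(
      "samples reach %.4g uV, outside the representable range [-%g, %g] uV",
      max_abs, phys_range, phys_range), "hoofbeat_range_error")
  }

  nch <- n_channels(rec)
  # digital mapping is the inverse of the reader's affine transform, so the
  # round-trip error is bounded by half a quantization step
  dig <- round((rec$samples + phys_range) / (2 * phys_range) * 65535) - 32768
  storage.mode(dig) <- "integer"

  # annotation TALs, one block per data record; each record starts with the
  # mandatory time-keeping TAL, then the annotations whose onset falls in it
  ann <- rec$annotations
  tal_num <- function(x) {
    s <- sprintf("%.7g", x)
    if (substr(s, 1, 1) != "-") s <- paste0("+", s)
    s
  }
  rec_tals <- lapply(seq_len(n_rec) - 1L, function(r) {
    t0 <- r * record_duration
    tals <- paste0(tal_num(t0), "\x14\x14") # mandatory time-keeping TAL
    if (nrow(ann) > 0L) {
      in_rec <- which(ann$onset >= t0 & ann$onset < t0 + record_duration)
      if (r == n_rec - 1L) { # catch boundary onsets at exactly the end
        in_rec <- union(in_rec, which(ann$onset >= t0 + record_duration))
      }
      for (i in in_rec) {
        tals <- c(tals, paste0(tal_num(ann$onset[i]), "\x15",
                               sprintf("%.7g", ann$duration[i]), "\x14",
                               ann$label[i], "\x14"))
      }
    }
    # each TAL is NUL-terminated; embedded NULs are illegal in R strings,
    # so assemble the byte block here
    unlist(lapply(tals, function(s) c(charToRaw(s), as.raw(0L))))
  })
  ann_bytes <- max(vapply(rec_tals, length, integer(1)))
  ann_spr <- as.integer(ceiling(ann_bytes / 2))
  ann_spr <- max(ann_spr, 8L)

  labels <- c(rec$channel_labels, EDF_ANN_LABEL)
  ns <- nch + 1L
  header_bytes <- 256L + 256L * ns

  startdate <- rec$meta$startdate %||% "01.01.01"
  starttime <- rec$meta$starttime %||% "00.00.00"
  patient <- rec$meta$patient %||% "X X X X"
  recording_id <- rec$meta$recording_id %||% "Startdate 01-JAN-2001 X X X"

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width) writeChar(pad_field(x, width), con, nchars = width, eos = NULL)

  put("0", 8)
  put(patient, 80)
  put(recording_id, 80)
  put(startdate, 8)
  put(starttime, 8)
  put(header_bytes, 8)
  put("EDF+C", 44)
  put(n_rec, 8)
  put(fmt_num(record_duration), 8)
  put(ns, 4)

  for (l in labels) put(l, 16)
  for (i in seq_len(ns)) put("", 80) # transducer
  for (i in seq_len(ns)) put(if (i <= nch) "uV" else "", 8)
  for (i in seq_len(ns)) put(if (i <= nch) fmt_num(-phys_range) else "-1", 8)
  for (i in seq_len(ns)) put(if (i <= nch) fmt_num(phys_range) else "1", 8)
  for (i in seq_len(ns)) put("-32768", 8)
  for (i in seq_len(ns)) put("32767", 8)
  for (i in seq_len(ns)) put("", 80) # prefiltering
  for (i in seq_len(ns)) put(if (i <= nch) spr else ann_spr, 8)
  for (i in seq_len(ns)) put("", 32) # reserved

  for (r in seq_len(n_rec) - 1L) {
    for (ch in seq_len(nch)) {
      writeBin(dig[ch, (r * spr + 1L):((r + 1L) * spr)],
               con, size = 2L, endian = "little")
    }
    tal_raw <- rec_tals[[r + 1L]]
    block <- raw(2L * ann_spr)
    block[seq_along(tal_raw)] <- tal_raw
    writeBin(block, con)
  }
  invisible(path)
}

#' Read a recording from an EDF/EDF+ file
#'
#' Imports samples (converted to microvolts via the header's physical and
#' digital ranges), the sampling rate, channel labels and any EDF+
#' annotations. All ordinary signals must share one sampling rate.
#'
#' @param path path to an EDF or EDF+ file.
#' @param mont optional [montage()]; when supplied, [check_montage()] is
#'   applied so a missing electrode raises a montage error naming it.
#' @return An [recording()] object.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, mont = NULL) {
  if (!file.exists(path)) {
    hb_stop(paste0("no such file: ", path), "hoofbeat_io_error")
  }
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 256L) {
    hb_stop("file too short to be EDF", "hoofbeat_io_error")
  }
  field <- function(off, width) {
    trimws(rawToChar(bytes[(off + 1L):(off + width)]))
  }
  numf <- function(off, width) {
    v <- suppressWarnings(as.numeric(field(off, width)))
    if (is.na(v)) hb_stop("corrupt EDF header (non-numeric field)", "hoofbeat_io_error")
    v
  }
  n_rec <- numf(236, 8)
  rec_dur <- numf(244, 8)
  ns <- as.integer(numf(252, 4))
  if (ns < 1L || n_rec < 1L) hb_stop("corrupt EDF header", "hoofbeat_io_error")

  sig_field <- function(block_off, width, parse = identity) {
    base <- 256L + block_off * ns
    vapply(seq_len(ns) - 1L, function(i) parse(field(base + i * width, width)),
           if (identical(parse, identity)) character(1) else numeric(1))
  }
  widths <- c(label = 16L, transducer = 80L, dim = 8L, pmin = 8L, pmax = 8L,
              dmin = 8L, dmax = 8L, prefilter = 80L, spr = 8L)
  offs <- cumsum(c(0L, head(unname(widths), -1L)))
  names(offs) <- names(widths)
  labels <- sig_field(offs["label"], 16L)
  pmin <- sig_field(offs["pmin"], 8L, as.numeric)
  pmax <- sig_field(offs["pmax"], 8L, as.numeric)
  dmin <- sig_field(offs["dmin"], 8L, as.numeric)
  dmax <- sig_field(offs["dmax"], 8L, as.numeric)
  spr <- as.integer(sig_field(offs["spr"], 8L, as.numeric))

  is_ann <- labels == EDF_ANN_LABEL
  data_idx <- which(!is_ann)
  if (length(data_idx) == 0L) {
    hb_stop("EDF file contains no ordinary signals", "hoofbeat_io_error")
  }
  if (length(unique(spr[data_idx])) != 1L) {
    hb_stop("channels with differing sampling rates are not supported",
            "hoofbeat_layout_error")
  }
  fs <- spr[data_idx[1L]] / rec_dur

  header_bytes <- as.integer(numf(184, 8))
  per_rec <- sum(spr)
  expected <- header_bytes + 2L * per_rec * n_rec
  if (length(bytes) < expected) {
    hb_stop("EDF file truncated", "hoofbeat_io_error")
  }
  dat <- readBin(bytes[(header_bytes + 1L):expected], "integer",
                 n = per_rec * n_rec, size = 2L, signed = TRUE,
                 endian = "little")

  sig_offsets <- c(0L, cumsum(spr))
  gain <- (pmax - pmin) / (dmax - dmin)
  samples <- matrix(0, nrow = length(data_idx), ncol = spr[data_idx[1L]] * n_rec)
  for (k in seq_along(data_idx)) {
    j <- data_idx[k]
    idx <- as.vector(outer(sig_offsets[j] + seq_len(spr[j]),
                           (seq_len(n_rec) - 1L) * per_rec, `+`))
    samples[k, ] <- pmin[j] + (dat[idx] - dmin[j]) * gain[j]
  }
  rownames(samples) <- labels[data_idx]

  anns <- data.frame(onset = numeric(0), duration = numeric(0),
                     label = character(0), stringsAsFactors = FALSE)
  for (j in which(is_ann)) {
    for (r in seq_len(n_rec) - 1L) {
      off <- header_bytes + 2L * (r * per_rec + sig_offsets[j])
      chunk <- bytes[(off + 1L):(off + 2L * spr[j])]
      anns <- rbind(anns, parse_tals(chunk))
    }
  }
  if (nrow(anns) > 0L) anns <- anns[order(anns$onset), , drop = FALSE]
  rownames(anns) <- NULL

  recording(samples, fs = fs, channel_labels = labels[data_idx],
            annotations = anns, meta = list(source_file = path)) -> rec
  if (!is.null(mont)) rec <- check_montage(rec, mont)
  rec
}

# Parse one record's annotation bytes into (onset, duration, label) rows,
# skipping the time-keeping TALs (those with an empty label).
parse_tals <- function(chunk) {
  out <- data.frame(onset = numeric(0), duration = numeric(0),
                    label = character(0), stringsAsFactors = FALSE)
  zero <- which(chunk == as.raw(0L))
  starts <- c(1L, zero + 1L)
  ends <- c(zero - 1L, length(chunk))
  for (i in seq_along(starts)) {
    if (starts[i] > ends[i]) next
    tal <- rawToChar(chunk[starts[i]:ends[i]])
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    labels <- parts[-1L]
    labels <- labels[nzchar(labels)]
    if (length(labels) == 0L) next # time-keeping TAL
    time_part <- strsplit(parts[1L], "\x15", fixed = TRUE)[[1]]
    onset <- as.numeric(time_part[1L])
    dur <- if (length(time_part) > 1L) as.numeric(time_part[2L]) else 0
    for (lab in labels) {
      out <- rbind(out, data.frame(onset = onset, duration = dur, label = lab,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
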