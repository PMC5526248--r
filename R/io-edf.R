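# Minimal EDF (European Data Format) reader/writer for continuous
# recordings. One data record holds the whole signal; samples are stored
# as 16-bit little-endian integers with per-channel physical scaling, so
# a round-trip is exact up to the quantization step
# (phys_max - phys_min) / 65535.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)                     # left-justified, space-padded
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = -1)
  .edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Stores the continuous multi-channel signal as plain EDF (16-bit,
#' single data record spanning the recording). Channel labels, sampling
#' rate and the microvolt unit are preserved; amplitudes are quantized
#' to 1/65535 of each channel's range. Events are not embedded — use
#' [write_events()] for the tab-separated sidecar.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$samples
  ns <- nrow(x)
  n <- ncol(x)
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  scale <- (pmax_ - pmin_) / (dmax - dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad(paste("Startdate 01-JAN-2026 X X", "erpspeller"), 80),
    "01.01.26", "00.00.00",
    .edf_pad(256 + 256 * ns, 8),
    .edf_pad("", 44),
    .edf_pad(1, 8),
    .edf_num(n / recording$fs, 8),
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(recording$channel_labels, 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  writeChar(paste0(vapply(pmin_, .edf_num, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmax_, .edf_num, "", width = 8), collapse = ""), con, eos = NULL)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep(recording$reference, ns), 80)
  field(rep(n, ns), 8)
  field(rep("", ns), 32)

  # re-derive scaling from the ASCII header fields so the round-trip is
  # consistent with what a reader will parse
  pmin_r <- as.numeric(vapply(pmin_, .edf_num, "", width = 8))
  pmax_r <- as.numeric(vapply(pmax_, .edf_num, "", width = 8))
  scale_r <- (pmax_r - pmin_r) / (dmax - dmin)
  for (ch in seq_len(ns)) {
    d <- as.integer(round((x[ch, ] - pmin_r[ch]) / scale_r[ch]) + dmin)
    d <- pmin(pmax(d, dmin), dmax)
    writeBin(d, con, size = 2, endian = "little")
  }
  invisible(path)
}

.edf_read_field <- function(con, width, n = 1) {
  vapply(seq_len(n), function(i) trimws(readChar(con, width)), "")
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses the EDF header and 16-bit data records back into an
#' [eeg_recording()]. Fails with an informative error naming the
#' offending header field on malformed input.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .edf_read_field(con, 8)
  if (version != "0") stop("EDF parse error: version field is not '0'", call. = FALSE)
  readChar(con, 160)                             # patient + recording id
  readChar(con, 16)                              # date + time
  hdr_bytes <- suppressWarnings(as.integer(.edf_read_field(con, 8)))
  if (is.na(hdr_bytes)) stop("EDF parse error: header-bytes field", call. = FALSE)
  readChar(con, 44)
  n_rec <- suppressWarnings(as.integer(.edf_read_field(con, 8)))
  rec_dur <- suppressWarnings(as.numeric(.edf_read_field(con, 8)))
  ns <- suppressWarnings(as.integer(.edf_read_field(con, 4)))
  if (is.na(n_rec) || n_rec < 1) stop("EDF parse error: record-count field", call. = FALSE)
  if (is.na(rec_dur) || rec_dur <= 0) stop("EDF parse error: record-duration field", call. = FALSE)
  if (is.na(ns) || ns < 1) stop("EDF parse error: signal-count field", call. = FALSE)

  labels <- .edf_read_field(con, 16, ns)
  .edf_read_field(con, 80, ns)                   # transducer
  .edf_read_field(con, 8, ns)                    # physical dimension
  pmin_ <- as.numeric(.edf_read_field(con, 8, ns))
  pmax_ <- as.numeric(.edf_read_field(con, 8, ns))
  dmin <- as.numeric(.edf_read_field(con, 8, ns))
  dmax <- as.numeric(.edf_read_field(con, 8, ns))
  if (anyNA(pmin_) || anyNA(pmax_)) stop("EDF parse error: physical min/max field", call. = FALSE)
  if (anyNA(dmin) || anyNA(dmax) || any(dmax <= dmin))
    stop("EDF parse error: digital min/max field", call. = FALSE)
  prefilter <- .edf_read_field(con, 80, ns)
  spr <- suppressWarnings(as.integer(.edf_read_field(con, 8, ns)))
  if (anyNA(spr) || any(spr < 1)) stop("EDF parse error: samples-per-record field", call. = FALSE)
  .edf_read_field(con, 32, ns)

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  out <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[ch], size = 2,
                   endian = "little", signed = TRUE)
      if (length(d) < spr[ch]) stop("EDF parse error: truncated data record", call. = FALSE)
      out[ch, (r - 1) * spr[ch] + seq_len(spr[ch])] <-
        (d - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  eeg_recording(out, labels, fs = spr[1] / rec_dur,
                reference = prefilter[1])
}
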