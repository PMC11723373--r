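# Minimal EDF (European Data Format) reader and writer for continuous
# multichannel recordings: 256-byte fixed header, 256 bytes per signal, and
# 16-bit little-endian samples in fixed-duration data records. Annotations
# travel in a CSV sidecar (`patient_id,start_s,end_s,label`) rather than as
# EDF+ events.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EEG record to an EDF file
#'
#' Samples are scaled per channel to the full 16-bit digital range. The
#' recording is split into 1-second data records; a trailing remainder
#' shorter than one record is dropped.
#' @param record an [eeg_record()]
#' @param path output file
#' @export
write_edf <- function(record, path) {
  ns <- nrow(record$data)
  spr <- as.integer(round(record$fs))      # samples per 1-s record
  n_rec <- ncol(record$data) %/% spr
  pmax_ <- apply(record$data, 1, function(x) max(abs(x), 1e-6))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.01", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(get, width)
    writeChar(paste0(vapply(seq_len(ns), function(i) pad_field(get(i), width),
                            "")), con, eos = NULL)
  field(function(i) record$channel_names[i], 16)
  field(function(i) "", 80)
  field(function(i) "uV", 8)
  field(function(i) sprintf("%.6g", -pmax_[i]), 8)
  field(function(i) sprintf("%.6g", pmax_[i]), 8)
  field(function(i) -32768, 8)
  field(function(i) 32767, 8)
  field(function(i) "", 80)
  field(function(i) spr, 8)
  field(function(i) "", 32)
  for (r in seq_len(n_rec)) {
    sel <- (r - 1L) * spr + seq_len(spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((record$data[ch, sel] + pmax_[ch]) /
                                (2 * pmax_[ch]) * 65535)) - 32768L
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an EEG record
#'
#' @param path EDF file
#' @param channels optional character vector of channel labels to keep
#' @param annotations optional data.frame of labeled intervals (columns
#'   `start_s`, `end_s`, `label`), e.g. from [read_annotations()]
#' @return an [eeg_record()]
#' @export
read_edf <- function(path, channels = NULL, annotations = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- per(16); per(80); per(8)
  pmin_ <- as.numeric(per(8)); pmax_ <- as.numeric(per(8))
  dmin_ <- as.numeric(per(8)); dmax_ <- as.numeric(per(8))
  per(80)
  spr <- as.integer(per(8)); per(32)
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[1] / dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little")
      data[ch, (r - 1L) * spr[1] + seq_len(spr[1])] <-
        pmin_[ch] + (dig - dmin_[ch]) * scale[ch]
    }
  }
  if (!is.null(channels)) {
    keep <- match(channels, labels)
    if (any(is.na(keep))) stop("channel not found: ",
                               paste(channels[is.na(keep)], collapse = ", "))
    data <- data[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  eeg_record(data, fs, channel_names = labels, intervals = annotations)
}

#' Read an annotation sidecar CSV
#'
#' Expected columns: `patient_id`, `start_s`, `end_s`, `label`.
#' @param path CSV file
#' @param patient_id optional filter
#' @export
read_annotations <- function(path, patient_id = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "start_s", "end_s", "label")
  if (!all(need %in% names(tab)))
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
  if (!is.null(patient_id))
    tab <- tab[tab$patient_id == patient_id, , drop = FALSE]
  tab[, c("start_s", "end_s", "label")]
}
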