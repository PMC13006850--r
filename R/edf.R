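#' Write an EEG night to an EDF file
#'
#' Minimal European Data Format writer: 16-bit samples, physical units
#' microvolts, one data record per second. The physical range is taken
#' per channel from the data (symmetric, rounded up), so quantisation
#' error is below 0.01% of the signal range. Channel qualities are not
#' part of EDF; they are stored in the reserved header field as
#' `quality=<q1,q2,...>` and recovered by [read_edf].
#'
#' @param night an [eeg_night].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(night, path) {
  stopifnot(inherits(night, "eeg_night"))
  sig <- night$signal
  fs <- night$fs
  ns <- ncol(sig)
  spr <- as.integer(round(fs)) # samples per 1-s record per channel
  n_rec <- floor(nrow(sig) / spr)
  if (n_rec < 1) stop("signal shorter than one 1-s data record")
  pad <- function(s, width) {
    s <- substr(as.character(s), 1, width)
    formatC(s, width = width, flag = "-")
  }
  phys_max <- pmax(ceiling(apply(abs(sig), 2, max)), 1)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad(paste0("X X X ", night$participant_id), 80),
    pad(paste0("Startdate X X X X ", night$night_id), 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8),
    pad(paste0("quality=", paste(sprintf("%.4f", night$channel_quality),
                                 collapse = ",")), 44),
    pad(n_rec, 8), pad("1", 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(colnames(sig), 16)                       # label
  field(rep("AgAgCl dry electrode", ns), 80)     # transducer
  field(rep("uV", ns), 8)                        # physical dimension
  field(-phys_max, 8)                            # physical minimum
  field(phys_max, 8)                             # physical maximum
  field(rep(-32768, ns), 8)                      # digital minimum
  field(rep(32767, ns), 8)                       # digital maximum
  field(rep("", ns), 80)                         # prefiltering
  field(rep(spr, ns), 8)                         # samples per record
  field(rep("", ns), 32)                         # reserved
  scale <- (2 * phys_max) / 65535
  for (r in seq_len(n_rec)) {
    i0 <- (r - 1L) * spr + 1L
    for (ch in seq_len(ns)) {
      dig <- round((sig[i0:(i0 + spr - 1L), ch] + phys_max[ch]) /
                     scale[ch]) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf]
#'
#' Parses the EDF header and data records, rescaling digital samples to
#' physical microvolts with each channel's calibration. Channel
#' qualities are recovered from the reserved header field when present
#' (1.0 otherwise).
#'
#' @param path EDF file path.
#' @return An [eeg_night].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  pid <- rd(80); rid <- rd(80)
  rd(8); rd(8); rd(8)         # date, time, header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8)); dmax_ <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  fs <- spr[1] / rec_dur
  out <- matrix(0, nrow = n_rec * spr[1], ncol = ns,
                dimnames = list(NULL, labels))
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      i0 <- (r - 1L) * spr[ch] + 1L
      out[i0:(i0 + spr[ch] - 1L), ch] <-
        (dig - dmin_[ch]) * scale[ch] + pmin_[ch]
    }
  }
  quality <- setNames(rep(1, ns), labels)
  if (grepl("^quality=", reserved)) {
    qv <- as.numeric(strsplit(sub("^quality=", "", reserved), ",")[[1]])
    if (length(qv) == ns) quality <- setNames(qv, labels)
  }
  pid <- sub("^X X X ", "", pid)
  rid <- sub("^Startdate X X X X ", "", rid)
  eeg_night(out, fs, quality, participant_id = pid, night_id = rid)
}

#' Write an event table (detections or ground truth) to CSV
#'
#' @param events event tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Write a hypnogram to CSV (`epoch_index`, `stage`)
#'
#' @param hyp a [hypnogram].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  write.csv(data.frame(epoch_index = seq_along(hyp$stages) - 1L,
                       stage = hyp$stages),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram CSV written by [write_hypnogram_csv]
#'
#' @param path CSV path.
#' @param epoch_len_s epoch length, s.
#' @return A [hypnogram].
#' @export
read_hypnogram_csv <- function(path, epoch_len_s = 30) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d <- d[order(d$epoch_index), , drop = FALSE]
  hypnogram(d$stage, epoch_len_s = epoch_len_s)
}
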