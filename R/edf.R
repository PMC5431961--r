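# Minimal European Data Format (EDF) reader/writer: continuous recordings,
# 16-bit samples, ASCII headers.  Covers what an electrophysiology rig
# exports for single- or multi-channel LFP; EDF+ annotations are not
# interpreted.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

num_field <- function(x, width) pad_field(format(x, digits = 8), width)

#' Write an LFP signal as EDF
#'
#' Single-channel EDF with one-second data records and 16-bit quantization
#' over the signal's range.  `fs` must be a whole number; a trace that is
#' not a whole number of seconds is padded with its final value to fill the
#' last record.
#'
#' @param sig An [lfp_signal()] (units mV).
#' @param path Output path.
#' @param label Channel label (<= 16 ASCII characters).
#' @return `path`, invisibly.
#' @export
write_edf <- function(sig, path, label = "LFP") {
  stopifnot(inherits(sig, "lfp_signal"))
  fs <- sig$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export needs an integer sampling rate, got fs = ", fs)
  fs <- as.integer(round(fs))
  x <- sig$samples
  n_rec <- ceiling(length(x) / fs)
  x <- c(x, rep(x[length(x)], n_rec * fs - length(x)))
  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ == pmin_) pmax_ <- pmin_ + 1
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) *
                            (dmax - dmin) + dmin))
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(pad_field("0", 8))                       # version
  wr(pad_field("X X X X", 80))                # patient id
  wr(pad_field("Startdate X X X X", 80))      # recording id
  wr(pad_field("01.01.00", 8))                # start date
  wr(pad_field("00.00.00", 8))                # start time
  wr(num_field(256 + 256, 8))                 # header length, 1 signal
  wr(pad_field("", 44))
  wr(num_field(n_rec, 8))
  wr(num_field(1, 8))                         # record duration (s)
  wr(num_field(1, 4))                         # number of signals
  wr(pad_field(label, 16))
  wr(pad_field("", 80))                       # transducer
  wr(pad_field("mV", 8))
  wr(num_field(pmin_, 8))
  wr(num_field(pmax_, 8))
  wr(num_field(dmin, 8))
  wr(num_field(dmax, 8))
  wr(pad_field("", 80))                       # prefiltering
  wr(num_field(fs, 8))                        # samples per record
  wr(pad_field("", 32))
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF signal
#'
#' @param path EDF file.
#' @param channel Channel index (1-based).
#' @return An [lfp_signal()] in the channel's physical units.
#' @export
read_edf <- function(path, channel = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rdn <- function(w) {
    v <- suppressWarnings(as.numeric(rd(w)))
    if (is.na(v)) stop("malformed EDF header in ", path)
    v
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_len <- rdn(8)
  rd(44)
  n_rec <- rdn(8)
  rec_dur <- rdn(8)
  ns <- rdn(4)
  if (ns < 1 || channel > ns)
    stop("EDF file has ", ns, " signal(s); requested channel ", channel)
  per_sig <- function(w, numeric = FALSE) {
    vapply(seq_len(ns), function(i) {
      if (numeric) rdn(w) else rd(w)
    }, if (numeric) numeric(1) else character(1))
  }
  per_sig(16); per_sig(80); per_sig(8)
  pmin_ <- per_sig(8, TRUE); pmax_ <- per_sig(8, TRUE)
  dmin <- per_sig(8, TRUE); dmax <- per_sig(8, TRUE)
  per_sig(80)
  spr <- per_sig(8, TRUE)
  per_sig(32)
  if (seek(con, NA) != header_len)
    stop("EDF header length mismatch in ", path)
  rec_samples <- sum(spr)
  raw <- readBin(con, "integer", n = n_rec * rec_samples, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * rec_samples)
    stop("truncated EDF data in ", path)
  offs <- c(0, cumsum(spr))
  idx <- as.vector(outer(seq_len(spr[channel]) + offs[channel],
                         (seq_len(n_rec) - 1) * rec_samples, `+`))
  dig <- raw[idx]
  phys <- (dig - dmin[channel]) / (dmax[channel] - dmin[channel]) *
    (pmax_[channel] - pmin_[channel]) + pmin_[channel]
  lfp_signal(phys, fs = spr[channel] / rec_dur)
}
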