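# Minimal EDF (European Data Format) 16-bit I/O.
# Scope: continuous multichannel signals with a common sampling rate, one
# data record per file (duration = whole recording), physical unit uV.
# This is deliberately a small, self-contained subset of EDF sufficient to
# round-trip recordings produced by this package and to ingest simple
# exported files; it is not a general EDF+ annotation parser.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop(sprintf("EDF field too wide: '%s' (> %d chars)", x, width))
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 7)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g", digits = width - 4), 1, width)
  edf_pad(s, width)
}

#' Write a recording to a 16-bit EDF file
#'
#' Signals are quantized to 16 bits over a symmetric physical range; the
#' physical dimension is microvolts. The whole recording is stored as a
#' single EDF data record so no padding or truncation occurs.
#'
#' @param rec an `eeg_recording`.
#' @param path output path (`.edf`).
#' @param phys_range_uv symmetric physical range in microvolts; samples are
#'   clipped to `[-phys_range_uv, +phys_range_uv]` before quantization.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path, phys_range_uv = 800) {
  n <- nrow(rec$data)
  nc <- ncol(rec$data)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * nc, 8), edf_pad("", 44),
    edf_pad(1, 8), edf_num(n / rec$fs, 8), edf_pad(nc, 4)
  )
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width), collapse = "")
  header <- paste0(
    header,
    field(rec$channel_labels, 16),
    field(rep("", nc), 80),
    field(rep("uV", nc), 8),
    field(rep(edf_num(-phys_range_uv, 8), nc), 8),
    field(rep(edf_num(phys_range_uv, 8), nc), 8),
    field(rep("-32768", nc), 8),
    field(rep("32767", nc), 8),
    field(rep("", nc), 80),
    field(rep(n, nc), 8),
    field(rep("", nc), 32)
  )
  writeChar(header, con, eos = NULL)
  scale <- 65535 / (2 * phys_range_uv)
  for (j in seq_len(nc)) {
    x <- pmin(pmax(rec$data[, j], -phys_range_uv), phys_range_uv)
    dig <- as.integer(round((x + phys_range_uv) * scale - 32768))
    dig <- pmin(pmax(dig, -32768L), 32767L)
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  if (is.na(nc) || nc < 1) stop("EDF header: invalid signal count")
  rdv <- function(w) vapply(seq_len(nc), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8) # physical dimension
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8))
  dmax_ <- as.numeric(rdv(8))
  rdv(80)
  nsamp <- as.integer(rdv(8))
  rdv(32)
  if (any(is.na(pmin_)) || any(is.na(nsamp))) stop("EDF header: malformed signal fields")
  if (length(unique(nsamp)) != 1L) {
    stop("EDF: signals have unequal samples per record; mixed-rate files unsupported")
  }
  if (is.na(dur) || dur <= 0) stop("EDF header: missing record duration (needed for fs)")
  fs <- nsamp[1L] / dur
  cols <- vector("list", nc)
  for (j in seq_len(nc)) cols[[j]] <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(nc)) {
      dig <- readBin(con, "integer", n = nsamp[j], size = 2L, endian = "little", signed = TRUE)
      phys <- pmin_[j] + (dig - dmin_[j]) * (pmax_[j] - pmin_[j]) / (dmax_[j] - dmin_[j])
      cols[[j]] <- c(cols[[j]], phys)
    }
  }
  eeg_recording(do.call(cbind, cols), fs = fs, channel_labels = labels,
                meta = list(source = path))
}
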