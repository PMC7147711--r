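# European Data Format (EDF) reader/writer for continuous multichannel
# recordings: ASCII header, 16-bit little-endian samples, 1-second data
# records. Covers the plain-EDF subset (equal sampling rate across
# signals, no annotations).

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a continuous recording to an EDF file
#'
#' Samples are scaled per channel into signed 16-bit integers spanning the
#' channel's physical range, so a write/read round trip agrees with the
#' input to within the format's quantization step. The recording is padded
#' with zeros to a whole number of 1-second data records. Header dates are
#' fixed, so identical data yield byte-identical files.
#'
#' @param x List with `data` (channels x samples matrix, microvolts),
#'   `srate` (Hz) and `channels` (labels), as returned by
#'   [epochs_to_continuous()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path) {
  stopifnot(is.list(x), is.matrix(x$data), length(x$channels) == nrow(x$data),
            x$srate > 0, x$srate == round(x$srate))
  nch <- nrow(x$data)
  spr <- as.integer(x$srate)                 # samples per 1-second record
  ndr <- ceiling(ncol(x$data) / spr)
  dat <- cbind(x$data, matrix(0, nch, ndr * spr - ncol(x$data)))
  pmax_ <- apply(abs(dat), 1, max)
  pmax_ <- ifelse(pmax_ < 1, 1, pmax_ * 1.0001)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80), pad_field("Startdate X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (nch + 1), 8), pad_field("", 44),
    pad_field(ndr, 8), pad_field(1, 8), pad_field(nch, 4))
  sig <- function(vals, width) paste(vapply(vals, pad_field, "", width = width),
                                     collapse = "")
  hdr <- paste0(hdr,
    sig(x$channels, 16), sig(rep("", nch), 80), sig(rep("uV", nch), 8),
    sig(sprintf("%.6g", -pmax_), 8), sig(sprintf("%.6g", pmax_), 8),
    sig(rep(-32767, nch), 8), sig(rep(32767, nch), 8),
    sig(rep("", nch), 80), sig(rep(spr, nch), 8), sig(rep("", nch), 32))
  writeChar(hdr, con, eos = NULL)
  scale <- 32767 / pmax_
  for (r in seq_len(ndr)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    block <- round(dat[, cols, drop = FALSE] * scale)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the header, checks structural consistency, and returns the
#' signals rescaled to physical units. All signals must share one sampling
#' rate. A truncated or malformed file raises a format error.
#'
#' @param path Path to an EDF file.
#' @return List with `data` (channels x samples matrix), `srate` (Hz) and
#'   `channels` (upper-cased labels).
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("EDF format error: file too short", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                       # version
  rd(160)                                     # patient + recording id
  rd(16)                                      # date + time
  hbytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  ndr <- suppressWarnings(as.integer(rd(8)))
  dur <- suppressWarnings(as.numeric(rd(8)))
  nch <- suppressWarnings(as.integer(rd(4)))
  if (is.na(nch) || nch < 1 || is.na(hbytes) ||
      hbytes != 256 * (nch + 1) || sz < hbytes) {
    stop("EDF format error: malformed header", call. = FALSE)
  }
  rdv <- function(width) {
    trimws(vapply(seq_len(nch), function(i) rd(width), ""))
  }
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr, dur)) || any(spr <= 0)) {
    stop("EDF format error: malformed signal headers", call. = FALSE)
  }
  if (length(unique(spr / dur)) != 1) {
    stop("EDF with mixed sampling rates is not supported", call. = FALSE)
  }
  rec_bytes <- 2 * sum(spr)
  if (is.na(ndr) || ndr < 0) ndr <- (sz - hbytes) %/% rec_bytes
  if (sz - hbytes < ndr * rec_bytes) {
    stop("EDF format error: file truncated", call. = FALSE)
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  dat <- matrix(0, nch, ndr * spr[1])
  for (r in seq_len(ndr)) {
    raw <- readBin(con, integer(), n = sum(spr), size = 2, endian = "little",
                   signed = TRUE)
    if (length(raw) < sum(spr)) stop("EDF format error: file truncated",
                                     call. = FALSE)
    off <- 0
    for (c in seq_len(nch)) {
      seg <- raw[(off + 1):(off + spr[c])]
      dat[c, ((r - 1) * spr[c] + 1):(r * spr[c])] <-
        pmin_[c] + gain[c] * (seg - dmin[c])
      off <- off + spr[c]
    }
  }
  list(data = dat, srate = spr[1] / dur, channels = toupper(labels))
}
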