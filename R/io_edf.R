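#' Write a recording to EDF (European Data Format)
#'
#' Minimal EDF writer: 16-bit samples, physical units microvolts, 1-second
#' data records. The physical range is set per channel from the data, so the
#' quantization step is `(max - min) / 65535`. Recordings whose duration is
#' not a whole number of seconds are zero-padded to the next full record.
#'
#' @param rec a `continuous_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "continuous_recording"))
  ns <- nrow(rec$data)
  spr <- as.integer(round(rec$sfreq))          # samples per 1 s record
  n <- ncol(rec$data)
  nrec <- as.integer(ceiling(n / spr))
  pad <- nrec * spr - n
  dat <- if (pad > 0) cbind(rec$data, matrix(0, ns, pad)) else rec$data

  pmin <- apply(dat, 1, min)
  pmax <- apply(dat, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  pad_field <- function(x, width) {
    x <- substr(as.character(x), 1, width)
    formatC(x, width = -width, flag = " ")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field(sprintf("Startdate X X X X ref=%s", rec$reference), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field("1", 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(f, width) writeChar(
    paste(vapply(f, pad_field, "", width = width), collapse = ""), con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(pmin, digits = 6, format = "g"), 8)
  field(formatC(pmax, digits = 6, format = "g"), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)

  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((dat[ch, idx] - pmin[ch]) / scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a continuous recording
#'
#' Supports the subset written by [write_edf()]: equal sampling rate across
#' signals, physical units scaled linearly from 16-bit digital values.
#' Truncated files (fewer data bytes than the header promises) are rejected.
#'
#' @param path EDF file path.
#' @return a `continuous_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) data_error("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8)
  if (!identical(ver, "0")) data_error("not an EDF file (version '%s'): %s", ver, path)
  rd(80); recid <- rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) data_error("corrupt EDF header (no signals): %s", path)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (anyDuplicated(labels)) data_error("duplicate channel labels in %s", path)
  if (length(unique(spr)) != 1) data_error(
    "mixed sampling rates are not supported: %s", path)
  sfreq <- spr[1] / recdur

  expected <- nrec * sum(spr) * 2
  raw_all <- readBin(con, "integer", n = nrec * sum(spr), size = 2,
                     endian = "little")
  if (length(raw_all) < nrec * sum(spr)) data_error(
    "truncated EDF data section in %s (expected %d bytes)", path, expected)
  dat <- matrix(0, ns, nrec * spr[1])
  pos <- 0
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dat[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        raw_all[(pos + 1):(pos + spr[ch])]
      pos <- pos + spr[ch]
    }
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  dat <- sweep(dat, 1, dmin, FUN = "-")
  dat <- sweep(dat, 1, scale, FUN = "*")
  dat <- sweep(dat, 1, pmin, FUN = "+")
  reference <- sub(".*ref=([^ ]+).*", "\\1", recid)
  if (identical(reference, recid)) reference <- "A1"
  continuous_recording(dat, labels, sfreq, reference = reference)
}
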