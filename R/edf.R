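# Minimal EDF (European Data Format) reader/writer: fixed-width ASCII header
# plus 16-bit little-endian samples, one physical-range scaling per channel.
# Covers plain continuous EDF only (no EDF+ annotations, one duration per
# record, integer samples-per-record).

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

num_field <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 7)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  pad_field(s, width)
}

#' Write a recording to an EDF file
#'
#' Writes 16-bit EDF with one-second data records. The per-channel physical
#' range is set symmetrically just above the observed amplitude, so the
#' quantisation step is \code{2 * phys_max / 65535} microvolts. The number of
#' samples must be a whole number of one-second records.
#'
#' @param rec An [ms_recording()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ms_recording"))
  srate <- rec$srate
  if (srate != round(srate))
    stop_io("EDF writer requires an integer sampling rate, got %g", srate)
  n <- ncol(rec$data)
  if (n %% srate != 0)
    stop_io("EDF writer requires whole 1-s records: %d samples at %g Hz",
            n, srate)
  n_rec <- n %/% srate
  nc <- nrow(rec$data)

  phys_max <- pmax(ceiling(apply(abs(rec$data), 1L, max)), 1)
  dig_max <- 32767L

  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(rec$subject_id, 80),
    pad_field(paste("group", rec$group), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    num_field(256L * (1L + nc), 8), pad_field("", 44),
    num_field(n_rec, 8), num_field(1L, 8), num_field(nc, 4))
  sig <- paste0(
    paste(vapply(rec$channel_names, pad_field, "", width = 16),
          collapse = ""),
    strrep(pad_field("", 80), nc),
    strrep(pad_field("uV", 8), nc),
    paste(vapply(-phys_max, num_field, "", width = 8), collapse = ""),
    paste(vapply(phys_max, num_field, "", width = 8), collapse = ""),
    strrep(num_field(-dig_max - 1L, 8), nc),
    strrep(num_field(dig_max, 8), nc),
    strrep(pad_field("", 80), nc),
    strrep(num_field(srate, 8), nc),
    strrep(pad_field("", 32), nc))
  writeChar(paste0(hdr, sig), con, eos = NULL)

  dig_min <- -dig_max - 1L
  gain <- (2 * phys_max) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * srate + 1L):(r * srate)
    block <- rec$data[, idx, drop = FALSE]
    block <- round(sweep(sweep(block, 1L, -phys_max, "-"), 1L, gain, "/")) +
      dig_min
    block <- pmin(pmax(block, dig_min), dig_max)
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_ascii <- function(con, n) {
  trimws(readChar(con, n, useBytes = TRUE))
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @param subject_id,group Cohort metadata to attach (EDF carries neither).
#' @return An [ms_recording()] in microvolts.
#' @export
read_edf <- function(path, subject_id = NULL, group = "control") {
  if (!file.exists(path)) stop_io("cannot read EDF file: %s", path)
  con <- file(path, open = "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                      # version
  patient <- read_ascii(con, 80)
  readChar(con, 80 + 8 + 8, useBytes = TRUE)             # recording/date/time
  read_ascii(con, 8)                                     # header bytes
  readChar(con, 44, useBytes = TRUE)
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  nc <- as.integer(read_ascii(con, 4))
  if (is.na(nc) || nc < 1L) stop_io("malformed EDF header in %s", path)

  field <- function(w) vapply(seq_len(nc), function(i) read_ascii(con, w), "")
  labels <- field(16); field(80)
  dims <- field(8)
  pmin_ <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))
  field(32)
  if (length(unique(spr)) != 1L)
    stop_io("EDF with heterogeneous per-channel rates is not supported: %s",
            path)
  srate <- spr[1L] / rec_dur

  out <- matrix(0, nrow = nc, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = nc * spr[1L], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1L], ncol = nc)
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    out[, idx] <- t(block)
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- (out - dmin) * gain + pmin_
  # convert to microvolts if the dimension field says millivolts or volts
  mult <- ifelse(tolower(dims) == "mv", 1e3,
                 ifelse(tolower(dims) == "v", 1e6, 1))
  out <- out * mult
  ms_recording(out, srate = srate, channel_names = labels,
               subject_id = if (is.null(subject_id)) patient else subject_id,
               group = group)
}
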