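# Recording and label file input/output, plus resampling.
#
# Two on-disk recording formats: (1) CSV with a `time,<ch1>,...` header and
# a JSON sidecar (`<path>.json`) carrying fs, channel roles and start time;
# (2) EDF (European Data Format): 256-byte ASCII header + 256 bytes per
# signal + data records of little-endian int16 with linear physical
# scaling. The EDF reader/writer below implements the 1992 base standard,
# which is sufficient for round-tripping continuous polysomnography-style
# recordings.

#' Read a recording from disk
#'
#' @param path file path. CSV expects a sidecar `<path>.json` with fields
#'   `fs`, `channels` (name/role/site), optional `start_time`.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  switch(format, csv = read_recording_csv(path), edf = read_edf(path))
}

#' Write a recording to disk
#'
#' @param rec a [recording()].
#' @param path output path (`.csv` or `.edf`).
#' @param format `"auto"`, `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  switch(format, csv = write_recording_csv(rec, path),
         edf = write_edf(rec, path))
  invisible(path)
}

read_recording_csv <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("header error: sidecar JSON not found: ", side)
  hdr <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(hdr$fs)) stop("header error: sampling rate missing from sidecar")
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("header error: empty recording file")
  chn <- setdiff(names(df), "time")
  sig <- t(as.matrix(df[, chn, drop = FALSE]))
  meta <- as.data.frame(hdr$channels, stringsAsFactors = FALSE)
  meta <- meta[match(chn, meta$name), , drop = FALSE]
  if (anyNA(meta$role))
    stop("header error: sidecar lacks role for some channel(s)")
  st <- if (!is.null(hdr$start_time))
    as.POSIXct(hdr$start_time, tz = "UTC")
  else as.POSIXct(format(Sys.Date()), tz = "UTC")
  recording(sig, hdr$fs, meta, st)
}

write_recording_csv <- function(rec, path) {
  n <- ncol(rec$signal)
  df <- data.frame(time = (seq_len(n) - 1L) / rec$fs)
  for (k in seq_len(nrow(rec$signal)))
    df[[rec$channels$name[k]]] <- rec$signal[k, ]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs,
         channels = rec$channels,
         start_time = format(rec$start_time, "%Y-%m-%d %H:%M:%S")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- EDF ------------------------------------------------------------------

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

write_edf <- function(rec, path) {
  fs <- rec$fs
  rec_dur <- NA
  for (d in c(1, 2, 5, 10)) {
    if (abs(fs * d - round(fs * d)) < 1e-9) { rec_dur <- d; break }
  }
  if (is.na(rec_dur))
    stop("EDF requires an integer number of samples per record; ",
         "fs = ", fs, " has none up to 10 s records — use CSV")
  spr <- round(fs * rec_dur)
  n <- ncol(rec$signal)
  n_rec <- floor(n / spr)
  if (n_rec < 1) stop("recording shorter than one EDF record")
  ns <- nrow(rec$signal)
  pmin_ <- pmax_ <- numeric(ns)
  for (k in seq_len(ns)) {
    r <- max(abs(rec$signal[k, ]), 1e-12)
    pmin_[k] <- -r; pmax_[k] <- r
  }
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  put(pad("0", 8))
  put(pad("X X X X", 80))
  put(pad("Startdate X X X X", 80))
  put(pad(format(rec$start_time, "%d.%m.%y"), 8))
  put(pad(format(rec$start_time, "%H.%M.%S"), 8))
  put(pad(256 * (ns + 1L), 8))
  put(pad("", 44))
  put(pad(n_rec, 8))
  put(pad(format(rec_dur, trim = TRUE), 8))
  put(pad(ns, 4))
  lab <- sprintf("%s %s", rec$channels$role, rec$channels$name)
  put(paste(vapply(lab, pad, "", width = 16), collapse = ""))
  put(paste(rep(pad("", 80), ns), collapse = ""))                 # transducer
  put(paste(rep(pad("uV", 8), ns), collapse = ""))                # dimension
  put(paste(vapply(sprintf("%.6g", pmin_), pad, "", width = 8), collapse = ""))
  put(paste(vapply(sprintf("%.6g", pmax_), pad, "", width = 8), collapse = ""))
  put(paste(rep(pad("-32768", 8), ns), collapse = ""))
  put(paste(rep(pad("32767", 8), ns), collapse = ""))
  put(paste(rep(pad("", 80), ns), collapse = ""))                 # prefilter
  put(paste(rep(pad(spr, 8), ns), collapse = ""))
  put(paste(rep(pad("", 32), ns), collapse = ""))
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * spr + seq_len(spr)
    for (k in seq_len(ns)) {
      dig <- round((rec$signal[k, idx] - pmin_[k]) /
                     (pmax_[k] - pmin_[k]) * 65535 - 32768)
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(nc) {
    raw <- readBin(con, "raw", nc)
    if (length(raw) < nc) stop("format error: truncated EDF header")
    trimws(rawToChar(raw))
  }
  get(8)                                         # version
  get(80); get(80)
  d <- get(8); tm <- get(8)
  get(8)                                         # header bytes
  get(44)
  n_rec <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  ns <- as.integer(get(4))
  if (!length(ns) || is.na(ns) || ns < 1)
    stop("header error: invalid signal count")
  lab <- vapply(seq_len(ns), function(i) get(16), "")
  for (i in seq_len(ns)) get(80)
  for (i in seq_len(ns)) get(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) get(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) get(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) get(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) get(8), ""))
  for (i in seq_len(ns)) get(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) get(8), ""))
  for (i in seq_len(ns)) get(32)
  if (anyNA(c(n_rec, rec_dur, spr)) || rec_dur <= 0)
    stop("header error: missing sampling information")
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[k], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[k]) stop("format error: truncated EDF data")
      phys <- pmin_[k] + (dig - dmin_[k]) /
        (dmax_[k] - dmin_[k]) * (pmax_[k] - pmin_[k])
      sig[k, (r - 1L) * spr[k] + seq_len(spr[k])] <- phys
    }
  }
  role <- sub(" .*", "", lab)
  role[!role %in% c("EEG", "EMG", "REF")] <- "EEG"
  nm <- sub("^[A-Z]+ ?", "", lab)
  nm[nm == ""] <- paste0("ch", seq_len(ns))[nm == ""]
  st <- tryCatch(
    as.POSIXct(paste(d, tm), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NA)
  if (is.na(st)) st <- as.POSIXct(format(Sys.Date()), tz = "UTC")
  recording(sig, spr[1L] / rec_dur,
            data.frame(name = nm, role = role, stringsAsFactors = FALSE),
            st)
}

# ---- resampling -----------------------------------------------------------

#' Downsample a recording
#'
#' Zero-phase anti-alias filtering (8th-order Butterworth at 45% of the
#' target rate, applied forward and backward) followed by cubic-spline
#' interpolation onto the exact target grid, so arbitrary (even
#' irrational) rate ratios are supported and total duration is preserved
#' within one output sample.
#'
#' @param rec a [recording()].
#' @param target_fs target rate, Hz (<= `rec$fs`).
#' @return a [recording()] at `target_fs`.
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs > rec$fs)
    stop("upsampling error: target_fs exceeds the recording rate")
  if (target_fs == rec$fs) return(rec)
  n_in <- ncol(rec$signal)
  t_in <- (seq_len(n_in) - 1L) / rec$fs
  n_out <- floor((n_in - 1L) / rec$fs * target_fs) + 1L
  t_out <- (seq_len(n_out) - 1L) / target_fs
  bf <- signal::butter(8, 0.45 * target_fs / (rec$fs / 2), type = "low")
  out <- matrix(0, nrow = nrow(rec$signal), ncol = n_out)
  for (k in seq_len(nrow(rec$signal))) {
    xf <- signal::filtfilt(bf, rec$signal[k, ])
    out[k, ] <- stats::spline(t_in, xf, xout = t_out)$y
  }
  recording(out, target_fs, rec$channels, rec$start_time)
}

# ---- labels ---------------------------------------------------------------

#' Write a label sequence to a plain-text file (one byte per epoch)
#'
#' The payload is newline-free: exactly one ASCII character per epoch.
#' A sequence containing the development-only 'U' is written, with a
#' warning, since 'U' should not appear in a final list.
#'
#' @param labels a [label_sequence()] or character vector.
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  lab <- if (inherits(labels, "label_sequence")) labels$labels else labels
  bad <- setdiff(unique(lab), names(label_alphabet))
  if (length(bad))
    stop("label error: characters outside the alphabet: ",
         paste(bad, collapse = ", "))
  if (any(lab == "U"))
    warning("label sequence contains unscored 'U' epochs")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste(lab, collapse = ""), con, eos = NULL)
  invisible(path)
}

#' Read a label sequence from a plain-text file
#'
#' @param path label file (one character per epoch, no newlines).
#' @param epoch_len epoch length in seconds to attach (default 1).
#' @return a [label_sequence()].
#' @export
read_labels <- function(path, epoch_len = 1) {
  raw <- readBin(path, "raw", file.info(path)$size)
  txt <- rawToChar(raw)
  txt <- gsub("[\r\n]", "", txt)
  lab <- strsplit(txt, "")[[1L]]
  bad <- setdiff(unique(lab), names(label_alphabet))
  if (length(bad))
    stop("label error: foreign character(s) in label file: ",
         paste(bad, collapse = ", "))
  label_sequence(lab, epoch_len)
}
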