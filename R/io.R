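# Readers and writers: tab-separated matrix recordings, a minimal EDF
# (European Data Format) codec, timeline event files, YAML pipeline
# configuration, and report export.

#' Read a multichannel recording
#'
#' Supports two formats: a tab-separated matrix (one row per channel,
#' optional leading header line `# fs=<Hz> channels=<a,b,...>`) and 16-bit
#' EDF (European Data Format), honoring per-channel physical scaling.
#' Format is inferred from the file when `format = "auto"` (EDF files start
#' with an 8-byte version field of `"0"`).
#'
#' @param path File path.
#' @param format `"auto"`, `"delimited"` or `"edf"`.
#' @param sample_rate Fallback sampling rate (Hz) for delimited files
#'   without a header line.
#' @return A [multichannel_signal()] with attribute `metadata` (list:
#'   `subject`, `sample_rate`, `channel_names`, `n_samples`, `source`).
#' @export
read_recording <- function(path, format = c("auto", "delimited", "edf"),
                           sample_rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    head8 <- readBin(path, "raw", 8L)
    format <- if (identical(rawToChar(head8), "0       ")) "edf" else "delimited"
  }
  if (format == "edf") return(read_edf(path))
  lines <- readLines(path)
  if (!length(lines)) stop("parse error: empty recording file ", path)
  fs <- sample_rate
  ch_names <- NULL
  if (startsWith(lines[1], "#")) {
    hdr <- lines[1]
    m <- regmatches(hdr, regexec("fs=([0-9.eE+-]+)", hdr))[[1]]
    if (length(m) == 2L) fs <- as.numeric(m[2])
    m <- regmatches(hdr, regexec("channels=([^ ]+)", hdr))[[1]]
    if (length(m) == 2L) ch_names <- strsplit(m[2], ",")[[1]]
    lines <- lines[-1L]
  }
  if (is.null(fs))
    stop("parse error: no sampling rate in header and none supplied")
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], "\t", fixed = TRUE)[[1]]))
    if (any(is.na(v)))
      stop(sprintf("parse error in %s at line %d: non-numeric field", path, i))
    v
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("parse error: rows of ", path, " have unequal lengths")
  data <- do.call(rbind, rows)
  sig <- multichannel_signal(data, fs, ch_names)
  attr(sig, "metadata") <- list(subject = basename(path), sample_rate = fs,
                                channel_names = sig$channel_names,
                                n_samples = ncol(data), source = "delimited")
  sig
}

#' @rdname read_recording
#' @param signal A [multichannel_signal()] to write.
#' @param header Write the `# fs=... channels=...` header line.
#' @export
write_recording <- function(signal, path, header = TRUE) {
  stopifnot(inherits(signal, "multichannel_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header)
    writeLines(sprintf("# fs=%.10g channels=%s", signal$sample_rate,
                       paste(signal$channel_names, collapse = ",")), con)
  utils::write.table(format(signal$data, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Minimal EDF reader and writer
#'
#' Reads 16-bit EDF recordings: the fixed 256-byte header, the per-signal
#' header block, and little-endian integer data records mapped to physical
#' units via each channel's digital/physical calibration. All channels must
#' share one sampling rate (equal samples-per-record); annotations channels
#' are not supported. `write_edf()` produces a single-record EDF file and
#' exists mainly to build round-trip fixtures in code (EDF is binary, so no
#' fixture files are shipped).
#'
#' @param path File path.
#' @return `read_edf()`: a [multichannel_signal()] with `metadata`
#'   attribute.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  version <- trimws(rd(8))
  patient <- trimws(rd(80)); recording <- trimws(rd(80))
  rd(8); rd(8)                           # start date, time
  rd(8)                                  # header bytes
  rd(44)                                 # reserved
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1L) stop("parse error: bad EDF signal count")
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), character(1))
  labels <- fld(16); fld(80); fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates in EDF (unequal samples per record) are not supported")
  if (rec_dur <= 0) stop("parse error: non-positive EDF record duration")
  fs <- spr[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[1], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) != spr[1]) stop("parse error: truncated EDF record ", r)
      cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
      data[s, cols] <- phys_min[s] + (dig - dig_min[s]) * gain[s]
    }
  }
  sig <- multichannel_signal(data, fs, labels)
  attr(sig, "metadata") <- list(subject = patient, recording = recording,
                                sample_rate = fs, channel_names = labels,
                                n_samples = ncol(data), source = "edf",
                                version = version)
  sig
}

#' @rdname read_edf
#' @param signal A [multichannel_signal()]; samples per channel must be an
#'   integer count.
#' @param subject,recording Free-text header fields.
#' @export
write_edf <- function(signal, path, subject = "X", recording = "synthetic") {
  stopifnot(inherits(signal, "multichannel_signal"))
  C <- n_channels(signal); T <- n_samples(signal)
  rng <- max(abs(signal$data), 1e-12)
  phys_min <- -rng; phys_max <- rng
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(.edf_pad(x, w)), con)
  wr("0", 8); wr(subject, 80); wr(recording, 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (C + 1L), 8); wr("", 44)
  wr(1L, 8)                                        # one data record
  wr(format(T / signal$sample_rate, digits = 8), 8)
  wr(C, 4)
  for (nm in signal$channel_names) wr(nm, 16)
  for (i in seq_len(C)) wr("", 80)
  for (i in seq_len(C)) wr("uV", 8)
  for (i in seq_len(C)) wr(format(phys_min, digits = 7), 8)
  for (i in seq_len(C)) wr(format(phys_max, digits = 7), 8)
  for (i in seq_len(C)) wr(dig_min, 8)
  for (i in seq_len(C)) wr(dig_max, 8)
  for (i in seq_len(C)) wr("", 80)
  for (i in seq_len(C)) wr(T, 8)
  for (i in seq_len(C)) wr("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (k in seq_len(C)) {
    dig <- round((signal$data[k, ] - phys_min) / gain + dig_min)
    dig <- as.integer(pmin(pmax(dig, dig_min), dig_max))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Anti-aliased sampling-rate conversion
#'
#' Polyphase FIR resampling (via [signal::resample()]) to a new rate; a
#' pure tone below the new Nyquist keeps its frequency.
#'
#' @param signal A [multichannel_signal()].
#' @param target_hz Target sampling rate (> 0).
#' @return A resampled [multichannel_signal()].
#' @export
resample_signal <- function(signal, target_hz) {
  stopifnot(inherits(signal, "multichannel_signal"))
  if (target_hz <= 0) stop("target_hz must be > 0")
  if (isTRUE(all.equal(target_hz, signal$sample_rate)))
    return(signal)
  r <- round(c(target_hz, signal$sample_rate) * 1e6)
  g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  d <- g(r[1], r[2])
  p <- r[1] / d; q <- r[2] / d
  out <- t(apply(signal$data, 1L, function(x) signal::resample(x, p, q)))
  multichannel_signal(out, target_hz, signal$channel_names)
}

#' Timeline event files
#'
#' Tab-separated event files with columns `event_type` (`onset` or
#' `label`), `timestamp_seconds` and `value`, plus a `# span=start,end`
#' header line.
#'
#' @param timeline A [seizure_timeline()].
#' @param path File path.
#' @export
write_timeline <- function(timeline, path) {
  stopifnot(inherits(timeline, "seizure_timeline"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# span=%.10g,%.10g", timeline$span[1], timeline$span[2]), con)
  writeLines("event_type\ttimestamp_seconds\tvalue", con)
  for (o in timeline$onsets)
    writeLines(sprintf("onset\t%.10g\t1", o), con)
  writeLines(sprintf("label\t%.10g\t%d", timeline$sample_times, timeline$labels), con)
  invisible(path)
}

#' @rdname write_timeline
#' @return `read_timeline()`: a [seizure_timeline()].
#' @export
read_timeline <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  span <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("span=([0-9.eE+-]+),([0-9.eE+-]+)", lines[1]))[[1]]
    if (length(m) == 3L) span <- as.numeric(m[2:3])
    lines <- lines[-1L]
  }
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("event_type", "timestamp_seconds", "value") %in% names(df)))
    stop("parse error: timeline file needs event_type/timestamp_seconds/value columns")
  lab <- df[df$event_type == "label", , drop = FALSE]
  ons <- df[df$event_type == "onset", , drop = FALSE]
  seizure_timeline(lab$timestamp_seconds, lab$value,
                   onsets = ons$timestamp_seconds, span = span)
}

#' Read a YAML pipeline configuration
#'
#' Assembles typed configuration objects from a YAML file with optional
#' sections `decomposition`, `removal_bands` (list of `[low, high]` Hz
#' pairs), `stft`, `alarm`, `simulate` and a top-level `seed`. Missing
#' sections fall back to package defaults.
#'
#' @param path YAML file path.
#' @return List with `decomposition` ([svmd_config()]), `band`
#'   ([removal_band()]), `stft` ([stft_config()]), `alarm`
#'   ([alarm_config()]), `seed` and the raw `simulate` section.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  build <- function(fn, args) do.call(fn, args[names(args) %in% names(formals(fn))])
  list(
    decomposition = build(svmd_config, as.list(y$decomposition)),
    band = if (length(y$removal_bands))
      removal_band(lapply(y$removal_bands, as.numeric)) else removal_band(),
    stft = build(stft_config, as.list(y$stft)),
    alarm = build(alarm_config, as.list(y$alarm)),
    seed = if (is.null(y$seed)) 1L else as.integer(y$seed),
    simulate = y$simulate
  )
}

#' Export a performance report
#'
#' @param report A `performance_report` (or compatible named list).
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  vals <- report[c("sensitivity", "fpr", "n_seizures", "n_predicted",
                   "n_false_alarms", "interictal_hours", "p_value")]
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (format == "json") {
    jsonlite::write_json(lapply(vals, as.numeric), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(
      data.frame(metric = names(vals), value = unlist(lapply(vals, as.numeric))),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
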