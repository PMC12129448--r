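# Minimal IEEE-float WAV read/write (format code 3, mono). Written in-package
# because the pipeline's session layout stores ear-canal pressure in Pa, which
# integer PCM would clip or quantize.

#' Write / read a mono 32-bit float WAV file
#'
#' @param x numeric waveform (Pa; stored as IEEE float32, no scaling)
#' @param path file path
#' @param fs sampling rate (Hz)
#' @return `readWavFloat()`: list(wave, fs)
#' @export
writeWavFloat <- function(x, path, fs) {
  con <- file(path, "wb")
  on.exit(close(con))
  nBytes <- 4L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + nBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")            # IEEE float
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nBytes, con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname writeWavFloat
#' @export
readWavFloat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fs <- NA_real_; fmt <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, raw(), n = sz - 8)
    } else if (id == "data") {
      if (fmt != 3L) stop("only IEEE-float WAV is supported")
      wave <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
      return(list(wave = wave, fs = fs))
    } else readBin(con, raw(), n = sz)
  }
}

#' Write / read a recording session as WAV files plus a JSON sidecar
#'
#' The on-disk layout is `{session}_{condition}_{rep}.wav` (condition in
#' probe/suppressor/both, float PCM at the session rate) plus `session.json`
#' holding the sweep specifications and, for synthetic sessions, the ground
#' truth.
#'
#' @param session a [RecordingSession-class]
#' @param dir output directory (created if needed)
#' @return `readRecordingSession()`: a [RecordingSession-class]
#' @export
writeRecordingSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  name <- session@metadata$session %||% "session"
  for (cond in c("probe", "suppressor", "both")) {
    w <- session@waveforms[[cond]]
    for (r in seq_len(ncol(w)))
      writeWavFloat(w[, r], file.path(dir, sprintf("%s_%s_%03d.wav", name, cond, r)),
                    session@fs)
  }
  sweeps <- lapply(session@sweeps, function(s)
    list(f_start = s@fStart, f_end = s@fEnd, duration = s@duration,
         level = s@level, ramp = s@ramp, fs = s@fs))
  jsonlite::write_json(list(session = name, fs = session@fs, sweeps = sweeps,
                            n_reps = ncol(session@waveforms$probe),
                            truth = session@metadata$truth),
                       file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeRecordingSession
#' @export
readRecordingSession <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"), simplifyVector = TRUE)
  sweeps <- lapply(meta$sweeps, function(s)
    sweepSpec(s$f_start, s$f_end, s$duration, s$level, s$ramp, s$fs))
  waveforms <- lapply(stats::setNames(nm = c("probe", "suppressor", "both")),
    function(cond) {
      files <- sort(list.files(dir, sprintf("^%s_%s_\\d+\\.wav$", meta$session, cond),
                               full.names = TRUE))
      if (!length(files)) stop("no WAV files for condition ", cond, " in ", dir)
      do.call(cbind, lapply(files, function(f) readWavFloat(f)$wave))
    })
  new("RecordingSession", waveforms = waveforms, sweeps = sweeps,
      fs = meta$fs, metadata = list(session = meta$session, truth = meta$truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
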