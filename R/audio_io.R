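#' Construct an audio recording
#'
#' Container for a mono auscultation waveform. Samples are dimensionless
#' amplitudes, nominally in \[-1, 1\]; `rate` is the sampling rate in Hz.
#'
#' @param samples numeric vector of amplitudes.
#' @param rate sampling rate in Hz (> 0).
#' @return An object of class `audio_recording` with fields `samples`,
#'   `rate`, `n_samples`.
#' @export
audio_recording <- function(samples, rate) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (length(samples) == 0L) stop("zero-length audio")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  structure(
    list(samples = as.double(samples), rate = as.double(rate),
         n_samples = length(samples)),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %d samples @ %g Hz (%.3f s)\n",
              x$n_samples, x$rate, duration_seconds(x)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `audio_recording`.
#' @return duration in seconds.
#' @export
duration_seconds <- function(rec) rec$n_samples / rec$rate

# ---- RIFF/WAVE I/O -------------------------------------------------------
# Minimal RIFF reader/writer for mono PCM16/PCM24/float32. Chunk walk is
# defensive: unknown chunks are skipped, "fmt " and "data" are required.

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file (PCM 16/24-bit or IEEE float32). Integer PCM is
#' scaled to \[-1, 1\] by the type's full scale (2^15 or 2^23). Multi-channel
#' files are rejected by default or averaged down to mono.
#'
#' @param path path to a WAV file.
#' @param downmix one of `"reject"` (default) or `"mean"`: policy for
#'   multi-channel files.
#' @return An [audio_recording()].
#' @export
read_wav <- function(path, downmix = c("reject", "mean")) {
  downmix <- match.arg(downmix)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate         = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1)  # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("missing fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0L) stop("zero-length audio: ", path)

  # 0xFFFE = WAVE_FORMAT_EXTENSIBLE; sub-format is assumed to match bits
  if (!fmt$audio_format %in% c(1L, 3L, 65534L))
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")")

  nch <- fmt$n_channels
  x <- if (fmt$audio_format == 3L || (fmt$audio_format == 65534L && fmt$bits == 32L)) {
    if (fmt$bits != 32L) stop("unsupported float bit depth: ", fmt$bits)
    readBin(data_raw, "double", length(data_raw) / 4L, 4L, endian = "little")
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2L, 2L, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    n <- length(data_raw) / 3L
    b <- matrix(as.integer(data_raw), nrow = 3L)
    v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits)
  }

  if (nch > 1L) {
    if (downmix == "reject")
      stop("multi-channel WAV (", nch, " channels); pass downmix = \"mean\" to average")
    x <- colMeans(matrix(x, nrow = nch))
  }
  audio_recording(x, fmt$rate)
}

#' Write a WAV file
#'
#' Writes a mono recording as RIFF/WAVE. `format = "float32"` (default)
#' round-trips samples bitwise; `"pcm16"`/`"pcm24"` quantize.
#'
#' @param rec an [audio_recording()].
#' @param path output path.
#' @param format one of `"float32"`, `"pcm16"`, `"pcm24"`.
#' @param clip if `TRUE` (default) out-of-range samples are clipped to
#'   \[-1, 1\]; if `FALSE` they raise an error.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, format = c("float32", "pcm16", "pcm24"),
                      clip = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "audio_recording"))
  x <- rec$samples
  if (any(!is.finite(x))) stop("non-finite samples")
  if (any(x < -1 | x > 1)) {
    if (!clip) stop("samples outside [-1, 1] and clip = FALSE")
    x <- pmin(1, pmax(-1, x))
  }

  bits <- switch(format, float32 = 32L, pcm16 = 16L, pcm24 = 24L)
  fmt_tag <- if (format == "float32") 3L else 1L
  bytes_per <- bits %/% 8L
  data_size <- length(x) * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(fmt_tag, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                       # mono
  writeBin(as.integer(rec$rate), con, 4L, endian = "little")
  writeBin(as.integer(rec$rate * bytes_per), con, 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, 2L, endian = "little")
  writeBin(bits, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")

  if (format == "float32") {
    writeBin(x, con, 4L, endian = "little")
  } else if (format == "pcm16") {
    q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
    writeBin(q, con, 2L, endian = "little")
  } else {
    q <- pmin(8388607, pmax(-8388608, round(x * 8388608)))
    q <- ifelse(q < 0, q + 16777216, q)
    b <- rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  }
  if (data_size %% 2L == 1L) writeBin(as.raw(0L), con)
  invisible(path)
}

#' Trim the edges of an auscultation recording
#'
#' The contact sensor of the stethoscope marks the auscultation start and
#' end; the samples immediately adjacent to those transitions are
#' excluded (default 0.2 s on each side). Trimming is performed in whole
#' samples, `round(edge_s * rate)` per side, so section lengths are exact.
#'
#' @param rec an [audio_recording()].
#' @param edge_s seconds excluded at each edge (default 0.2).
#' @return An object of class `auscultation_section`: fields `parent`,
#'   `start_s`, `end_s`, `samples` (the trimmed waveform) and `rate`.
#' @export
trim_auscultation <- function(rec, edge_s = 0.2) {
  stopifnot(inherits(rec, "audio_recording"), edge_s >= 0)
  edge_n <- round(edge_s * rec$rate)
  if (rec$n_samples <= 2 * edge_n)
    stop(sprintf("trial too short: %.3f s recording cannot lose 2 x %.3f s edges",
                 duration_seconds(rec), edge_s))
  idx <- if (edge_n > 0) (edge_n + 1):(rec$n_samples - edge_n) else seq_len(rec$n_samples)
  structure(
    list(parent = rec,
         start_s = edge_n / rec$rate,
         end_s = (rec$n_samples - edge_n) / rec$rate,
         samples = rec$samples[idx],
         rate = rec$rate),
    class = "auscultation_section"
  )
}

#' @export
print.auscultation_section <- function(x, ...) {
  cat(sprintf("<auscultation_section> [%.3f, %.3f] s of a %.3f-s recording (%d samples)\n",
              x$start_s, x$end_s, duration_seconds(x$parent), length(x$samples)))
  invisible(x)
}

# Coerce a bare recording to a full (untrimmed) section; internal.
as_section <- function(x) {
  if (inherits(x, "auscultation_section")) return(x)
  trim_auscultation(x, edge_s = 0)
}
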