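#' Construct an audio clip
#'
#' A lightweight container for a mono speech clip: the sample vector, its
#' sampling rate, a speaker identifier, and an optional categorical emotion
#' label.  All feature extraction and model code operates on these objects.
#'
#' @param samples Numeric vector of amplitudes (dimensionless). Must be
#'   non-empty and finite.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @param speaker_id Opaque speaker identifier (coerced to character).
#' @param label Optional emotion label (character scalar or `NA`).
#' @param clip_id Opaque clip identifier; defaults to an anonymous id.
#' @return An object of class `audio_clip`.
#' @examples
#' clip <- audio_clip(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)),
#'                    sample_rate = 8000, speaker_id = "s1")
#' clip
#' @export
audio_clip <- function(samples, sample_rate, speaker_id = "unknown",
                       label = NA_character_, clip_id = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    rlang::abort("`samples` must be non-empty.", class = "resemote_empty_clip")
  }
  if (!all(is.finite(samples))) {
    rlang::abort("`samples` must be finite.", class = "resemote_bad_clip")
  }
  sample_rate <- as.numeric(sample_rate)
  stopifnot(length(sample_rate) == 1L, sample_rate > 0)
  structure(
    list(
      samples = samples,
      sample_rate = sample_rate,
      speaker_id = as.character(speaker_id),
      label = as.character(label),
      clip_id = if (is.null(clip_id)) "clip" else as.character(clip_id)
    ),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf(
    "<audio_clip %s> %.3f s @ %g Hz, speaker %s, label %s\n",
    x$clip_id, length(x$samples) / x$sample_rate, x$sample_rate,
    x$speaker_id, x$label
  ))
  invisible(x)
}

#' Clip duration in seconds
#' @param clip An [audio_clip()].
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

#' Resample a clip to a target rate
#'
#' Clips are brought to a common rate (16 kHz by default, the native rate of
#' the Emo-DB corpus) before framing so that the Mel filterbank covers the
#' same frequency range for every input.
#'
#' @param clip An [audio_clip()].
#' @param rate Target sampling rate in Hz.
#' @return An [audio_clip()] at `rate`.
#' @export
resample_clip <- function(clip, rate = 16000) {
  if (clip$sample_rate == rate) return(clip)
  p <- rate
  q <- clip$sample_rate
  g <- gcd_int(round(p), round(q))
  y <- signal::resample(clip$samples, p = round(p) / g, q = round(q) / g)
  audio_clip(y, rate, clip$speaker_id, clip$label, clip$clip_id)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# ---- minimal RIFF/WAVE reader and writer -----------------------------------
# PCM 16-bit and IEEE float32, mono or stereo (stereo is downmixed by
# averaging the two channels).  Only the canonical little-endian layout is
# supported; that covers Emo-DB and everything this package writes.

#' Read a WAV file into an audio clip
#'
#' Supports PCM 16-bit and IEEE float 32-bit RIFF/WAVE files; stereo input is
#' downmixed to mono by averaging channels.  Samples are returned in
#' \[-1, 1\] for PCM input.
#'
#' @param path Path to a `.wav` file.
#' @param speaker_id,label,clip_id Metadata attached to the returned clip;
#'   `clip_id` defaults to the file name.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path, speaker_id = "unknown", label = NA_character_,
                     clip_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    rlang::abort(sprintf("'%s' is not a RIFF/WAVE file.", path),
                 class = "resemote_wav_error")
  }
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    rlang::abort(sprintf("'%s' is not a RIFF/WAVE file.", path),
                 class = "resemote_wav_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format = rawpair_to_int(body[1:2]),
        channels = rawpair_to_int(body[3:4]),
        rate = raw4_to_int(body[5:8]),
        bits = rawpair_to_int(body[15:16])
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    rlang::abort(sprintf("'%s': missing fmt or data chunk.", path),
                 class = "resemote_wav_error")
  }
  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2L, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", length(data_raw) / 4L, size = 4,
                 endian = "little")
  } else {
    rlang::abort(sprintf(
      "'%s': unsupported WAV encoding (format %d, %d bits).",
      path, fmt$format, fmt$bits
    ), class = "resemote_wav_error")
  }
  if (fmt$channels == 2L) {
    x <- (x[seq(1, length(x), by = 2)] + x[seq(2, length(x), by = 2)]) / 2
  } else if (fmt$channels != 1L) {
    rlang::abort(sprintf("'%s': %d channels unsupported.", path, fmt$channels),
                 class = "resemote_wav_error")
  }
  audio_clip(x, fmt$rate, speaker_id, label,
             clip_id = if (is.null(clip_id)) basename(path) else clip_id)
}

rawpair_to_int <- function(r) as.integer(r[1]) + 256L * as.integer(r[2])
raw4_to_int <- function(r) sum(as.numeric(r) * 256^(0:3))

#' Write an audio clip to a PCM 16-bit WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16 bits.
#'
#' @param clip An [audio_clip()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  x <- pmax(pmin(clip$samples, 1), -1)
  pcm <- as.integer(pmin(round(x * 32768), 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(clip$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
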