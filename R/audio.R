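#' Mono audio buffer
#'
#' PCM samples normalised to [-1, 1] at a fixed sample rate. Only mono audio
#' is accepted; stereo recordings must be down-mixed explicitly by the caller
#' (no silent channel selection).
#'
#' @param samples numeric vector of amplitudes in [-1, 1]
#' @param sample_rate sampling rate in Hz (default 16000)
#' @return an `audio_buffer`
#' @export
audio_buffer <- function(samples, sample_rate = 16000) {
  if (!is.numeric(samples)) stop_input("samples must be numeric")
  if (!is_scalar_num(sample_rate) || sample_rate <= 0)
    stop_input("sample_rate must be > 0")
  if (any(!is.finite(samples))) stop_input("samples must all be finite")
  if (length(samples) && max(abs(samples)) > 1 + 1e-9)
    stop_input("samples must lie in [-1, 1]")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 channels = 1L),
            class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer %d samples @ %g Hz (%.2f s)>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Read a mono WAV file
#'
#' Supports uncompressed RIFF/WAVE with 16-bit integer PCM (format 1) or
#' 32-bit float (format 3) samples. Multichannel files are rejected with an
#' instruction to down-mix; see [audio_buffer()].
#'
#' @param path path to a .wav file
#' @return an [audio_buffer()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_input(path, ": not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_input(path, ": not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format = sum(as.integer(fmt_raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(fmt_raw[3:4]) * c(1, 256)),
        rate = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(fmt_raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop_input(path, ": missing fmt/data chunk")
  if (fmt$channels != 1)
    stop_input(path, ": has ", fmt$channels,
               " channels; down-mix to mono before reading")
  if (fmt$format == 1 && fmt$bits == 16) {
    s <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3 && fmt$bits == 32) {
    s <- readBin(data_raw, "numeric", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop_input(path, ": unsupported WAV encoding (format ", fmt$format,
               ", ", fmt$bits, " bit)")
  }
  audio_buffer(pmin(1, pmax(-1, s)), fmt$rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param audio an [audio_buffer()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "audio_buffer"))
  s <- as.integer(pmin(32767, pmax(-32768, round(audio$samples * 32768))))
  n <- length(s)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + 2 * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(1); w16(1); w32(audio$sample_rate); w32(audio$sample_rate * 2)
  w16(2); w16(16)
  writeChar("data", con, eos = NULL); w32(2 * n)
  writeBin(s, con, 2, endian = "little")
  invisible(path)
}
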