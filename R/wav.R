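#' Write an audio buffer as mono 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE writer (mono, 16-bit little-endian PCM). Samples are
#' quantized as `round(s * 32767)` clamped to the int16 range, so a read-back
#' differs from the input by at most `1/32767`. Identical buffers produce
#' byte-identical files.
#'
#' @param buffer an `audio_buffer` (see [render_fm()]).
#' @param path output `.wav` path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(buffer, path) {
  s <- buffer$samples
  if (any(!is.finite(s))) stop("audio samples must be finite")
  q <- as.integer(pmin(pmax(round(s * 32767), -32768), 32767))
  n <- length(q)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36L + 2L * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L)                      # PCM fmt chunk size
  w16(1L)                       # audio format: PCM
  w16(1L)                       # channels: mono
  w32(buffer$sample_rate_hz)
  w32(buffer$sample_rate_hz * 2L)  # byte rate
  w16(2L)                       # block align
  w16(16L)                      # bits per sample
  writeChar("data", con, eos = NULL)
  w32(2L * n)
  w16(q)
  invisible(path)
}

#' Read a mono 16-bit PCM WAV written by [write_wav()]
#'
#' @param path `.wav` path.
#' @return An `audio_buffer` with samples on the `[-1, 1]` scale
#'   (`int16 / 32767`).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r16 <- function(nn = 1L) readBin(con, "integer", n = nn, size = 2L,
                                   endian = "little", signed = TRUE)
  r32 <- function(nn = 1L) readBin(con, "integer", n = nn, size = 4L,
                                   endian = "little")
  if (readChar(con, 4L) != "RIFF") stop("not a RIFF file: ", path)
  r32()
  if (readChar(con, 4L) != "WAVE") stop("not a WAVE file: ", path)
  sr <- NA_integer_
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    size <- r32()
    if (id == "fmt ") {
      fmt <- r16(); ch <- r16(); sr <- r32(); r32(); r16(); bits <- r16()
      if (fmt != 1L || ch != 1L || bits != 16L)
        stop("only mono 16-bit PCM WAV is supported")
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (id == "data") {
      q <- r16(size %/% 2L)
      break
    } else {
      readBin(con, "raw", n = size)
    }
  }
  structure(list(samples = q / 32767, sample_rate_hz = sr),
            class = "audio_buffer")
}
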