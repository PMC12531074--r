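# Minimal RIFF/WAVE I/O (32-bit IEEE float and 16-bit PCM). The R stack this
# package targets ships no WAV package, and the format subset needed here --
# canonical fmt + data chunks, multichannel, 48 kHz -- is small enough to
# read and write directly.

#' Write a multichannel recording as a WAV file
#'
#' @param audio a [multichannel_audio()].
#' @param path output path.
#' @param format `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly. The channel map is not stored in the file; keep
#'   it alongside (see [write_channel_map()]).
#' @export
write_wav <- function(audio, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  x <- audio$samples
  nch <- ncol(x); nsamp <- nrow(x)
  bits <- if (format == "float32") 32L else 16L
  block <- nch * bits %/% 8L
  data_bytes <- nsamp * block
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(if (format == "float32") 3L else 1L, nch), con, size = 2, endian = "little")
  writeBin(as.integer(c(audio$sr, audio$sr * block)), con, size = 4, endian = "little")
  writeBin(c(as.integer(block), bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  inter <- as.numeric(t(x))           # interleave channels
  if (format == "float32") {
    writeBin(inter, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(pmax(-32768, pmin(32767, round(inter * 32767)))),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file into a multichannel recording
#'
#' Supports 32-bit IEEE float and 16-bit PCM. If `channels` is omitted the
#' channel map is filled with placeholder participant ids.
#'
#' @param path WAV file path.
#' @param channels optional channel-map data.frame (participant, role).
#' @return a [multichannel_audio()].
#' @export
read_wav <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  stop_if(readChar(con, 4) != "RIFF", "%s: not a RIFF file", path)
  readBin(con, integer(), size = 4, endian = "little")
  stop_if(readChar(con, 4) != "WAVE", "%s: not a WAVE file", path)
  fmt <- NULL; dat <- NULL
  while (length(id <- readChar(con, 4)) == 1 && nchar(id) == 4) {
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little", signed = FALSE),
        nch = readBin(con, integer(), size = 2, endian = "little"),
        sr = readBin(con, integer(), size = 4, endian = "little"))
      readBin(con, integer(), size = 4, endian = "little")  # byte rate
      readBin(con, integer(), size = 2, endian = "little")  # block align
      fmt$bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16L)
    } else if (id == "data") {
      stop_if(is.null(fmt), "%s: data chunk before fmt chunk", path)
      if (fmt$code == 3L && fmt$bits == 32L) {
        dat <- readBin(con, numeric(), n = sz %/% 4L, size = 4, endian = "little")
      } else if (fmt$code == 1L && fmt$bits == 16L) {
        dat <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                       endian = "little", signed = TRUE) / 32767
      } else {
        stop_if(TRUE, "%s: unsupported WAV encoding (format %d, %d bits)",
                path, fmt$code, fmt$bits)
      }
    } else {
      readBin(con, raw(), n = sz + sz %% 2L)
    }
  }
  stop_if(is.null(dat), "%s: no data chunk", path)
  x <- matrix(dat, ncol = fmt$nch, byrow = TRUE)
  if (is.null(channels)) {
    channels <- data.frame(participant = paste0("ch", seq_len(fmt$nch)),
                           role = "close_mouth")
  }
  multichannel_audio(x, fmt$sr, channels)
}

#' Write / read a channel map as CSV
#'
#' @param audio a [multichannel_audio()] (for writing).
#' @param path CSV path.
#' @return the channel-map data.frame.
#' @export
write_channel_map <- function(audio, path) {
  write.csv(audio$channels, path, row.names = FALSE)
  invisible(audio$channels)
}

#' @rdname write_channel_map
#' @export
read_channel_map <- function(path) read.csv(path, stringsAsFactors = FALSE)
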