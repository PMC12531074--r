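#' Multichannel audio container
#'
#' Synchronised per-channel waveforms with a participant-by-microphone channel
#' map. The full rig is 3 participants x 3 microphones (one close-mouth, two
#' in-ear), i.e. a 9-channel recording, but any subset is representable.
#'
#' @param samples numeric matrix, one column per channel.
#' @param sr sample rate in Hz.
#' @param channels data.frame with columns `participant` and
#'   `role` (one of `"close_mouth"`, `"in_ear_L"`, `"in_ear_R"`), one row per
#'   column of `samples`.
#' @param t0 start-time offset in seconds (default 0).
#' @return object of class `multichannel_audio`.
#' @export
multichannel_audio <- function(samples, sr, channels, t0 = 0) {
  samples <- as.matrix(samples)
  stop_if(!is.numeric(samples), "samples must be numeric")
  stop_if(sr <= 0, "sample rate must be > 0")
  stop_if(nrow(channels) != ncol(samples),
          "channel map has %d rows but audio has %d channels",
          nrow(channels), ncol(samples))
  stop_if(!all(c("participant", "role") %in% names(channels)),
          "channel map needs columns participant, role")
  bad <- setdiff(unique(channels$role), c("close_mouth", "in_ear_L", "in_ear_R"))
  stop_if(length(bad) > 0, "unknown microphone role: %s", paste(bad, collapse = ", "))
  structure(list(samples = samples, sr = sr,
                 channels = as.data.frame(channels, stringsAsFactors = FALSE),
                 t0 = t0),
            class = "multichannel_audio")
}

#' @export
print.multichannel_audio <- function(x, ...) {
  cat(sprintf("<multichannel_audio> %d channels, %.2f s @ %d Hz\n",
              ncol(x$samples), nrow(x$samples) / x$sr, as.integer(x$sr)))
  invisible(x)
}

#' Duration of a multichannel recording in seconds
#' @param audio a `multichannel_audio`.
#' @export
audio_duration <- function(audio) nrow(audio$samples) / audio$sr

#' Index of a channel by participant and microphone role
#' @param audio a `multichannel_audio`.
#' @param participant participant id.
#' @param role microphone role.
#' @export
channel_index <- function(audio, participant, role) {
  i <- which(audio$channels$participant == participant & audio$channels$role == role)
  stop_if(length(i) != 1, "channel (%s, %s) not found", participant, role)
  i
}

#' Zero-phase high-pass filtering of conversation audio
#'
#' Removes breathing and handling noise below the cutoff with the squared
#' magnitude response of a 4th-order Butterworth high-pass applied in the
#' frequency domain -- the spectral equivalent of forward-backward
#' (`filtfilt`) filtering, so no group delay shifts interval timing
#' downstream. Channels are processed in complex pairs for speed.
#'
#' @param audio a `multichannel_audio`.
#' @param cutoff_hz high-pass cutoff in Hz (default 100).
#' @param order Butterworth order of the underlying one-pass filter.
#' @return filtered `multichannel_audio`.
#' @export
highpass_filter <- function(audio, cutoff_hz = 100, order = 4) {
  stop_if(cutoff_hz <= 0, "cutoff must be > 0")
  stop_if(cutoff_hz >= audio$sr / 2, "cutoff %.0f Hz is at or above Nyquist", cutoff_hz)
  n <- nrow(audio$samples)
  nfft <- stats::nextn(n + round(audio$sr / 4), c(2, 3, 5))
  f <- c(0:(nfft %/% 2), -((nfft - nfft %/% 2 - 1):1)) * (audio$sr / nfft)
  af <- abs(f)
  # |H|^2 of an order-`order` Butterworth high-pass (zero-phase application)
  resp <- ifelse(af > 0, 1 / (1 + (cutoff_hz / pmax(af, 1e-12))^(2 * order)), 0)
  out <- audio
  nch <- ncol(audio$samples)
  j <- 1L
  while (j <= nch) {
    if (j < nch) {
      z <- complex(real = c(audio$samples[, j], numeric(nfft - n)),
                   imaginary = c(audio$samples[, j + 1], numeric(nfft - n)))
      zf <- stats::fft(stats::fft(z) * resp, inverse = TRUE) / nfft
      out$samples[, j] <- Re(zf)[seq_len(n)]
      out$samples[, j + 1] <- Im(zf)[seq_len(n)]
      j <- j + 2L
    } else {
      z <- c(audio$samples[, j], numeric(nfft - n))
      zf <- Re(stats::fft(stats::fft(z) * resp, inverse = TRUE)) / nfft
      out$samples[, j] <- zf[seq_len(n)]
      j <- j + 1L
    }
  }
  out
}

#' Frame-wise RMS of each channel
#'
#' Splits each channel into rectangular frames (default 20 ms with 50%
#' overlap, i.e. 10-ms hop) and computes the root-mean-square per frame.
#' Frame k covers samples in `[k*hop, k*hop + frame)`; a trailing partial
#' frame is dropped.
#'
#' @param audio a `multichannel_audio`.
#' @param frame_s frame length in seconds (default 0.020).
#' @param hop_s hop in seconds (default `frame_s/2`).
#' @return object of class `frame_series`: list with `t` (frame start times,
#'   s), `rms` (frames x channels, linear), `db` (dB re full scale),
#'   `frame_s`, `hop_s`, and the audio's channel map.
#' @export
compute_frame_rms <- function(audio, frame_s = 0.020, hop_s = frame_s / 2) {
  flen <- round(frame_s * audio$sr)
  hop <- round(hop_s * audio$sr)
  n <- nrow(audio$samples)
  stop_if(n < flen, "audio shorter than one frame")
  nframes <- (n - flen) %/% hop + 1L
  starts <- (seq_len(nframes) - 1L) * hop
  val <- matrix(0, nframes, ncol(audio$samples))
  for (j in seq_len(ncol(audio$samples))) {
    cs <- cumsum(c(0, audio$samples[, j]^2))
    val[, j] <- sqrt((cs[starts + flen + 1L] - cs[starts + 1L]) / flen)
  }
  structure(list(t = audio$t0 + starts / audio$sr,
                 rms = val, db = db(val),
                 frame_s = flen / audio$sr, hop_s = hop / audio$sr,
                 channels = audio$channels),
            class = "frame_series")
}
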