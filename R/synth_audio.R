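#' Acoustic scene parameters for audio rendering
#'
#' Describes the simplified acoustics of the triadic recording rig: each
#' talker's speech reaches their own close-mouth microphone at the
#' direct-path gain, the other participants' microphones attenuated by the
#' crosstalk attenuation and delayed by the inter-seat propagation delay
#' (seat distance / speed of sound), and their own in-ear microphones after
#' the mouth-to-in-ear delay. Diffuse 8-talker babble is added to every
#' channel at a condition-dependent level.
#'
#' Levels are dB re full scale and describe what the *close-mouth
#' microphone* captures, not the room: a boom microphone a few centimetres
#' from the mouth keeps a healthy speech-to-babble ratio even when the room
#' babble is loud. The defaults put speech at -20 dB FS with babble 30 dB
#' below speech in the quiet condition and 12 dB below speech in the noise
#' condition -- a realistic close-talk contrast for the 48/78 dB SPL room
#' levels of the underlying paradigm.
#'
#' @param direct_gain_db close-mouth direct-path gain, dB (0 = reference).
#' @param crosstalk_att_db attenuation of a talker's speech on other
#'   participants' microphones, dB (>= 0; default 10).
#' @param seat_distance_m distance between participants (default 1.5 m).
#' @param speed_of_sound m/s (default 343).
#' @param mouth_ear_delay_s delay from a talker's mouth to their own in-ear
#'   microphones, seconds. Default 1.0 ms, placed above the 0.8-ms in-ear
#'   cross-correlation gate so that ground-truth speech is unambiguous with
#'   respect to that rule (see the methods vignette).
#' @param inear_gain_db level of own speech on the in-ear microphones, dB.
#' @param speech_db RMS level of rendered speech on the close-mouth channel.
#' @param babble_db named levels per condition, dB FS.
#' @param sr sample rate, Hz.
#' @param n_babble number of independent babble streams (default 8).
#' @return object of class `acoustic_scene`.
#' @export
acoustic_scene <- function(direct_gain_db = 0,
                           crosstalk_att_db = 10,
                           seat_distance_m = 1.5,
                           speed_of_sound = 343,
                           mouth_ear_delay_s = 1.0e-3,
                           inear_gain_db = -3,
                           speech_db = -20,
                           babble_db = c(quiet = -50, noise = -32),
                           sr = 48000,
                           n_babble = 8) {
  stop_if(crosstalk_att_db < 0, "crosstalk attenuation must be >= 0")
  stop_if(seat_distance_m <= 0 || speed_of_sound <= 0, "geometry must be positive")
  stop_if(mouth_ear_delay_s < 0, "delays must be >= 0")
  stop_if(sr <= 0, "sample rate must be > 0")
  structure(list(direct_gain_db = direct_gain_db,
                 crosstalk_att_db = crosstalk_att_db,
                 seat_distance_m = seat_distance_m,
                 speed_of_sound = speed_of_sound,
                 seat_delay_s = seat_distance_m / speed_of_sound,
                 mouth_ear_delay_s = mouth_ear_delay_s,
                 inear_gain_db = inear_gain_db,
                 speech_db = speech_db,
                 babble_db = babble_db,
                 sr = sr, n_babble = n_babble),
            class = "acoustic_scene")
}

# Speech-shaped noise carrier: white noise shaped in the frequency domain to
# a speech-like long-term spectrum (band-limited 100-8000 Hz with a -6 dB/oct
# tilt above ~1 kHz). RMS normalised to 1. Envelope modulation is applied
# separately (syllabic_envelope) so that independent streams can be derived
# from one carrier by large circular shifts.
shaped_noise_carrier <- function(n, sr) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  f <- abs(c(0:(nfft %/% 2), -((nfft - nfft %/% 2 - 1):1))) * (sr / nfft)
  fs <- pmax(f, 1e-12)
  mag <- sqrt(1 / (1 + (100 / fs)^4)) *       # high-pass edge at 100 Hz
    sqrt(1 / (1 + (fs / 8000)^4)) *           # low-pass edge at 8 kHz
    sqrt(1 / (1 + (fs / 1000)^2))             # spectral tilt
  mag[f == 0] <- 0
  x <- Re(stats::fft(stats::fft(stats::rnorm(nfft)) * mag, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x / rms(x)
}

# 4-Hz raised-cosine syllabic envelope in [1 - depth, 1].
syllabic_envelope <- function(n, sr, mod_hz = 4, mod_depth = 0.8, phase = 0) {
  t <- (seq_len(n) - 1) / sr
  1 - mod_depth * 0.5 * (1 + sin(2 * pi * mod_hz * t + phase))
}

circ_shift <- function(x, s) {
  n <- length(x)
  s <- ((as.integer(round(s)) %% n) + n) %% n
  if (s == 0L) return(x)
  c(x[(n - s + 1L):n], x[seq_len(n - s)])
}

# One amplitude-modulated speech-shaped stream derived from the carrier.
speech_shaped_noise <- function(carrier, sr, shift, phase) {
  x <- circ_shift(carrier, shift) *
    syllabic_envelope(length(carrier), sr, phase = phase)
  x / rms(x)
}

# Gate vector (0/1 with 10-ms raised-cosine ramps) for a set of intervals.
interval_gate <- function(n, sr, onsets, offsets, ramp_s = 0.010) {
  g <- numeric(n)
  nr <- max(2L, round(ramp_s * sr))
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
  for (k in seq_along(onsets)) {
    i0 <- max(1L, round(onsets[k] * sr) + 1L)
    i1 <- min(n, round(offsets[k] * sr))
    if (i1 <= i0) next
    g[i0:i1] <- 1
    up <- i0:min(i1, i0 + nr - 1L)
    g[up] <- pmax(g[up] * ramp[seq_along(up)], 0)
    dn <- max(i0, i1 - nr + 1L):i1
    g[dn] <- g[dn] * rev(ramp[seq_along(dn)])
  }
  g
}

#' Render 9-channel conversation audio from a plan and an acoustic scene
#'
#' Each talker's speech is an amplitude-modulated speech-shaped noise
#' surrogate gated by their turns. Channels are mixed per the scene: direct
#' path to the own close-mouth microphone, attenuated and delayed crosstalk
#' to the other participants' microphones, the mouth-to-in-ear delay to the
#' talker's own in-ear microphones, and diffuse babble on every channel at
#' the condition level (each channel receives the 8 babble streams through
#' its own random delays/weights, decorrelating the channels).
#'
#' @param plan a [simulate_turn_sequence()] plan.
#' @param scene an [acoustic_scene()].
#' @param seed integer seed.
#' @return list with `audio` (a [multichannel_audio()], 9 channels) and
#'   `ground_truth` (true turns, condition, seed).
#' @export
render_multichannel_audio <- function(plan, scene = acoustic_scene(), seed = 1) {
  stop_if(!inherits(plan, "conversation_plan"), "plan must be a conversation_plan")
  stop_if(!inherits(scene, "acoustic_scene"), "scene must be an acoustic_scene")
  stop_if(nrow(plan$turns) > 0 && max(plan$turns$offset) > plan$duration + 1e-9,
          "plan turns exceed the trial duration")
  set.seed(seed)
  sr <- scene$sr
  n <- round(plan$duration * sr)
  parts <- plan$participants
  roles <- c("close_mouth", "in_ear_L", "in_ear_R")
  chmap <- data.frame(participant = rep(parts, each = 3),
                      role = rep(roles, times = 3), stringsAsFactors = FALSE)
  x <- matrix(0, n, nrow(chmap))
  ci <- function(p, r) which(chmap$participant == p & chmap$role == r)

  seat_d <- scene$seat_delay_s * sr
  ear_d <- scene$mouth_ear_delay_s * sr
  g_direct <- undb(scene$direct_gain_db + scene$speech_db)
  g_cross <- undb(scene$direct_gain_db + scene$speech_db - scene$crosstalk_att_db)
  g_ear <- undb(scene$direct_gain_db + scene$speech_db + scene$inear_gain_db)

  carrier <- shaped_noise_carrier(n, sr)
  shifts <- round(stats::runif(length(parts) + scene$n_babble + ncol(x),
                               sr, n - sr))

  for (pi in seq_along(parts)) {
    p <- parts[pi]
    tu <- plan$turns[plan$turns$talker == p, , drop = FALSE]
    if (nrow(tu) == 0) next
    s <- speech_shaped_noise(carrier, sr, shifts[pi], stats::runif(1, 0, 2 * pi)) *
      interval_gate(n, sr, tu$onset, tu$offset)
    # re-normalise so RMS *within* turns hits the target speech level
    act <- interval_gate(n, sr, tu$onset, tu$offset, ramp_s = 0) > 0
    s <- s / rms(s[act])
    x[, ci(p, "close_mouth")] <- x[, ci(p, "close_mouth")] + g_direct * s
    s_ear <- delay_samples(s, ear_d)
    x[, ci(p, "in_ear_L")] <- x[, ci(p, "in_ear_L")] + g_ear * s_ear
    x[, ci(p, "in_ear_R")] <- x[, ci(p, "in_ear_R")] + g_ear * s_ear
    s_far <- delay_samples(s, seat_d)
    for (q in setdiff(parts, p)) {
      for (r in roles) x[, ci(q, r)] <- x[, ci(q, r)] + g_cross * s_far
    }
  }

  # diffuse 8-talker babble: the 8 modulated streams are summed once, and
  # each channel receives the mix through its own large circular shift,
  # decorrelating the channels (a diffuse-field approximation)
  bl <- scene$babble_db[[plan$condition]]
  bab <- numeric(n)
  for (k in seq_len(scene$n_babble)) {
    bab <- bab + speech_shaped_noise(carrier, sr, shifts[length(parts) + k],
                                     stats::runif(1, 0, 2 * pi))
  }
  bab <- bab / rms(bab)
  for (j in seq_len(ncol(x))) {
    x[, j] <- x[, j] + undb(bl) *
      circ_shift(bab, shifts[length(parts) + scene$n_babble + j])
  }

  audio <- multichannel_audio(x, sr, chmap)
  list(audio = audio,
       ground_truth = list(turns = plan$turns, condition = plan$condition,
                           noise_onset_s = plan$noise_onset_s, seed = seed))
}
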