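#' Segmentation parameters
#'
#' All thresholds of the speech-segmentation stage, overridable but
#' defaulting to the canonical values: 100-Hz high-pass, 20-ms frames with
#' 50% overlap, 6-dB crosstalk level rule, +/-300-sample cross-correlation
#' lag search, 0.8-ms in-ear delay gate, 180-ms gap merging, 90-ms minimum
#' utterance, 1-s minimum turn.
#'
#' @param cutoff_hz high-pass cutoff.
#' @param frame_s,hop_s RMS frame length and hop (s).
#' @param crosstalk_db level-difference threshold for the crosstalk test.
#' @param lag_range_samples cross-correlation lag search range.
#' @param context_s half-width of the audio context around a frame used for
#'   the frame-level cross-correlation test.
#' @param inear_min_delay_s in-ear delay gate (s).
#' @param inear_rule `"below"` removes segments whose close-mouth/in-ear peak
#'   delay magnitude is below the gate (the rule as printed); `"above"`
#'   inverts it; `"off"` disables it.
#' @param merge_gap_s merge gaps shorter than this before filtering.
#' @param min_utterance_s remove merged intervals shorter than this.
#' @param min_turn_s exclude turns shorter than this.
#' @param nbins histogram bins for the bimodal RMS threshold.
#' @export
segmentation_params <- function(cutoff_hz = 100,
                                frame_s = 0.020, hop_s = 0.010,
                                crosstalk_db = 6,
                                lag_range_samples = 300,
                                context_s = 0.100,
                                inear_min_delay_s = 0.8e-3,
                                inear_rule = c("below", "above", "off"),
                                merge_gap_s = 0.180,
                                min_utterance_s = 0.090,
                                min_turn_s = 1.0,
                                nbins = 64) {
  inear_rule <- match.arg(inear_rule)
  as.list(environment())
}

# Otsu's threshold on a histogram of x: the cut maximising the between-class
# variance of the two resulting groups. Returns the bin edge.
otsu_threshold <- function(x, nbins = 64) {
  br <- seq(min(x), max(x), length.out = nbins + 1)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mut <- mu0[nbins]
  sb <- (mut * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-nbins])
  br[k + 1]
}

#' Estimate the speech/background RMS threshold for one participant
#'
#' The frame-wise dB RMS of a close-mouth channel during a conversation is
#' bimodal: one mode is background (plus crosstalk), the other the wearer's
#' own speech. The threshold is placed between the modes with Otsu's method
#' on a 64-bin histogram of the dB values. Degenerate (effectively unimodal)
#' distributions fall back to `max - 6 dB` and carry a warning record.
#'
#' @param frames a `frame_series` from [compute_frame_rms()].
#' @param participant participant id.
#' @param params [segmentation_params()].
#' @return list with `threshold_db`, `method` ("otsu" or "fallback"),
#'   `warning` (NULL or message).
#' @export
estimate_rms_threshold <- function(frames, participant, params = segmentation_params()) {
  stop_if(length(frames$t) < 100, "need at least 100 frames")
  j <- which(frames$channels$participant == participant &
               frames$channels$role == "close_mouth")
  stop_if(length(j) != 1, "no close-mouth channel for %s", participant)
  x <- frames$db[, j]
  fallback <- function() {
    w <- sprintf("degenerate RMS distribution for %s; falling back to max - 6 dB",
                 participant)
    warning(w, call. = FALSE)
    list(threshold_db = max(x) - 6, method = "fallback", warning = w)
  }
  if (diff(range(x)) < 3) return(fallback())
  th <- otsu_threshold(x, params$nbins)
  # unimodality guard: a genuine speech/background split separates the class
  # means by far more than the 6-dB crosstalk margin; a background-only
  # channel does not
  sep <- mean(x[x > th]) - mean(x[x <= th])
  if (!is.finite(sep) || sep < 8) return(fallback())
  list(threshold_db = th, method = "otsu", warning = NULL)
}

#' Energy-based speech mask for all participants
#'
#' @param frames a `frame_series`.
#' @param thresholds named list/vector of per-participant thresholds (dB), as
#'   from [estimate_rms_threshold()].
#' @return logical matrix frames x participants.
#' @export
speech_energy_mask <- function(frames, thresholds) {
  parts <- unique(frames$channels$participant)
  m <- sapply(parts, function(p) {
    j <- which(frames$channels$participant == p & frames$channels$role == "close_mouth")
    th <- if (is.list(thresholds)) thresholds[[p]]$threshold_db else thresholds[[p]]
    frames$db[, j] > th
  })
  colnames(m) <- parts
  m
}

# Extract the high-passed audio context around frame k (center +/- context_s),
# for channel j.
frame_context <- function(audio, frames, k, j, context_s) {
  ctr <- round(((frames$t[k] - audio$t0) + frames$frame_s / 2) * audio$sr)
  half <- round(context_s * audio$sr)
  lo <- max(1L, ctr - half); hi <- min(nrow(audio$samples), ctr + half)
  audio$samples[lo:hi, j]
}

#' Crosstalk rejection on an energy-based speech mask
#'
#' Applies the three crosstalk tests, in order, to every above-threshold
#' frame of every participant:
#'
#' 1. *Level*: frames where the participant's close-mouth dB RMS is more than
#'    `crosstalk_db` below another talker's are removed as crosstalk.
#' 2. *Lag sign*: frames where the level difference to another talker is
#'    smaller than `crosstalk_db` in magnitude are retained only if the peak
#'    cross-correlation lag (searched over `lag_range_samples`) between the
#'    two close-mouth channels indicates the participant's own channel leads
#'    (the signal originates closer to their microphone).
#' 3. *In-ear delay*: maximal retained segments whose peak close-mouth-to-
#'    in-ear cross-correlation delay magnitude is below `inear_min_delay_s`
#'    are removed (rule direction configurable via `inear_rule`).
#'
#' Provenance flags record which test removed each frame.
#'
#' @param frames a `frame_series` of the high-passed audio.
#' @param mask logical matrix frames x participants ([speech_energy_mask()]).
#' @param audio the high-passed [multichannel_audio()].
#' @param params [segmentation_params()].
#' @return object of class `speech_mask`: list with `mask` (logical matrix),
#'   `provenance` (character matrix: "off", "energy", "crosstalk_removed",
#'   "delay_removed"), `t`, `frame_s`, `hop_s`, `participants`.
#' @export
reject_crosstalk <- function(frames, mask, audio, params = segmentation_params()) {
  parts <- colnames(mask)
  for (p in parts) {
    need <- c("close_mouth", "in_ear_L", "in_ear_R")
    have <- audio$channels$role[audio$channels$participant == p]
    stop_if(!all(need %in% have), "participant %s is missing channels: %s",
            p, paste(setdiff(need, have), collapse = ", "))
  }
  close_idx <- vapply(parts, function(p) channel_index(audio, p, "close_mouth"), 1L)
  nfr <- length(frames$t)
  prov <- matrix("off", nfr, length(parts), dimnames = list(NULL, parts))
  prov[mask] <- "energy"
  out <- mask

  for (p in parts) {
    own_j <- close_idx[[p]]
    own_db <- frames$db[, own_j]
    others <- setdiff(parts, p)
    other_db <- frames$db[, close_idx[others], drop = FALSE]

    active <- which(out[, p])
    if (!length(active)) next
    # test 1: level difference
    diffs <- own_db[active] - other_db[active, , drop = FALSE]
    t1 <- if (ncol(diffs) > 0) apply(diffs, 1, min) < -params$crosstalk_db
          else rep(FALSE, length(active))
    rm1 <- active[t1]
    out[rm1, p] <- FALSE
    prov[rm1, p] <- "crosstalk_removed"

    # test 2: lag sign, for frames with a close-level competitor
    active <- active[!t1]
    diffs <- diffs[!t1, , drop = FALSE]
    amb <- if (ncol(diffs) > 0) which(apply(abs(diffs) < params$crosstalk_db, 1, any))
           else integer(0)
    for (ii in amb) {
      k <- active[ii]
      ok <- TRUE
      for (oi in which(abs(diffs[ii, ]) < params$crosstalk_db)) {
        oj <- close_idx[others[oi]]
        x <- frame_context(audio, frames, k, own_j, params$context_s)
        y <- frame_context(audio, frames, k, oj, params$context_s)
        r <- xcorr_lag(x, y, params$lag_range_samples)
        if (r$lag <= 0) { ok <- FALSE; break }  # own channel does not lead
      }
      if (!ok) {
        out[k, p] <- FALSE
        prov[k, p] <- "crosstalk_removed"
      }
    }

    # test 3: in-ear delay, per maximal retained segment
    if (params$inear_rule != "off") {
      ears <- c(channel_index(audio, p, "in_ear_L"), channel_index(audio, p, "in_ear_R"))
      runs <- logical_runs(out[, p])
      for (ri in seq_len(nrow(runs))) {
        kmid <- (runs$first[ri] + runs$last[ri]) %/% 2L
        ctx_s <- min(0.5, max(params$context_s,
                              (runs$last[ri] - runs$first[ri]) * frames$hop_s / 2))
        x <- frame_context(audio, frames, kmid, own_j, ctx_s)
        best <- NULL
        for (ej in ears) {
          y <- frame_context(audio, frames, kmid, ej, ctx_s)
          r <- xcorr_lag(x, y, params$lag_range_samples)
          if (is.null(best) || r$corr > best$corr) best <- r
        }
        lag_s <- abs(best$lag) / audio$sr
        drop_seg <- if (params$inear_rule == "below") {
          lag_s < params$inear_min_delay_s
        } else {
          lag_s >= params$inear_min_delay_s
        }
        if (drop_seg) {
          sel <- runs$first[ri]:runs$last[ri]
          out[sel, p] <- FALSE
          prov[sel, p] <- "delay_removed"
        }
      }
    }
  }
  structure(list(mask = out, provenance = prov, t = frames$t,
                 frame_s = frames$frame_s, hop_s = frames$hop_s,
                 participants = parts),
            class = "speech_mask")
}

# frame-mask runs -> intervals (start = first frame start, end = last frame
# start + frame length)
mask_to_intervals <- function(maskvec, t, frame_s) {
  runs <- logical_runs(maskvec)
  data.frame(start = t[runs$first], end = t[runs$last] + frame_s)
}

merge_close_intervals <- function(iv, gap_s) {
  if (nrow(iv) < 2) return(iv)
  iv <- iv[order(iv$start), ]
  start <- iv$start[1]; end <- iv$end[1]
  out <- list()
  for (i in 2:nrow(iv)) {
    if (iv$start[i] - end < gap_s) {
      end <- max(end, iv$end[i])
    } else {
      out[[length(out) + 1L]] <- c(start, end)
      start <- iv$start[i]; end <- iv$end[i]
    }
  }
  out[[length(out) + 1L]] <- c(start, end)
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Build utterances from a speech mask
#'
#' Contiguous speech runs become intervals; gaps shorter than the merge
#' threshold (180 ms) are merged first, then intervals shorter than the
#' minimum (90 ms) are removed -- in that order.
#'
#' @param speech_mask a `speech_mask` from [reject_crosstalk()], or a logical
#'   matrix with attributes supplied through `t`, `frame_s` arguments.
#' @param params [segmentation_params()].
#' @return data.frame with `talker`, `start`, `end`, sorted and
#'   non-overlapping per talker.
#' @export
build_utterances <- function(speech_mask, params = segmentation_params()) {
  out <- lapply(speech_mask$participants, function(p) {
    iv <- mask_to_intervals(speech_mask$mask[, p], speech_mask$t, speech_mask$frame_s)
    if (nrow(iv) == 0) return(NULL)
    iv <- merge_close_intervals(iv, params$merge_gap_s)
    iv <- iv[iv$end - iv$start >= params$min_utterance_s, , drop = FALSE]
    if (nrow(iv) == 0) return(NULL)
    data.frame(talker = p, start = iv$start, end = iv$end, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(talker = character(0), start = numeric(0), end = numeric(0))
  }
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Combine utterances into turns
#'
#' Consecutive utterances of the same talker are merged into one turn when
#' the intervening pause is uninterrupted, i.e. no other talker's utterance
#' *starts* within it. Turns shorter than the minimum turn duration (1 s) are
#' excluded as likely noise or vocal backchannels. Onset/offset are the first
#' utterance onset and last utterance offset.
#'
#' @param utterances data.frame (talker, start, end) for all talkers, as from
#'   [build_utterances()].
#' @param params [segmentation_params()].
#' @return data.frame with `talker`, `onset`, `offset`, `n_utterances`.
#' @export
build_turns <- function(utterances, params = segmentation_params()) {
  if (nrow(utterances) == 0) {
    return(data.frame(talker = character(0), onset = numeric(0),
                      offset = numeric(0), n_utterances = integer(0)))
  }
  out <- list()
  for (p in unique(utterances$talker)) {
    u <- utterances[utterances$talker == p, , drop = FALSE]
    u <- u[order(u$start), , drop = FALSE]
    o <- utterances[utterances$talker != p, , drop = FALSE]
    onset <- u$start[1]; offset <- u$end[1]; cnt <- 1L
    flush <- function(onset, offset, cnt) {
      out[[length(out) + 1L]] <<- data.frame(
        talker = p, onset = onset, offset = offset, n_utterances = cnt,
        stringsAsFactors = FALSE)
    }
    if (nrow(u) > 1) for (i in 2:nrow(u)) {
      interrupted <- any(o$start > offset & o$start < u$start[i])
      if (!interrupted) {
        offset <- u$end[i]; cnt <- cnt + 1L
      } else {
        flush(onset, offset, cnt)
        onset <- u$start[i]; offset <- u$end[i]; cnt <- 1L
      }
    }
    flush(onset, offset, cnt)
  }
  res <- do.call(rbind, out)
  res <- res[res$offset - res$onset >= params$min_turn_s, , drop = FALSE]
  res <- res[order(res$onset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Full speech-segmentation stage
#'
#' High-pass filter, frame RMS, per-participant bimodal threshold, energy
#' mask, crosstalk rejection, utterance building and turn building, in one
#' call.
#'
#' @param audio a 9-channel [multichannel_audio()].
#' @param params [segmentation_params()].
#' @return list with `turns`, `utterances`, `thresholds`, `speech_mask`.
#' @export
segment_speech <- function(audio, params = segmentation_params()) {
  hp <- highpass_filter(audio, params$cutoff_hz)
  frames <- compute_frame_rms(hp, params$frame_s, params$hop_s)
  parts <- unique(audio$channels$participant)
  thresholds <- lapply(stats::setNames(parts, parts), function(p)
    estimate_rms_threshold(frames, p, params))
  emask <- speech_energy_mask(frames, thresholds)
  smask <- reject_crosstalk(frames, emask, hp, params)
  utts <- build_utterances(smask, params)
  turns <- build_turns(utts, params)
  list(turns = turns, utterances = utts, thresholds = thresholds,
       speech_mask = smask)
}
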