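# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive (loops, literal definitions) and share no code with the
# implementation paths they check.

# cross-correlation peak lag by direct summation; positive lag means y is a
# delayed copy of x
oracle_xcorr_lag <- function(x, y, max_lag) {
  lags <- (-max_lag):max_lag
  vals <- vapply(lags, function(l) {
    if (l >= 0) {
      n <- min(length(x), length(y) - l)
      if (n < 1) return(-Inf)
      sum(x[seq_len(n)] * y[seq_len(n) + l])
    } else {
      n <- min(length(x) + l, length(y))
      if (n < 1) return(-Inf)
      sum(x[seq_len(n) - l] * y[seq_len(n)])
    }
  }, numeric(1))
  lags[which.max(vals)]
}

# frame RMS by explicit framing
oracle_frame_rms <- function(x, sr, frame_s = 0.02, hop_s = 0.01) {
  flen <- round(frame_s * sr); hop <- round(hop_s * sr)
  starts <- seq(1, length(x) - flen + 1, by = hop)
  vapply(starts, function(s) sqrt(mean(x[s:(s + flen - 1)]^2)), numeric(1))
}

# literal merge-then-remove on interval tables
oracle_merge_remove <- function(iv, gap_s = 0.18, min_s = 0.09) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] - out$end[nrow(out)] < gap_s) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], iv$end[i])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out[out$end - out$start >= min_s, , drop = FALSE]
}

# exhaustive window-growing I-DT on one valid run (no missing samples);
# returns fixations as a data.frame(start_idx, end_idx)
oracle_idt_run <- function(t, h, v, disp = 1.5, min_dur = 0.1) {
  n <- length(t)
  fx <- NULL
  dsp <- function(a, b) (max(h[a:b]) - min(h[a:b])) + (max(v[a:b]) - min(v[a:b]))
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && t[j] - t[i] < min_dur) j <- j + 1
    if (t[j] - t[i] < min_dur) break
    if (dsp(i, j) <= disp) {
      while (j < n && dsp(i, j + 1) <= disp) j <- j + 1
      fx <- rbind(fx, data.frame(start_idx = i, end_idx = j))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (is.null(fx)) data.frame(start_idx = integer(0), end_idx = integer(0)) else fx
}

# centered sliding median with shrinking edges, literal
oracle_sliding_median <- function(x, width) {
  half <- width %/% 2
  vapply(seq_along(x), function(i) {
    w <- x[max(1, i - half):min(length(x), i + half)]
    if (all(is.na(w))) NA_real_ else median(w, na.rm = TRUE)
  }, numeric(1))
}

# band-limited noise for constructed audio cases
bl_noise <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  as.numeric(stats::filter(x, rep(1 / 9, 9), sides = 2, circular = TRUE))
}

# Constructed crosstalk scenario: participant 1 talks; every other channel
# carries a delayed, attenuated copy of the source; in-ear channels are the
# close-mouth channel delayed by a common mouth-to-ear delay. Level
# differences and delays are sampled away from the rule boundaries so the
# expected outcome is unambiguous.
make_crosstalk_case <- function(seed, sr = 8000, dur_s = 0.5) {
  set.seed(seed)
  n <- round(dur_s * sr)
  s <- bl_noise(n)
  s <- s / sqrt(mean(s^2))
  repeat {
    att <- vapply(1:2, function(i) {
      if (runif(1) < 0.5) -runif(1, 6.6, 12) else -runif(1, 0, 5.4)
    }, numeric(1))
    if (abs(att[1] - att[2]) < 5.5 || abs(att[1] - att[2]) > 6.5) break
  }
  repeat {
    d_seat <- sample(8:60, 2)
    if (abs(diff(d_seat)) >= 4) break
  }
  d_ear <- if (runif(1) < 0.5) sample(1:4, 1) else sample(10:40, 1)
  att_db <- c(0, att)
  delays <- c(0, d_seat)
  delay <- function(x, d) c(numeric(d), x[seq_len(length(x) - d)])
  parts <- c("P1", "P2", "P3")
  chmap <- data.frame(participant = rep(parts, each = 3),
                      role = rep(c("close_mouth", "in_ear_L", "in_ear_R"), 3))
  ch <- list()
  for (i in 1:3) {
    base <- 10^(att_db[i] / 20) * delay(s, delays[i])
    ear <- delay(base, d_ear)
    ch[[3 * i - 2]] <- base; ch[[3 * i - 1]] <- ear; ch[[3 * i]] <- ear
  }
  list(audio = multichannel_audio(do.call(cbind, ch), sr, chmap),
       att_db = att_db, delays = delays, d_ear = d_ear, sr = sr, parts = parts)
}

# literal-definition oracle for the three crosstalk rules on a constructed
# case: expected per-participant retention (uniform over the active frames)
oracle_crosstalk_keep <- function(case, params) {
  db <- case$att_db
  d <- case$delays
  keep <- logical(3)
  for (p in 1:3) {
    others <- setdiff(1:3, p)
    k <- TRUE
    if (any(db[p] - db[others] < -params$crosstalk_db)) {
      k <- FALSE                                          # rule 1: level
    } else {
      for (q in others) {                                 # rule 2: lag sign
        if (abs(db[p] - db[q]) < params$crosstalk_db && !(d[p] < d[q])) k <- FALSE
      }
    }
    if (k && params$inear_rule == "below" &&              # rule 3: in-ear delay
        case$d_ear / case$sr < params$inear_min_delay_s) k <- FALSE
    keep[p] <- k
  }
  keep
}

# run the crosstalk stage on a constructed case, returning the retained mask
# over the middle frames (away from context edges)
run_crosstalk_case <- function(case, params) {
  frames <- compute_frame_rms(case$audio, params$frame_s, params$hop_s)
  nfr <- length(frames$t)
  mid <- 13:(nfr - 12)
  mask <- matrix(FALSE, nfr, 3, dimnames = list(NULL, case$parts))
  mask[mid, ] <- TRUE
  sm <- reject_crosstalk(frames, mask, case$audio, params)
  list(got = sm$mask[mid, , drop = FALSE], mid = mid)
}

# small random angular trace with missing runs, on a regular 20-ms grid
make_random_trace <- function(seed, max_n = 50) {
  set.seed(seed)
  n <- sample(10:max_n, 1)
  t <- (seq_len(n) - 1) * 0.02
  h <- numeric(n); v <- numeric(n)
  pos <- c(0, 0)
  i <- 1
  while (i <= n) {
    len <- min(n - i + 1, sample(3:12, 1))
    jump <- runif(1) < 0.4
    if (jump) pos <- pos + runif(2, -4, 4)
    sd <- sample(c(0.05, 0.3, 0.8), 1)
    h[i:(i + len - 1)] <- pos[1] + rnorm(len, 0, sd)
    v[i:(i + len - 1)] <- pos[2] + rnorm(len, 0, sd)
    i <- i + len
  }
  valid <- rep(TRUE, n)
  if (runif(1) < 0.4) {
    g0 <- sample(seq_len(n - 2), 1)
    valid[g0:min(n, g0 + sample(1:4, 1))] <- FALSE
  }
  h[!valid] <- NA; v[!valid] <- NA
  data.frame(t = t, h = h, v = v, valid = valid)
}

# default-seeded simulation shared by several gaze tests
quick_sim <- function(duration_s = 60, condition = "quiet", seed = 11,
                      participant = "P1", script = gaze_script(), ...) {
  plan <- simulate_turn_sequence(duration_s = duration_s, condition = condition,
                                 seed = seed, ...)
  sim <- simulate_gaze_trace(plan, script, aoi_layout(), participant,
                             seed = seed + 100)
  list(plan = plan, sim = sim)
}

# standard gaze processing chain up to annotation
process_sim <- function(sim, gaze = gaze_params()) {
  gz <- sim$gaze
  bl <- detect_blinks(gz, gaze)
  tr <- preprocess_gaze(gz, bl, gaze)
  ev <- classify_fixations_idt(tr, gaze$idt_dispersion_deg, gaze$idt_min_dur_s)
  pp <- postprocess_aoi_track(sim$tracks)
  pxy <- deg_to_px(tr$h, tr$v)
  ann <- annotate_gaze(data.frame(t = tr$t, px = pxy$px, py = pxy$py), pp)
  list(blinks = bl, trace = tr, events = ev, tracks = pp, annotation = ann)
}
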