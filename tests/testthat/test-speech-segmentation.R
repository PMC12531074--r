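mono_audio <- function(x, sr = 48000) {
  multichannel_audio(matrix(x, ncol = 1), sr,
                     data.frame(participant = "P1", role = "close_mouth"))
}

test_that("high-pass filter passes speech and rejects breathing-band energy", {
  sr <- 48000
  t <- seq(0, 1, by = 1 / sr)
  lo <- mono_audio(sin(2 * pi * 50 * t), sr)
  hi <- mono_audio(sin(2 * pi * 1000 * t), sr)
  lo_f <- highpass_filter(lo, 100)
  hi_f <- highpass_filter(hi, 100)
  att_lo <- 20 * log10(sqrt(mean(lo_f$samples^2)) / sqrt(mean(lo$samples^2)))
  att_hi <- 20 * log10(sqrt(mean(hi_f$samples^2)) / sqrt(mean(hi$samples^2)))
  expect_lt(att_lo, -12)
  expect_gt(att_hi, -1)
  # zero phase: the 1-kHz carrier is not shifted
  mid <- 20000:28000
  expect_lt(max(abs(hi_f$samples[mid] - hi$samples[mid])), 0.05)
  # all-zero input stays zero
  z <- highpass_filter(mono_audio(numeric(sr)), 100)
  expect_true(all(abs(z$samples) < 1e-12))
  expect_error(highpass_filter(lo, 30000), "Nyquist")
})

test_that("frame RMS follows the 20-ms/50%-overlap framing exactly", {
  sr <- 48000
  const <- compute_frame_rms(mono_audio(rep(0.25, sr)))
  expect_true(all(abs(const$rms - 0.25) < 1e-12))
  # unit sinusoid with integer periods per frame -> RMS 1/sqrt(2)
  t <- seq(0, 1 - 1 / sr, by = 1 / sr)
  sine <- compute_frame_rms(mono_audio(sin(2 * pi * 500 * t), sr))
  expect_true(all(abs(sine$rms - 1 / sqrt(2)) < 1e-3))
  # 1.000 s at 48 kHz -> 99 frames, matching the brute-force framing oracle
  expect_equal(nrow(sine$rms), 99)
  set.seed(42)
  x <- rnorm(19000)
  got <- compute_frame_rms(mono_audio(x, sr = 16000))
  expect_equal(as.numeric(got$rms), oracle_frame_rms(x, 16000), tolerance = 1e-12)
  expect_error(compute_frame_rms(mono_audio(numeric(10))), "shorter")
})

test_that("the bimodal RMS threshold separates the two modes", {
  set.seed(1)
  db_vals <- c(rnorm(500, -40, 2), rnorm(500, -15, 2))
  frames <- list(t = seq_along(db_vals), db = matrix(db_vals, ncol = 1),
                 channels = data.frame(participant = "P1", role = "close_mouth"))
  class(frames) <- "frame_series"
  th <- estimate_rms_threshold(frames, "P1")
  expect_identical(th$method, "otsu")
  expect_gt(th$threshold_db, -35)
  expect_lt(th$threshold_db, -20)
  # identical frames: fallback with a warning record
  frames$db <- matrix(rep(-30, 500), ncol = 1)
  frames$t <- seq_len(500)
  expect_warning(th2 <- estimate_rms_threshold(frames, "P1"), "degenerate")
  expect_identical(th2$method, "fallback")
  expect_equal(th2$threshold_db, -36)
})

test_that("threshold separates speech from background on a synthetic trial", {
  plan <- simulate_turn_sequence(duration_s = 20, seed = 3)
  rend <- render_multichannel_audio(plan, acoustic_scene(), seed = 4)
  hp <- highpass_filter(rend$audio)
  frames <- compute_frame_rms(hp)
  for (p in plan$participants) {
    tu <- plan$turns[plan$turns$talker == p, ]
    if (nrow(tu) == 0) next
    th <- estimate_rms_threshold(frames, p)
    j <- which(frames$channels$participant == p &
                 frames$channels$role == "close_mouth")
    # frames fully inside true turns clear the threshold >= 95% of the time
    inside <- rep(FALSE, length(frames$t))
    for (i in seq_len(nrow(tu))) {
      inside <- inside | (frames$t >= tu$onset[i] + 0.05 &
                            frames$t + frames$frame_s <= tu$offset[i] - 0.05)
    }
    expect_gt(mean(frames$db[inside, j] > th$threshold_db), 0.95)
  }
})

test_that("crosstalk rules act in order with provenance flags", {
  params <- segmentation_params()
  case <- make_crosstalk_case(seed = 101)   # P1 talks
  # force a clear rule-1 configuration: others 10 dB down
  set.seed(101)
  res <- run_crosstalk_case(case, params)
  keep <- oracle_crosstalk_keep(case, params)
  for (p in 1:3) expect_true(all(res$got[, p] == keep[p]))

  # provenance: a 10-dB attenuated copy is removed from the copy's mask as
  # crosstalk by the level rule
  s <- bl_noise(4000, seed = 7); s <- s / sqrt(mean(s^2))
  delay <- function(x, d) c(numeric(d), x[seq_len(length(x) - d)])
  chmap <- data.frame(participant = rep(c("A", "B"), each = 3),
                      role = rep(c("close_mouth", "in_ear_L", "in_ear_R"), 2))
  d_ear <- 10
  ch <- cbind(s, delay(s, d_ear), delay(s, d_ear),
              0.316 * delay(s, 30), 0.316 * delay(s, 30 + d_ear),
              0.316 * delay(s, 30 + d_ear))
  audio <- multichannel_audio(ch, 8000, chmap)
  frames <- compute_frame_rms(audio)
  mask <- matrix(FALSE, length(frames$t), 2, dimnames = list(NULL, c("A", "B")))
  mask[13:(length(frames$t) - 12), ] <- TRUE
  sm <- reject_crosstalk(frames, mask, audio, params)
  mid <- 13:(length(frames$t) - 12)
  expect_true(all(sm$mask[mid, "A"]))
  expect_true(all(!sm$mask[mid, "B"]))
  expect_true(all(sm$provenance[mid, "B"] == "crosstalk_removed"))
  expect_true(all(sm$provenance[mid, "A"] == "energy"))
  # missing channels are rejected
  audio2 <- multichannel_audio(ch[, 1:5], 8000, chmap[1:5, ])
  expect_error(reject_crosstalk(frames, mask, audio2, params), "missing channels")
})

test_that("equal-level competitors are resolved by the lag-sign rule", {
  params <- segmentation_params()
  # two equal-level channels, own leads by 4 ms: retained for the leader,
  # removed for the lagger
  sr <- 8000
  s <- bl_noise(6000, seed = 8); s <- s / sqrt(mean(s^2))
  delay <- function(x, d) c(numeric(d), x[seq_len(length(x) - d)])
  d_ear <- 12
  chmap <- data.frame(participant = rep(c("A", "B"), each = 3),
                      role = rep(c("close_mouth", "in_ear_L", "in_ear_R"), 2))
  ch <- cbind(s, delay(s, d_ear), delay(s, d_ear),
              delay(s, 32), delay(s, 32 + d_ear), delay(s, 32 + d_ear))
  audio <- multichannel_audio(ch, sr, chmap)
  frames <- compute_frame_rms(audio)
  mask <- matrix(FALSE, length(frames$t), 2, dimnames = list(NULL, c("A", "B")))
  mid <- 13:(length(frames$t) - 12)
  mask[mid, ] <- TRUE
  sm <- reject_crosstalk(frames, mask, audio, params)
  expect_true(all(sm$mask[mid, "A"]))
  expect_true(all(!sm$mask[mid, "B"]))
})

test_that("the in-ear delay gate removes segments as printed, invertibly", {
  sr <- 8000
  s <- bl_noise(6000, seed = 9); s <- s / sqrt(mean(s^2))
  delay <- function(x, d) c(numeric(d), x[seq_len(length(x) - d)])
  chmap <- data.frame(participant = rep("A", 3),
                      role = c("close_mouth", "in_ear_L", "in_ear_R"))
  mk <- function(d_ear) {
    audio <- multichannel_audio(cbind(s, delay(s, d_ear), delay(s, d_ear)),
                                sr, chmap)
    frames <- compute_frame_rms(audio)
    mask <- matrix(FALSE, length(frames$t), 1, dimnames = list(NULL, "A"))
    mask[13:(length(frames$t) - 12), ] <- TRUE
    list(audio = audio, frames = frames, mask = mask,
         mid = 13:(length(frames$t) - 12))
  }
  small <- mk(3)    # 0.375 ms < 0.8 ms gate
  large <- mk(16)   # 2 ms > gate
  p_below <- segmentation_params(inear_rule = "below")
  p_above <- segmentation_params(inear_rule = "above")
  p_off <- segmentation_params(inear_rule = "off")
  expect_true(all(!reject_crosstalk(small$frames, small$mask, small$audio,
                                    p_below)$mask[small$mid, ]))
  expect_true(all(reject_crosstalk(large$frames, large$mask, large$audio,
                                   p_below)$mask[large$mid, ]))
  expect_true(all(reject_crosstalk(small$frames, small$mask, small$audio,
                                   p_above)$mask[small$mid, ]))
  expect_true(all(reject_crosstalk(small$frames, small$mask, small$audio,
                                   p_off)$mask[small$mid, ]))
  prov <- reject_crosstalk(small$frames, small$mask, small$audio, p_below)$provenance
  expect_true(all(prov[small$mid, ] == "delay_removed"))
})

mask_obj <- function(mask_vec, hop_s = 0.01, frame_s = 0.02) {
  structure(list(mask = matrix(mask_vec, ncol = 1, dimnames = list(NULL, "P1")),
                 t = (seq_along(mask_vec) - 1) * hop_s,
                 frame_s = frame_s, hop_s = hop_s, participants = "P1"),
            class = "speech_mask")
}

test_that("utterance building merges short gaps before removing short intervals", {
  # intervals [0, 0.50] and [0.60, 1.20]: 100-ms gap -> one utterance
  m <- rep(FALSE, 130)
  m[1:49] <- TRUE    # frames 0..0.48 -> interval [0, 0.50]
  m[61:119] <- TRUE  # frames 0.60..1.18 -> interval [0.60, 1.20]
  u <- build_utterances(mask_obj(m))
  expect_equal(nrow(u), 1)
  expect_equal(u$start, 0)
  expect_equal(u$end, 1.20)
  # an isolated 80-ms interval is removed
  m2 <- rep(FALSE, 100); m2[11:17] <- TRUE   # [0.10, 0.18] -> 80 ms
  expect_equal(nrow(build_utterances(mask_obj(m2))), 0)
  # empty mask -> empty list
  expect_equal(nrow(build_utterances(mask_obj(rep(FALSE, 50)))), 0)
})

test_that("merge-then-remove matches the literal oracle on random masks", {
  params <- segmentation_params()
  for (seed in 1:300) {
    set.seed(seed)
    m <- runif(80) < 0.35
    u <- build_utterances(mask_obj(m), params)
    runs <- rle(m)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    iv <- data.frame(start = (starts[runs$values] - 1) * 0.01,
                     end = (ends[runs$values] - 1) * 0.01 + 0.02)
    want <- oracle_merge_remove(iv, params$merge_gap_s, params$min_utterance_s)
    expect_equal(nrow(u), nrow(want))
    if (nrow(u) > 0) {
      expect_equal(u$start, want$start, tolerance = 1e-9)
      expect_equal(u$end, want$end, tolerance = 1e-9)
    }
  }
})

test_that("utterance building is idempotent on its own re-rasterised output", {
  params <- segmentation_params()
  for (seed in 1:50) {
    set.seed(seed)
    m <- runif(120) < 0.3
    u <- build_utterances(mask_obj(m), params)
    if (nrow(u) == 0) next
    # re-rasterise the utterances onto the frame grid
    grid_t <- (0:150) * 0.01
    m2 <- rep(FALSE, length(grid_t))
    for (i in seq_len(nrow(u))) {
      m2 <- m2 | (grid_t >= u$start[i] - 1e-9 & grid_t + 0.02 <= u$end[i] + 1e-9)
    }
    u2 <- build_utterances(mask_obj(m2), params)
    expect_equal(u2$start, u$start, tolerance = 1e-9)
    expect_equal(u2$end, u$end, tolerance = 1e-9)
  }
})

test_that("rule order matters and the merge-first order is implemented", {
  # [0, 0.05] and [0.10, 0.30]: merge-first keeps the 50-ms piece by fusing it;
  # remove-first would have dropped it
  m <- rep(FALSE, 60)
  m[1:4] <- TRUE     # [0, 0.05]
  m[11:29] <- TRUE   # [0.10, 0.30]
  u <- build_utterances(mask_obj(m))
  expect_equal(nrow(u), 1)
  expect_equal(u$start, 0)
  # remove-then-merge oracle for contrast
  iv <- data.frame(start = c(0, 0.10), end = c(0.05, 0.30))
  removed_first <- iv[iv$end - iv$start >= 0.09, ]
  expect_equal(nrow(removed_first), 1)
  expect_equal(removed_first$start, 0.10)  # differs from the implementation
})

test_that("turns merge across uninterrupted pauses and drop short ones", {
  params <- segmentation_params()
  # A: [0,2], [2.4,4]; nothing in between -> one turn [0,4]
  u <- data.frame(talker = c("A", "A"), start = c(0, 2.4), end = c(2, 4))
  tu <- build_turns(u, params)
  expect_equal(nrow(tu), 1)
  expect_equal(tu$onset, 0)
  expect_equal(tu$offset, 4)
  expect_equal(tu$n_utterances, 2L)
  # an interruption inside the pause blocks the merge
  u2 <- rbind(u, data.frame(talker = "B", start = 2.1, end = 2.3))
  tu2 <- build_turns(u2, params)
  a <- tu2[tu2$talker == "A", ]
  expect_equal(nrow(a), 2)
  expect_equal(a$onset, c(0, 2.4))
  # a 0.9-s isolated utterance yields no turn
  u3 <- data.frame(talker = "C", start = 10, end = 10.9)
  expect_equal(nrow(build_turns(u3, params)), 0)
})
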