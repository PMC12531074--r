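parts <- c("A", "B", "C")

test_that("conversation states label talking and listening correctly", {
  turns <- data.frame(talker = c("A", "B"), onset = c(0, 5), offset = c(4, 8))
  st <- label_states(turns, parts)
  cs <- st[st$participant == "C", ]
  expect_true(all(cs$state == "listening"))
  expect_equal(cs$start, c(0, 5))
  expect_equal(cs$end, c(4, 8))
  # overlap: simultaneous speech counts as talking
  turns2 <- data.frame(talker = c("A", "B"), onset = c(0, 3), offset = c(4, 5))
  st2 <- label_states(turns2, parts)
  b <- st2[st2$participant == "B", ]
  expect_equal(b$state[b$start == 3], "talking")
  listen_b <- b[b$state == "listening", ]
  expect_equal(listen_b$end, 3)   # listening stops where own talking starts
  # no turns -> all unlabeled
  expect_equal(nrow(label_states(turns[0, ], parts)), 0)
})

test_that("transitions resolve roles with exactly one next talker", {
  turns <- data.frame(talker = c("A", "B", "B", "C"),
                      onset = c(0, 5, 9, 14), offset = c(4, 8, 13, 18))
  tr <- turn_transitions(turns, parts)
  # the B->B pair produces no transition
  expect_equal(nrow(tr), 2)
  expect_equal(tr$prev_talker, c("A", "B"))
  expect_equal(tr$next_talker, c("B", "C"))
  expect_equal(tr$remaining_listener, c("C", "A"))
  # role bookkeeping: next talker and remaining listener partition the
  # listeners at each talking offset
  for (i in seq_len(nrow(tr))) {
    expect_setequal(c(tr$prev_talker[i], tr$next_talker[i],
                      tr$remaining_listener[i]), parts)
  }
})

make_ann <- function(t, label) {
  kind <- ifelse(label == "none", "none",
                 ifelse(label == "task", "task", sub(":.*", "", label)))
  identity <- ifelse(kind %in% c("face", "person"), sub(".*:", "", label), NA)
  data.frame(t = t, label = label, kind = kind, identity = identity,
             missing = FALSE, stringsAsFactors = FALSE)
}

test_that("dwell percentages are normalised and faces nest into people", {
  t <- seq(0, 10, by = 0.02)
  lab <- rep("task", length(t))
  lab[t < 6] <- "face:B"
  lab[t >= 6 & t < 7] <- "person:B"
  ann <- make_ann(t, lab)
  st <- data.frame(participant = "A", state = "listening", start = 0, end = 10)
  dw <- dwell_time(ann, st)
  expect_equal(sum(dw$pct[dw$aoi %in% c("face", "person", "task", "none")]), 100,
               tolerance = 1e-9)
  expect_equal(dw$pct[dw$aoi == "people"],
               dw$pct[dw$aoi == "face"] + dw$pct[dw$aoi == "person"])
  expect_equal(dw$pct[dw$aoi == "face"], 60, tolerance = 0.5)
  # all gaze on task -> task 100%
  dw2 <- dwell_time(make_ann(t, rep("task", length(t))), st)
  expect_equal(dw2$pct[dw2$aoi == "task"], 100)
  expect_equal(dw2$pct[dw2$aoi == "face"], 0)
})

test_that("onset metrics recover constructed latencies and first fixations", {
  t <- seq(0, 30, by = 0.02)
  # B talks at 10; observer A reaches B's face at 10.4
  lab <- rep("task", length(t))
  lab[t >= 10.4 & t < 14] <- "face:B"
  ann <- make_ann(t, lab)
  turns <- data.frame(talker = "B", onset = 10, offset = 14)
  fx <- data.frame(kind = "fixation", start = c(8.0, 10.44, 12.0),
                   end = c(9.9, 11.8, 13.5))
  on <- onset_metrics(turns, ann, fx, "A", parts, window_s = 4)
  e <- on$events
  expect_equal(nrow(e), 1)
  expect_equal(e$latency, 0.4, tolerance = 0.021)
  expect_true(e$first_fix_on_target)
  s <- on$summary
  expect_equal(s$value[s$metric == "median_latency_s"], 0.4, tolerance = 0.021)
  # gaze already on the talker at onset: latency is the first in-window
  # in-AOI time (negative)
  lab2 <- rep("face:B", length(t))
  on2 <- onset_metrics(turns, make_ann(t, lab2), fx, "A", parts, 4)
  expect_equal(on2$events$latency, -4, tolerance = 0.021)
  # no gaze on the talker within the window: the event contributes nothing
  # and the empty summary is flagged
  expect_warning(
    on3 <- onset_metrics(turns, make_ann(t, rep("task", length(t))), fx,
                         "A", parts, 4),
    "no qualifying")
  expect_true(is.na(on3$events$latency))
  expect_null(on3$summary)
})

test_that("offset metrics split by role and recover constructed departures", {
  t <- seq(0, 40, by = 0.02)
  turns <- data.frame(talker = c("B", "A", "C", "B"),
                      onset = c(2, 8.25, 14.5, 21), offset = c(8, 14, 20, 26))
  trans <- turn_transitions(turns, parts)
  # observer A: during B's first turn, on B's face until 7.7 (offset 8 - 0.3)
  lab <- rep("task", length(t))
  lab[t >= 2.4 & t <= 7.7] <- "face:B"
  lab[t >= 14.9 & t <= 19.7] <- "face:C"
  ann <- make_ann(t, lab)
  fx <- data.frame(kind = "fixation",
                   start = c(2.44, 9.0, 14.94),
                   end = c(7.7, 13.0, 19.7))
  of <- offset_metrics(trans, ann, fx, "A", window_s = 4)
  e <- of$events
  # B's offset at 8: A takes the next turn -> self_turn, departure -0.3
  e1 <- e[e$state == "listening" & e$anchor == 8, ]
  expect_equal(e1$role, "self_turn")
  expect_equal(e1$latency, -0.3, tolerance = 0.021)
  expect_equal(e1$latency_fix, -0.3, tolerance = 0.021)
  expect_true(e1$last_fix_on_target)
  # C's offset at 20: B takes over -> other_turn for A
  e2 <- e[e$state == "listening" & e$anchor == 20, ]
  expect_equal(e2$role, "other_turn")
  expect_equal(e2$latency, -0.3, tolerance = 0.021)
  # A's talking offset at 14: toward next talker C and remaining listener B
  e3 <- e[e$state == "talking", ]
  expect_equal(sort(e3$role), c("next_talker", "remaining_listener"))
  # dwell difference: A gazes C in (14.9, 18] of the window [10, 18]
  en <- e3[e3$role == "next_talker", ]
  expect_equal(en$target, "C")
  expect_gt(en$dwell_pct, 30)
  # summary has the next-vs-remaining dwell difference
  s <- of$summary
  expect_true(any(s$role == "next_vs_remaining" & s$metric == "dwell_diff_pct"))
})

test_that("no window sample outside +/-4 s contributes to onset latencies", {
  t <- seq(0, 30, by = 0.02)
  lab <- rep("task", length(t))
  lab[t < 5.5] <- "face:B"    # on the talker long before the window opens
  ann <- make_ann(t, lab)
  turns <- data.frame(talker = "B", onset = 10, offset = 14)
  expect_warning(
    on <- onset_metrics(turns, ann,
                        data.frame(kind = character(0), start = numeric(0),
                                   end = numeric(0)), "A", parts, 4),
    "no qualifying")
  expect_true(is.na(on$events$latency))   # the pre-window samples are ignored
})

test_that("movement features follow their definitions", {
  st <- data.frame(participant = "A", state = "listening", start = 0, end = 20)
  ev <- data.frame(kind = c(rep("saccade", 10), rep("fixation", 2)),
                   start = c(seq(1, 19, by = 2), 3, 10),
                   end = c(seq(1, 19, by = 2) + 0.04, 3.2, 10.4))
  ev$duration <- ev$end - ev$start
  mv <- movement_features(ev, st)
  expect_equal(mv$value[mv$metric == "saccade_rate_hz"], 0.5)
  expect_equal(mv$value[mv$metric == "mean_fixation_duration_s"], 0.3)
})

test_that("pupil features restrict to face samples per state", {
  t <- seq(0, 10, by = 0.02)
  dil <- data.frame(t = t, dilation = ifelse(t < 5, 0.2, NA), face = "B")
  st <- data.frame(participant = "A", state = c("listening", "talking"),
                   start = c(0, 6), end = c(5, 10))
  expect_warning(pf <- pupil_features(dil, st), "no face-gaze")
  expect_equal(pf$value[pf$state == "listening" &
                          pf$metric == "mean_pupil_dilation_mm"], 0.2)
  expect_equal(pf$value[pf$state == "listening" &
                          pf$metric == "max_pupil_dilation_mm"], 0.2)
  expect_false("talking" %in% pf$state)
})

test_that("feature export is tidy, complete and round-trips", {
  f1 <- data.frame(participant = rep(c("A", "B", "C"), each = 12),
                   state = rep(c("talking", "listening"), 18),
                   metric = rep(sprintf("feat%d", 1:6), each = 2),
                   value = rnorm(36))
  trial <- list(group = "G1", trial = "T1", condition = "quiet", features = f1)
  out <- export_features(list(trial))
  expect_equal(nrow(out), 36)   # 3 participants x 2 states x 6 features
  expect_named(out, c("group", "participant", "trial", "condition", "state",
                      "feature", "value"))
  # missing feature -> row absent
  f2 <- f1; f2$value[5] <- NA
  out2 <- export_features(list(list(group = "G1", trial = "T2",
                                    condition = "noise", features = f2)))
  expect_equal(nrow(out2), 35)
  # round-trip preserves values bit-exactly
  path <- tempfile(fileext = ".csv")
  write_features_csv(out, path)
  back <- read_features_csv(path)
  expect_identical(back$value, out$value)
  unlink(path)
})
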