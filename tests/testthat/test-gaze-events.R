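# construct a minimal gaze recording at 50 Hz
make_gaze <- function(n = 100, px = 960, py = 540, pupil = 4, sr = 50) {
  data.frame(t = (seq_len(n) - 1) / sr,
             px = rep(px, length.out = n), py = rep(py, length.out = n),
             dir_lx = 0, dir_ly = 0, dir_lz = 1,
             dir_rx = 0, dir_ry = 0, dir_rz = 1,
             pupil_l = rep(pupil, length.out = n),
             pupil_r = rep(pupil, length.out = n),
             valid_l = TRUE, valid_r = TRUE)
}

test_that("trial exclusion follows the 30% missing-data rule", {
  g <- make_gaze(200)
  drop_n <- function(g, k) {
    g$px[seq_len(k)] <- NA; g$py[seq_len(k)] <- NA
    g$valid_l[seq_len(k)] <- FALSE; g$valid_r[seq_len(k)] <- FALSE
    g
  }
  expect_true(exclude_trial_if_missing(g)$keep)
  expect_equal(exclude_trial_if_missing(g)$missing_fraction, 0)
  expect_true(exclude_trial_if_missing(drop_n(g, 58))$keep)    # 29%
  expect_false(exclude_trial_if_missing(drop_n(g, 62))$keep)   # 31%
  expect_error(exclude_trial_if_missing(g[1, ]), "zero-span")
})

test_that("blink detection applies the binocular and duration rules", {
  g <- make_gaze(200)
  mark <- function(g, i) {
    g$valid_l[i] <- FALSE; g$valid_r[i] <- FALSE
    g$px[i] <- NA; g$py[i] <- NA; g$pupil_l[i] <- NA; g$pupil_r[i] <- NA
    g
  }
  b300 <- detect_blinks(mark(g, 51:65))        # 300 ms
  expect_equal(nrow(b300), 1)
  expect_equal(b300$duration, 0.30, tolerance = 1e-9)
  expect_equal(nrow(detect_blinks(mark(g, 51))), 0)        # 20 ms dropout
  expect_equal(nrow(detect_blinks(mark(g, 51:126))), 0)    # 1.52 s gap
  # pupil-noise extension: a 1.5-mm jump adjacent to the gap joins the blink
  g2 <- mark(g, 51:62)
  g2$pupil_l[50] <- 5.6; g2$pupil_r[50] <- 5.6
  b <- detect_blinks(g2)
  expect_equal(nrow(b), 1)
  expect_lt(b$start, g$t[50] + 1e-9)
})

test_that("preprocessing preserves constants and bridges culled spikes", {
  g <- make_gaze(120, px = 800, py = 400)
  tr <- preprocess_gaze(g, detect_blinks(g))
  ang <- px_to_deg(800, 400)
  expect_true(all(abs(tr$h - ang$h) < 1e-9))
  expect_true(all(abs(tr$v - ang$v) < 1e-9))

  # one-sample spike at > 1000 deg/s is culled, then bridged
  g2 <- make_gaze(120, px = 800, py = 400)
  spike <- deg_to_px(ang$h + 45, ang$v)
  g2$px[60] <- spike$px
  tr2 <- preprocess_gaze(g2, detect_blinks(g2))
  expect_lt(abs(tr2$h[60] - ang$h), 1)
  expect_true(tr2$interpolated[60])
})

test_that("gap interpolation stops at the 200-ms rule", {
  g <- make_gaze(200, px = 700, py = 500)
  kill <- function(g, i) {
    g$px[i] <- NA; g$py[i] <- NA
    g$valid_l[i] <- FALSE; g$valid_r[i] <- FALSE; g
  }
  # 7 missing samples = 140-ms gap -> filled
  tr <- preprocess_gaze(kill(g, 61:67), data.frame(start = numeric(0), end = numeric(0)))
  expect_true(all(tr$valid[61:67]))
  # 13 missing samples = 260-ms gap -> stays missing
  tr2 <- preprocess_gaze(kill(g, 61:73), data.frame(start = numeric(0), end = numeric(0)))
  expect_true(all(!tr2$valid[61:73]))
})

test_that("I-DT handles the canonical textbook cases", {
  mk_trace <- function(h, v) {
    n <- length(h)
    data.frame(t = (seq_len(n) - 1) * 0.02, h = h, v = v, valid = !is.na(h))
  }
  # 300-ms stationary trace -> one fixation covering it
  tr <- mk_trace(rep(5, 15), rep(-3, 15))
  ev <- classify_fixations_idt(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "fixation")
  expect_equal(ev$duration, 0.28)
  expect_equal(ev$centroid_h, 5)
  expect_equal(ev$centroid_v, -3)
  # two stationary epochs 3 deg apart joined by a 40-ms transit
  h <- c(rep(0, 10), 1.5, rep(3, 10))
  tr2 <- mk_trace(h, rep(0, 21))
  ev2 <- classify_fixations_idt(tr2)
  expect_equal(sum(ev2$kind == "fixation"), 2)
  expect_equal(sum(ev2$kind == "saccade"), 1)
  # the transit sample sits within the dispersion bound of the first epoch,
  # so it is absorbed there and pulls the centroid slightly forward
  expect_equal(ev2$amplitude[ev2$kind == "saccade"], 3, tolerance = 0.2)
  # random walk with steps > 1.5 deg -> no fixations
  set.seed(5)
  steps <- matrix(runif(80, 1.6, 3) * sample(c(-1, 1), 80, TRUE), ncol = 2)
  walk <- apply(steps, 2, cumsum)
  ev3 <- classify_fixations_idt(mk_trace(walk[, 1], walk[, 2]))
  expect_equal(nrow(ev3), 0)
})

test_that("I-DT equals the exhaustive window-growing oracle on random traces", {
  for (seed in 1:200) {
    tr <- make_random_trace(seed)
    ev <- classify_fixations_idt(tr)
    fx <- ev[ev$kind == "fixation", ]
    runs <- rle(!is.na(tr$h))
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    want <- NULL
    for (r in which(runs$values)) {
      sel <- starts[r]:ends[r]
      o <- oracle_idt_run(tr$t[sel], tr$h[sel], tr$v[sel])
      if (nrow(o) > 0) {
        want <- rbind(want, data.frame(start = tr$t[sel[o$start_idx]],
                                       end = tr$t[sel[o$end_idx]]))
      }
    }
    nwant <- if (is.null(want)) 0 else nrow(want)
    expect_equal(nrow(fx), nwant, info = paste("seed", seed))
    if (nwant > 0) {
      expect_equal(fx$start, want$start, info = paste("seed", seed))
      expect_equal(fx$end, want$end, info = paste("seed", seed))
    }
  }
})

test_that("every emitted fixation satisfies the duration and dispersion bounds", {
  qs <- quick_sim(duration_s = 60, seed = 31)
  pr <- process_sim(qs$sim)
  fx <- pr$events[pr$events$kind == "fixation", ]
  expect_gt(nrow(fx), 20)
  expect_true(all(fx$duration >= 0.1 - 1e-9))
  expect_true(all(fx$dispersion <= 1.5 + 1e-9))
})

test_that("valid samples partition into at most one fixation or saccade", {
  qs <- quick_sim(duration_s = 45, seed = 32)
  pr <- process_sim(qs$sim)
  ev <- pr$events
  tr <- pr$trace
  cover <- integer(nrow(tr))
  for (i in seq_len(nrow(ev))) {
    sel <- if (ev$kind[i] == "fixation") {
      tr$t >= ev$start[i] - 1e-9 & tr$t <= ev$end[i] + 1e-9
    } else {
      tr$t > ev$start[i] + 1e-9 & tr$t < ev$end[i] - 1e-9
    }
    cover <- cover + sel
  }
  expect_true(all(cover <= 1))
  # blink samples belong to no fixation or saccade
  for (i in seq_len(nrow(pr$blinks))) {
    sel <- tr$t >= pr$blinks$start[i] & tr$t < pr$blinks$end[i]
    expect_true(all(cover[sel & !tr$valid] == 0))
  }
})

test_that("scripted fixations are recovered on clean simulated traces", {
  # recoverable scripted fixations: long enough to survive smoothing and not
  # clipped by a blink
  tot_gt <- 0; tot_det <- 0; errs <- c()
  for (seed in c(41, 42, 43)) {
    qs <- quick_sim(duration_s = 60, seed = seed,
                    script = gaze_script(noise_sd_deg = 0.05))
    pr <- process_sim(qs$sim)
    fx <- pr$events[pr$events$kind == "fixation", ]
    gt <- qs$sim$ground_truth$fixations
    bl <- qs$sim$ground_truth$blinks
    clipped <- vapply(seq_len(nrow(gt)), function(i)
      any(bl$start < gt$end[i] & bl$end > gt$start[i]), logical(1))
    core <- gt[gt$end - gt$start >= 0.25 & !clipped, ]
    tot_gt <- tot_gt + nrow(core); tot_det <- tot_det + nrow(fx)
    for (i in seq_len(nrow(core))) {
      j <- which.min(abs(fx$start - core$start[i]))
      errs <- c(errs, max(abs(fx$start[j] - core$start[i]),
                          abs(fx$end[j] - core$end[i])))
    }
  }
  # every recoverable scripted fixation has a detected counterpart within
  # four sample periods for 95% of cases (the Savitzky-Golay window spreads
  # each saccadic transition over about two samples, and I-DT absorbs
  # sub-dispersion transition samples; see the vignette)
  expect_gt(mean(errs <= 0.0801), 0.95)
  # detected counts stay close to the scripted counts
  expect_lt(abs(tot_det - tot_gt) / tot_gt, 0.25)
})

test_that("pupil preprocessing medians out artefacts and keeps ramps", {
  g <- make_gaze(100, pupil = 4)
  g$pupil_l[40] <- 6; g$pupil_r[40] <- 6
  pt <- process_pupil(g, data.frame(start = numeric(0), end = numeric(0)))
  expect_equal(pt$mm[40], 4, tolerance = 1e-9)
  # linear ramp is invariant under the sliding median away from the edges
  g2 <- make_gaze(100)
  ramp <- seq(3, 5, length.out = 100)
  g2$pupil_l <- ramp; g2$pupil_r <- ramp
  pt2 <- process_pupil(g2, data.frame(start = numeric(0), end = numeric(0)))
  expect_equal(pt2$mm[10:90], ramp[10:90], tolerance = 1e-9)
  expect_equal(pt2$mm, oracle_sliding_median(ramp, 11), tolerance = 1e-9)
  # samples inside a blink are absent before interpolation
  bl <- data.frame(start = 0.98, end = 1.2)
  pt3 <- process_pupil(g, bl)
  expect_true(all(!pt3$valid[g$t >= 0.98 & g$t < 1.2]))
  # all-missing trace flags
  g3 <- make_gaze(50)
  g3$pupil_l <- NA; g3$pupil_r <- NA
  expect_warning(process_pupil(g3, data.frame(start = numeric(0), end = numeric(0))),
                 "all-missing")
})
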