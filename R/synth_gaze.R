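#' Default AOI layout for one participant's head-camera view
#'
#' Two interlocutor person boxes left and right of the frame centre, each
#' with a nested face box, and one task-sheet box at the bottom centre --
#' the seating geometry of a triadic conversation as seen from one head
#' camera. Coordinates are scene-video pixels (origin top-left).
#'
#' @param frame_px frame size c(width, height).
#' @return data.frame with columns `kind` (face/person/task), `side`
#'   (left/right/NA), `x`, `y`, `w`, `h`.
#' @export
aoi_layout <- function(frame_px = c(1920, 1080)) {
  lay <- data.frame(
    kind = c("person", "person", "face", "face", "task"),
    side = c("left", "right", "left", "right", NA),
    x = c(260, 1240, 380, 1360, 760),
    y = c(140, 140, 190, 190, 780),
    w = c(420, 420, 180, 180, 400),
    h = c(820, 820, 230, 230, 260),
    stringsAsFactors = FALSE)
  validate_aoi_layout(lay, frame_px)
  lay
}

#' Validate an AOI layout
#'
#' Checks that all boxes lie inside the frame, that each face box is nested
#' in the person box on its side, and that person and task boxes do not
#' overlap each other.
#'
#' @param layout a layout data.frame as from [aoi_layout()].
#' @param frame_px frame size c(width, height).
#' @return the layout, invisibly; errors on violation.
#' @export
validate_aoi_layout <- function(layout, frame_px = c(1920, 1080)) {
  stop_if(any(layout$x < 0 | layout$y < 0 |
              layout$x + layout$w > frame_px[1] |
              layout$y + layout$h > frame_px[2]),
          "layout boxes must lie inside the %dx%d frame", frame_px[1], frame_px[2])
  for (s in c("left", "right")) {
    f <- layout[layout$kind == "face" & layout$side %in% s, ]
    p <- layout[layout$kind == "person" & layout$side %in% s, ]
    if (nrow(f) == 1 && nrow(p) == 1) {
      stop_if(f$x < p$x || f$y < p$y ||
              f$x + f$w > p$x + p$w || f$y + f$h > p$y + p$h,
              "face box (%s) must be nested in its person box", s)
    }
  }
  tops <- layout[layout$kind != "face", ]
  if (nrow(tops) > 1) {
    for (i in seq_len(nrow(tops) - 1)) for (j in (i + 1):nrow(tops)) {
      a <- tops[i, ]; b <- tops[j, ]
      ov <- a$x < b$x + b$w && b$x < a$x + a$w && a$y < b$y + b$h && b$y < a$y + a$h
      stop_if(ov, "non-face layout boxes must not overlap")
    }
  }
  invisible(layout)
}

#' Gaze-script parameters for the synthetic trial generator
#'
#' Controls the scripted coupling between gaze and turn-taking (injected
#' onset/offset latencies), the fixation-saccade-blink process, measurement
#' noise, the pupil model, and AOI-track degradation. All times in seconds,
#' angles in degrees, pupil in mm.
#'
#' @param onset_latency_s gaze shift to a new talker's face, relative to the
#'   turn onset (default 0.4 s).
#' @param talk_onset_latency_s shift to the task sheet after taking a turn.
#' @param offset_departure_s departure of the listener's gaze from the
#'   current talker, relative to the turn offset (negative = before).
#' @param talk_offset_departure_s end of the talker's final next-talker
#'   fixation, relative to their own turn offset.
#' @param talk_window_fracs fractions of the final pre-offset window a talker
#'   spends on the task sheet, the remaining listener, and the next talker.
#' @param window_s length of the pre-offset scripted window.
#' @param fix_dur_mean_s mean fixation duration per state.
#' @param fix_dur_cv coefficient of variation of fixation durations.
#' @param fix_dur_min_s floor on fixation durations.
#' @param saccade_dur_s saccadic transit duration.
#' @param jump_deg minimum angular distance between consecutive fixation
#'   centroids within one AOI (must exceed the I-DT dispersion threshold to
#'   be recoverable as distinct fixations).
#' @param noise_sd_deg gaze measurement noise, per axis.
#' @param blink_rate_hz Poisson blink rate.
#' @param blink_dur_range_s blink duration range. The default 100-180 ms
#'   keeps blinks within the 200-ms gap-interpolation bridge so scripted
#'   fixation counts stay recoverable; longer blinks are legal input.
#' @param leadin_fix_s duration of the alternating face fixations before
#'   noise onset (used for pupil baselines).
#' @param pupil_base_mm,pupil_noise_offset_mm baseline pupil diameter and the
#'   condition-dependent dilation added after noise onset in the noise
#'   condition.
#' @param pupil_ar_phi,pupil_ar_sd AR(1) pupil noise parameters.
#' @param pupil_spike_rate_hz rate of single-sample 1-mm pupil artefacts.
#' @param sr gaze sampling rate (Hz).
#' @param clock_offset_s eye-tracker clock offset relative to the room audio.
#' @param frame_px,fov_deg scene-camera geometry.
#' @param video_fps scene-video (AOI track) frame rate.
#' @param aoi_jitter_px detection jitter on box coordinates.
#' @param aoi_dropout_rate_hz rate of dropout runs per track.
#' @param aoi_dropout_frames dropout run length range (frames; < 50 so the
#'   temporal post-processing can repair them).
#' @param aoi_spurious_prob probability that a dropout contains a short
#'   (< 4 frame) spurious detection.
#' @return list of class `gaze_script`.
#' @export
gaze_script <- function(onset_latency_s = 0.4,
                        talk_onset_latency_s = 0.3,
                        offset_departure_s = -0.3,
                        talk_offset_departure_s = 0.15,
                        talk_window_fracs = c(task = 0.3, remaining = 0.2, next_talker = 0.5),
                        window_s = 4,
                        fix_dur_mean_s = c(listening = 1.2, talking = 0.45),
                        fix_dur_cv = 0.3,
                        fix_dur_min_s = 0.15,
                        saccade_dur_s = 0.04,
                        jump_deg = 2.5,
                        noise_sd_deg = 0.1,
                        blink_rate_hz = 0.08,
                        blink_dur_range_s = c(0.10, 0.18),
                        leadin_fix_s = 2,
                        pupil_base_mm = 4.0,
                        pupil_noise_offset_mm = 0.15,
                        pupil_ar_phi = 0.8,
                        pupil_ar_sd = 0.008,
                        pupil_spike_rate_hz = 0.3,
                        sr = 50,
                        clock_offset_s = 0,
                        frame_px = c(1920, 1080),
                        fov_deg = c(95, 63),
                        video_fps = 25,
                        aoi_jitter_px = 2,
                        aoi_dropout_rate_hz = 0.05,
                        aoi_dropout_frames = c(5, 45),
                        aoi_spurious_prob = 0.5) {
  stop_if(sr <= 0, "sampling rate must be > 0")
  stop_if(blink_dur_range_s[1] < 0 || diff(blink_dur_range_s) < 0,
          "blink duration range must be non-negative and ordered")
  structure(as.list(environment()), class = "gaze_script")
}

# Sample a fixation centroid (deg) inside the angular rectangle `rect`
# (h0,h1,v0,v1), at least `jump` degrees from `prev` (c(h,v) or NULL).
sample_centroid <- function(rect, prev, jump) {
  for (i in 1:25) {
    h <- stats::runif(1, rect[1], rect[2])
    v <- stats::runif(1, rect[3], rect[4])
    if (is.null(prev) || sqrt((h - prev[1])^2 + (v - prev[2])^2) >= jump)
      return(c(h, v))
  }
  # fall back to the corner farthest from prev
  corners <- rbind(c(rect[1], rect[3]), c(rect[1], rect[4]),
                   c(rect[2], rect[3]), c(rect[2], rect[4]))
  d <- sqrt((corners[, 1] - prev[1])^2 + (corners[, 2] - prev[2])^2)
  corners[which.max(d), ]
}

# Point-in-box AOI labelling with priority face > task > person.
# boxes: data.frame(kind, identity, x, y, w, h). Returns list(label, kind,
# identity) vectors for points (px, py); NA points -> "none".
point_label <- function(px, py, boxes) {
  n <- length(px)
  kind <- rep("none", n); identity <- rep(NA_character_, n)
  for (k in c("person", "task", "face")) {  # apply in increasing priority
    bb <- boxes[boxes$kind == k, , drop = FALSE]
    for (i in seq_len(nrow(bb))) {
      hit <- !is.na(px) & px >= bb$x[i] & px <= bb$x[i] + bb$w[i] &
        !is.na(py) & py >= bb$y[i] & py <= bb$y[i] + bb$h[i]
      kind[hit] <- k
      identity[hit] <- bb$identity[i]
    }
  }
  label <- ifelse(kind == "none", "none",
                  ifelse(kind == "task", "task", paste0(kind, ":", identity)))
  list(label = label, kind = kind, identity = identity)
}

#' Simulate one participant's gaze, pupil and AOI-track streams
#'
#' Generates a 50-Hz gaze trace realised as a fixation-saccade-blink process
#' whose target AOI is coupled to the conversation plan: as a listener, gaze
#' shifts to each new talker's face at turn onset plus the injected onset
#' latency and departs at turn offset plus the injected departure; as the
#' talker, gaze goes to the task sheet and, in the final window before the
#' turn offset, to the remaining listener and then to the next talker.
#' Before noise onset the participant alternates fixations between the two
#' faces (pupil-baseline material). Also produces 25-Hz AOI bounding-box
#' tracks with jitter, dropout runs and short spurious detections, and a
#' pupil trace with a condition-dependent dilation offset. Ground truth
#' (true events, per-sample AOI occupancy, injected latencies, dwell
#' fractions) is exported alongside.
#'
#' @param plan a [simulate_turn_sequence()] plan.
#' @param script a [gaze_script()].
#' @param layout an [aoi_layout()] data.frame.
#' @param participant which participant's view to simulate (default first).
#' @param seed integer seed; output is deterministic given all arguments.
#' @return list of class `gaze_simulation` with `gaze` (data.frame), `tracks`
#'   (AOI track data.frame), `boxes` (identity-resolved layout), and
#'   `ground_truth`.
#' @export
simulate_gaze_trace <- function(plan, script = gaze_script(), layout = aoi_layout(),
                                participant = plan$participants[1], seed = 1) {
  stop_if(!inherits(plan, "conversation_plan"), "plan must be a conversation_plan")
  stop_if(!participant %in% plan$participants, "unknown participant %s", participant)
  validate_aoi_layout(layout, script$frame_px)
  set.seed(seed)
  sr <- script$sr
  dt <- 1 / sr
  n <- floor(plan$duration * sr)
  t <- (seq_len(n) - 1) * dt
  others <- sort(setdiff(plan$participants, participant))
  side_of <- stats::setNames(c("left", "right"), others)

  # identity-resolved boxes for this view
  boxes <- layout
  boxes$identity <- ifelse(boxes$kind == "task", "task",
                           names(side_of)[match(boxes$side, side_of)])

  # angular rectangles (inner margin 0.5 deg) per target
  rect_of <- function(kind, id) {
    b <- boxes[boxes$kind == kind &
                 (kind == "task" | boxes$identity == id), ][1, ]
    c0 <- px_to_deg(b$x, b$y, script$frame_px, script$fov_deg)
    c1 <- px_to_deg(b$x + b$w, b$y + b$h, script$frame_px, script$fov_deg)
    c(c0$h + 0.5, c1$h - 0.5, c0$v + 0.5, c1$v - 0.5)
  }

  ## ---- target schedule -----------------------------------------------------
  segs <- list()
  cursor <- 0
  events <- list()   # injected/realised latency bookkeeping
  add_seg <- function(start, end, target) {
    start <- max(start, cursor)
    if (end - start < 0.06) return(invisible(NULL))
    segs[[length(segs) + 1L]] <<- list(start = start, end = end, target = target)
    cursor <<- end
    invisible(start)
  }
  # lead-in: alternate faces for pupil baselines
  k <- 0
  while (cursor < plan$noise_onset_s - 0.05) {
    tgt <- paste0("face:", others[k %% 2 + 1])
    add_seg(cursor, min(cursor + script$leadin_fix_s, plan$noise_onset_s), tgt)
    k <- k + 1
  }
  turns <- plan$turns
  for (i in seq_len(nrow(turns))) {
    T <- turns$talker[i]; o <- turns$onset[i]; f <- turns$offset[i]
    nxt <- if (i < nrow(turns)) turns$talker[i + 1] else NA_character_
    if (T != participant) {
      arr <- o + script$onset_latency_s
      dep <- f + script$offset_departure_s
      add_seg(cursor, arr, "task")
      real_arr <- add_seg(arr, dep, paste0("face:", T))
      if (!is.null(real_arr)) {
        events[[length(events) + 1L]] <- data.frame(
          type = "listen_onset", turn = i, anchor = o,
          injected = script$onset_latency_s, realized = real_arr - o,
          target = T, stringsAsFactors = FALSE)
        events[[length(events) + 1L]] <- data.frame(
          type = "listen_offset", turn = i, anchor = f,
          injected = script$offset_departure_s, realized = dep - f,
          target = T, stringsAsFactors = FALSE)
      }
    } else {
      arr <- o + script$talk_onset_latency_s
      add_seg(cursor, arr, "task")
      events[[length(events) + 1L]] <- data.frame(
        type = "talk_onset", turn = i, anchor = o,
        injected = script$talk_onset_latency_s, realized = arr - o,
        target = "task", stringsAsFactors = FALSE)
      w <- min(script$window_s, f - o - 0.5)
      fr <- script$talk_window_fracs
      if (!is.na(nxt) && nxt != participant && w > 0.6 &&
          fr[["next_talker"]] > 0) {
        rem <- setdiff(others, nxt)
        wstart <- f - w
        add_seg(cursor, wstart + fr[["task"]] * w, "task")
        if (fr[["remaining"]] > 0) {
          add_seg(cursor, cursor + fr[["remaining"]] * w, paste0("face:", rem))
        }
        end_next <- f + script$talk_offset_departure_s
        real <- add_seg(cursor, end_next, paste0("face:", nxt))
        if (!is.null(real)) {
          events[[length(events) + 1L]] <- data.frame(
            type = "talk_offset", turn = i, anchor = f,
            injected = script$talk_offset_departure_s, realized = end_next - f,
            target = nxt, stringsAsFactors = FALSE)
        }
      } else {
        add_seg(cursor, f + script$talk_offset_departure_s, "task")
      }
    }
  }
  add_seg(cursor, plan$duration, "task")
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), turn = integer(0), anchor = numeric(0),
               injected = numeric(0), realized = numeric(0), target = character(0))

  ## ---- fixation decomposition ---------------------------------------------
  own <- turns[turns$talker == participant, , drop = FALSE]
  in_own_turn <- function(tt) {
    nrow(own) > 0 && any(tt >= own$onset & tt < own$offset)
  }
  shp <- 1 / script$fix_dur_cv^2
  fix <- list(); prev_cent <- NULL; prev_end <- -Inf
  for (sg in segs) {
    tgt <- sg$target
    state <- if (in_own_turn((sg$start + sg$end) / 2)) "talking" else "listening"
    fmean <- script$fix_dur_mean_s[[state]]
    kind <- if (tgt == "task") "task" else "face"
    id <- if (tgt == "task") "task" else sub("^face:", "", tgt)
    rect <- rect_of(kind, id)
    # transit placement around a segment boundary: entering a face target the
    # eye lands exactly at the scripted boundary (the transit occupies the
    # tail of the previous segment; injected arrival latencies are exact);
    # entering the task the eye leaves the previous target exactly at the
    # boundary (the transit occupies the head of the task segment; injected
    # departures are exact)
    pos <- sg$start
    if (length(fix) > 0) {
      if (grepl("^face:", sg$target)) {
        if (fix[[length(fix)]]$end > sg$start - script$saccade_dur_s) {
          fix[[length(fix)]]$end <- sg$start - script$saccade_dur_s
        }
      } else {
        pos <- sg$start + script$saccade_dur_s
      }
    }
    seg_first_fix <- length(fix) + 1L
    while (pos < sg$end - 0.05) {
      d <- max(script$fix_dur_min_s, stats::rgamma(1, shape = shp, rate = shp / fmean))
      end <- min(pos + d, sg$end)
      if (sg$end - end < script$fix_dur_min_s + script$saccade_dur_s) end <- sg$end
      if (end - pos < script$fix_dur_min_s && length(fix) >= seg_first_fix) {
        # tail too short for a fixation of its own: extend the previous one,
        # honouring the scripted minimum fixation duration
        fix[[length(fix)]]$end <- sg$end
        prev_end <- sg$end
        break
      }
      # every scripted saccade jumps at least jump_deg, also across segments,
      # so consecutive scripted fixations are separable at the I-DT threshold
      cent <- sample_centroid(rect, prev_cent, script$jump_deg)
      fix[[length(fix) + 1L]] <- data.frame(
        start = pos, end = end, h = cent[1], v = cent[2],
        target = tgt, state = state, stringsAsFactors = FALSE)
      prev_cent <- cent; prev_end <- end
      first_of_seg <- FALSE
      pos <- end + script$saccade_dur_s
    }
  }
  fix <- do.call(rbind, fix)
  sac <- if (nrow(fix) > 1) {
    data.frame(start = fix$end[-nrow(fix)], end = fix$start[-1])
  } else data.frame(start = numeric(0), end = numeric(0))

  ## ---- rasterise ----------------------------------------------------------
  h <- numeric(n); v <- numeric(n)
  idx_fix <- pmin(n, pmax(1L, findInterval(t, fix$start)))
  idx_fix[t < fix$start[1]] <- 1L
  h <- fix$h[idx_fix]; v <- fix$v[idx_fix]
  # saccadic transits: linear interpolation between centroids
  if (nrow(sac) > 0) {
    for (i in seq_len(nrow(sac))) {
      sel <- which(t > sac$start[i] & t < sac$end[i])
      if (!length(sel)) next
      a <- (t[sel] - sac$start[i]) / (sac$end[i] - sac$start[i])
      h[sel] <- fix$h[i] + a * (fix$h[i + 1] - fix$h[i])
      v[sel] <- fix$v[i] + a * (fix$v[i + 1] - fix$v[i])
    }
  }

  # ground-truth AOI occupancy from noiseless positions vs enlarged clean boxes
  eb <- boxes
  eb$x <- pmax(0, eb$x - 40); eb$y <- pmax(0, eb$y - 40)
  eb$w <- pmin(script$frame_px[1] - eb$x, eb$w + 80)
  eb$h <- pmin(script$frame_px[2] - eb$y, eb$h + 80)
  clean_px <- deg_to_px(h, v, script$frame_px, script$fov_deg)
  gt_lab <- point_label(clean_px$px, clean_px$py, eb)

  # measurement noise (angular domain)
  hn <- h + stats::rnorm(n, 0, script$noise_sd_deg)
  vn <- v + stats::rnorm(n, 0, script$noise_sd_deg)
  pxy <- deg_to_px(hn, vn, script$frame_px, script$fov_deg)

  ## ---- blinks -------------------------------------------------------------
  nb <- stats::rpois(1, script$blink_rate_hz * plan$duration)
  bl_start <- sort(stats::runif(nb, 0.5, plan$duration - 1.5))
  bl_dur <- stats::runif(nb, script$blink_dur_range_s[1], script$blink_dur_range_s[2])
  keep <- rep(TRUE, nb)
  if (nb > 1) for (i in 2:nb) {
    if (bl_start[i] < bl_start[i - 1] + bl_dur[i - 1] + 0.3) keep[i] <- FALSE
  }
  blinks <- data.frame(start = bl_start[keep], end = (bl_start + bl_dur)[keep])
  in_blink <- rep(FALSE, n)
  for (i in seq_len(nrow(blinks))) {
    in_blink <- in_blink | (t >= blinks$start[i] & t < blinks$end[i])
  }

  ## ---- pupil --------------------------------------------------------------
  is_noise <- plan$condition == "noise" & t >= plan$noise_onset_s
  ar <- as.numeric(stats::filter(stats::rnorm(n, 0, script$pupil_ar_sd),
                                 script$pupil_ar_phi, method = "recursive"))
  pup <- script$pupil_base_mm + script$pupil_noise_offset_mm * is_noise + ar
  pup_l <- pup + stats::rnorm(n, 0, 0.005)
  pup_r <- pup + stats::rnorm(n, 0, 0.005)
  nsp <- stats::rpois(1, script$pupil_spike_rate_hz * plan$duration)
  if (nsp > 0) {
    si <- sample.int(n, nsp)
    eye <- stats::runif(nsp) < 0.5
    pup_l[si[eye]] <- pup_l[si[eye]] + sample(c(-1, 1), sum(eye), TRUE)
    pup_r[si[!eye]] <- pup_r[si[!eye]] + sample(c(-1, 1), sum(!eye), TRUE)
  }

  valid_l <- !in_blink; valid_r <- !in_blink
  px_o <- pxy$px; py_o <- pxy$py
  px_o[in_blink] <- NA; py_o[in_blink] <- NA
  pup_l[in_blink] <- NA; pup_r[in_blink] <- NA

  # binocular eye-direction unit vectors from the (noisy) angles
  hr <- hn * pi / 180; vr <- vn * pi / 180
  dz <- cos(hr) * cos(vr); dx <- sin(hr) * cos(vr); dy <- sin(vr)
  dx[in_blink] <- NA; dy[in_blink] <- NA; dz[in_blink] <- NA

  gaze <- data.frame(t = t + script$clock_offset_s,
                     px = px_o, py = py_o,
                     dir_lx = dx, dir_ly = dy, dir_lz = dz,
                     dir_rx = dx, dir_ry = dy, dir_rz = dz,
                     pupil_l = pup_l, pupil_r = pup_r,
                     valid_l = valid_l, valid_r = valid_r)
  attr(gaze, "sr") <- sr
  attr(gaze, "frame_px") <- script$frame_px
  attr(gaze, "fov_deg") <- script$fov_deg

  ## ---- AOI tracks (25 Hz) -------------------------------------------------
  nf <- floor(plan$duration * script$video_fps)
  tf <- (seq_len(nf) - 1) / script$video_fps
  tr <- list()
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    present <- rep(TRUE, nf)
    spurious <- rep(FALSE, nf)
    ndrop <- stats::rpois(1, script$aoi_dropout_rate_hz * plan$duration)
    for (d in seq_len(ndrop)) {
      len <- sample(script$aoi_dropout_frames[1]:script$aoi_dropout_frames[2], 1)
      if (nf - len - 10 < 6) next
      s0 <- sample(6:(nf - len - 5), 1)
      present[s0:(s0 + len - 1)] <- FALSE
      if (len >= 8 && stats::runif(1) < script$aoi_spurious_prob) {
        bl <- sample(seq_len(min(3, len - 5L)), 1)
        b0 <- s0 + 2 + sample.int(len - bl - 4L, 1)
        present[b0:(b0 + bl - 1)] <- TRUE
        spurious[b0:(b0 + bl - 1)] <- TRUE
      }
    }
    xj <- b$x + stats::rnorm(nf, 0, script$aoi_jitter_px)
    yj <- b$y + stats::rnorm(nf, 0, script$aoi_jitter_px)
    wj <- b$w + stats::rnorm(nf, 0, script$aoi_jitter_px / 2)
    hj <- b$h + stats::rnorm(nf, 0, script$aoi_jitter_px / 2)
    # spurious detections: displaced, and half of them under the size floor
    if (any(spurious)) {
      xj[spurious] <- xj[spurious] + 80
      und <- spurious & stats::runif(nf) < 0.5
      wj[und] <- 40
    }
    xj[!present] <- NA; yj[!present] <- NA; wj[!present] <- NA; hj[!present] <- NA
    tr[[i]] <- data.frame(frame = seq_len(nf), t = tf,
                          kind = b$kind, identity = b$identity,
                          x = xj, y = yj, w = wj, h = hj,
                          present = present, stringsAsFactors = FALSE)
  }
  tracks <- do.call(rbind, tr)
  rownames(tracks) <- NULL

  ## ---- ground-truth summaries --------------------------------------------
  lab <- gt_lab$label
  lab[in_blink] <- NA
  cls <- gt_lab$kind
  cls[in_blink] <- NA
  state <- rep(NA_character_, n)
  for (i in seq_len(nrow(turns))) {
    sel <- t >= turns$onset[i] & t < turns$offset[i]
    state[sel] <- if (turns$talker[i] == participant) "talking" else "listening"
  }
  dwell <- do.call(rbind, lapply(c("listening", "talking", "overall"), function(st) {
    sel <- if (st == "overall") t >= plan$noise_onset_s else (!is.na(state) & state == st)
    cc <- cls[sel]
    cc <- cc[!is.na(cc)]
    if (!length(cc)) return(NULL)
    data.frame(state = st,
               aoi = c("face", "person", "task", "none"),
               frac = as.numeric(table(factor(cc, c("face", "person", "task", "none"))) / length(cc)),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    participant = participant,
    gaze = gaze,
    tracks = tracks,
    boxes = boxes,
    script = script,
    ground_truth = list(
      fixations = fix, saccades = sac, blinks = blinks,
      labels = data.frame(t = t, label = lab, kind = cls,
                          state = state, stringsAsFactors = FALSE),
      events = events, dwell = dwell,
      turns = turns, condition = plan$condition,
      noise_onset_s = plan$noise_onset_s,
      pupil_offset_mm = if (plan$condition == "noise") script$pupil_noise_offset_mm else 0,
      seed = seed)),
    class = "gaze_simulation")
}
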