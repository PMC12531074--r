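#' Gaze-processing parameters
#'
#' @param max_missing trial-exclusion threshold on the missing-data fraction.
#' @param blink_min_s,blink_max_s blink duration bounds (50-1000 ms).
#' @param pupil_slope_mm per-sample pupil-diameter change treated as
#'   pupillometry noise adjacent to a binocular gap.
#' @param vel_max_deg_s angular-velocity cull threshold (1000 deg/s).
#' @param sg_order,sg_length Savitzky-Golay order and window (samples).
#' @param interp_gap_s linear-interpolation limit: gaps shorter than this are
#'   filled (200 ms).
#' @param idt_dispersion_deg,idt_min_dur_s I-DT dispersion threshold and
#'   minimum fixation duration.
#' @param pupil_median_s moving-median window for pupil smoothing.
#' @param frame_px,fov_deg scene-camera geometry for the angular conversion.
#' @param sr nominal gaze sampling rate (Hz).
#' @export
gaze_params <- function(max_missing = 0.30,
                        blink_min_s = 0.050, blink_max_s = 1.000,
                        pupil_slope_mm = 1.0,
                        vel_max_deg_s = 1000,
                        sg_order = 5, sg_length = 9,
                        interp_gap_s = 0.200,
                        idt_dispersion_deg = 1.5, idt_min_dur_s = 0.100,
                        pupil_median_s = 0.200,
                        frame_px = c(1920, 1080), fov_deg = c(95, 63),
                        sr = 50) {
  as.list(environment())
}

#' Trial-level missing-data exclusion
#'
#' Computes the fraction of invalid-or-absent gaze samples relative to the
#' number expected at the nominal sampling rate over the recording span, and
#' decides whether to keep the trial (drop iff fraction > `max_missing`).
#'
#' @param gaze gaze recording data.frame (columns `t`, `px`, `py`,
#'   `valid_l`, `valid_r`).
#' @param max_missing exclusion threshold (default 0.30).
#' @param sr nominal sampling rate.
#' @return list with `keep` (logical) and `missing_fraction`.
#' @export
exclude_trial_if_missing <- function(gaze, max_missing = 0.30, sr = 50) {
  stop_if(nrow(gaze) == 0, "empty recording")
  span <- diff(range(gaze$t))
  stop_if(span <= 0, "zero-span recording")
  expected <- round(span * sr) + 1
  invalid <- is.na(gaze$px) | is.na(gaze$py) | (!gaze$valid_l & !gaze$valid_r)
  missing <- (expected - nrow(gaze)) + sum(invalid)
  frac <- max(0, missing) / expected
  list(keep = frac <= max_missing, missing_fraction = frac)
}

#' Blink detection from binocular missing data and pupillometry noise
#'
#' A blink candidate is a maximal run where both eyes are missing, extended
#' over adjacent samples whose pupil diameter changes faster than the noise
#' slope; candidates are kept iff their duration lies within [50, 1000] ms.
#'
#' @param gaze gaze recording data.frame.
#' @param params [gaze_params()].
#' @return data.frame of blink events (`kind`, `start`, `end`, `duration`).
#' @export
detect_blinks <- function(gaze, params = gaze_params()) {
  stop_if(!all(c("valid_l", "valid_r") %in% names(gaze)),
          "both eyes' validity flags are required")
  n <- nrow(gaze)
  dtm <- if (n > 1) stats::median(diff(gaze$t)) else 1 / params$sr
  both_missing <- (!gaze$valid_l & !gaze$valid_r) | (is.na(gaze$px) & is.na(gaze$py))
  pup <- pupil_diameter(gaze)
  slope <- c(0, abs(diff(pup)))
  slope[is.na(slope)] <- 0
  runs <- logical_runs(both_missing)
  if (nrow(runs) == 0) {
    return(data.frame(kind = character(0), start = numeric(0),
                      end = numeric(0), duration = numeric(0)))
  }
  ev <- lapply(seq_len(nrow(runs)), function(i) {
    a <- runs$first[i]; b <- runs$last[i]
    # extend over adjacent samples whose pupil diameter jumps faster than the
    # noise slope (slope[k] is the change from sample k-1 to k)
    while (a > 1 && slope[a - 1] > params$pupil_slope_mm) a <- a - 1
    while (b < n - 1 && slope[b + 2] > params$pupil_slope_mm) b <- b + 1
    dur <- (b - a + 1) * dtm
    if (dur < params$blink_min_s || dur > params$blink_max_s) return(NULL)
    data.frame(kind = "blink", start = gaze$t[a], end = gaze$t[a] + dur,
               duration = dur, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, ev)
  if (is.null(res)) {
    res <- data.frame(kind = character(0), start = numeric(0),
                      end = numeric(0), duration = numeric(0))
  }
  res
}

# Binocular pupil diameter: mean of the two eyes where both valid, else the
# valid eye.
pupil_diameter <- function(gaze) {
  l <- gaze$pupil_l; r <- gaze$pupil_r
  out <- ifelse(!is.na(l) & !is.na(r), (l + r) / 2, ifelse(!is.na(l), l, r))
  as.numeric(out)
}

in_events <- function(t, events) {
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(events))) {
    out <- out | (t >= events$start[i] & t < events$end[i])
  }
  out
}

#' Preprocess a gaze recording into an angular trace
#'
#' Stage order: blink/invalid removal, conversion of 2D gaze to visual angles
#' through the scene-camera pinhole model, removal of samples with angular
#' velocity above 1000 deg/s or zero position, Savitzky-Golay smoothing
#' (order 5, window 9) of the gaze location per contiguous valid run, and
#' linear interpolation of gaps shorter than 200 ms. Longer gaps remain
#' missing. Valid runs shorter than the smoothing window are left unsmoothed
#' and flagged.
#'
#' @param gaze gaze recording data.frame.
#' @param blinks blink events from [detect_blinks()].
#' @param params [gaze_params()].
#' @return angular-trace data.frame: `t`, `h`, `v` (deg), `valid`, `vel`
#'   (deg/s, central difference), `interpolated`, `smoothed`.
#' @export
preprocess_gaze <- function(gaze, blinks = detect_blinks(gaze, params),
                            params = gaze_params()) {
  n <- nrow(gaze)
  dtm <- if (n > 1) stats::median(diff(gaze$t)) else 1 / params$sr
  px <- gaze$px; py <- gaze$py
  bad <- is.na(px) | is.na(py) | (!gaze$valid_l & !gaze$valid_r)
  bad <- bad | in_events(gaze$t, blinks)
  bad <- bad | (px == 0 & py == 0)          # zero position
  px[bad] <- NA; py[bad] <- NA

  ang <- px_to_deg(px, py, params$frame_px, params$fov_deg)
  h <- ang$h; v <- ang$v

  # velocity cull: a sample is discarded when the velocity both into and out
  # of it exceeds the threshold (removes single-sample spikes without eating
  # into genuine fast movements); reported velocity is the central difference
  w <- sqrt(diff(h)^2 + diff(v)^2) / diff(gaze$t)
  cull <- c(FALSE, w > params$vel_max_deg_s) & c(w > params$vel_max_deg_s, FALSE)
  cull[is.na(cull)] <- FALSE
  h[cull] <- NA; v[cull] <- NA

  # Savitzky-Golay per contiguous valid run; runs are reflection-padded by
  # half a window so the run edges are filtered by the interior FIR kernel
  # (the filter's own edge-startup polynomial fits are unstable on noisy data)
  smoothed <- rep(FALSE, n)
  sg_pad <- (params$sg_length - 1) %/% 2
  sg_smooth <- function(x) {
    m <- length(x)
    xp <- c(2 * x[1] - rev(x[2:(sg_pad + 1)]), x,
            2 * x[m] - rev(x[(m - sg_pad):(m - 1)]))
    signal::sgolayfilt(xp, p = params$sg_order, n = params$sg_length)[sg_pad + seq_len(m)]
  }
  runs <- logical_runs(!is.na(h))
  for (i in seq_len(nrow(runs))) {
    sel <- runs$first[i]:runs$last[i]
    if (length(sel) >= params$sg_length) {
      h[sel] <- sg_smooth(h[sel])
      v[sel] <- sg_smooth(v[sel])
      smoothed[sel] <- TRUE
    }
  }

  # linear interpolation of short gaps (< interp_gap_s)
  maxgap <- ceiling(params$interp_gap_s / dtm) - 1L
  pre_na <- is.na(h)
  h <- interp_short_gaps(h, maxgap)
  v <- interp_short_gaps(v, maxgap)
  interpolated <- pre_na & !is.na(h)

  vel <- angular_velocity(gaze$t, h, v)
  data.frame(t = gaze$t, h = h, v = v, valid = !is.na(h),
             vel = vel, interpolated = interpolated, smoothed = smoothed)
}

#' Angular velocity by central differences
#'
#' Defined only between consecutive valid samples; NA elsewhere.
#' @param t,h,v time (s) and angles (deg).
#' @export
angular_velocity <- function(t, h, v) {
  n <- length(t)
  vel <- rep(NA_real_, n)
  if (n < 3) return(vel)
  i <- 2:(n - 1)
  d <- sqrt((h[i + 1] - h[i - 1])^2 + (v[i + 1] - v[i - 1])^2)
  vel[i] <- d / (t[i + 1] - t[i - 1])
  # forward/backward differences at the trace ends
  fwd <- sqrt(diff(h)^2 + diff(v)^2) / diff(t)
  vel[1] <- fwd[1]
  vel[n] <- fwd[n - 1]
  vel
}

idt_dispersion <- function(h, v) {
  (max(h) - min(h)) + (max(v) - min(v))
}

#' Fixation/saccade classification with the I-DT algorithm
#'
#' Dispersion-threshold identification: a window is initialised to cover the
#' minimum duration and accepted as a fixation seed if its dispersion
#' (horizontal range + vertical range) is at or below the threshold; the
#' window then grows until adding the next sample would exceed the threshold,
#' and a fixation is emitted with centroid = mean position. Windows whose
#' initial dispersion exceeds the threshold advance by one sample. Valid
#' inter-fixation intervals become saccades; intervals containing missing
#' samples become neither.
#'
#' @param trace angular trace from [preprocess_gaze()].
#' @param dispersion_deg dispersion threshold (default 1.5 deg).
#' @param min_dur_s minimum fixation duration (default 0.1 s).
#' @return data.frame of events: `kind` (fixation/saccade), `start`, `end`,
#'   `duration`, `centroid_h`, `centroid_v`, `dispersion`, `amplitude`.
#' @export
classify_fixations_idt <- function(trace, dispersion_deg = 1.5, min_dur_s = 0.100) {
  fixes <- list()
  runs <- logical_runs(trace$valid)
  for (ri in seq_len(nrow(runs))) {
    sel <- runs$first[ri]:runs$last[ri]
    t <- trace$t[sel]; h <- trace$h[sel]; v <- trace$v[sel]
    n <- length(sel)
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && t[j] - t[i] < min_dur_s) j <- j + 1L
      if (t[j] - t[i] < min_dur_s) break            # tail shorter than min duration
      if (idt_dispersion(h[i:j], v[i:j]) <= dispersion_deg) {
        maxh <- max(h[i:j]); minh <- min(h[i:j])
        maxv <- max(v[i:j]); minv <- min(v[i:j])
        while (j < n) {
          nh <- c(max(maxh, h[j + 1]), min(minh, h[j + 1]))
          nv <- c(max(maxv, v[j + 1]), min(minv, v[j + 1]))
          if ((nh[1] - nh[2]) + (nv[1] - nv[2]) > dispersion_deg) break
          j <- j + 1L
          maxh <- nh[1]; minh <- nh[2]; maxv <- nv[1]; minv <- nv[2]
        }
        fixes[[length(fixes) + 1L]] <- data.frame(
          kind = "fixation", start = t[i], end = t[j], duration = t[j] - t[i],
          centroid_h = mean(h[i:j]), centroid_v = mean(v[i:j]),
          dispersion = (maxh - minh) + (maxv - minv),
          amplitude = NA_real_, run = ri, i0 = sel[i], i1 = sel[j],
          stringsAsFactors = FALSE)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(fixes)) {
    return(data.frame(kind = character(0), start = numeric(0), end = numeric(0),
                      duration = numeric(0), centroid_h = numeric(0),
                      centroid_v = numeric(0), dispersion = numeric(0),
                      amplitude = numeric(0)))
  }
  fx <- do.call(rbind, fixes)
  # saccades: consecutive fixations within the same valid run
  sacs <- list()
  if (nrow(fx) > 1) for (i in 1:(nrow(fx) - 1)) {
    if (fx$run[i] == fx$run[i + 1]) {
      amp <- sqrt((fx$centroid_h[i + 1] - fx$centroid_h[i])^2 +
                    (fx$centroid_v[i + 1] - fx$centroid_v[i])^2)
      sacs[[length(sacs) + 1L]] <- data.frame(
        kind = "saccade", start = fx$end[i], end = fx$start[i + 1],
        duration = fx$start[i + 1] - fx$end[i],
        centroid_h = NA_real_, centroid_v = NA_real_, dispersion = NA_real_,
        amplitude = amp, run = fx$run[i], i0 = fx$i1[i], i1 = fx$i0[i + 1],
        stringsAsFactors = FALSE)
    }
  }
  ev <- rbind(fx, do.call(rbind, sacs))
  ev <- ev[order(ev$start), setdiff(names(ev), c("run", "i0", "i1"))]
  rownames(ev) <- NULL
  ev
}

#' Pupil preprocessing
#'
#' Binocular pupil diameter (mean of valid eyes) with blink samples removed,
#' smoothed by a 200-ms moving median (shrinking window at the trace ends),
#' then linearly interpolated across missing runs.
#'
#' @param gaze gaze recording data.frame.
#' @param blinks blink events.
#' @param params [gaze_params()].
#' @return pupil-trace data.frame: `t`, `mm`, `valid` (TRUE where the value
#'   is measured rather than interpolated).
#' @export
process_pupil <- function(gaze, blinks = detect_blinks(gaze, params),
                          params = gaze_params()) {
  n <- nrow(gaze)
  dtm <- if (n > 1) stats::median(diff(gaze$t)) else 1 / params$sr
  mm <- pupil_diameter(gaze)
  mm[in_events(gaze$t, blinks)] <- NA
  if (all(is.na(mm))) {
    warning("all-missing pupil trace", call. = FALSE)
    return(data.frame(t = gaze$t, mm = NA_real_, valid = FALSE))
  }
  width <- round(params$pupil_median_s / dtm)
  if (width %% 2L == 0L) width <- width + 1L
  sm <- moving_median(mm, width)
  valid <- !is.na(sm)
  out <- as.numeric(zoo::na.approx(sm, x = gaze$t, na.rm = FALSE))
  data.frame(t = gaze$t, mm = out, valid = valid)
}
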