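#' AOI post-processing parameters
#'
#' @param size_ranges valid box-width ranges in px per kind (face 50-300,
#'   person 50-900, task 100-1400); detections outside their kind's range are
#'   invalidated. The ranges apply to the box width by default
#'   (`size_dim = "w"`), configurable to height or both.
#' @param size_dim which box dimension the ranges constrain.
#' @param median_window moving-median window (frames) on coordinates/sizes.
#' @param min_run_frames presence runs shorter than this are false positives.
#' @param max_gap_frames absence runs shorter than this are interpolated.
#' @param enlarge_px margin added on every side of each box (about 2 deg of
#'   visual angle under the scene-camera model).
#' @param frame_px frame size for clamping.
#' @export
aoi_params <- function(size_ranges = list(face = c(50, 300),
                                          person = c(50, 900),
                                          task = c(100, 1400)),
                       size_dim = c("w", "h", "both"),
                       median_window = 3,
                       min_run_frames = 4,
                       max_gap_frames = 50,
                       enlarge_px = 40,
                       frame_px = c(1920, 1080)) {
  size_dim <- match.arg(size_dim)
  as.list(environment())
}

#' Post-process an AOI bounding-box track
#'
#' Stage order, per (kind, identity) track: window-3 moving median on the
#' coordinate and size vectors; size clamp to the per-kind valid ranges
#' (out-of-range detections invalidated); removal of presence runs shorter
#' than 4 frames (false positives); linear interpolation of absence runs
#' shorter than 50 frames (false negatives); enlargement by 40 px on every
#' side, clamped to the frame.
#'
#' @param track AOI track data.frame (`frame`, `t`, `kind`, `identity`, `x`,
#'   `y`, `w`, `h`, `present`), possibly containing several (kind, identity)
#'   tracks.
#' @param params [aoi_params()].
#' @return post-processed track of the same shape; boxes are the enlarged
#'   ones.
#' @export
postprocess_aoi_track <- function(track, params = aoi_params()) {
  bad <- setdiff(unique(track$kind), names(params$size_ranges))
  stop_if(length(bad) > 0, "unknown AOI kind: %s", paste(bad, collapse = ", "))
  key <- paste(track$kind, track$identity)
  pieces <- lapply(split(track, key), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    for (col in c("x", "y", "w", "h")) {
      tr[[col]][!tr$present] <- NA
      tr[[col]] <- moving_median(tr[[col]], params$median_window)
    }
    rng <- params$size_ranges[[tr$kind[1]]]
    within_range <- function(z) !is.na(z) & z >= rng[1] & z <= rng[2]
    ok <- switch(params$size_dim,
                 w = within_range(tr$w),
                 h = within_range(tr$h),
                 both = within_range(tr$w) & within_range(tr$h))
    drop <- tr$present & !ok
    tr$present[drop] <- FALSE
    for (col in c("x", "y", "w", "h")) tr[[col]][drop] <- NA

    runs <- logical_runs(tr$present)
    for (i in seq_len(nrow(runs))) {
      if (runs$last[i] - runs$first[i] + 1L < params$min_run_frames) {
        sel <- runs$first[i]:runs$last[i]
        tr$present[sel] <- FALSE
        for (col in c("x", "y", "w", "h")) tr[[col]][sel] <- NA
      }
    }

    maxgap <- params$max_gap_frames - 1L
    for (col in c("x", "y", "w", "h")) {
      tr[[col]] <- interp_short_gaps(tr[[col]], maxgap)
    }
    tr$present <- !is.na(tr$x)

    m <- params$enlarge_px
    x0 <- pmax(0, tr$x - m); y0 <- pmax(0, tr$y - m)
    tr$w <- pmin(params$frame_px[1], tr$x + tr$w + m) - x0
    tr$h <- pmin(params$frame_px[2], tr$y + tr$h + m) - y0
    tr$x <- x0; tr$y <- y0
    tr
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$kind, out$identity, out$frame), ]
  rownames(out) <- NULL
  out
}

# Interpolate a per-frame box track to arbitrary times. Returns a data.frame
# (x, y, w, h, covered); covered is FALSE where either bracketing frame is
# absent or outside the track span.
interp_track_to <- function(tr, t_out) {
  pres <- tr$present
  if (!any(pres)) {
    return(data.frame(x = NA_real_, y = NA_real_, w = NA_real_, h = NA_real_,
                      covered = FALSE)[rep(1, length(t_out)), ])
  }
  ap <- function(col) stats::approx(tr$t[pres], tr[[col]][pres], xout = t_out,
                                    rule = 1)$y
  cov <- stats::approx(tr$t, as.numeric(pres), xout = t_out, rule = 1)$y
  data.frame(x = ap("x"), y = ap("y"), w = ap("w"), h = ap("h"),
             covered = !is.na(cov) & cov >= 1)
}

#' Annotate gaze samples with their AOI
#'
#' Tests gaze positions against the (post-processed, enlarged) AOI boxes with
#' priority face > task > person and emits one label per sample. By default
#' the AOI boxes are interpolated to the native gaze timestamps
#' (`direction = "to_gaze"`), preserving the 50-Hz resolution of the
#' turn-aligned latency metrics; alternatively the gaze positions are
#' linearly interpolated to the 25-Hz video frame times
#' (`direction = "gaze_to_frames"`). Samples with missing gaze are labelled
#' `none` and flagged missing.
#'
#' @param gaze gaze recording data.frame (`t`, `px`, `py`).
#' @param tracks post-processed AOI tracks ([postprocess_aoi_track()]).
#' @param direction annotation grid, see above.
#' @return data.frame: `t`, `label` (e.g. `"face:P2"`, `"task"`, `"none"`),
#'   `kind`, `identity`, `missing`.
#' @export
annotate_gaze <- function(gaze, tracks, direction = c("to_gaze", "gaze_to_frames")) {
  direction <- match.arg(direction)
  if (direction == "to_gaze") {
    t_out <- gaze$t
    px <- gaze$px; py <- gaze$py
  } else {
    t_out <- sort(unique(tracks$t))
    ok <- !is.na(gaze$px)
    px <- stats::approx(gaze$t[ok], gaze$px[ok], xout = t_out, rule = 1)$y
    py <- stats::approx(gaze$t[ok], gaze$py[ok], xout = t_out, rule = 1)$y
    # do not bridge long missing runs: mark frame times without a gaze
    # sample within one frame interval as missing
    near <- stats::approx(gaze$t[ok], gaze$t[ok], xout = t_out, method = "constant",
                          rule = 2)$y
    dtv <- stats::median(diff(t_out))
    far <- abs(near - t_out) > 2 * dtv
    px[far] <- NA; py[far] <- NA
  }
  n <- length(t_out)
  kind <- rep("none", n); identity <- rep(NA_character_, n)
  key <- paste(tracks$kind, tracks$identity)
  for (k in c("person", "task", "face")) {   # increasing priority
    for (g in unique(key[tracks$kind == k])) {
      tr <- tracks[key == g, , drop = FALSE]
      bb <- interp_track_to(tr, t_out)
      hit <- bb$covered & !is.na(px) &
        px >= bb$x & px <= bb$x + bb$w & py >= bb$y & py <= bb$y + bb$h
      kind[hit] <- k
      identity[hit] <- tr$identity[1]
    }
  }
  label <- ifelse(kind == "none", "none",
                  ifelse(kind == "task", "task", paste0(kind, ":", identity)))
  data.frame(t = t_out, label = label, kind = kind, identity = identity,
             missing = is.na(px), stringsAsFactors = FALSE)
}

# Majority AOI label of the annotation samples within [start, end].
fixation_label <- function(annotation, start, end) {
  sel <- annotation$t >= start & annotation$t <= end & !annotation$missing
  if (!any(sel)) return("none")
  tab <- table(annotation$label[sel])
  names(tab)[which.max(tab)]
}

# TRUE if `label` means gaze on participant `who` (their face or person box).
label_on_person <- function(label, who) {
  label %in% paste0(c("face:", "person:"), who)
}

#' Per-face pupil baselines
#'
#' For each interlocutor face, the baseline is the mean pupil diameter during
#' the longest fixation labelled with that face that ends at or before noise
#' onset. Faces without a qualifying pre-onset fixation get a missing
#' baseline and a warning; downstream pupil features for that face are
#' skipped.
#'
#' @param pupil pupil trace from [process_pupil()].
#' @param annotation gaze-AOI annotation from [annotate_gaze()].
#' @param fixations event table from [classify_fixations_idt()].
#' @param noise_onset_s noise onset time (s).
#' @return list with `baselines` (named numeric, NA where missing) and
#'   `fixation` (data.frame of the chosen fixation per face).
#' @export
compute_pupil_baseline <- function(pupil, annotation, fixations, noise_onset_s) {
  faces <- unique(annotation$identity[annotation$kind == "face"])
  faces <- faces[!is.na(faces)]
  fx <- fixations[fixations$kind == "fixation" & fixations$end <= noise_onset_s, ,
                  drop = FALSE]
  baselines <- stats::setNames(rep(NA_real_, length(faces)), faces)
  chosen <- list()
  for (f in faces) {
    if (nrow(fx) > 0) {
      lab <- vapply(seq_len(nrow(fx)), function(i)
        fixation_label(annotation, fx$start[i], fx$end[i]), character(1))
      cand <- fx[lab == paste0("face:", f), , drop = FALSE]
    } else cand <- fx
    if (nrow(cand) == 0) {
      warning(sprintf("no pre-onset fixation on face %s; baseline missing", f),
              call. = FALSE)
      next
    }
    b <- cand[which.max(cand$duration), ]
    sel <- pupil$t >= b$start & pupil$t <= b$end & !is.na(pupil$mm)
    baselines[f] <- mean(pupil$mm[sel])
    b$face <- f
    chosen[[f]] <- b
  }
  list(baselines = baselines,
       fixation = if (length(chosen)) do.call(rbind, chosen) else NULL)
}

#' Baseline-subtracted pupil dilation on face samples
#'
#' Dilation is defined only on samples whose gaze is on an interlocutor's
#' face with an available baseline.
#'
#' @param pupil pupil trace.
#' @param annotation gaze-AOI annotation (on the same time grid).
#' @param baselines named baselines from [compute_pupil_baseline()].
#' @return data.frame `t`, `dilation`, `face`.
#' @export
pupil_dilation <- function(pupil, annotation, baselines) {
  stopifnot(nrow(pupil) == nrow(annotation))
  face <- ifelse(annotation$kind == "face", annotation$identity, NA_character_)
  base <- unname(baselines[face])
  data.frame(t = pupil$t, dilation = pupil$mm - base, face = face,
             stringsAsFactors = FALSE)
}
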