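#' Align the eye-tracker audio with the room recording
#'
#' The wearable eye tracker runs on its own clock; its built-in microphone
#' records the same acoustic scene as the room microphones. The clock offset
#' is estimated as the lag of the maximum normalised cross-correlation
#' between the two (mono) audio streams, searched within
#' `+/- search_range_s`. A peak correlation below `min_corr` flags an
#' alignment failure. The clock model is a constant offset (no drift).
#'
#' @param reference mono reference (room) signal.
#' @param glasses mono eye-tracker microphone signal at the same sample rate.
#' @param sr sample rate of both signals, Hz.
#' @param search_range_s lag search range (default 30 s).
#' @param min_corr failure floor on the peak normalised correlation.
#' @return list of class `alignment_result`: `offset_s` (positive when the
#'   glasses stream lags the reference; subtract from glasses timestamps to
#'   move them onto the reference clock), `peak_corr`, `ok`.
#' @export
align_streams <- function(reference, glasses, sr, search_range_s = 30,
                          min_corr = 0.2) {
  stop_if(sr <= 0, "sample rate must be > 0")
  max_lag <- min(round(search_range_s * sr),
                 max(length(reference), length(glasses)) - 1L)
  r <- xcorr_lag(reference, glasses, max_lag)
  ok <- r$corr >= min_corr
  if (!ok) warning("alignment failure: peak correlation below floor", call. = FALSE)
  structure(list(offset_s = r$lag / sr, peak_corr = r$corr, ok = ok),
            class = "alignment_result")
}

#' Trial configuration with all stage thresholds at their defaults
#'
#' Collects every tunable of the pipeline in one object: simulation
#' parameters (plan, acoustic scene, gaze script, AOI layout), segmentation
#' and gaze-processing thresholds, the AOI post-processing settings and the
#' metric windows. Every threshold defaults to the pipeline's canonical
#' value.
#'
#' @param seed trial seed; every stochastic stage derives its stream from it.
#' @param condition `"quiet"` or `"noise"`.
#' @param duration_s trial duration (s).
#' @param participants three participant ids.
#' @param group,trial group and trial identifiers for the feature export.
#' @param lead_in_s pre-conversation lead-in (noise onset time).
#' @param gap_params,overlap_prob,turn_params plan parameters
#'   ([simulate_turn_sequence()]).
#' @param scene,script,layout simulation components.
#' @param segmentation,gaze,aoi stage parameter lists.
#' @param window_s half-window of the turn-aligned metrics.
#' @param faces_in_people count face dwell inside the people AOI.
#' @param use_ground_truth_turns base the state timeline on the simulation's
#'   true turns instead of the detected ones (parameter-recovery mode).
#' @param align run the audio/eye-tracker clock alignment stage.
#' @param align_search_s,align_min_corr alignment stage settings.
#' @return list of class `trial_config`.
#' @export
trial_config <- function(seed = 1,
                         condition = c("quiet", "noise"),
                         duration_s = 60,
                         participants = c("P1", "P2", "P3"),
                         group = "G1", trial = "T1",
                         lead_in_s = 5,
                         gap_params = c(mean = 0.25, sd = 0.15),
                         overlap_prob = 0,
                         turn_params = c(mean = 3, sd = 1.5, min = 1.5),
                         scene = acoustic_scene(),
                         script = gaze_script(),
                         layout = aoi_layout(),
                         segmentation = segmentation_params(),
                         gaze = gaze_params(),
                         aoi = aoi_params(),
                         window_s = 4,
                         faces_in_people = TRUE,
                         use_ground_truth_turns = FALSE,
                         align = TRUE,
                         align_search_s = 2,
                         align_min_corr = 0.2) {
  condition <- match.arg(condition)
  structure(as.list(environment()), class = "trial_config")
}

#' Load a trial configuration from YAML
#'
#' Scalar fields override [trial_config()] defaults directly; the nested
#' `scene`, `script`, `segmentation`, `gaze`, `aoi` sections are merged into
#' the corresponding defaults field by field.
#'
#' @param path YAML file path.
#' @return a `trial_config`.
#' @export
load_trial_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- trial_config()
  nested <- intersect(names(y), c("scene", "script", "segmentation", "gaze", "aoi"))
  for (nm in nested) cfg[[nm]] <- utils::modifyList(cfg[[nm]], y[[nm]])
  scalars <- setdiff(names(y), nested)
  for (nm in scalars) cfg[[nm]] <- y[[nm]]
  for (nm in c("gap_params", "turn_params")) cfg[[nm]] <- unlist(cfg[[nm]])
  cfg
}

#' Simulate a complete synthetic trial
#'
#' Plan, 9-channel audio, and per-participant gaze/pupil/AOI streams with
#' ground truth, all derived deterministically from one seed.
#'
#' @param config a [trial_config()].
#' @return list with `plan`, `audio`, `audio_ground_truth`, `sims` (named per
#'   participant).
#' @export
simulate_trial <- function(config = trial_config()) {
  plan <- simulate_turn_sequence(config$participants, config$duration_s,
                                 config$gap_params, config$overlap_prob,
                                 config$turn_params, config$condition,
                                 config$lead_in_s, seed = config$seed)
  rend <- render_multichannel_audio(plan, config$scene, seed = config$seed + 1000L)
  sims <- lapply(seq_along(config$participants), function(i)
    simulate_gaze_trace(plan, config$script, config$layout,
                        config$participants[i], seed = config$seed + i))
  names(sims) <- config$participants
  list(plan = plan, audio = rend$audio, audio_ground_truth = rend$ground_truth,
       sims = sims)
}

# cheap deterministic checksum of a config for the output manifest
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 4294967291)
}

process_participant <- function(p, sim, turns, config, clock_offset_s = 0,
                                noise_onset_s) {
  log <- character(0)
  gz <- sim$gaze
  tracks <- sim$tracks
  gz$t <- gz$t - clock_offset_s
  tracks$t <- tracks$t - clock_offset_s

  excl <- exclude_trial_if_missing(gz, config$gaze$max_missing, config$gaze$sr)
  log <- c(log, sprintf("%s: missing fraction %.3f (%s)", p,
                        excl$missing_fraction, if (excl$keep) "keep" else "drop"))
  if (!excl$keep) {
    return(list(excluded = TRUE, missing_fraction = excl$missing_fraction,
                features = NULL, log = log))
  }
  blinks <- detect_blinks(gz, config$gaze)
  trace <- preprocess_gaze(gz, blinks, config$gaze)
  events <- classify_fixations_idt(trace, config$gaze$idt_dispersion_deg,
                                   config$gaze$idt_min_dur_s)
  pupil <- process_pupil(gz, blinks, config$gaze)
  log <- c(log, sprintf("%s: %d blinks, %d fixations, %d saccades", p,
                        nrow(blinks), sum(events$kind == "fixation"),
                        sum(events$kind == "saccade")))

  tracks_pp <- postprocess_aoi_track(tracks, config$aoi)
  pxy <- deg_to_px(trace$h, trace$v, config$gaze$frame_px, config$gaze$fov_deg)
  gaze_pp <- data.frame(t = trace$t, px = pxy$px, py = pxy$py)
  ann <- annotate_gaze(gaze_pp, tracks_pp)

  base <- compute_pupil_baseline(pupil, ann, events, noise_onset_s)
  dil <- pupil_dilation(pupil, ann, base$baselines)

  states <- label_states(turns, config$participants)
  st_p <- states[states$participant == p, , drop = FALSE]
  tr <- turn_transitions(turns, config$participants)

  dw <- dwell_time(ann, st_p, config$faces_in_people)
  on <- onset_metrics(turns, ann, events, p, config$participants, config$window_s)
  of <- offset_metrics(tr, ann, events, p, config$window_s)
  mv <- movement_features(events, st_p)
  pu <- pupil_features(dil, st_p)

  feats <- rbind(
    if (nrow(dw)) data.frame(state = dw$state,
                             metric = sprintf("dwell_%s_pct", dw$aoi),
                             value = dw$pct),
    if (!is.null(on$summary)) data.frame(state = on$summary$state,
                                         metric = paste0("onset_", on$summary$metric),
                                         value = on$summary$value),
    if (!is.null(of$summary)) data.frame(state = of$summary$state,
                                         metric = sprintf("offset_%s_%s",
                                                          of$summary$role,
                                                          of$summary$metric),
                                         value = of$summary$value),
    if (nrow(mv)) mv[, c("state", "metric", "value")],
    if (nrow(pu)) pu[, c("state", "metric", "value")])
  feats <- feats[!is.na(feats$value), , drop = FALSE]
  feats$participant <- p

  list(excluded = FALSE, missing_fraction = excl$missing_fraction,
       blinks = blinks, events = events, annotation = ann, pupil = pupil,
       baselines = base$baselines, states = st_p,
       onset_events = on$events, offset_events = of$events,
       features = feats[, c("participant", "state", "metric", "value")],
       log = log)
}

#' Run one trial end-to-end
#'
#' Simulates (or, in a later file mode, loads) a trial, aligns the
#' eye-tracker clock, segments speech into turns, extracts eye events,
#' annotates gaze with AOIs, and computes the per-participant turn-aligned
#' features. Deterministic for a fixed seed. Participant-level exclusions
#' (e.g. > 30% missing gaze) are recorded, not fatal.
#'
#' @param config a [trial_config()].
#' @return list of class `trial_result`: `features` (long data.frame),
#'   `turns` (detected), `ground_truth`, `participants` (per-participant
#'   stage outputs), `manifest`, `log`.
#' @export
run_trial <- function(config = trial_config()) {
  stop_if(!inherits(config, "trial_config"), "config must be a trial_config")
  sim <- simulate_trial(config)
  log <- sprintf("trial %s/%s: condition=%s seed=%d duration=%.0fs",
                 config$group, config$trial, config$condition, config$seed,
                 config$duration_s)

  # clock alignment on a decimated downmix of the close-mouth channels
  clock_offset <- config$script$clock_offset_s
  est_offset <- 0
  if (isTRUE(config$align) && clock_offset != 0) {
    dec <- 6L
    mix <- rowMeans(sim$audio$samples[, sim$audio$channels$role == "close_mouth"])
    room <- mix[seq(1, length(mix), by = dec)]
    glasses <- delay_samples(mix, clock_offset * sim$audio$sr)[
      seq(1, length(mix), by = dec)]
    al <- align_streams(room, glasses, sim$audio$sr / dec, config$align_search_s,
                        config$align_min_corr)
    stop_if(!al$ok, "alignment stage failed (peak correlation %.2f)", al$peak_corr)
    est_offset <- al$offset_s
    log <- c(log, sprintf("alignment: offset %.4f s (true %.4f), corr %.2f",
                          est_offset, clock_offset, al$peak_corr))
  } else if (clock_offset != 0) {
    est_offset <- clock_offset   # trust the configured offset when not aligning
  }

  seg <- tryCatch(segment_speech(sim$audio, config$segmentation),
                  error = function(e) stop("speech_segmentation: ",
                                           conditionMessage(e), call. = FALSE))
  log <- c(log, sprintf("segmentation: %d utterances, %d turns",
                        nrow(seg$utterances), nrow(seg$turns)))
  turns <- if (config$use_ground_truth_turns) sim$plan$turns else seg$turns

  parts <- lapply(config$participants, function(p)
    tryCatch(process_participant(p, sim$sims[[p]], turns, config, est_offset,
                                 config$lead_in_s),
             error = function(e) stop("gaze_pipeline[", p, "]: ",
                                      conditionMessage(e), call. = FALSE)))
  names(parts) <- config$participants
  for (p in parts) log <- c(log, p$log)

  feats <- do.call(rbind, lapply(parts, `[[`, "features"))
  rownames(feats) <- NULL
  structure(list(
    group = config$group, trial = config$trial, condition = config$condition,
    features = feats, turns = seg$turns,
    ground_truth = c(list(plan = sim$plan, audio = sim$audio_ground_truth),
                     lapply(sim$sims, `[[`, "ground_truth")),
    participants = parts,
    manifest = list(config_hash = config_hash(config), seed = config$seed,
                    package_version = as.character(utils::packageVersion("convoscope")),
                    r_version = R.version.string),
    log = log), class = "trial_result")
}

#' Run a batch of trials and export the tidy feature table
#'
#' @param configs list of [trial_config()] objects (e.g. 3 quiet + 3 noise
#'   mirroring one session).
#' @return list with `trials` (list of `trial_result`) and `features`
#'   (combined long table from [export_features()]).
#' @export
run_batch <- function(configs) {
  trials <- lapply(configs, run_trial)
  list(trials = trials, features = export_features(trials))
}
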