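# Interval algebra on data.frames with columns start, end (closed-open).
interval_union <- function(iv) {
  if (nrow(iv) < 2) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  merge_close_intervals(iv, 0)
}

interval_diff <- function(a, b) {
  # a minus b, both data.frames(start, end)
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  b <- interval_union(b)
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]; e <- a$end[i]
    segs <- data.frame(start = s, end = e)
    for (j in seq_len(nrow(b))) {
      new <- list()
      for (k in seq_len(nrow(segs))) {
        s0 <- segs$start[k]; e0 <- segs$end[k]
        if (b$end[j] <= s0 || b$start[j] >= e0) {
          new[[length(new) + 1L]] <- c(s0, e0)
        } else {
          if (b$start[j] > s0) new[[length(new) + 1L]] <- c(s0, b$start[j])
          if (b$end[j] < e0) new[[length(new) + 1L]] <- c(b$end[j], e0)
        }
      }
      segs <- if (length(new)) as.data.frame(do.call(rbind, new)) else
        data.frame(V1 = numeric(0), V2 = numeric(0))
      names(segs) <- c("start", "end")
      if (nrow(segs) == 0) break
    }
    out[[length(out) + 1L]] <- segs
  }
  res <- do.call(rbind, out)
  res[res$end - res$start > 0, , drop = FALSE]
}

in_intervals <- function(t, iv) {
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) out <- out | (t >= iv$start[i] & t < iv$end[i])
  out
}

#' Conversation-state timeline
#'
#' For each participant, labels intervals as `talking` (their own turns) or
#' `listening` (another participant's turns minus their own talking;
#' simultaneous speech counts as talking). Time outside any turn is
#' unlabeled.
#'
#' @param turns turn table (`talker`, `onset`, `offset`).
#' @param participants participant ids.
#' @return data.frame `participant`, `state`, `start`, `end`.
#' @export
label_states <- function(turns, participants) {
  out <- list()
  for (p in participants) {
    own <- turns[turns$talker == p, , drop = FALSE]
    own_iv <- data.frame(start = own$onset, end = own$offset)
    oth <- turns[turns$talker != p, , drop = FALSE]
    oth_iv <- interval_union(data.frame(start = oth$onset, end = oth$offset))
    listen <- interval_diff(oth_iv, own_iv)
    if (nrow(own_iv) > 0) {
      out[[length(out) + 1L]] <- data.frame(participant = p, state = "talking",
                                            start = own_iv$start, end = own_iv$end)
    }
    if (nrow(listen) > 0) {
      out[[length(out) + 1L]] <- data.frame(participant = p, state = "listening",
                                            start = listen$start, end = listen$end)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(participant = character(0), state = character(0),
                      start = numeric(0), end = numeric(0))
  }
  res <- res[order(res$participant, res$start), ]
  rownames(res) <- NULL
  res
}

#' Turn transitions with role labels
#'
#' Consecutive turns (ordered by onset) by different talkers form a
#' transition. Per transition, the talker of the next turn is the
#' `next_talker`; for the outgoing talker the third participant is the
#' `remaining_listener`; a listener's role at the listening offset is
#' `self_turn` if they take the next turn, else `other_turn`. Consecutive
#' turns by the same talker produce no transition.
#'
#' @param turns turn table.
#' @param participants all participant ids (needed to resolve the remaining
#'   listener).
#' @return data.frame `prev_talker`, `next_talker`, `remaining_listener`,
#'   `prev_offset`, `next_onset`.
#' @export
turn_transitions <- function(turns, participants) {
  turns <- turns[order(turns$onset), , drop = FALSE]
  if (nrow(turns) < 2) {
    return(data.frame(prev_talker = character(0), next_talker = character(0),
                      remaining_listener = character(0),
                      prev_offset = numeric(0), next_onset = numeric(0)))
  }
  i <- 1:(nrow(turns) - 1)
  tr <- data.frame(prev_talker = turns$talker[i],
                   next_talker = turns$talker[i + 1],
                   prev_offset = turns$offset[i],
                   next_onset = turns$onset[i + 1],
                   stringsAsFactors = FALSE)
  tr <- tr[tr$prev_talker != tr$next_talker, , drop = FALSE]
  tr$remaining_listener <- vapply(seq_len(nrow(tr)), function(k)
    setdiff(participants, c(tr$prev_talker[k], tr$next_talker[k]))[1], character(1))
  rownames(tr) <- NULL
  tr[, c("prev_talker", "next_talker", "remaining_listener",
         "prev_offset", "next_onset")]
}

#' Dwell time per AOI and conversation state
#'
#' Percentage of a state's non-missing gaze samples labelled with each AOI
#' class. Face dwell is reported separately; `people` additionally reports
#' faces counted inside the person AOI (the three-AOI presentation:
#' task, interlocutors, faces).
#'
#' @param annotation gaze-AOI annotation for one participant.
#' @param states state timeline rows for that participant.
#' @param faces_in_people logical: count face samples inside `people`.
#' @return data.frame `state`, `aoi` (face/person/task/none/people), `pct`.
#'   The classes face + person + task + none sum to 100 per state.
#' @export
dwell_time <- function(annotation, states, faces_in_people = TRUE) {
  out <- list()
  for (st in unique(states$state)) {
    iv <- states[states$state == st, c("start", "end")]
    sel <- in_intervals(annotation$t, iv) & !annotation$missing
    if (!any(sel)) {
      warning(sprintf("no valid gaze samples in state %s", st), call. = FALSE)
      next
    }
    kinds <- factor(annotation$kind[sel], c("face", "person", "task", "none"))
    pct <- 100 * as.numeric(table(kinds)) / sum(sel)
    df <- data.frame(state = st, aoi = levels(kinds), pct = pct,
                     stringsAsFactors = FALSE)
    if (faces_in_people) {
      df <- rbind(df, data.frame(state = st, aoi = "people",
                                 pct = pct[1] + pct[2]))
    }
    out[[length(out) + 1L]] <- df
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(state = character(0), aoi = character(0),
                                      pct = numeric(0))
  rownames(res) <- NULL
  res
}

# first annotated sample within [anchor - w, anchor + w] whose label is on
# any of `targets`; returns signed latency or NA
first_entry_latency <- function(annotation, anchor, targets, window_s) {
  sel <- annotation$t >= anchor - window_s & annotation$t <= anchor + window_s &
    !annotation$missing
  if (!any(sel)) return(NA_real_)
  tt <- annotation$t[sel]; lab <- annotation$label[sel]
  on <- Reduce(`|`, lapply(targets, function(x) label_on_person(lab, x)))
  if (!any(on)) return(NA_real_)
  tt[which(on)[1]] - anchor
}

#' Gaze metrics at turn onsets
#'
#' For each listening onset (another talker's turn onset), the latency is the
#' signed time relative to the onset at which gaze first enters the new
#' talker's AOI within a +/- `window_s` window; the trial summary is the
#' median and IQR of the latencies and the probability that the first
#' fixation starting after the onset (within the window) is on the talker.
#' Talking onsets are treated analogously with the listeners' (people) AOIs
#' as target. Events with no qualifying sample/fixation contribute nothing
#' and the event count is decremented.
#'
#' @param turns turn table.
#' @param annotation gaze-AOI annotation for the observed participant.
#' @param fixations event table ([classify_fixations_idt()]).
#' @param participant the observed participant.
#' @param participants all ids.
#' @param window_s half-window around the onset (default 4 s).
#' @return list with `summary` (data.frame state/metric/value/n) and `events`
#'   (per-event audit table).
#' @export
onset_metrics <- function(turns, annotation, fixations, participant,
                          participants, window_s = 4) {
  fx <- fixations[fixations$kind == "fixation", , drop = FALSE]
  if (nrow(fx) > 0) {
    fx$label <- vapply(seq_len(nrow(fx)), function(i)
      fixation_label(annotation, fx$start[i], fx$end[i]), character(1))
  }
  ev <- list()
  for (i in seq_len(nrow(turns))) {
    o <- turns$onset[i]; talker <- turns$talker[i]
    state <- if (talker == participant) "talking" else "listening"
    targets <- if (state == "listening") talker else setdiff(participants, participant)
    lat <- first_entry_latency(annotation, o, targets, window_s)
    ffix <- NA
    if (nrow(fx) > 0) {
      cand <- fx[fx$start > o & fx$start <= o + window_s, , drop = FALSE]
      if (nrow(cand) > 0) {
        lab1 <- cand$label[1]
        ffix <- any(vapply(targets, function(x) label_on_person(lab1, x), logical(1)))
      }
    }
    ev[[length(ev) + 1L]] <- data.frame(
      state = state, anchor = o, target = paste(targets, collapse = "+"),
      latency = lat, first_fix_on_target = ffix, stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(state = character(0), anchor = numeric(0), target = character(0),
               latency = numeric(0), first_fix_on_target = logical(0))
  summ <- do.call(rbind, lapply(unique(events$state), function(st) {
    e <- events[events$state == st, ]
    lat <- e$latency[!is.na(e$latency)]
    ff <- e$first_fix_on_target[!is.na(e$first_fix_on_target)]
    if (!length(lat)) {
      warning(sprintf("no qualifying %s-onset events", st), call. = FALSE)
      return(NULL)
    }
    data.frame(state = st,
               metric = c("median_latency_s", "iqr_latency_s", "p_first_fixation"),
               value = c(stats::median(lat), stats::IQR(lat),
                         if (length(ff)) mean(ff) else NA_real_),
               n = c(length(lat), length(lat), length(ff)),
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, events = events)
}

# dwell percentage on a person within [anchor - w, anchor + w]
window_dwell_pct <- function(annotation, anchor, who, window_s) {
  sel <- annotation$t >= anchor - window_s & annotation$t <= anchor + window_s &
    !annotation$missing
  if (!any(sel)) return(NA_real_)
  100 * mean(label_on_person(annotation$label[sel], who))
}

#' Gaze metrics at turn offsets, split by role
#'
#' For each transition between turns of different talkers:
#'
#' * Listening offsets (the observed participant was listening to the
#'   outgoing talker): the latency is the signed time, relative to the
#'   offset, at which gaze last leaves the outgoing talker's AOI within the
#'   window (`latency`, sample-based; `latency_fix` anchors to the end of
#'   the last fixation instead); the last-fixation probability asks whether the final
#'   fixation ending before the offset is on the talker; the dwell
#'   difference is dwell%(outgoing talker) - dwell%(other listener) within
#'   the window. All three are split by role: `self_turn` (the observed
#'   listener takes the next turn) vs `other_turn`.
#' * Talking offsets (the observed participant is the outgoing talker): the
#'   same measures computed toward the listener who takes the next turn
#'   (`next_talker`) vs the one who keeps listening (`remaining_listener`),
#'   with the dwell difference reported as next-talker minus remaining
#'   listener.
#'
#' @inheritParams onset_metrics
#' @param transitions transitions from [turn_transitions()].
#' @return list with `summary` and `events`.
#' @export
offset_metrics <- function(transitions, annotation, fixations, participant,
                           window_s = 4) {
  fx <- fixations[fixations$kind == "fixation", , drop = FALSE]
  if (nrow(fx) > 0) {
    fx$label <- vapply(seq_len(nrow(fx)), function(i)
      fixation_label(annotation, fx$start[i], fx$end[i]), character(1))
  }
  last_fix_latency <- function(anchor, who) {
    cand <- fx[fx$end >= anchor - window_s & fx$end <= anchor + window_s &
                 vapply(fx$label, label_on_person, logical(1), who = who), ,
               drop = FALSE]
    if (nrow(cand) == 0) return(NA_real_)
    max(cand$end) - anchor
  }
  # sample-based departure: last annotated sample on `who` within the window
  last_sample_latency <- function(anchor, who) {
    sel <- annotation$t >= anchor - window_s & annotation$t <= anchor + window_s &
      !annotation$missing
    if (!any(sel)) return(NA_real_)
    tt <- annotation$t[sel]
    on <- label_on_person(annotation$label[sel], who)
    if (!any(on)) return(NA_real_)
    tt[max(which(on))] - anchor
  }
  last_fix_before <- function(anchor) {
    cand <- fx[fx$end <= anchor & fx$end >= anchor - window_s, , drop = FALSE]
    if (nrow(cand) == 0) return(NA_character_)
    cand$label[which.max(cand$end)]
  }
  ev <- list()
  for (i in seq_len(nrow(transitions))) {
    tr <- transitions[i, ]
    off <- tr$prev_offset
    if (tr$prev_talker == participant) {
      # talking offset: measures toward each listener role
      for (role in c("next_talker", "remaining_listener")) {
        who <- tr[[role]]
        lab <- last_fix_before(off)
        ev[[length(ev) + 1L]] <- data.frame(
          state = "talking", role = role, anchor = off, target = who,
          latency = last_sample_latency(off, who),
          latency_fix = last_fix_latency(off, who),
          last_fix_on_target = if (is.na(lab)) NA else label_on_person(lab, who),
          dwell_pct = window_dwell_pct(annotation, off, who, window_s),
          stringsAsFactors = FALSE)
      }
    } else {
      # listening offset
      role <- if (tr$next_talker == participant) "self_turn" else "other_turn"
      other_listener <- setdiff(c(tr$next_talker, tr$remaining_listener),
                                participant)
      lab <- last_fix_before(off)
      ev[[length(ev) + 1L]] <- data.frame(
        state = "listening", role = role, anchor = off, target = tr$prev_talker,
        latency = last_sample_latency(off, tr$prev_talker),
        latency_fix = last_fix_latency(off, tr$prev_talker),
        last_fix_on_target = if (is.na(lab)) NA
                             else label_on_person(lab, tr$prev_talker),
        dwell_pct = window_dwell_pct(annotation, off, tr$prev_talker, window_s) -
          window_dwell_pct(annotation, off, other_listener, window_s),
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(state = character(0), role = character(0), anchor = numeric(0),
               target = character(0), latency = numeric(0),
               latency_fix = numeric(0), last_fix_on_target = logical(0),
               dwell_pct = numeric(0))
  combos <- unique(events[, c("state", "role")])
  summ <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    e <- events[events$state == combos$state[k] & events$role == combos$role[k], ]
    lat <- e$latency[!is.na(e$latency)]
    lf <- e$last_fix_on_target[!is.na(e$last_fix_on_target)]
    dw <- e$dwell_pct[!is.na(e$dwell_pct)]
    # listening events already carry talker-minus-other-listener differences;
    # talking events carry the dwell toward the role's target
    dw_metric <- if (combos$state[k] == "listening") "dwell_diff_pct" else "dwell_pct"
    data.frame(state = combos$state[k], role = combos$role[k],
               metric = c("median_latency_s", "p_last_fixation", dw_metric),
               value = c(if (length(lat)) stats::median(lat) else NA_real_,
                         if (length(lf)) mean(lf) else NA_real_,
                         if (length(dw)) stats::median(dw) else NA_real_),
               n = c(length(lat), length(lf), length(dw)),
               stringsAsFactors = FALSE)
  }))
  # talking: dwell difference next talker minus remaining listener, per event
  tk <- events[events$state == "talking", , drop = FALSE]
  if (nrow(tk) > 0) {
    nx <- tk[tk$role == "next_talker", c("anchor", "dwell_pct")]
    rm_ <- tk[tk$role == "remaining_listener", c("anchor", "dwell_pct")]
    m <- merge(nx, rm_, by = "anchor", suffixes = c("_next", "_rem"))
    d <- m$dwell_pct_next - m$dwell_pct_rem
    d <- d[!is.na(d)]
    if (length(d)) {
      summ <- rbind(summ, data.frame(
        state = "talking", role = "next_vs_remaining",
        metric = "dwell_diff_pct", value = stats::median(d), n = length(d),
        stringsAsFactors = FALSE))
    }
  }
  list(summary = summ, events = events)
}

#' Eye-movement features per conversation state
#'
#' Saccade rate = number of saccade onsets inside the state's intervals
#' divided by the state's total duration; mean fixation duration over
#' fixations whose midpoint lies in the state.
#'
#' @param events event table from [classify_fixations_idt()].
#' @param states state timeline rows for the participant.
#' @return data.frame `state`, `metric`, `value`, `n`.
#' @export
movement_features <- function(events, states) {
  out <- list()
  for (st in unique(states$state)) {
    iv <- states[states$state == st, c("start", "end")]
    dur <- sum(iv$end - iv$start)
    if (dur <= 0) next
    sac <- events[events$kind == "saccade", , drop = FALSE]
    fx <- events[events$kind == "fixation", , drop = FALSE]
    nsac <- sum(in_intervals(sac$start, iv))
    mid <- (fx$start + fx$end) / 2
    infx <- in_intervals(mid, iv)
    out[[length(out) + 1L]] <- data.frame(
      state = st,
      metric = c("saccade_rate_hz", "mean_fixation_duration_s"),
      value = c(nsac / dur,
                if (any(infx)) mean(fx$duration[infx]) else NA_real_),
      n = c(nsac, sum(infx)), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(state = character(0), metric = character(0),
                                      value = numeric(0), n = integer(0))
  res
}

#' Pupil features per conversation state
#'
#' Mean and maximum baseline-subtracted pupil dilation, restricted to
#' samples recorded while gaze was on an interlocutor's face.
#'
#' @param dilation dilation trace from [pupil_dilation()].
#' @param states state timeline rows for the participant.
#' @return data.frame `state`, `metric`, `value`, `n`.
#' @export
pupil_features <- function(dilation, states) {
  out <- list()
  for (st in unique(states$state)) {
    iv <- states[states$state == st, c("start", "end")]
    sel <- in_intervals(dilation$t, iv) & !is.na(dilation$dilation)
    if (!any(sel)) {
      warning(sprintf("no face-gaze pupil samples in state %s", st), call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      state = st,
      metric = c("mean_pupil_dilation_mm", "max_pupil_dilation_mm"),
      value = c(mean(dilation$dilation[sel]), max(dilation$dilation[sel])),
      n = sum(sel), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(state = character(0), metric = character(0),
                                      value = numeric(0), n = integer(0))
  res
}

#' Export per-trial features as a tidy long table
#'
#' One row per (group, participant, trial, condition, state, feature);
#' missing features produce no row. The schema mirrors the factors of the
#' downstream mixed-model analysis (condition x conversation state, grouped
#' by participant within group).
#'
#' @param trial_features list of per-trial results as produced by
#'   [run_trial()] (or a list with elements `group`, `trial`, `condition`,
#'   `features` where `features` has participant/state/metric/value columns).
#' @return data.frame `group`, `participant`, `trial`, `condition`, `state`,
#'   `feature`, `value`.
#' @export
export_features <- function(trial_features) {
  rows <- lapply(trial_features, function(tr) {
    f <- tr$features
    if (is.null(f) || nrow(f) == 0) return(NULL)
    data.frame(group = tr$group, participant = f$participant, trial = tr$trial,
               condition = tr$condition, state = f$state, feature = f$metric,
               value = f$value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(group = character(0), participant = character(0),
                      trial = character(0), condition = character(0),
                      state = character(0), feature = character(0),
                      value = numeric(0))
  }
  res <- res[!is.na(res$value), , drop = FALSE]
  rownames(res) <- NULL
  res
}
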