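#' Simulate a triadic conversation turn sequence
#'
#' Generates a plan of talker-attributed turns for a three-party
#' conversation: an alternating-talker sequence (the next talker is always
#' one of the other two participants) with inter-turn gaps drawn from a
#' truncated normal distribution and optional onset overlaps. Turn durations
#' are drawn from a gamma distribution and floored well above 1 s so that
#' every ground-truth turn survives the downstream 1-s minimum-turn filter.
#'
#' Conversation proper starts after a lead-in period (`lead_in_s`) during
#' which only background is present; the lead-in models the pre-noise-onset
#' interval used for pupil baselines.
#'
#' @param participants character vector of exactly 3 participant ids.
#' @param duration_s trial duration in seconds (> 0), including the lead-in.
#' @param gap_params named numeric `c(mean =, sd =)` of the inter-turn gap in
#'   seconds. Default mean 0.25 s, the canonical conversational gap.
#' @param overlap_prob probability that a turn starts before the previous one
#'   ends (overlap drawn uniformly from 0.1-0.4 s).
#' @param turn_params named numeric `c(mean =, sd =, min =)` of turn duration
#'   in seconds (gamma-distributed, floored at `min`).
#' @param condition condition label, `"quiet"` or `"noise"`.
#' @param lead_in_s seconds before the first turn (noise onset time).
#' @param seed integer seed; the plan is deterministic given all arguments.
#' @return object of class `conversation_plan`: list with `participants`,
#'   `turns` (data.frame talker/onset/offset), `duration`, `condition`,
#'   `noise_onset_s`, `gap_params`, `overlap_prob`, `seed`.
#' @export
simulate_turn_sequence <- function(participants = c("P1", "P2", "P3"),
                                   duration_s = 60,
                                   gap_params = c(mean = 0.25, sd = 0.15),
                                   overlap_prob = 0,
                                   turn_params = c(mean = 3, sd = 1.5, min = 1.5),
                                   condition = c("quiet", "noise"),
                                   lead_in_s = 5,
                                   seed = 1) {
  condition <- match.arg(condition)
  stop_if(duration_s <= 0, "duration_s must be > 0")
  stop_if(length(participants) != 3, "exactly 3 participants required")
  stop_if(anyDuplicated(participants) > 0, "participant ids must be unique")
  stop_if(lead_in_s < 0 || lead_in_s >= duration_s, "lead_in_s must be in [0, duration)")
  stop_if(overlap_prob < 0 || overlap_prob > 1, "overlap_prob must be in [0, 1]")

  set.seed(seed)
  tmean <- turn_params[["mean"]]; tsd <- turn_params[["sd"]]
  tmin <- if ("min" %in% names(turn_params)) turn_params[["min"]] else 1.5
  shape <- (tmean / tsd)^2; rate <- tmean / tsd^2

  talker <- character(0); onset <- numeric(0); offset <- numeric(0)
  cur <- sample(participants, 1)
  t <- lead_in_s
  while (TRUE) {
    dur <- max(tmin, stats::rgamma(1, shape = shape, rate = rate))
    if (t + tmin > duration_s) break
    end <- min(t + dur, duration_s)
    if (end - t < tmin - 1e-9) break   # truncated tail too short for a turn
    talker <- c(talker, cur); onset <- c(onset, t); offset <- c(offset, end)
    # hand over to one of the other two participants
    cur <- sample(setdiff(participants, cur), 1)
    if (stats::runif(1) < overlap_prob) {
      t <- end - stats::runif(1, 0.1, 0.4)
    } else {
      gap <- max(0.05, stats::rnorm(1, gap_params[["mean"]], gap_params[["sd"]]))
      t <- end + gap
    }
  }
  structure(list(participants = participants,
                 turns = data.frame(talker = talker, onset = onset, offset = offset,
                                    stringsAsFactors = FALSE),
                 duration = duration_s, condition = condition,
                 noise_onset_s = lead_in_s,
                 gap_params = gap_params, overlap_prob = overlap_prob,
                 turn_params = turn_params, seed = seed),
            class = "conversation_plan")
}

#' @export
print.conversation_plan <- function(x, ...) {
  cat(sprintf("<conversation_plan> %d turns, %.0f s, condition=%s, participants=%s\n",
              nrow(x$turns), x$duration, x$condition,
              paste(x$participants, collapse = ",")))
  invisible(x)
}
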