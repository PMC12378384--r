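#' Simulate a turn-taking conversation as a list of inter-pausal units
#'
#' Generates a sequence of non-overlapping IPUs (inter-pausal units: stretches
#' of continuous speech bounded by silences longer than 200 ms) on a single
#' shared timeline. Speakers alternate stochastically; every inter-IPU gap is
#' strictly longer than 200 ms so the generated sequence satisfies the IPU
#' definition by construction.
#'
#' IPU durations are gamma-distributed (shape 2) with mean
#' `turn_params$mean_turn`; gaps are 0.201 s plus an exponential with mean
#' `mean_gap - 0.201` so that the mean gap equals `mean_gap`. The expected IPU
#' count is therefore approximately `duration / (mean_turn + mean_gap)`.
#'
#' @param duration Conversation duration in seconds.
#' @param turn_params List with elements `mean_turn` (mean IPU duration,
#'   seconds; default 3), `mean_gap` (mean inter-IPU silence, seconds;
#'   default 1), `p_switch` (probability the next IPU changes speaker;
#'   default 0.75), `min_turn` (shortest IPU, seconds; default 0.15).
#' @param seed Integer seed; the call is deterministic given it.
#' @param trial_id Identifier stored on every IPU (block/trial number).
#' @param first_speaker `"participant"`, `"interlocutor"`, or `"random"`.
#' @return A data frame with columns `onset`, `offset`, `speaker`
#'   (`participant`/`interlocutor`), `trial_id`. Empty (with a warning) if
#'   `duration` is too short to place one IPU.
#' @seealso [generate_respiration()], [render_rms_envelope()]
#' @export
#' @examples
#' ipus <- generate_conversation(60, seed = 1)
#' head(ipus)
generate_conversation <- function(duration,
                                  turn_params = list(),
                                  seed = 1L,
                                  trial_id = 1L,
                                  first_speaker = "random") {
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  p <- utils::modifyList(
    list(mean_turn = 3, mean_gap = 1, p_switch = 0.75, min_turn = 0.15),
    turn_params)
  stopifnot(p$mean_turn > 0, p$mean_gap > 0.201, p$p_switch >= 0,
            p$p_switch <= 1)
  set.seed(child_seed(seed, 11L))

  speakers <- c("participant", "interlocutor")
  cur <- switch(first_speaker,
                random = sample(speakers, 1L),
                participant = "participant",
                interlocutor = "interlocutor",
                stop_bad("unknown first_speaker '%s'", first_speaker))

  onset <- numeric(0); offset <- numeric(0); who <- character(0)
  t <- rexp(1L, rate = 1 / p$mean_gap)  # lead-in silence
  repeat {
    len <- max(p$min_turn, rgamma(1L, shape = 2, scale = p$mean_turn / 2))
    if (t + len > duration) break
    onset <- c(onset, t); offset <- c(offset, t + len); who <- c(who, cur)
    gap <- 0.201 + rexp(1L, rate = 1 / (p$mean_gap - 0.201))
    t <- t + len + gap
    if (runif(1L) < p$p_switch) cur <- setdiff(speakers, cur)
  }
  if (length(onset) == 0L) {
    warn_msg("duration %.3f s too short to place one IPU; returning empty list",
             duration)
  }
  data.frame(onset = onset, offset = offset, speaker = who,
             trial_id = rep(as.integer(trial_id), length(onset)),
             stringsAsFactors = FALSE)
}
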