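#' Render a synthetic RMS speech envelope from an IPU list
#'
#' Stands in for the RMS envelope of denoised conversational audio: frames
#' whose centre falls inside an IPU carry the speech level, all others the
#' background-noise level, each with multiplicative log-normal jitter (so a
#' zero noise level yields an exactly zero envelope outside speech).
#'
#' @param ipu_list Data frame with `onset`/`offset` (seconds); typically the
#'   participant's IPUs only, emulating a single audio channel.
#' @param duration Envelope duration in seconds (default: last IPU offset).
#' @param frame Frame spacing in seconds (grid step; default 0.01).
#' @param speech_level,noise_level RMS levels in a.u.;
#'   `speech_level > noise_level >= 0`.
#' @param jitter_sd Standard deviation of the log-normal jitter (default 0.1).
#' @param seed Integer seed.
#' @return An object of class `rms_env`: list with `value`, `time` (frame
#'   centres), `hop`, `frame`.
#' @export
render_rms_envelope <- function(ipu_list, duration = NULL, frame = 0.01,
                                speech_level = 1, noise_level = 0.1,
                                jitter_sd = 0.1, seed = 1L) {
  stopifnot(frame > 0, speech_level > noise_level, noise_level >= 0)
  if (is.null(duration)) {
    duration <- if (nrow(ipu_list)) max(ipu_list$offset) else 1
  }
  set.seed(child_seed(seed, 23L))
  centers <- seq(frame / 2, duration, by = frame)
  inside <- rep(FALSE, length(centers))
  for (i in seq_len(nrow(ipu_list))) {
    inside <- inside | (centers >= ipu_list$onset[i] &
                          centers < ipu_list$offset[i])
  }
  level <- ifelse(inside, speech_level, noise_level)
  value <- level * exp(rnorm(length(centers), 0, jitter_sd))
  structure(list(value = value, time = centers, hop = frame, frame = frame),
            class = "rms_env")
}

#' @export
print.rms_env <- function(x, ...) {
  cat(sprintf("<rms_env> %d frames, hop %g s, span [%.3f, %.3f] s\n",
              length(x$value), x$hop, x$time[1], x$time[length(x$time)]))
  invisible(x)
}
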