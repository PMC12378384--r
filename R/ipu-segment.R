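#' Root-mean-square envelope of an audio signal
#'
#' Per-frame RMS amplitude on a hop-spaced grid; frame centres are reported.
#' Defaults (25 ms frame, 10 ms hop) are standard speech-analysis
#' granularity.
#'
#' @param samples Numeric audio samples (mono).
#' @param rate Sampling rate, Hz.
#' @param frame Frame length, seconds (`frame >= hop`).
#' @param hop Hop between frame starts, seconds.
#' @return An object of class `rms_env` (see [render_rms_envelope()]).
#' @export
rms_envelope <- function(samples, rate, frame = 0.025, hop = 0.010) {
  stopifnot(frame >= hop, hop > 0, rate > 0)
  n <- length(samples)
  flen <- max(1L, round(frame * rate))
  hlen <- max(1L, round(hop * rate))
  if (n < flen) stop_bad("audio (%d samples) shorter than one frame (%d)",
                         n, flen)
  starts <- seq(1L, n - flen + 1L, by = hlen)
  s2 <- cumsum(c(0, samples^2))
  value <- sqrt((s2[starts + flen] - s2[starts]) / flen)
  centers <- (starts - 1L + (flen - 1L) / 2) / rate
  structure(list(value = value, time = centers, hop = hlen / rate,
                 frame = flen / rate),
            class = "rms_env")
}

#' Speech/silence threshold from the RMS distribution
#'
#' A float coefficient applied to the mean of the RMS distribution gives the
#' participant-specific amplitude threshold that separates silence from
#' speech. Coefficients outside the working range 0.20-0.95 are accepted
#' with a warning.
#'
#' @param envelope An `rms_env` or a numeric vector of RMS values.
#' @param coefficient Multiplier on the envelope mean.
#' @return Threshold in a.u.
#' @export
threshold_from_rms <- function(envelope, coefficient) {
  v <- if (inherits(envelope, "rms_env")) envelope$value else envelope
  if (!length(v)) stop_bad("empty envelope")
  if (coefficient < 0.20 || coefficient > 0.95) {
    warn_msg("coefficient %.3f outside the working range [0.20, 0.95]",
             coefficient)
  }
  thr <- coefficient * mean(v)
  if (thr == 0) {
    message("zero envelope: threshold 0, everything will classify as speech")
  }
  thr
}

#' Segment an RMS envelope into inter-pausal units
#'
#' Frames at or above the threshold are speech. Sub-threshold runs lasting
#' `min_pause` or less are merged into the surrounding speech (an IPU is
#' bounded by silences lasting *longer than* 200 ms, so a pause of exactly
#' 200 ms merges); remaining speech runs shorter than `min_ipu` are dropped
#' (click suppression). Boundaries are placed at frame-tile edges
#' (`centre +/- hop/2`), i.e. at frame-centre resolution.
#'
#' @param envelope An `rms_env` ([rms_envelope()] or
#'   [render_rms_envelope()]).
#' @param threshold Amplitude threshold, a.u. (see [threshold_from_rms()]).
#' @param min_pause Longest pause merged into an IPU, seconds (default 0.2).
#' @param min_ipu Shortest retained IPU, seconds (default 0.1).
#' @param speaker Speaker label stored on the IPUs.
#' @param trial_id Trial identifier stored on the IPUs.
#' @return IPU data frame (`onset`, `offset`, `speaker`, `trial_id`).
#' @export
segment_ipus <- function(envelope, threshold, min_pause = 0.2,
                         min_ipu = 0.1, speaker = "participant",
                         trial_id = 1L) {
  stopifnot(inherits(envelope, "rms_env"))
  v <- envelope$value
  tm <- envelope$time
  hop <- envelope$hop
  speech <- v >= threshold
  if (!any(speech)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      speaker = character(0), trial_id = integer(0),
                      stringsAsFactors = FALSE))
  }
  # merge short pauses: a silent run of k frames spans k * hop seconds
  sil <- find_runs(!speech)
  for (i in seq_len(nrow(sil))) {
    k <- sil[i, 2] - sil[i, 1] + 1L
    interior <- sil[i, 1] > 1L && sil[i, 2] < length(v)
    if (interior && k * hop <= min_pause + 1e-9) {
      speech[sil[i, 1]:sil[i, 2]] <- TRUE
    }
  }
  runs <- find_runs(speech)
  onset <- tm[runs[, 1]] - hop / 2
  offset <- tm[runs[, 2]] + hop / 2
  keep <- (offset - onset) >= min_ipu - 1e-9
  data.frame(onset = onset[keep], offset = offset[keep],
             speaker = rep(speaker, sum(keep)),
             trial_id = rep(as.integer(trial_id), sum(keep)),
             stringsAsFactors = FALSE)
}

#' Grid-search the RMS coefficient against reference IPU annotations
#'
#' Convenience extension: when manually annotated IPUs are available, the
#' per-participant coefficient can be chosen by maximising boundary
#' agreement between the segmentation and the annotations (fraction of
#' reference onsets/offsets matched within `tol` seconds).
#'
#' @param envelope An `rms_env`.
#' @param reference_ipus IPU data frame with `onset`/`offset`.
#' @param grid Candidate coefficients (default `seq(0.20, 0.95, 0.05)`).
#' @param tol Matching tolerance in seconds (default 0.05).
#' @param ... Passed to [segment_ipus()].
#' @return List with `coefficient` (best), `score` (agreement in `[0, 1]`),
#'   and `grid_scores` (named vector).
#' @export
tune_rms_coefficient <- function(envelope, reference_ipus,
                                 grid = seq(0.20, 0.95, by = 0.05),
                                 tol = 0.05, ...) {
  stopifnot(inherits(envelope, "rms_env"), nrow(reference_ipus) > 0)
  ref <- c(reference_ipus$onset, reference_ipus$offset)
  scores <- vapply(grid, function(co) {
    seg <- segment_ipus(envelope, threshold_from_rms(envelope, co), ...)
    if (!nrow(seg)) return(0)
    got <- c(seg$onset, seg$offset)
    mean(vapply(ref, function(b) any(abs(got - b) <= tol), logical(1)))
  }, numeric(1))
  names(scores) <- sprintf("%.2f", grid)
  best <- which.max(scores)
  list(coefficient = grid[best], score = scores[[best]],
       grid_scores = scores)
}
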