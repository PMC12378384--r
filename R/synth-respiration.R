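#' Breath-cycle parameters
#'
#' Describes the asymmetric respiratory cycle used by the generator: a short,
#' rapid inhalation (200-500 ms) followed by a prolonged exhalation. The
#' default exhalation range (1.2-2.5 s) gives a mean cycle of about 2.2 s,
#' i.e. roughly 210 maxima in a 464 s scanning session, the breathing rate
#' typical of supine conversational speech.
#'
#' @param inhale_dur_range Seconds, `c(low, high)` inhalation duration.
#' @param exhale_dur_range Seconds, `c(low, high)` exhalation duration.
#' @param amplitude_range Arbitrary units, `c(low, high)` peak amplitude.
#' @param baseline_drift_sd Stationary standard deviation of the slow
#'   baseline wander, a.u. The wander is mean-reverting
#'   (Ornstein-Uhlenbeck, 60 s time constant), so its spread does not grow
#'   with recording length - belts drift, they do not walk away.
#' @param noise_sd Additive white noise, a.u.
#' @return A list of class `breath_cycle_params`.
#' @export
breath_cycle_params <- function(inhale_dur_range = c(0.2, 0.5),
                                exhale_dur_range = c(1.2, 2.5),
                                amplitude_range = c(0.8, 1.2),
                                baseline_drift_sd = 0.05,
                                noise_sd = 0.01) {
  rng <- function(r, what) {
    if (length(r) != 2L || r[1] > r[2]) {
      stop_bad("%s must be c(low, high) with low <= high", what)
    }
  }
  rng(inhale_dur_range, "inhale_dur_range")
  rng(exhale_dur_range, "exhale_dur_range")
  rng(amplitude_range, "amplitude_range")
  stopifnot(inhale_dur_range[1] > 0, exhale_dur_range[1] > 0,
            baseline_drift_sd >= 0, noise_sd >= 0)
  structure(list(inhale_dur_range = inhale_dur_range,
                 exhale_dur_range = exhale_dur_range,
                 amplitude_range = amplitude_range,
                 baseline_drift_sd = baseline_drift_sd,
                 noise_sd = noise_sd),
            class = "breath_cycle_params")
}

#' Lag model for speech-coupled inhalation peaks
#'
#' Distribution of the lag between a speech-coupled respiration maximum and
#' its IPU onset (peak time minus onset time; negative = breath peak precedes
#' speech). The default is a negated, shifted gamma whose density peaks at
#' -200 ms: left-skewed, with a short positive tail, matching the shape
#' expected of pre-speech inhalation timing.
#'
#' @param family `"shifted_negative_gamma"`, `"gaussian"`, or `"point_mass"`.
#' @param mode Seconds; location of the density maximum (default -0.200).
#' @param spread Seconds; standard deviation of the lag (ignored for
#'   `point_mass`).
#' @param shape Gamma shape for the skewed family; larger is less skewed.
#' @return A list of class `lag_model`.
#' @export
lag_model <- function(family = c("shifted_negative_gamma", "gaussian",
                                 "point_mass"),
                      mode = -0.200, spread = 0.165, shape = 6) {
  family <- match.arg(family)
  stopifnot(is.finite(mode), spread >= 0, shape > 1)
  skew <- switch(family, shifted_negative_gamma = "left", gaussian = "none",
                 point_mass = "none")
  structure(list(family = family, mode = mode, spread = spread,
                 shape = shape, skew_direction = skew),
            class = "lag_model")
}

#' Draw lags from a lag model
#'
#' @param model A [lag_model()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of lags in seconds.
#' @export
draw_lags <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "lag_model"), n >= 0)
  set.seed(child_seed(seed, 13L))
  switch(model$family,
    point_mass = rep(model$mode, n),
    gaussian = rnorm(n, model$mode, model$spread),
    shifted_negative_gamma = {
      k <- model$shape
      theta <- model$spread / sqrt(k)
      g <- rgamma(n, shape = k, scale = theta)
      # negate so the long tail points to negative lags; density mode at
      # (k - 1) * theta maps onto `mode`
      model$mode - (g - (k - 1) * theta)
    })
}

#' Respiration-belt trace container
#'
#' @param samples Numeric vector of belt amplitudes (arbitrary units).
#' @param rate Sampling rate in Hz.
#' @param origin Session-clock time of the first sample, seconds.
#' @param saturation_mask Logical vector flagging saturated/repaired samples.
#' @return A list of class `resp_trace`.
#' @export
resp_trace <- function(samples, rate, origin = 0,
                       saturation_mask = logical(length(samples))) {
  stopifnot(is.numeric(samples), rate > 0,
            length(saturation_mask) == length(samples))
  structure(list(samples = as.numeric(samples), rate = rate,
                 origin = origin,
                 saturation_mask = as.logical(saturation_mask)),
            class = "resp_trace")
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf(
    "<resp_trace> %d samples @ %g Hz, origin %.3f s, duration %.3f s, %d flagged\n",
    length(x$samples), x$rate, x$origin, trace_duration(x),
    sum(x$saturation_mask)))
  invisible(x)
}

#' Duration of a trace in seconds (first to last sample)
#' @param trace A [resp_trace()].
#' @return Seconds.
#' @export
trace_duration <- function(trace) {
  (length(trace$samples) - 1L) / trace$rate
}

# session-clock times of every sample
trace_times <- function(trace) {
  trace$origin + (seq_along(trace$samples) - 1L) / trace$rate
}

#' Synthesize a respiration-belt trace coupled to a conversation
#'
#' Builds a piecewise raised-cosine belt signal whose maxima
#' (inspiration-to-expiration transitions) are of two kinds: *speech-coupled*
#' peaks placed at `onset + lag` for a fraction of the participant's IPU
#' onsets (lags drawn from `lag_model`), and *metabolic* peaks that fill the
#' remaining time at the natural breathing rhythm while staying at least
#' `metabolic_clearance` seconds away from every participant IPU onset, so
#' ground-truth labels are unambiguous. Baseline drift (random walk) and
#' white noise are added on top of the clean waveform.
#'
#' @param ipu_list Data frame as returned by [generate_conversation()]
#'   (sorted by onset).
#' @param breath_params A [breath_cycle_params()].
#' @param lag_model A [lag_model()].
#' @param coupled_fraction Fraction of participant IPU onsets that receive a
#'   dedicated coupled peak (default 1: pre-speech inhalation is the norm in
#'   conversational turn-taking; onsets following another onset too closely
#'   lose their peak through the collision rule and share the preceding
#'   breath instead, emulating multi-utterance breath groups).
#' @param sampling_rate Hz, must be >= 50 (default 200).
#' @param duration Trace duration in seconds; default runs one mean cycle
#'   past the last IPU offset.
#' @param metabolic_clearance Minimum distance (s) between a metabolic peak
#'   and any participant IPU onset (default 1).
#' @param seed Integer seed.
#' @return A list with elements `trace` (a [resp_trace()], noisy) and
#'   `truth`, a list of class `resp_ground_truth` with `true_peak_times`,
#'   `true_labels` (`speech_coupled`/`metabolic`), `true_lags` (NA for
#'   metabolic peaks), `ipu_id` (NA for metabolic peaks),
#'   `saturated_intervals` (empty here; filled by [apply_saturation()]),
#'   `ipu_list`, and `clean` (the noise-free samples, whose local argmax
#'   positions match `true_peak_times` to one sample).
#' @export
generate_respiration <- function(ipu_list,
                                 breath_params = breath_cycle_params(),
                                 lag_model = breathturn::lag_model(),
                                 coupled_fraction = 1,
                                 sampling_rate = 200,
                                 duration = NULL,
                                 metabolic_clearance = 1,
                                 seed = 1L) {
  stopifnot(inherits(breath_params, "breath_cycle_params"),
            inherits(lag_model, "lag_model"),
            sampling_rate >= 50,
            coupled_fraction >= 0, coupled_fraction <= 1)
  if (nrow(ipu_list) > 0 && is.unsorted(ipu_list$onset)) {
    stop_bad("ipu_list must be sorted by onset")
  }
  bp <- breath_params
  mean_inhale <- mean(bp$inhale_dur_range)
  mean_cycle <- mean_inhale + mean(bp$exhale_dur_range)
  if (is.null(duration)) {
    duration <- (if (nrow(ipu_list)) max(ipu_list$offset) else 10) + mean_cycle
  }
  set.seed(child_seed(seed, 17L))

  part_onsets <- ipu_list$onset[ipu_list$speaker == "participant"]
  n_part <- length(part_onsets)
  n_coupled <- round(coupled_fraction * n_part)
  coupled_idx <- sort(sample.int(n_part, n_coupled))
  lags <- draw_lags(lag_model, n_coupled, seed = child_seed(seed, 19L))
  coupled_times <- part_onsets[coupled_idx] + lags

  # keep coupled peaks inside the trace and strictly increasing; peaks closer
  # than one minimal exhalation are collisions -> drop the later one
  ok <- coupled_times > bp$inhale_dur_range[1] & coupled_times < duration
  if (n_coupled > 0 && any(ok)) {
    keep <- which(ok)
    sep_ok <- c(TRUE, diff(coupled_times[keep]) >= bp$exhale_dur_range[1])
    if (any(!sep_ok)) {
      message(sprintf("dropped %d colliding coupled peak(s)", sum(!sep_ok)))
    }
    keep <- keep[sep_ok]
  } else {
    keep <- integer(0)
  }
  coupled_times <- coupled_times[keep]
  coupled_lags <- lags[keep]
  coupled_ipu <- which(ipu_list$speaker == "participant")[coupled_idx][keep]

  # fill remaining time with metabolic cycles, >= metabolic_clearance from
  # every participant IPU onset and >= one exhalation from coupled peaks
  draw_cycle <- function() {
    runif(1L, bp$inhale_dur_range[1], bp$inhale_dur_range[2]) +
      runif(1L, bp$exhale_dur_range[1], bp$exhale_dur_range[2])
  }
  min_gap <- bp$exhale_dur_range[1]
  metabolic <- numeric(0)
  t <- bp$inhale_dur_range[2]
  next_anchor <- 1L
  n_dropped <- 0L
  while (t < duration) {
    while (next_anchor <= length(coupled_times) &&
           coupled_times[next_anchor] < t) {
      next_anchor <- next_anchor + 1L
    }
    # too close to (or past) the next coupled peak: jump behind it
    if (next_anchor <= length(coupled_times) &&
        t > coupled_times[next_anchor] - min_gap) {
      t <- coupled_times[next_anchor] + draw_cycle()
      next_anchor <- next_anchor + 1L
      n_dropped <- n_dropped + 1L
      next
    }
    if (n_part > 0) {
      d <- min(abs(part_onsets - t))
      if (d < metabolic_clearance) {
        nearest <- part_onsets[which.min(abs(part_onsets - t))]
        t <- nearest + metabolic_clearance + 1e-3
        next
      }
    }
    if (t >= duration) break
    prev <- if (length(metabolic)) metabolic[length(metabolic)] else -Inf
    last_coupled_before <- coupled_times[coupled_times < t]
    prev <- max(prev, if (length(last_coupled_before))
      max(last_coupled_before) else -Inf)
    if (t - prev >= min_gap) metabolic <- c(metabolic, t)
    t <- t + draw_cycle()
  }
  if (n_dropped > 0) {
    message(sprintf("%d metabolic cycle(s) skipped around coupled peaks",
                    n_dropped))
  }

  peak_times <- c(coupled_times, metabolic)
  ord <- order(peak_times)
  peak_times <- peak_times[ord]
  labels <- c(rep("speech_coupled", length(coupled_times)),
              rep("metabolic", length(metabolic)))[ord]
  lag_out <- c(coupled_lags, rep(NA_real_, length(metabolic)))[ord]
  ipu_out <- c(coupled_ipu, rep(NA_integer_, length(metabolic)))[ord]

  amps <- runif(length(peak_times), bp$amplitude_range[1],
                bp$amplitude_range[2])

  # knot sequence: troughs (value 0) between consecutive peaks; every
  # segment is a half raised-cosine between adjacent knots, so each peak is
  # the exact argmax of the clean waveform
  kt <- 0; kv <- 0
  if (length(peak_times)) {
    inhales <- runif(length(peak_times), bp$inhale_dur_range[1],
                     bp$inhale_dur_range[2])
    prev_t <- 0
    for (i in seq_along(peak_times)) {
      tr_t <- max(peak_times[i] - inhales[i], (prev_t + peak_times[i]) / 2)
      if (tr_t > prev_t + 1e-9) { kt <- c(kt, tr_t); kv <- c(kv, 0) }
      kt <- c(kt, peak_times[i]); kv <- c(kv, amps[i])
      prev_t <- peak_times[i]
    }
    end_t <- peak_times[length(peak_times)] +
      mean(bp$exhale_dur_range)
    kt <- c(kt, end_t); kv <- c(kv, 0)
  } else {
    kt <- c(0, duration + 1); kv <- c(0, 0)
  }

  n <- floor(duration * sampling_rate) + 1L
  tt <- (seq_len(n) - 1L) / sampling_rate
  seg <- findInterval(tt, kt, rightmost.closed = FALSE)
  seg[seg < 1L] <- 1L
  seg[seg >= length(kt)] <- length(kt) - 1L
  t0 <- kt[seg]; t1 <- kt[seg + 1L]
  v0 <- kv[seg]; v1 <- kv[seg + 1L]
  s <- pmin(1, pmax(0, (tt - t0) / (t1 - t0)))
  clean <- v0 + (v1 - v0) * (1 - cos(pi * s)) / 2

  # mean-reverting baseline wander (OU, 60 s time constant), stationary
  # sd = baseline_drift_sd regardless of trace duration
  a <- 1 - 1 / (60 * sampling_rate)
  innov_sd <- bp$baseline_drift_sd * sqrt(1 - a^2)
  drift <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), a,
                                    method = "recursive"))
  noise <- rnorm(n, 0, bp$noise_sd)
  trace <- resp_trace(clean + drift + noise, rate = sampling_rate, origin = 0)

  truth <- structure(list(true_peak_times = peak_times,
                          true_labels = labels,
                          true_lags = lag_out,
                          ipu_id = ipu_out,
                          saturated_intervals = matrix(
                            integer(0), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))),
                          ipu_list = ipu_list,
                          clean = clean),
                     class = "resp_ground_truth")
  list(trace = trace, truth = truth)
}

#' Clip a trace at amplitude rails, recording the saturated runs
#'
#' Emulates the measurement rails of a respiration belt: samples outside
#' `[rail_low, rail_high]` are clamped, and the maximal runs of clamped
#' samples are returned as saturation intervals. With only the high rail
#' binding, the plateaus sit at the signal maxima (strong inspirations).
#'
#' @param trace A [resp_trace()].
#' @param rail_low,rail_high Rail levels in a.u.; `rail_low < rail_high`.
#' @return List with `trace` (clipped, saturation mask set) and `intervals`,
#'   an integer matrix of inclusive sample index runs (columns `start`,
#'   `end`). Errors if every sample is clipped.
#' @export
apply_saturation <- function(trace, rail_low = -Inf, rail_high = Inf) {
  stopifnot(inherits(trace, "resp_trace"), rail_low < rail_high)
  x <- trace$samples
  clipped <- x < rail_low | x > rail_high
  if (all(clipped)) {
    stop_bad("rails [%g, %g] exclude the entire signal range: everything saturated",
             rail_low, rail_high)
  }
  y <- pmin(pmax(x, rail_low), rail_high)
  out <- trace
  out$samples <- y
  out$saturation_mask <- trace$saturation_mask | clipped
  list(trace = out, intervals = find_runs(clipped))
}
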