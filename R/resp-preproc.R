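#' Centred moving average
#'
#' Mean filter used throughout the belt preprocessing (the saturation
#' detector smooths with a 50-bin window, i.e. 250 ms at 200 Hz). Even window
#' lengths are centred on the leading sample: a 50-bin window covers samples
#' `[i - 25, i + 24]`. Edges use shrinking windows, so the output has the
#' input's length and a constant signal is returned unchanged.
#'
#' @param x Numeric vector, or a [resp_trace()] (smoothed in place).
#' @param window_bins Window length in samples (>= 1).
#' @return Same type as `x`.
#' @export
moving_average <- function(x, window_bins = 50L) {
  if (inherits(x, "resp_trace")) {
    x$samples <- moving_average(x$samples, window_bins)
    return(x)
  }
  n <- length(x)
  window_bins <- as.integer(window_bins)
  stopifnot(window_bins >= 1L)
  if (window_bins > n) stop_bad("window (%d) longer than signal (%d)",
                                window_bins, n)
  l <- window_bins %/% 2L
  r <- window_bins - 1L - l
  s <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - l)
  hi <- pmin(n, i + r)
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

#' Detect saturation plateaus in a belt trace
#'
#' Saturation shows up as flat runs of identical extreme values where the
#' belt hit a measurement rail, typically during strong inspirations. The
#' trace is smoothed with a centred moving average, runs where the smoothed
#' first difference is (near-)null are located, and runs are kept only when
#' long enough and sitting in the top or bottom amplitude decile -- without
#' the level restriction, flat mid-range breathing pauses would be falsely
#' flagged. Each kept run is then refined to the maximal raw-sample run at
#' the rail value, so the returned intervals match the actual clipped
#' samples rather than the smoothing-shrunk core.
#'
#' @param trace A [resp_trace()].
#' @param deriv_tol Tolerance on the smoothed first difference, a.u. per
#'   bin. Default: 0 (plus float-rounding slack) when all samples are
#'   integer-valued (quantised belts), otherwise `1e-9` of the amplitude
#'   range.
#' @param min_run Minimum plateau length in samples (default 10, i.e. 50 ms
#'   at 200 Hz).
#' @param smooth_bins Moving-average window (default 50).
#' @param decile Width of the extreme-amplitude bands (default 0.1).
#' @param rail_margin Half-width of the rail neighbourhood used when
#'   growing a plateau outwards, a.u.; default three robust noise standard
#'   deviations (`3 * 1.4826 * median(|diff(x)|) / sqrt(2)`). Samples this
#'   close to a detected rail are part of the unreliable region (noise
#'   rides on the rail at plateau edges and fragments the exact-value run).
#' @return Integer matrix of inclusive sample-index intervals (columns
#'   `start`, `end`); zero rows when no plateau is found.
#' @export
detect_saturation <- function(trace, deriv_tol = NULL, min_run = 10L,
                              smooth_bins = 50L, decile = 0.1,
                              rail_margin = NULL) {
  stopifnot(inherits(trace, "resp_trace"), min_run >= 2L)
  x <- trace$samples
  n <- length(x)
  rng <- diff(range(x))
  if (is.null(deriv_tol)) {
    deriv_tol <- if (all(x == round(x))) 0 else 1e-9 * rng
  }
  stopifnot(deriv_tol >= 0)
  empty <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))

  # core plateaus, two complementary views: null derivative of the
  # smoothed signal, and runs of identical raw values (clipping repeats
  # the rail value exactly even when noise fragments the smoothed run)
  s <- moving_average(x, smooth_bins)
  slack <- 64 * .Machine$double.eps * max(abs(x), 1)  # cumsum rounding
  flat <- abs(diff(s)) <= deriv_tol + slack
  runs <- find_runs(flat)
  if (nrow(runs)) runs[, "end"] <- runs[, "end"] + 1L  # k diffs = k+1 samples
  rep_runs <- find_runs(c(abs(diff(x)) <= deriv_tol, FALSE))
  if (nrow(rep_runs)) rep_runs[, "end"] <- rep_runs[, "end"] + 1L
  runs <- rbind(runs, rep_runs)
  if (nrow(runs) == 0L) return(empty)
  len_ok <- (runs[, "end"] - runs[, "start"] + 1L) >= min_run
  runs <- runs[len_ok, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)

  # keep only extreme-amplitude plateaus: flat mid-range breathing pauses
  # are genuine signal, saturation sits at the rails
  q_lo <- quantile(s, decile, names = FALSE)
  q_hi <- quantile(s, 1 - decile, names = FALSE)
  lvl <- vapply(seq_len(nrow(runs)), function(i) {
    median(x[runs[i, 1]:runs[i, 2]])
  }, numeric(1))
  runs <- runs[lvl <= q_lo | lvl >= q_hi, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)

  # grow each core outwards through the rail neighbourhood
  if (is.null(rail_margin)) {
    rail_margin <- 3 * 1.4826 * median(abs(diff(x))) / sqrt(2)
  }
  tol_grow <- max(deriv_tol, 1e-12 * max(rng, 1), rail_margin)
  out <- t(vapply(seq_len(nrow(runs)), function(i) {
    a <- runs[i, 1]; b <- runs[i, 2]
    rail <- median(x[a:b])
    while (a > 1L && abs(x[a - 1L] - rail) <= tol_grow) a <- a - 1L
    while (b < n && abs(x[b + 1L] - rail) <= tol_grow) b <- b + 1L
    c(a, b)
  }, integer(2)))
  colnames(out) <- c("start", "end")

  # merge overlaps and fragments separated by less than min_run samples
  out <- out[order(out[, 1]), , drop = FALSE]
  merged <- list(out[1L, ])
  for (i in seq_len(nrow(out))[-1L]) {
    last <- merged[[length(merged)]]
    if (out[i, 1] <= last[2] + min_run) {
      merged[[length(merged)]] <- c(last[1], max(last[2], out[i, 2]))
    } else {
      merged[[length(merged) + 1L]] <- out[i, ]
    }
  }
  out <- do.call(rbind, merged)
  colnames(out) <- c("start", "end")
  out
}

#' Repair flagged intervals by local regression-spline fits
#'
#' Samples inside the flagged intervals are treated as missing and rebuilt
#' from the surrounding signal, restoring peaks above the rail level. Each
#' gap is bridged by a natural cubic regression spline (knots every
#' `knot_s` seconds) fitted by least squares to the non-flagged samples in
#' a symmetric context window around the gap (each side as wide as the gap
#' itself, at least `min_context_s`). A least-squares spline is used rather
#' than an interpolating spline through every sample because interpolation
#' reproduces each sample's noise exactly and amplifies it into large
#' overshoots inside the gap; the regression averages the noise while
#' leaving every sample outside the intervals unchanged. Intervals touching
#' either end of the signal cannot be bridged; they are filled by
#' nearest-value hold with a warning.
#'
#' @param trace A [resp_trace()].
#' @param intervals Integer matrix (columns `start`, `end`, inclusive sample
#'   indices), e.g. from [detect_saturation()].
#' @param min_context_s Minimum one-sided context window, seconds
#'   (default 0.3).
#' @param knot_s Spline knot spacing, seconds (default 0.05, resolving the
#'   fastest respiratory feature, the 200 ms inhalation).
#' @return The repaired [resp_trace()]; repaired samples are flagged in
#'   `saturation_mask`. With an empty interval list the trace is returned
#'   unchanged.
#' @export
interpolate_gaps <- function(trace, intervals, min_context_s = 0.3,
                             knot_s = 0.05) {
  stopifnot(inherits(trace, "resp_trace"))
  if (is.null(intervals) || nrow(intervals) == 0L) return(trace)
  x <- trace$samples
  n <- length(x)
  if (any(intervals < 1L) || any(intervals > n)) {
    stop_bad("intervals outside the trace")
  }
  gap_idx <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    intervals[i, 1]:intervals[i, 2]
  }))
  gap_idx <- sort(unique(gap_idx))
  if (length(gap_idx) >= n / 2) {
    stop_bad("flagged intervals cover >= 50%% of the session; refusing repair")
  }
  gap <- rep(FALSE, n); gap[gap_idx] <- TRUE

  hold_idx <- integer(0)
  if (gap[1L]) {
    e <- which(!gap)[1L] - 1L
    hold_idx <- c(hold_idx, 1:e)
  }
  if (gap[n]) {
    s0 <- n - which(!rev(gap))[1L] + 2L
    hold_idx <- c(hold_idx, s0:n)
  }
  interp_idx <- setdiff(gap_idx, hold_idx)

  y <- x
  if (length(interp_idx)) {
    min_ctx <- max(4L, as.integer(round(min_context_s * trace$rate)))
    knot_gap <- max(4L, as.integer(round(knot_s * trace$rate)))
    for (i in seq_len(nrow(intervals))) {
      a <- intervals[i, 1]; b <- intervals[i, 2]
      span <- a:b
      span <- span[span %in% interp_idx]
      if (!length(span)) next
      ctx <- max(b - a + 1L, min_ctx)
      repeat {
        win <- max(1L, a - ctx):min(n, b + ctx)
        pts <- win[!gap[win]]
        if (length(pts) >= 20L || ctx >= n) break
        ctx <- ctx * 2L
      }
      if (length(pts) < 8L) next  # nothing sensible to fit
      # knots at data quantiles: every interior knot has sample support,
      # so the basis stays full rank even around a wide data-free gap
      nk <- max(1L, (max(pts) - min(pts)) %/% knot_gap - 1L)
      kn <- unique(quantile(pts, seq_len(nk) / (nk + 1L), names = FALSE,
                            type = 1L))
      kn <- kn[kn > min(pts) & kn < max(pts)]
      basis <- splines::ns(pts, knots = kn, Boundary.knots = range(pts))
      fit <- stats::lm.fit(cbind(1, basis), x[pts])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      y[span] <- drop(cbind(1, predict(basis, span)) %*% beta)
    }
  }
  if (length(hold_idx)) {
    warn_msg("%d flagged sample(s) touch the signal ends; filled by nearest-value hold, not extrapolated",
             length(hold_idx))
    keep <- which(!gap)
    for (i in hold_idx) y[i] <- x[keep[which.min(abs(keep - i))]]
  }
  out <- trace
  out$samples <- y
  out$saturation_mask[gap_idx] <- TRUE
  out
}

#' Resample a trace to millisecond resolution
#'
#' Linear interpolation onto a 1 ms grid spanning the same time range; the
#' first and last timestamps are preserved to 1 ms.
#'
#' @param trace A [resp_trace()] with `rate <= 1000` Hz.
#' @return A [resp_trace()] at 1000 Hz.
#' @export
resample_to_ms <- function(trace) {
  stopifnot(inherits(trace, "resp_trace"))
  if (trace$rate > 1000) stop_bad("trace already above 1000 Hz")
  if (trace$rate == 1000) return(trace)
  n <- length(trace$samples)
  t_old <- (seq_len(n) - 1L) / trace$rate
  t_new <- seq(0, floor(t_old[n] * 1000) / 1000, by = 1e-3)
  y <- approx(t_old, trace$samples, xout = t_new)$y
  m_old <- approx(t_old, as.numeric(trace$saturation_mask), xout = t_new)$y
  resp_trace(y, rate = 1000, origin = trace$origin,
             saturation_mask = m_old > 0)
}

#' Align a trace to the session clock by its known end-synchronisation
#'
#' The belt recording stops with the end of the scanning session, so the
#' last sample maps exactly onto the session end:
#' `origin = session_duration - trace_duration`.
#'
#' @param trace A [resp_trace()].
#' @param timeline A [session_timeline()].
#' @return The trace with its `origin` set.
#' @export
align_to_session <- function(trace, timeline) {
  stopifnot(inherits(trace, "resp_trace"),
            inherits(timeline, "session_timeline"))
  trace$origin <- timeline$session_duration - trace_duration(trace)
  trace
}

# local maxima (plateau-safe: centre index of any flat top) of a numeric
# vector; interior only
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # collapse zero steps onto the previous non-zero direction
  sgn <- sign(d)
  nz <- which(sgn != 0)
  if (!length(nz)) return(integer(0))
  filled <- sgn
  # forward-fill zeros with the last non-zero sign
  last <- 0
  for (i in seq_len(n - 1L)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  idx <- which(filled[-length(filled)] > 0 & filled[-1L] < 0) + 1L
  # centre plateau tops
  vapply(idx, function(i) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    as.integer((i + j) %/% 2L)
  }, integer(1))
}

# Threshold check on topographic prominence, evaluated on the candidate /
# valley sequence rather than sample by sample: a peak passes when, on each
# side, the signal drops by at least min_prom before rising above the
# peak's height. Valley minima between consecutive candidates are
# precomputed, and the per-peak walk exits as soon as the drop is reached
# (for genuine breath maxima that is the adjacent trough), so the check is
# effectively O(1) per candidate.
has_prominence <- function(x, cand, min_prom) {
  k <- length(cand)
  if (k == 0L) return(logical(0))
  n <- length(x)
  bounds <- c(1L, cand, n)
  valleys <- vapply(seq_len(k + 1L), function(i) {
    min(x[bounds[i]:bounds[i + 1L]])
  }, numeric(1))
  heights <- x[cand]
  side_ok <- function(i, dir) {
    h <- heights[i]
    run_min <- h
    j <- i
    repeat {
      v_idx <- if (dir < 0) j else j + 1L
      run_min <- min(run_min, valleys[v_idx])
      if (h - run_min >= min_prom) return(TRUE)
      j <- j + dir
      if (j < 1L || j > k) return(FALSE)  # signal end: base is run_min
      if (heights[j] > h) return(h - run_min >= min_prom)
    }
  }
  vapply(seq_len(k), function(i) side_ok(i, -1L) && side_ok(i, 1L),
         logical(1))
}

#' Detect respiration maxima (inspiration-to-expiration transitions)
#'
#' Candidate maxima are found on a smoothed copy of the trace (centred
#' moving average over `smooth_ms`), screened by topographic prominence and
#' a minimum pairwise separation. Peak *times* are then refined. The
#' default `"upstroke_centroid"` refinement exploits the shape of a breath:
#' the inhalation upstroke's derivative is a roughly symmetric bump ending
#' at the maximum, so its centroid estimates the mid-rise without the
#' systematic late bias that any symmetric smoothing imposes on the argmax
#' of an asymmetric (fast-rise, slow-fall) peak; the peak time is the
#' centroid plus half the rise duration, with the rise duration recovered
#' from the bump's second moment (kernel-corrected). `"argmax"` refinement
#' (local argmax of a lightly smoothed copy) is kept for symmetric or
#' non-respiratory signals, though the centroid method reduces to it there
#' as well.
#'
#' @param trace A repaired, resampled [resp_trace()].
#' @param min_separation Minimum distance between peaks, seconds (default 1,
#'   the shortest plausible breath cycle).
#' @param min_prominence Minimum prominence in a.u.; default 10% of the
#'   5th-95th percentile amplitude range (scale-invariant).
#' @param smooth_ms Candidate-detection smoothing window, ms (default 100).
#' @param refine `"upstroke_centroid"`, `"argmax"`, or `"none"`.
#' @param refine_smooth_ms Smoothing window for the refinement signal, ms
#'   (default 40).
#' @return A data frame of class `resp_peaks` with columns `time`
#'   (session clock, seconds; sub-sample resolution), `amplitude` (a.u.),
#'   `label` (all `"UNLABELLED"`), `ipu_id` (NA), sorted by time.
#' @export
detect_peaks <- function(trace, min_separation = 1.0, min_prominence = NULL,
                         smooth_ms = 100,
                         refine = c("upstroke_centroid", "argmax", "none"),
                         refine_smooth_ms = 40) {
  stopifnot(inherits(trace, "resp_trace"), min_separation >= 0)
  refine <- match.arg(refine)
  x <- trace$samples
  n <- length(x)
  rate <- trace$rate
  w <- max(3L, round(smooth_ms / 1000 * rate))
  s <- moving_average(x, w)
  if (is.null(min_prominence)) {
    q <- quantile(s, c(0.05, 0.95), names = FALSE)
    min_prominence <- 0.1 * (q[2] - q[1])
  }
  cand <- local_maxima(s)
  if (length(cand)) {
    cand <- cand[has_prominence(s, cand, min_prominence)]
  }
  # enforce separation, keeping the higher peak on conflict
  if (length(cand) > 1L) {
    ord <- cand[order(s[cand], decreasing = TRUE)]
    kept <- numeric(0)
    min_gap <- min_separation * rate
    for (p in ord) {
      if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
    }
    cand <- sort(as.integer(kept))
  }

  times <- (cand - 1L) / rate
  if (length(cand) && refine != "none") {
    wr <- max(3L, round(refine_smooth_ms / 1000 * rate))
    sr <- moving_average(x, wr)
    if (refine == "argmax") {
      half <- max(1L, as.integer(round(0.1 * rate)))
      idx <- vapply(cand, function(p) {
        lo <- max(1L, p - half); hi <- min(n, p + half)
        as.integer(lo + which.max(sr[lo:hi]) - 1L)
      }, integer(1))
      times <- (idx - 1L) / rate
    } else {
      times <- refine_upstroke_centroid(sr, cand, rate, wr / rate)
    }
  }
  ord2 <- order(times)
  cand <- cand[ord2]; times <- times[ord2]
  out <- data.frame(time = trace$origin + times,
                    amplitude = x[cand],
                    label = rep("UNLABELLED", length(cand)),
                    ipu_id = rep(NA_integer_, length(cand)),
                    stringsAsFactors = FALSE)
  class(out) <- c("resp_peaks", "data.frame")
  out
}

# Upstroke-centroid peak-time refinement. For each candidate index, the
# search window runs from the preceding smoothed trough (or the previous
# candidate) to 100 ms past the candidate. Within it, the maximal
# contiguous run of the first difference above 10% of its local maximum is
# the inhalation upstroke; the refined peak time is the run's weighted
# centroid plus half the rise duration. The rise duration comes from the
# bump's second moment: for a half-sine upstroke truncated at 10% of its
# height and smoothed with a w-second moving average,
# var = 0.046441 * Ti^2 + 0.0421 * w^2 (numerical calibration of the ideal
# shape), hence Ti = sqrt((var - 0.0421 w^2) / 0.046441).
refine_upstroke_centroid <- function(sr, cand, rate, w_sec) {
  n <- length(sr)
  d <- c(diff(sr), 0)
  vapply(seq_along(cand), function(i) {
    p <- cand[i]
    lo_bound <- if (i > 1L) cand[i - 1L] else 1L
    lo <- if (p - lo_bound > 1L) {
      lo_bound + which.min(sr[lo_bound:p]) - 1L
    } else {
      lo_bound
    }
    hi <- min(n, p + as.integer(round(0.1 * rate)))
    if (hi - lo < 3L) return((p - 1L) / rate)
    seg <- d[lo:hi]
    im <- which.max(seg)
    if (seg[im] <= 0) return((p - 1L) / rate)
    th <- 0.1 * seg[im]
    a <- im; while (a > 1L && seg[a - 1L] > th) a <- a - 1L
    b <- im; while (b < length(seg) && seg[b + 1L] > th) b <- b + 1L
    if ((a == 1L && lo == 1L) || (b == length(seg) && hi == n)) {
      # upstroke truncated by the trace boundary: argmax fallback
      half <- as.integer(round(0.1 * rate))
      l2 <- max(1L, p - half); h2 <- min(n, p + half)
      return((l2 + which.max(sr[l2:h2]) - 2L) / rate)
    }
    wgt <- seg[a:b]
    tloc <- (lo + (a:b) - 2L) / rate
    m <- sum(tloc * wgt) / sum(wgt)
    v <- sum((tloc - m)^2 * wgt) / sum(wgt)
    ti <- sqrt(max(0, v - 0.0421 * w_sec^2) / 0.046441)
    est <- m + ti / 2
    # stay within the breath this candidate belongs to
    min(max(est, (lo - 1L) / rate), (hi - 1L) / rate)
  }, numeric(1))
}
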