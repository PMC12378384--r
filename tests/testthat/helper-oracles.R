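# Brute-force oracles used across tests; deliberately naive and independent
# of the package's implementation paths.

# nearest-peak classification by exhaustive search
brute_classify <- function(peak_times, onsets) {
  nearest <- integer(length(onsets))
  for (i in seq_along(onsets)) {
    d <- abs(peak_times - onsets[i])
    cand <- which(d == min(d))
    nearest[i] <- cand[1]  # earlier peak on tie
  }
  labels <- rep("RESP_MINUS", length(peak_times))
  labels[nearest] <- "RESP_PLUS"
  list(labels = labels, nearest = nearest,
       delta_t = peak_times[nearest] - onsets)
}

# MAD outlier rule, re-derived step by step
brute_mad_outliers <- function(x, k = 3, c_scale = 1.4826) {
  med <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) {
    s <- sort(x)
    med <- (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2
  }
  dev <- abs(x - med)
  sdev <- sort(dev)
  mad <- if (length(x) %% 2 == 0) {
    (sdev[length(x) / 2] + sdev[length(x) / 2 + 1]) / 2
  } else {
    sdev[ceiling(length(x) / 2)]
  }
  dev > k * c_scale * mad
}

# run-length IPU segmentation: frames >= thr are speech; silent runs of
# k * hop <= min_pause (interior) merge; speech runs shorter than min_ipu drop
brute_segment <- function(values, hop, thr, min_pause, min_ipu) {
  speech <- values >= thr
  n <- length(speech)
  i <- 1L
  while (i <= n) {
    if (!speech[i]) {
      j <- i
      while (j < n && !speech[j + 1L]) j <- j + 1L
      if (i > 1L && j < n && (j - i + 1L) * hop <= min_pause + 1e-9) {
        speech[i:j] <- TRUE
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (speech[i]) {
      j <- i
      while (j < n && speech[j + 1L]) j <- j + 1L
      len <- (j - i + 1L) * hop
      if (len >= min_ipu - 1e-9) out <- rbind(out, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# moving-average by explicit window loop (even windows centred on the
# leading sample: [i - floor(w/2), i + w - 1 - floor(w/2)])
brute_moving_average <- function(x, w) {
  n <- length(x)
  l <- w %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - l); hi <- min(n, i + (w - 1 - l))
    out[i] <- mean(x[lo:hi])
  }
  out
}

# a small default synthetic session for reuse in tests
make_session <- function(seed = 1, duration = 300) {
  ip <- suppressMessages(generate_conversation(duration, seed = seed))
  r <- suppressMessages(generate_respiration(ip, seed = seed + 10,
                                             duration = duration))
  list(ipus = ip, trace = r$trace, truth = r$truth)
}
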