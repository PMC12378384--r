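#' MAD outlier rejection
#'
#' Removes values more than `k` median absolute deviations from the median,
#' in one pass on the full sample. By default the MAD is scaled by 1.4826
#' (the consistency constant for a normal distribution, matching the common
#' default of robust-outlier routines); `scale = "raw"` uses the unscaled
#' MAD for a literal three-MAD reading of the rule.
#'
#' @param x Numeric vector (`length >= 3`).
#' @param k Cutoff in (scaled) MADs (default 3).
#' @param scale `"normal"` (c = 1.4826) or `"raw"` (c = 1).
#' @return List with `kept`, `removed`, and `is_outlier` (logical, in the
#'   input order). A zero MAD with non-identical values falls back to
#'   removing everything different from the median (with a message).
#' @export
remove_outliers_mad <- function(x, k = 3, scale = c("normal", "raw")) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(x), length(x) >= 3L, k > 0)
  check_finite(x, "delta_t")
  med <- median(x)
  mad_raw <- median(abs(x - med))
  cc <- if (scale == "normal") 1.4826 else 1
  if (mad_raw == 0 && any(x != med)) {
    message("MAD is zero with non-identical values: removing all values != median")
    is_out <- x != med
  } else {
    is_out <- abs(x - med) > k * cc * mad_raw
  }
  list(kept = x[!is_out], removed = x[is_out], is_outlier = is_out)
}

#' Lilliefors-corrected Kolmogorov-Smirnov test of normality
#'
#' One-sample KS test against a normal whose mean and standard deviation
#' are estimated from the data; the Lilliefors correction accounts for that
#' estimation (a plain KS test would be anti-conservative).
#'
#' @param x Numeric vector (`n >= 5`).
#' @return The p-value. Zero variance yields p = 0 with a warning.
#' @export
ks_normality <- function(x) {
  stopifnot(is.numeric(x))
  if (length(x) < 5L) stop_bad("ks_normality needs n >= 5 (got %d)", length(x))
  if (stats::sd(x) == 0) {
    warn_msg("zero variance: returning p = 0")
    return(0)
  }
  nortest::lillie.test(x)$p.value
}

# adjusted Fisher-Pearson standardized moment coefficient
sample_skewness <- function(x, adjust = TRUE) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  if (adjust) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Skewness and test of asymmetry
#'
#' Adjusted Fisher-Pearson sample skewness G1 together with D'Agostino's
#' (1970) two-sided test of zero skewness.
#'
#' @param x Numeric vector (`n >= 8`; the test's small-sample transformation
#'   needs it).
#' @return List with `g1` (adjusted skewness), `statistic` (approximately
#'   standard-normal under symmetry), `p` (two-sided). Zero variance errors.
#' @export
skewness_test <- function(x) {
  stopifnot(is.numeric(x))
  n <- length(x)
  if (n < 8L) stop_bad("skewness_test needs n >= 8 (got %d)", n)
  if (stats::sd(x) == 0) stop_bad("skewness undefined for zero-variance data")
  b1 <- sample_skewness(x, adjust = FALSE)   # plain g1 = m3 / m2^(3/2)
  g1_adj <- sample_skewness(x, adjust = TRUE)
  # D'Agostino (1970) normalizing transformation of sqrt(b1)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  p <- 2 * pnorm(-abs(z))
  list(g1 = g1_adj, statistic = z, p = p)
}

#' Mode of the lag distribution by kernel density estimation
#'
#' Argmax of a Gaussian kernel density estimate evaluated on a 1 ms grid
#' over the data range. Bandwidth defaults to Silverman's rule of thumb.
#'
#' @param x Numeric vector (`n >= 50`).
#' @param bandwidth `"silverman"` or a numeric bandwidth in seconds.
#' @return The mode, seconds.
#' @export
density_mode <- function(x, bandwidth = "silverman") {
  stopifnot(is.numeric(x))
  if (length(x) < 50L) stop_bad("density_mode needs n >= 50 (got %d)",
                                length(x))
  if (diff(range(x)) == 0) return(x[1])
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(x) else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  grid <- seq(min(x), max(x), by = 1e-3)
  dens <- vapply(grid, function(g) sum(dnorm((g - x) / bw)), numeric(1))
  grid[which.max(dens)]
}

#' Compare lag distributions between two conditions
#'
#' Two-sample t test of the mean lag between conditions (e.g. human vs
#' robot interlocutor); both the pooled-variance (Student) and
#' unequal-variance (Welch) versions are reported, with per-group means and
#' standard deviations.
#'
#' @param deltas_a,deltas_b Numeric lag vectors (`n >= 2` each).
#' @return List with `means`, `sds`, `n` (each length-2, `a`/`b`),
#'   `student` and `welch` (each `t`, `dof`, `p`). Zero variance in both
#'   groups with equal means yields t = 0, p = 1.
#' @export
compare_conditions <- function(deltas_a, deltas_b) {
  stopifnot(length(deltas_a) >= 2L, length(deltas_b) >= 2L)
  ms <- c(a = mean(deltas_a), b = mean(deltas_b))
  ss <- c(a = sd(deltas_a), b = sd(deltas_b))
  ns <- c(a = length(deltas_a), b = length(deltas_b))
  if (all(ss == 0)) {
    eq <- ms[1] == ms[2]
    z <- list(t = if (eq) 0 else Inf,
              dof = sum(ns) - 2, p = if (eq) 1 else 0)
    return(list(means = ms, sds = ss, n = ns, student = z, welch = z))
  }
  st <- t.test(deltas_a, deltas_b, var.equal = TRUE)
  we <- t.test(deltas_a, deltas_b, var.equal = FALSE)
  list(means = ms, sds = ss, n = ns,
       student = list(t = unname(st$statistic), dof = unname(st$parameter),
                      p = st$p.value),
       welch = list(t = unname(we$statistic), dof = unname(we$parameter),
                    p = we$p.value))
}

#' Summarise per-IPU lag records
#'
#' Applies the MAD outlier filter, then characterises the cleaned lag
#' distribution: Lilliefors normality, skewness (with test), density mode,
#' per-condition means/sds and the two-sample comparison when a two-level
#' `condition` column is present, and a cumulative-density table for
#' plotting. When `n_peaks` is supplied, the Resp+ fraction is reported as
#' the number of distinct linked maxima over the total maxima count.
#'
#' @param records Data frame with at least `delta_t`; optionally
#'   `peak_time` (for the distinct-Resp+ count) and `condition`.
#' @param n_peaks Total number of detected respiration maxima (optional).
#' @param mad_k,mad_scale Passed to [remove_outliers_mad()].
#' @param bandwidth Passed to [density_mode()].
#' @return An object of class `delta_t_summary`: list with `n_total`,
#'   `n_removed`, `pct_removed`, `n_kept`, `mean`, `sd`, `ks_p`, `skewness`,
#'   `skewness_p`, `mode`, `n_resp_plus`, `pct_resp_plus`, `group`
#'   (comparison or NULL), `cdf` (data frame `delta_t`, `cum`), `records`
#'   (input with the `outlier` flag filled).
#' @export
summarize_deltas <- function(records, n_peaks = NULL, mad_k = 3,
                             mad_scale = "normal", bandwidth = "silverman") {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            "delta_t" %in% names(records))
  x <- records$delta_t
  check_finite(x, "delta_t")
  n_total <- length(x)
  if (n_total >= 3L) {
    flt <- remove_outliers_mad(x, k = mad_k, scale = mad_scale)
  } else {
    flt <- list(kept = x, removed = numeric(0),
                is_outlier = rep(FALSE, n_total))
  }
  kept <- flt$kept
  records$outlier <- flt$is_outlier
  n_removed <- sum(flt$is_outlier)

  ks_p <- if (length(kept) >= 5L && sd(kept) > 0) ks_normality(kept) else NA_real_
  sk <- if (length(kept) >= 8L && sd(kept) > 0) skewness_test(kept) else
    list(g1 = NA_real_, statistic = NA_real_, p = NA_real_)
  mode <- if (length(kept) >= 50L) density_mode(kept, bandwidth) else NA_real_

  group <- NULL
  if ("condition" %in% names(records)) {
    cond <- records$condition[!records$outlier]
    lv <- unique(cond)
    if (length(lv) == 2L && all(table(cond) >= 2L)) {
      group <- compare_conditions(kept[cond == lv[1]], kept[cond == lv[2]])
      group$levels <- lv
    }
  }

  n_resp_plus <- if ("peak_time" %in% names(records)) {
    length(unique(records$peak_time))
  } else {
    n_total
  }
  pct_resp_plus <- if (!is.null(n_peaks)) 100 * n_resp_plus / n_peaks else
    NA_real_

  xs <- sort(kept)
  cdf <- data.frame(delta_t = xs,
                    cum = seq_along(xs) / length(xs))

  structure(list(n_total = n_total, n_removed = n_removed,
                 pct_removed = 100 * n_removed / n_total,
                 n_kept = length(kept),
                 mean = mean(kept), sd = sd(kept),
                 ks_p = ks_p, skewness = sk$g1, skewness_p = sk$p,
                 mode = mode,
                 n_resp_plus = n_resp_plus, pct_resp_plus = pct_resp_plus,
                 group = group, cdf = cdf, records = records),
            class = "delta_t_summary")
}

#' @export
print.delta_t_summary <- function(x, ...) {
  cat("Lag (delta-t) summary: breath maximum relative to speech onset\n")
  cat(sprintf("  records: %d (removed %d outliers, %.2f%%)\n",
              x$n_total, x$n_removed, x$pct_removed))
  cat(sprintf("  mean %.4f s, sd %.4f s, density mode %s\n",
              x$mean, x$sd,
              if (is.na(x$mode)) "n/a" else sprintf("%.4f s", x$mode)))
  cat(sprintf("  skewness G1 = %.3f (p = %.3g), Lilliefors p = %.3g\n",
              x$skewness, x$skewness_p, x$ks_p))
  if (!is.na(x$pct_resp_plus)) {
    cat(sprintf("  Resp+ maxima: %d (%.2f%% of all maxima)\n",
                x$n_resp_plus, x$pct_resp_plus))
  }
  if (!is.null(x$group)) {
    cat(sprintf("  %s vs %s: Student t(%.0f) = %.3f, p = %.3g; Welch t(%.1f) = %.3f, p = %.3g\n",
                x$group$levels[1], x$group$levels[2],
                x$group$student$dof, x$group$student$t, x$group$student$p,
                x$group$welch$dof, x$group$welch$t, x$group$welch$p))
  }
  invisible(x)
}
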