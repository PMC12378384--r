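#' Read and write respiration-belt traces as plain TSV
#'
#' The exchange format is a two-column UTF-8 TSV with header
#' `time_s<TAB>amplitude` (decimal point, never comma). A single-column file
#' (amplitudes only) is accepted when `rate` is supplied. Time must be
#' monotone; if the sampling jitter exceeds half a sample period the trace
#' is resampled onto a uniform grid with a warning. Amplitudes round-trip at
#' full float precision.
#'
#' @param path File path.
#' @param rate Sampling rate in Hz, required for single-column files.
#' @return `read_belt_tsv` returns a [resp_trace()] (origin = first
#'   timestamp); `write_belt_tsv` invisibly returns `path`.
#' @export
read_belt_tsv <- function(path, rate = NULL) {
  tab <- read_numeric_tsv(path, what = "belt trace")
  if (nrow(tab) == 0L) stop_bad("empty belt file: %s", path)
  if (ncol(tab) == 1L) {
    if (is.null(rate)) {
      stop_bad("single-column belt file needs a declared sampling rate: %s",
               path)
    }
    check_finite(tab[[1]], "amplitude")
    return(resp_trace(tab[[1]], rate = rate, origin = 0))
  }
  tm <- tab[[1]]; amp <- tab[[2]]
  check_finite(tm, "time_s")
  check_finite(amp, "amplitude")
  if (nrow(tab) < 2L) stop_bad("belt file has fewer than 2 samples: %s", path)
  dt <- diff(tm)
  if (any(dt <= 0)) {
    stop_bad("non-monotone time in belt file at row %d", which(dt <= 0)[1] + 1L)
  }
  period <- median(dt)
  est_rate <- (length(tm) - 1L) / (tm[length(tm)] - tm[1])
  if (max(abs(dt - period)) >= period / 2) {
    warn_msg("sampling jitter exceeds half a period; resampling onto a uniform grid")
    grid <- seq(tm[1], tm[length(tm)], by = period)
    amp <- approx(tm, amp, xout = grid)$y
    est_rate <- 1 / period
  }
  resp_trace(amp, rate = est_rate, origin = tm[1])
}

#' @param trace A [resp_trace()].
#' @rdname read_belt_tsv
#' @export
write_belt_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "resp_trace"))
  tm <- trace_times(trace)
  lines <- c("time_s\tamplitude",
             paste(fmt_ms(tm), fmt_full(trace$samples), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Read a whitespace/TSV table of numbers, tolerating an optional header
# line; rejects NaN/Inf with the offending row named.
read_numeric_tsv <- function(path, what = "table") {
  if (!file.exists(path)) stop_bad("no such file: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop_bad("empty %s file: %s", what, path)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "[\t ,]+")[[1]][1])))
  tab <- read.table(path, header = has_header, sep = "\t",
                    stringsAsFactors = FALSE)
  for (j in seq_along(tab)) {
    if (is.numeric(tab[[j]]) && any(!is.finite(tab[[j]]))) {
      stop_bad("non-finite value in %s (%s) at row %d", what, path,
               which(!is.finite(tab[[j]]))[1])
    }
  }
  tab
}
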