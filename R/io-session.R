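#' Session timeline: scanning-session clock bookkeeping
#'
#' Times throughout the package live in seconds on the session clock, origin
#' at the start of the scanning session. A session is described by its
#' volume count and repetition time (e.g. 385 volumes at TR 1.205 s =
#' 463.925 s) plus the onsets of the conversation blocks.
#'
#' @param n_volumes Number of acquired volumes.
#' @param tr Repetition time in seconds.
#' @param session_duration Seconds; defaults to `n_volumes * tr` and must
#'   agree with it within 1 ms when supplied.
#' @param block_onsets Sorted block onsets, seconds on the session clock.
#' @return A list of class `session_timeline`.
#' @export
session_timeline <- function(n_volumes, tr, session_duration = NULL,
                             block_onsets = numeric(0)) {
  stopifnot(n_volumes > 0, tr > 0)
  implied <- n_volumes * tr
  if (is.null(session_duration)) session_duration <- implied
  if (abs(session_duration - implied) > 1e-3) {
    stop_bad("declared duration %.3f s inconsistent with n_volumes * tr = %.3f s (beyond 1 ms)",
             session_duration, implied)
  }
  block_onsets <- as.numeric(block_onsets)
  if (is.unsorted(block_onsets)) stop_bad("block_onsets must be sorted")
  if (length(block_onsets) &&
      (min(block_onsets) < 0 || max(block_onsets) > session_duration)) {
    stop_bad("block_onsets outside [0, %.3f]", session_duration)
  }
  structure(list(session_duration = session_duration,
                 n_volumes = as.integer(n_volumes), tr = tr,
                 block_onsets = block_onsets),
            class = "session_timeline")
}

#' @export
print.session_timeline <- function(x, ...) {
  cat(sprintf("<session_timeline> %d volumes x TR %.3f s = %.3f s, %d block(s)\n",
              x$n_volumes, x$tr, x$session_duration, length(x$block_onsets)))
  invisible(x)
}

#' Read / write a session log
#'
#' The log is a two-column TSV (`field`, `value`) with fields `n_volumes`,
#' `tr`, optionally `session_duration`, and one `block_onset` row per
#' conversation block. (The scanner's own log schema is proprietary; this
#' plain-text stand-in carries the same information.)
#'
#' @param path File path.
#' @return `read_session_log` returns a [session_timeline()].
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop_bad("no such file: %s", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "numeric"))
  if (!all(c("field", "value") %in% names(tab))) {
    stop_bad("session log must have columns field, value: %s", path)
  }
  check_finite(tab$value, "session log value")
  get1 <- function(f) {
    v <- tab$value[tab$field == f]
    if (length(v) > 1L) stop_bad("duplicated field '%s' in %s", f, path)
    if (length(v)) v else NULL
  }
  n_volumes <- get1("n_volumes")
  tr <- get1("tr")
  dur <- get1("session_duration")
  onsets <- tab$value[tab$field == "block_onset"]
  if (is.null(dur) && (is.null(n_volumes) || is.null(tr))) {
    stop_bad("session log needs session_duration or both n_volumes and tr: %s",
             path)
  }
  if (is.null(n_volumes)) { n_volumes <- 1; tr <- dur }
  session_timeline(n_volumes, tr, session_duration = dur,
                   block_onsets = sort(onsets))
}

#' @param timeline A [session_timeline()].
#' @rdname read_session_log
#' @export
write_session_log <- function(timeline, path) {
  stopifnot(inherits(timeline, "session_timeline"))
  lines <- c("field\tvalue",
             sprintf("n_volumes\t%d", timeline$n_volumes),
             sprintf("tr\t%s", fmt_ms(timeline$tr)),
             sprintf("session_duration\t%s", fmt_ms(timeline$session_duration)),
             sprintf("block_onset\t%s", fmt_ms(timeline$block_onsets)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
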