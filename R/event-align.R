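#' Shift block-relative IPUs onto the session clock
#'
#' Each conversation block's IPU onsets/offsets are shifted by that block's
#' onset taken from the session log, yielding session-clock times.
#'
#' @param ipu_list IPU data frame whose `trial_id` indexes into
#'   `block_onsets`.
#' @param block_onsets Numeric block onsets (seconds, session clock), or a
#'   [session_timeline()].
#' @return The IPU data frame on the session clock, ordering preserved. An
#'   IPU extending past the next block's onset is kept with a warning.
#' @export
ipus_to_session_clock <- function(ipu_list, block_onsets) {
  if (inherits(block_onsets, "session_timeline")) {
    block_onsets <- block_onsets$block_onsets
  }
  if (!nrow(ipu_list)) return(ipu_list)
  tid <- ipu_list$trial_id
  if (any(tid < 1L) || any(tid > length(block_onsets))) {
    stop_bad("IPU trial_id without a matching block onset")
  }
  shift <- block_onsets[tid]
  out <- ipu_list
  out$onset <- ipu_list$onset + shift
  out$offset <- ipu_list$offset + shift
  nxt <- c(block_onsets[-1L], Inf)[tid]
  if (any(out$offset > nxt)) {
    warn_msg("%d IPU(s) extend past the next block onset; kept",
             sum(out$offset > nxt))
  }
  out
}

#' Classify respiration maxima as Resp+ / Resp- and compute per-IPU lags
#'
#' For every participant IPU onset, the respiration maximum that is
#' temporally closest in absolute value is labelled `RESP_PLUS` and linked
#' to that IPU; all never-linked maxima are `RESP_MINUS`. The two labels
#' partition the peak set. One lag record is produced per IPU:
#' `delta_t = peak_time - ipu_onset` (negative = the breath maximum precedes
#' speech onset). A peak closest to several IPU onsets is a single Resp+
#' event but contributes one lag per IPU. There is no maximum matching
#' window: the nearest peak is Resp+ however far away; extreme lags are
#' handled downstream by the MAD filter. Two equidistant peaks tie toward
#' the earlier one (inhalation precedes speech physiologically).
#'
#' @param peaks A `resp_peaks` data frame ([detect_peaks()]), sorted by
#'   time, with at least one peak.
#' @param participant_ipu_onsets Numeric vector of participant IPU onsets
#'   (session clock), or a session-clock IPU data frame (its participant
#'   rows are used).
#' @return List with `peaks` (labelled; `ipu_id` = first linked IPU) and
#'   `deltas`, a data frame (`ipu_id`, `peak_time`, `ipu_onset`, `delta_t`,
#'   `outlier` = NA). With no IPUs, all peaks are `RESP_MINUS` and `deltas`
#'   is empty.
#' @export
classify_peaks <- function(peaks, participant_ipu_onsets) {
  stopifnot(inherits(peaks, "data.frame"), nrow(peaks) >= 1L)
  if (is.unsorted(peaks$time)) stop_bad("peaks must be sorted by time")
  onsets <- if (is.data.frame(participant_ipu_onsets)) {
    p <- participant_ipu_onsets
    p$onset[p$speaker == "participant"]
  } else {
    as.numeric(participant_ipu_onsets)
  }
  pt <- peaks$time
  out <- peaks
  out$label <- rep("RESP_MINUS", nrow(peaks))
  out$ipu_id <- rep(NA_integer_, nrow(peaks))
  if (!length(onsets)) {
    return(list(peaks = out,
                deltas = data.frame(ipu_id = integer(0),
                                    peak_time = numeric(0),
                                    ipu_onset = numeric(0),
                                    delta_t = numeric(0),
                                    outlier = logical(0))))
  }
  nearest <- vapply(onsets, function(o) {
    d <- abs(pt - o)
    m <- min(d)
    which(d <= m + 0)[1L]  # first index = earlier peak on exact tie
  }, integer(1))
  out$label[nearest] <- "RESP_PLUS"
  first_link <- !duplicated(nearest)
  out$ipu_id[nearest[first_link]] <- seq_along(onsets)[first_link]
  deltas <- data.frame(ipu_id = seq_along(onsets),
                       peak_time = pt[nearest],
                       ipu_onset = onsets,
                       delta_t = pt[nearest] - onsets,
                       outlier = rep(NA, length(onsets)))
  list(peaks = out, deltas = deltas)
}

#' Export labelled peaks and IPUs as a GLM-ready events table
#'
#' Resp+ / Resp- maxima are written as zero-duration events (`resp_plus`,
#' `resp_minus`); participant and interlocutor IPUs as `ipu_participant` /
#' `ipu_interlocutor` with their true durations. Rows are sorted by onset.
#'
#' @param labelled_peaks Labelled `resp_peaks` (from [classify_peaks()]).
#' @param ipu_list Session-clock IPU data frame (both speakers).
#' @param path Optional path; when given the table is also written as TSV.
#' @return The [events_table()], invisibly when `path` is given.
#' @export
export_glm_events <- function(labelled_peaks, ipu_list, path = NULL) {
  stopifnot(all(labelled_peaks$label %in% c("RESP_PLUS", "RESP_MINUS")))
  onset <- c(labelled_peaks$time, ipu_list$onset)
  duration <- c(rep(0, nrow(labelled_peaks)),
                ipu_list$offset - ipu_list$onset)
  type <- c(ifelse(labelled_peaks$label == "RESP_PLUS",
                   "resp_plus", "resp_minus"),
            paste0("ipu_", ipu_list$speaker))
  ord <- order(onset)
  ev <- events_table(onset[ord], duration[ord], type[ord])
  if (!is.null(path)) {
    write_events(ev, path)
    return(invisible(ev))
  }
  ev
}
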