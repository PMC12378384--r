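#' Events table (BIDS events dialect)
#'
#' Tab-separated events with header `onset<TAB>duration<TAB>trial_type`,
#' suitable as GLM inputs. The trial_type vocabulary used by the pipeline is
#' `resp_plus`, `resp_minus` (zero-duration respiration-maximum events),
#' `ipu_participant`, `ipu_interlocutor` (speech turns with true durations).
#'
#' @param onset Numeric onsets, seconds (sorted).
#' @param duration Numeric durations, seconds (>= 0; exactly 0 for `resp_*`).
#' @param trial_type Character labels.
#' @return A validated data frame of class `events_table`.
#' @export
events_table <- function(onset, duration, trial_type) {
  stopifnot(length(onset) == length(duration),
            length(onset) == length(trial_type))
  check_finite(onset, "onset")
  check_finite(duration, "duration")
  if (is.unsorted(onset)) stop_bad("event onsets must be sorted")
  if (any(duration < 0)) {
    stop_bad("negative duration at row %d", which(duration < 0)[1])
  }
  resp <- grepl("^resp_", trial_type)
  if (any(resp & duration != 0)) {
    stop_bad("resp_* events must have duration exactly 0 (row %d)",
             which(resp & duration != 0)[1])
  }
  structure(data.frame(onset = as.numeric(onset),
                       duration = as.numeric(duration),
                       trial_type = as.character(trial_type),
                       stringsAsFactors = FALSE),
            class = c("events_table", "data.frame"))
}

#' Read / write events TSV
#'
#' @param path File path.
#' @return `read_events` returns an [events_table()]; round-trips preserve
#'   onsets and durations to 1 ms.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_bad("no such file: %s", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(tab))) {
    stop_bad("events file must have columns onset, duration, trial_type: %s",
             path)
  }
  events_table(tab$onset, tab$duration, tab$trial_type)
}

#' @param events An [events_table()].
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "events_table"))
  lines <- c("onset\tduration\ttrial_type",
             paste(fmt_ms(events$onset), fmt_ms(events$duration),
                   events$trial_type, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read IPU annotations from a TextGrid or events TSV
#'
#' For TextGrids, every interval with a non-empty label on an interval tier
#' becomes an IPU (empty labels are silences); tier names containing
#' "interlocutor" map to the interlocutor, all other tiers to the
#' participant. For events TSVs, rows with trial_type `ipu_participant` /
#' `ipu_interlocutor` are used.
#'
#' @param path File path (`.TextGrid` or `.tsv`).
#' @return IPU data frame (`onset`, `offset`, `speaker`, `trial_id`).
#' @export
read_ipu_annotations <- function(path) {
  if (grepl("\\.textgrid$", path, ignore.case = TRUE)) {
    return(read_textgrid_ipus(path))
  }
  ev <- read_events(path)
  keep <- ev$trial_type %in% c("ipu_participant", "ipu_interlocutor")
  ev <- ev[keep, , drop = FALSE]
  data.frame(onset = ev$onset, offset = ev$onset + ev$duration,
             speaker = sub("^ipu_", "", ev$trial_type),
             trial_id = rep(1L, nrow(ev)), stringsAsFactors = FALSE)
}
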