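# Minimal Praat TextGrid reader/writer (long "ooTextFile" format, interval
# tiers only). Hand-written because no installed R package parses the
# format; covers the subset needed for IPU interchange.

#' Read IPUs from a Praat TextGrid
#'
#' @param path TextGrid path (long text format).
#' @return IPU data frame (`onset`, `offset`, `speaker`, `trial_id`).
#'   Overlapping intervals within one tier raise an error.
#' @export
read_textgrid_ipus <- function(path) {
  if (!file.exists(path)) stop_bad("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  num_after <- function(l) as.numeric(sub(".*= *", "", l))
  str_after <- function(l) sub("\" *$", "", sub(".*= *\"", "", l))

  tier_starts <- grep("class = \"IntervalTier\"", lines)
  if (!length(tier_starts)) stop_bad("no interval tier in %s", path)
  out <- list()
  for (ts in tier_starts) {
    tier_name <- str_after(lines[ts + 1L])
    speaker <- if (grepl("interlocutor", tier_name, ignore.case = TRUE)) {
      "interlocutor"
    } else {
      "participant"
    }
    # intervals run until the next tier (or EOF)
    next_tier <- tier_starts[tier_starts > ts]
    stop_at <- if (length(next_tier)) next_tier[1] - 1L else length(lines)
    block <- lines[ts:stop_at]
    xmins <- num_after(grep("^ *xmin", block, value = TRUE)[-1L])
    xmaxs <- num_after(grep("^ *xmax", block, value = TRUE)[-1L])
    texts <- str_after(grep("^ *text", block, value = TRUE))
    if (length(xmins) != length(texts)) {
      stop_bad("malformed TextGrid tier '%s' in %s", tier_name, path)
    }
    if (any(!is.finite(xmins)) || any(!is.finite(xmaxs))) {
      stop_bad("non-finite interval bound in tier '%s'", tier_name)
    }
    ord <- order(xmins)
    xmins <- xmins[ord]; xmaxs <- xmaxs[ord]; texts <- texts[ord]
    if (any(xmins[-1L] < xmaxs[-length(xmaxs)] - 1e-9)) {
      stop_bad("overlapping intervals in tier '%s' of %s", tier_name, path)
    }
    keep <- nzchar(trimws(texts))
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        onset = xmins[keep], offset = xmaxs[keep],
        speaker = speaker, trial_id = 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      speaker = character(0), trial_id = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$onset), , drop = FALSE]
}

#' Write IPUs to a Praat TextGrid
#'
#' One interval tier per speaker (named `ipu-participant` /
#' `ipu-interlocutor`); gaps between IPUs are written as empty-label
#' (silence) intervals.
#'
#' @param ipu_list IPU data frame (`onset`, `offset`, `speaker`).
#' @param path Output path.
#' @param xmax Total duration; default last offset.
#' @return Invisibly, `path`.
#' @export
write_ipu_textgrid <- function(ipu_list, path, xmax = NULL) {
  if (is.null(xmax)) {
    xmax <- if (nrow(ipu_list)) max(ipu_list$offset) else 1
  }
  speakers <- intersect(c("participant", "interlocutor"),
                        unique(ipu_list$speaker))
  if (!length(speakers)) speakers <- "participant"
  fmt <- function(x) sprintf("%.6f", x)

  tier_lines <- function(sp, tier_idx) {
    ip <- ipu_list[ipu_list$speaker == sp, , drop = FALSE]
    ip <- ip[order(ip$onset), , drop = FALSE]
    # interleave silences
    bounds_min <- numeric(0); bounds_max <- numeric(0); labs <- character(0)
    t <- 0
    for (i in seq_len(nrow(ip))) {
      if (ip$onset[i] > t + 1e-9) {
        bounds_min <- c(bounds_min, t); bounds_max <- c(bounds_max, ip$onset[i])
        labs <- c(labs, "")
      }
      bounds_min <- c(bounds_min, ip$onset[i])
      bounds_max <- c(bounds_max, ip$offset[i])
      labs <- c(labs, "ipu")
      t <- ip$offset[i]
    }
    if (t < xmax - 1e-9 || !length(bounds_min)) {
      bounds_min <- c(bounds_min, t); bounds_max <- c(bounds_max, xmax)
      labs <- c(labs, "")
    }
    c(sprintf("    item [%d]:", tier_idx),
      "        class = \"IntervalTier\"",
      sprintf("        name = \"ipu-%s\"", sp),
      sprintf("        xmin = %s", fmt(0)),
      sprintf("        xmax = %s", fmt(xmax)),
      sprintf("        intervals: size = %d", length(labs)),
      unlist(lapply(seq_along(labs), function(i) {
        c(sprintf("        intervals [%d]:", i),
          sprintf("            xmin = %s", fmt(bounds_min[i])),
          sprintf("            xmax = %s", fmt(bounds_max[i])),
          sprintf("            text = \"%s\"", labs[i]))
      })))
  }

  lines <- c("File type = \"ooTextFile\"",
             "Object class = \"TextGrid\"",
             "",
             "xmin = 0.000000",
             sprintf("xmax = %s", fmt(xmax)),
             "tiers? <exists>",
             sprintf("size = %d", length(speakers)),
             "item []:",
             unlist(lapply(seq_along(speakers), function(i) {
               tier_lines(speakers[i], i)
             })))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
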