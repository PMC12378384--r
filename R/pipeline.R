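# End-to-end orchestration: synthesize -> preprocess -> segment -> align ->
# stats, with YAML config, plain-text logging and reproducibility controls.
# Stage boundaries are exactly the on-disk formats of the I/O module, so any
# stage can be replaced by external tooling.

#' Default run configuration
#'
#' Every parameter the pipeline stages consume, with its default. The
#' session layout mirrors a standard scanning session: 385 volumes at TR
#' 1.205 s (463.925 s) holding six one-minute conversation blocks. The
#' config round-trips losslessly through YAML ([read_run_config()] /
#' [write_run_config()]).
#'
#' @param seed Master integer seed; all stage randomness derives from it via
#'   [child_seed()].
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    session = list(n_volumes = 385L, tr = 1.205,
                   block_onsets = 15 + (0:5) * 73, block_length = 60,
                   conditions = c("human", "robot", "human",
                                  "robot", "human", "robot")),
    conversation = list(mean_turn = 3, mean_gap = 1, p_switch = 0.75,
                        min_turn = 0.15),
    breath = list(inhale_dur_range = c(0.2, 0.5),
                  exhale_dur_range = c(1.2, 2.5),
                  amplitude_range = c(0.8, 1.2),
                  baseline_drift_sd = 0.05, noise_sd = 0.01),
    lag = list(family = "shifted_negative_gamma", mode = -0.2,
               spread = 0.165, shape = 6),
    coupling = list(coupled_fraction = 1, metabolic_clearance = 1,
                    sampling_rate = 200),
    saturation = list(rail_low = -Inf, rail_high = 1.1),
    envelope = list(frame = 0.01, speech_level = 1, noise_level = 0.1,
                    jitter_sd = 0.1),
    segment = list(coefficient = 0.5, min_pause = 0.2, min_ipu = 0.1),
    peaks = list(min_separation = 1.0, smooth_ms = 100,
                 refine = "upstroke_centroid", refine_smooth_ms = 40),
    stats = list(mad_k = 3, mad_scale = "normal", bandwidth = "silverman")),
    class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  out <- utils::modifyList(unclass(base), cfg)
  class(out) <- "run_config"
  out
}

#' @param config A `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

config_hash <- function(config) {
  fnv1a(yaml::as.yaml(unclass(config), precision = 12))
}

#' Read / write detected respiration peaks as TSV
#'
#' Columns `time_s`, `amplitude`, `label`, `ipu_id`.
#'
#' @param path File path.
#' @return `read_peaks` returns a `resp_peaks` data frame.
#' @export
read_peaks <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  check_finite(tab$time_s, "time_s")
  out <- data.frame(time = tab$time_s, amplitude = tab$amplitude,
                    label = tab$label,
                    ipu_id = suppressWarnings(as.integer(tab$ipu_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("resp_peaks", "data.frame")
  out
}

#' @param peaks A `resp_peaks` data frame.
#' @rdname read_peaks
#' @export
write_peaks <- function(peaks, path) {
  lines <- c("time_s\tamplitude\tlabel\tipu_id",
             paste(fmt_ms(peaks$time), fmt_full(peaks$amplitude),
                   peaks$label,
                   ifelse(is.na(peaks$ipu_id), "NA", peaks$ipu_id),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

write_deltas_tsv <- function(deltas, path) {
  cols <- c("ipu_id", "peak_time", "ipu_onset", "delta_t")
  lines <- c(paste(c(cols, "outlier", "condition"), collapse = "\t"),
             paste(deltas$ipu_id, fmt_ms(deltas$peak_time),
                   fmt_ms(deltas$ipu_onset), fmt_ms(deltas$delta_t),
                   ifelse(is.na(deltas$outlier), "NA",
                          as.integer(deltas$outlier)),
                   deltas$condition %||% "pooled",
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a deltas TSV written by [run_session()]
#' @param path File path.
#' @return Data frame of per-IPU lag records.
#' @export
read_deltas_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
  check_finite(tab$delta_t, "delta_t")
  tab
}

#' Run one synthetic session end-to-end
#'
#' Synthesizes a session (conversation, respiration, saturation, envelope),
#' writes every intermediate to `out_dir` in the package's plain-text
#' formats, then runs the full analysis chain on the written files:
#' belt preprocessing (smooth, flag, repair, resample, end-align), envelope
#' segmentation into IPUs, Resp+/Resp- classification, and the lag summary.
#' Re-running with the same config produces byte-identical outputs; no
#' stage mutates its inputs.
#'
#' @param config A `run_config` ([default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `summary` (a `delta_t_summary`), `files`
#'   (named paths of all outputs), `truth` (ground truth), and `provenance`.
#' @export
run_session <- function(config = default_config(), out_dir = tempfile("session")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))
  fp <- function(f) file.path(out_dir, f)
  seed <- config$seed
  logf("breathturn %s", as.character(utils::packageVersion("breathturn")))
  logf("config hash %s, master seed %d", config_hash(config), seed)

  ses <- config$session
  timeline <- session_timeline(ses$n_volumes, ses$tr,
                               block_onsets = ses$block_onsets)
  write_session_log(timeline, fp("session_log.tsv"))
  logf("session: %d volumes x TR %.3f s = %.3f s, %d blocks",
       timeline$n_volumes, timeline$tr, timeline$session_duration,
       length(ses$block_onsets))

  # --- synthesize -----------------------------------------------------
  blocks <- lapply(seq_along(ses$block_onsets), function(b) {
    generate_conversation(ses$block_length, config$conversation,
                          seed = child_seed(seed, 100L + b), trial_id = b)
  })
  ipus_block <- do.call(rbind, blocks)
  ipus_true <- ipus_to_session_clock(ipus_block, ses$block_onsets)
  ipus_true <- ipus_true[order(ipus_true$onset), , drop = FALSE]
  logf("synthesized %d IPUs (%d participant) across %d blocks",
       nrow(ipus_true), sum(ipus_true$speaker == "participant"),
       length(blocks))
  ev_true <- events_table(ipus_true$onset,
                          ipus_true$offset - ipus_true$onset,
                          paste0("ipu_", ipus_true$speaker))
  write_events(ev_true, fp("ipus_true.tsv"))

  bp <- do.call(breath_cycle_params, config$breath)
  lm <- do.call(lag_model, config$lag)
  resp <- generate_respiration(
    ipus_true, breath_params = bp, lag_model = lm,
    coupled_fraction = config$coupling$coupled_fraction,
    sampling_rate = config$coupling$sampling_rate,
    duration = timeline$session_duration,
    metabolic_clearance = config$coupling$metabolic_clearance,
    seed = child_seed(seed, 200L))
  sat <- apply_saturation(resp$trace, config$saturation$rail_low,
                          config$saturation$rail_high)
  resp$truth$saturated_intervals <- sat$intervals
  logf("generated %d true maxima (%d speech-coupled), %d saturated runs",
       length(resp$truth$true_peak_times),
       sum(resp$truth$true_labels == "speech_coupled"), nrow(sat$intervals))
  write_belt_tsv(sat$trace, fp("belt.tsv"))
  truth_json <- list(
    true_peak_times = resp$truth$true_peak_times,
    true_labels = resp$truth$true_labels,
    true_lags = resp$truth$true_lags,
    saturated_intervals = resp$truth$saturated_intervals,
    n_ipus = nrow(ipus_true))
  jsonlite::write_json(truth_json, fp("truth.json"), digits = 10,
                       auto_unbox = TRUE, na = "null", pretty = TRUE)

  part_true <- ipus_true[ipus_true$speaker == "participant", , drop = FALSE]
  env <- render_rms_envelope(part_true,
                             duration = timeline$session_duration,
                             frame = config$envelope$frame,
                             speech_level = config$envelope$speech_level,
                             noise_level = config$envelope$noise_level,
                             jitter_sd = config$envelope$jitter_sd,
                             seed = child_seed(seed, 300L))
  writeLines(c("time_s\tvalue",
               paste(fmt_ms(env$time), fmt_full(env$value), sep = "\t")),
             fp("envelope.tsv"), useBytes = TRUE)

  # --- preprocess the belt from disk ----------------------------------
  belt <- read_belt_tsv(fp("belt.tsv"))
  intervals <- detect_saturation(belt)
  logf("flagged %d saturation run(s) covering %d samples", nrow(intervals),
       if (nrow(intervals)) sum(intervals[, 2] - intervals[, 1] + 1L) else 0L)
  repaired <- interpolate_gaps(belt, intervals)
  resampled <- resample_to_ms(repaired)
  aligned <- align_to_session(resampled, timeline)
  logf("belt: %d samples at %g Hz -> %d at 1000 Hz, origin %.3f s",
       length(belt$samples), belt$rate, length(aligned$samples),
       aligned$origin)
  peaks <- detect_peaks(aligned,
                        min_separation = config$peaks$min_separation,
                        smooth_ms = config$peaks$smooth_ms,
                        refine = config$peaks$refine,
                        refine_smooth_ms = config$peaks$refine_smooth_ms)
  logf("detected %d respiration maxima (min_separation %.2f s, default prominence)",
       nrow(peaks), config$peaks$min_separation)

  # --- segment the envelope -------------------------------------------
  thr <- threshold_from_rms(env, config$segment$coefficient)
  ipus_seg <- segment_ipus(env, thr, min_pause = config$segment$min_pause,
                           min_ipu = config$segment$min_ipu)
  logf("segmented %d participant IPUs (coefficient %.2f, threshold %.4f)",
       nrow(ipus_seg), config$segment$coefficient, thr)
  seg_ev <- events_table(ipus_seg$onset, ipus_seg$offset - ipus_seg$onset,
                         rep("ipu_participant", nrow(ipus_seg)))
  write_events(seg_ev, fp("ipus_detected.tsv"))

  # --- align & classify ------------------------------------------------
  cls <- classify_peaks(peaks, ipus_seg$onset)
  write_peaks(cls$peaks, fp("peaks.tsv"))
  interloc <- ipus_true[ipus_true$speaker == "interlocutor", , drop = FALSE]
  all_ipus <- rbind(ipus_seg,
                    interloc[, c("onset", "offset", "speaker", "trial_id")])
  export_glm_events(cls$peaks, all_ipus, fp("events.tsv"))
  n_plus <- sum(cls$peaks$label == "RESP_PLUS")
  logf("classified %d Resp+ / %d Resp- (%d lag records)",
       n_plus, sum(cls$peaks$label == "RESP_MINUS"), nrow(cls$deltas))

  deltas <- cls$deltas
  blk <- findInterval(deltas$ipu_onset, ses$block_onsets)
  blk[blk < 1L] <- 1L
  deltas$condition <- ses$conditions[pmin(blk, length(ses$conditions))]

  # --- summarise -------------------------------------------------------
  summary <- summarize_deltas(deltas, n_peaks = nrow(peaks),
                              mad_k = config$stats$mad_k,
                              mad_scale = config$stats$mad_scale,
                              bandwidth = config$stats$bandwidth)
  deltas$outlier <- summary$records$outlier
  write_deltas_tsv(deltas, fp("deltas.tsv"))
  logf("lag summary: n %d, removed %.2f%%, mode %s s, skewness %.3f",
       summary$n_total, summary$pct_removed,
       if (is.na(summary$mode)) "n/a" else sprintf("%.4f", summary$mode),
       summary$skewness)

  provenance <- list(package = "breathturn",
                     version = as.character(utils::packageVersion("breathturn")),
                     seed = seed, config_hash = config_hash(config))
  summary_json <- list(
    provenance = provenance,
    n_total = summary$n_total, n_removed = summary$n_removed,
    pct_removed = summary$pct_removed,
    mean = summary$mean, sd = summary$sd,
    ks_p = summary$ks_p, skewness = summary$skewness,
    skewness_p = summary$skewness_p, mode = summary$mode,
    n_peaks = nrow(peaks), n_resp_plus = n_plus,
    pct_resp_plus = 100 * n_plus / max(1L, nrow(peaks)))
  jsonlite::write_json(summary_json, fp("summary.json"), digits = 10,
                       auto_unbox = TRUE, na = "null", pretty = TRUE)
  writeLines(log_lines, fp("run.log"), useBytes = TRUE)

  invisible(list(summary = summary, truth = resp$truth,
                 files = setNames(
                   fp(c("session_log.tsv", "belt.tsv", "truth.json",
                        "envelope.tsv", "ipus_true.tsv", "ipus_detected.tsv",
                        "peaks.tsv", "events.tsv", "deltas.tsv",
                        "summary.json", "run.log")),
                   c("session_log", "belt", "truth", "envelope", "ipus_true",
                     "ipus_detected", "peaks", "events", "deltas", "summary",
                     "log")),
                 provenance = provenance))
}

#' Run a cohort of synthetic sessions and pool the lag records
#'
#' Pools at two aggregation levels: all IPU-level lag records together, and
#' the per-session mean lags (one value per session). Conditions are pooled
#' across interlocutor types, as supported by the absence of a group
#' difference, but the per-condition comparison is still reported.
#'
#' @param n_sessions Number of sessions.
#' @param base_config `run_config` template; session `i` runs with master
#'   seed `child_seed(base_config$seed, i)`.
#' @param out_dir Output directory (one subdirectory per session).
#' @return List with `pooled` (a `delta_t_summary` over all IPU records),
#'   `session_means` (numeric), `per_session` (list of summaries), and
#'   `pooled_mean_of_sessions`.
#' @export
run_cohort <- function(n_sessions, base_config = default_config(),
                       out_dir = tempfile("cohort")) {
  stopifnot(n_sessions >= 1L)
  per <- vector("list", n_sessions)
  all_deltas <- vector("list", n_sessions)
  n_peaks_tot <- 0L
  for (i in seq_len(n_sessions)) {
    cfg <- base_config
    cfg$seed <- child_seed(base_config$seed, 1000L + i)
    res <- run_session(cfg, file.path(out_dir, sprintf("session%03d", i)))
    per[[i]] <- res$summary
    d <- res$summary$records
    d$session <- i
    all_deltas[[i]] <- d
    n_peaks_tot <- n_peaks_tot + res$summary$n_resp_plus /
      (res$summary$pct_resp_plus / 100)
  }
  deltas <- do.call(rbind, all_deltas)
  pooled <- summarize_deltas(deltas[, setdiff(names(deltas), "outlier")],
                             n_peaks = round(n_peaks_tot))
  session_means <- vapply(per, function(s) s$mean, numeric(1))
  list(pooled = pooled, session_means = session_means,
       per_session = per,
       pooled_mean_of_sessions = mean(session_means))
}
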