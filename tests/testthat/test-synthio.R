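test_that("generated conversations respect the pause rule and time bounds", {
  ip <- generate_conversation(60, seed = 1)
  expect_gt(nrow(ip), 0)
  expect_true(all(ip$onset >= 0 & ip$offset <= 60))
  expect_true(all(ip$offset > ip$onset))
  for (sp in unique(ip$speaker)) {
    s <- ip[ip$speaker == sp, ]
    if (nrow(s) > 1) {
      expect_true(all(s$onset[-1] - s$offset[-nrow(s)] > 0.2))
    }
  }
})

test_that("a too-short conversation yields an empty list with a warning", {
  expect_warning(ip <- generate_conversation(0.1, seed = 1), "too short")
  expect_equal(nrow(ip), 0)
})

test_that("IPU count matches the closed-form expectation", {
  counts <- vapply(1:8, function(s) {
    nrow(generate_conversation(600, list(mean_turn = 3, mean_gap = 1),
                               seed = s))
  }, numeric(1))
  expected <- 600 / (3 + 1)
  expect_lt(abs(mean(counts) - expected) / expected, 0.15)
})

test_that("generators are reproducible from the seed", {
  expect_identical(generate_conversation(120, seed = 7),
                   generate_conversation(120, seed = 7))
  ip <- generate_conversation(60, seed = 2)
  a <- suppressMessages(generate_respiration(ip, seed = 3))
  b <- suppressMessages(generate_respiration(ip, seed = 3))
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth$true_peak_times, b$truth$true_peak_times)
  i1 <- generate_sulcus_image(seed = 5)
  i2 <- generate_sulcus_image(seed = 5)
  expect_identical(i1$image, i2$image)
})

test_that("default lag model is left-skewed; point mass is exact", {
  for (s in 1:5) {
    l <- draw_lags(lag_model(), 1000, seed = s)
    expect_lt(breathturn:::sample_skewness(l), 0)
  }
  pm <- draw_lags(lag_model("point_mass", mode = -0.2), 50, seed = 1)
  expect_identical(pm, rep(-0.2, 50))
})

test_that("respiration ground truth has coherent labels, lags and spacing", {
  ip <- generate_conversation(300, seed = 4)
  r <- suppressMessages(generate_respiration(ip, seed = 5, duration = 300))
  tr <- r$truth
  expect_true(all(diff(tr$true_peak_times) > 0))
  expect_true(all(tr$true_labels %in% c("speech_coupled", "metabolic")))
  coup <- tr$true_labels == "speech_coupled"
  expect_true(all(!is.na(tr$true_lags[coup])))
  expect_true(all(is.na(tr$true_lags[!coup])))
  # every coupled peak maps to exactly one IPU
  expect_false(any(duplicated(tr$ipu_id[coup])))
  # metabolic maxima keep >= 1 s clearance from participant onsets
  po <- ip$onset[ip$speaker == "participant"]
  met <- tr$true_peak_times[!coup]
  expect_gte(min(vapply(met, function(m) min(abs(po - m)), numeric(1))), 1)
  # coupled peak sits at onset + lag
  onset_of <- ip$onset[tr$ipu_id[coup]]
  expect_equal(tr$true_peak_times[coup], onset_of + tr$true_lags[coup],
               tolerance = 1e-9)
})

test_that("coupled_fraction = 0 produces only metabolic maxima", {
  ip <- generate_conversation(120, seed = 6)
  r <- generate_respiration(ip, coupled_fraction = 0, seed = 7,
                            duration = 120)
  expect_true(all(r$truth$true_labels == "metabolic"))
})

test_that("point-mass lags place every coupled peak exactly at onset - 200 ms", {
  ip <- generate_conversation(120, seed = 8)
  r <- suppressMessages(generate_respiration(
    ip, lag_model = lag_model("point_mass", mode = -0.2),
    seed = 9, duration = 120))
  coup <- r$truth$true_labels == "speech_coupled"
  expect_true(all(abs(r$truth$true_lags[coup] + 0.2) < 1e-12))
})

test_that("true peak times are the argmax of the clean trace to one sample", {
  s <- make_session(seed = 2, duration = 200)
  cl <- s$truth$clean
  idx <- round(s$truth$true_peak_times * s$trace$rate) + 1
  ok <- vapply(idx, function(i) {
    lo <- max(1, i - 30); hi <- min(length(cl), i + 30)
    abs((lo + which.max(cl[lo:hi]) - 1) - i) <= 1
  }, logical(1))
  expect_true(all(ok))
})

test_that("peak count tracks the breath-cycle expectation", {
  bp <- breath_cycle_params(inhale_dur_range = c(0.2, 0.5),
                            exhale_dur_range = c(2, 3))
  counts <- vapply(1:10, function(s) {
    ip <- generate_conversation(600, seed = s)
    r <- suppressMessages(generate_respiration(ip, breath_params = bp,
                                               seed = s + 50,
                                               duration = 600))
    length(r$truth$true_peak_times)
  }, numeric(1))
  expected <- 600 / (0.35 + 2.5)
  expect_true(all(abs(counts - expected) / expected < 0.15))
})

test_that("apply_saturation clamps, records runs, and rejects total clipping", {
  t <- seq(0, 20, by = 1 / 200)
  x <- sin(2 * pi * t / 4)
  tr <- resp_trace(x, 200)
  no <- apply_saturation(tr, rail_low = -2, rail_high = 2)
  expect_identical(no$trace$samples, x)
  expect_equal(nrow(no$intervals), 0)

  s <- apply_saturation(tr, rail_low = -0.9, rail_high = 0.9)
  expect_true(all(s$trace$samples <= 0.9 & s$trace$samples >= -0.9))
  expect_identical(s$trace$samples, pmin(pmax(x, -0.9), 0.9))
  # analytic clipped-run width: phase where |sin| > 0.9
  width_s <- (pi - 2 * asin(0.9)) / (2 * pi / 4)
  widths <- (s$intervals[, 2] - s$intervals[, 1] + 1) / 200
  interior <- s$intervals[, 1] > 1 & s$intervals[, 2] < length(x)
  expect_true(all(abs(widths[interior] - width_s) < 2 / 200))

  expect_error(apply_saturation(tr, rail_low = 2, rail_high = 3),
               "everything saturated")
  # high rail only: clipped runs sit at signal maxima
  hi <- apply_saturation(tr, rail_high = 0.9)
  mids <- rowMeans(hi$intervals) / 200
  expect_true(all(vapply(mids, function(m)
    min(abs(m - (1 + 4 * (0:4)))) < 0.2, logical(1))))
})

test_that("rendered envelopes separate speech from silence", {
  ip <- generate_conversation(30, seed = 3)
  env0 <- render_rms_envelope(ip, duration = 30, noise_level = 0, seed = 1)
  inside <- rep(FALSE, length(env0$time))
  for (i in seq_len(nrow(ip))) {
    inside <- inside | (env0$time >= ip$onset[i] & env0$time < ip$offset[i])
  }
  expect_true(all(env0$value[!inside] == 0))
  env <- render_rms_envelope(ip, duration = 30, noise_level = 0.1, seed = 1)
  expect_gt(mean(env$value[inside]), mean(env$value[!inside]))
})

test_that("envelope round-trips through segmentation at high SNR", {
  ip <- generate_conversation(120, seed = 11)
  ip <- ip[ip$speaker == "participant", ]
  env <- render_rms_envelope(ip, duration = 120, speech_level = 1,
                             noise_level = 0.1, seed = 2)
  thr <- threshold_from_rms(env, 0.5)
  seg <- segment_ipus(env, thr)
  expect_equal(nrow(seg), nrow(ip))
  derr <- c(abs(seg$onset - ip$onset), abs(seg$offset - ip$offset))
  expect_gte(mean(derr <= env$frame + 1e-9), 0.99)
})

test_that("segmentation recall does not degrade as SNR rises", {
  ip <- generate_conversation(60, seed = 12)
  ip <- ip[ip$speaker == "participant", ]
  recall <- vapply(c(0.3, 0.15, 0.05), function(nl) {
    env <- render_rms_envelope(ip, duration = 60, speech_level = 1,
                               noise_level = nl, seed = 3)
    seg <- segment_ipus(env, threshold_from_rms(env, 0.5))
    hits <- vapply(ip$onset, function(o)
      any(abs(seg$onset - o) <= 2 * env$frame), logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(recall) >= 0))
})

test_that("synthetic sulcus images carry a dark path and labelled probes", {
  g <- generate_sulcus_image(size = 96, noise_sd = 0, seed = 4)
  img <- g$image
  off <- img
  off[g$true_path] <- NA
  expect_lt(max(img[g$true_path]), min(off, na.rm = TRUE))
  expect_setequal(g$probe_points$label,
                  c("ON_LINE", "FUNDUS", "ANTERIOR", "POSTERIOR"))
  near <- g$probe_points[g$probe_points$label == "FUNDUS", ]
  expect_lt(sqrt((near$row - g$seed_px[1])^2 + (near$col - g$seed_px[2])^2), 1)
  expect_warning(generate_sulcus_image(depth_contrast = 0.2, noise_sd = 0.3,
                                       seed = 1),
                 "not guaranteed")
})

test_that("a straight vertical dark line is the column of minimal intensity", {
  g <- generate_sulcus_image(
    size = 64, noise_sd = 0,
    path_spec = list(start = c(10, 40), length = 35, amplitude = 0,
                     cycles = 0, hemisphere = "left"),
    seed = 1)
  expect_true(all(g$true_path[, 1] == 10))
  expect_equal(sort(g$true_path[, 2]), 5:40)
  expect_true(all(g$image[g$true_path] < median(g$image)))
})
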