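mk_peaks <- function(times) {
  out <- data.frame(time = times, amplitude = seq_along(times),
                    label = "UNLABELLED", ipu_id = NA_integer_,
                    stringsAsFactors = FALSE)
  class(out) <- c("resp_peaks", "data.frame")
  out
}

test_that("block-relative IPUs shift onto the session clock", {
  ip <- data.frame(onset = c(3.2, 10), offset = c(5.0, 12),
                   speaker = "participant", trial_id = c(1L, 1L))
  same <- ipus_to_session_clock(ip, c(0))
  expect_equal(same$onset, ip$onset)

  shifted <- ipus_to_session_clock(ip, c(120))
  expect_equal(shifted$onset, c(123.2, 130))
  expect_equal(shifted$offset, c(125.0, 132))

  ip2 <- data.frame(onset = c(3, 55), offset = c(5, 65),
                    speaker = "participant", trial_id = c(1L, 1L))
  expect_warning(ipus_to_session_clock(ip2, c(0, 60)), "past the next block")
  expect_error(ipus_to_session_clock(
    data.frame(onset = 1, offset = 2, speaker = "participant",
               trial_id = 3L), c(0)), "matching block onset")
})

test_that("the worked nearest-peak example classifies as expected", {
  cls <- classify_peaks(mk_peaks(c(1, 3, 5)), c(2.9, 5.2))
  expect_equal(cls$peaks$label, c("RESP_MINUS", "RESP_PLUS", "RESP_PLUS"))
  expect_equal(cls$deltas$delta_t, c(0.1, -0.2), tolerance = 1e-12)
  expect_equal(cls$deltas$ipu_onset, c(2.9, 5.2))
})

test_that("with no IPUs every maximum is Resp-", {
  cls <- classify_peaks(mk_peaks(c(1, 2, 3)), numeric(0))
  expect_true(all(cls$peaks$label == "RESP_MINUS"))
  expect_equal(nrow(cls$deltas), 0)
})

test_that("classification matches the exhaustive brute force on random instances", {
  set.seed(99)
  for (i in 1:120) {
    np <- sample(1:20, 1)
    no <- sample(0:10, 1)
    pt <- sort(runif(np, 0, 100))
    on <- runif(no, 0, 100)
    cls <- classify_peaks(mk_peaks(pt), on)
    want <- brute_classify(pt, on)
    expect_identical(cls$peaks$label, want$labels)
    expect_equal(cls$deltas$delta_t, want$delta_t, tolerance = 1e-12)
    # labels partition the peak set
    expect_true(all(cls$peaks$label %in% c("RESP_PLUS", "RESP_MINUS")))
    expect_lte(sum(cls$peaks$label == "RESP_PLUS"), min(np, max(no, np)))
  }
})

test_that("equidistant peaks tie toward the earlier peak", {
  cls <- classify_peaks(mk_peaks(c(1, 3)), 2)
  expect_equal(cls$peaks$label, c("RESP_PLUS", "RESP_MINUS"))
})

test_that("a peak shared by two IPUs is one event but two lag records", {
  cls <- classify_peaks(mk_peaks(c(10, 30)), c(9.9, 10.3))
  expect_equal(sum(cls$peaks$label == "RESP_PLUS"), 1)
  expect_equal(nrow(cls$deltas), 2)
  expect_equal(cls$deltas$peak_time, c(10, 10))
})

test_that("classification is invariant under a global time shift", {
  set.seed(5)
  pt <- sort(runif(15, 0, 60))
  on <- runif(6, 0, 60)
  a <- classify_peaks(mk_peaks(pt), on)
  b <- classify_peaks(mk_peaks(pt + 1000), on + 1000)
  expect_identical(a$peaks$label, b$peaks$label)
  expect_equal(a$deltas$delta_t, b$deltas$delta_t, tolerance = 1e-9)
})

test_that("ground-truth labels are recovered on well-separated synthetic data", {
  ok <- 0; tot <- 0; lag_ok <- 0; lag_tot <- 0
  for (seed in 1:3) {
    ip <- generate_conversation(400, seed = seed)
    r <- suppressMessages(generate_respiration(
      ip, lag_model = lag_model("gaussian", mode = -0.2, spread = 0.07),
      coupled_fraction = 1, seed = seed + 30, duration = 400))
    pk <- detect_peaks(resample_to_ms(r$trace))
    po <- ip$onset[ip$speaker == "participant"]
    cls <- classify_peaks(pk, po)
    # match detected peaks to truth and compare labels
    tt <- r$truth$true_peak_times
    lab <- r$truth$true_labels
    for (j in seq_len(nrow(pk))) {
      i <- which.min(abs(tt - pk$time[j]))
      if (abs(tt[i] - pk$time[j]) < 0.3) {
        tot <- tot + 1
        want <- if (lab[i] == "speech_coupled") "RESP_PLUS" else "RESP_MINUS"
        ok <- ok + (cls$peaks$label[j] == want)
      }
    }
    # matched lags agree with the generated lags
    ids <- r$truth$ipu_id[lab == "speech_coupled"]
    lag_true <- r$truth$true_lags[lab == "speech_coupled"]
    part_ids <- which(ip$speaker == "participant")
    for (m in seq_along(ids)) {
      rec <- which(abs(cls$deltas$ipu_onset - ip$onset[ids[m]]) < 1e-6)
      if (length(rec) == 1) {
        lag_tot <- lag_tot + 1
        lag_ok <- lag_ok + (abs(cls$deltas$delta_t[rec] - lag_true[m]) <= 0.05)
      }
    }
  }
  expect_gte(ok / tot, 0.99)
  expect_gte(lag_ok / lag_tot, 0.99)
})

test_that("GLM event export writes zero-duration resp events that round-trip", {
  pk <- mk_peaks(c(1, 4, 7))
  pk$label <- c("RESP_PLUS", "RESP_MINUS", "RESP_PLUS")
  ip <- data.frame(onset = c(1.2, 3.0), offset = c(2.4, 3.9),
                   speaker = c("participant", "interlocutor"),
                   trial_id = 1L)
  f <- withr::local_tempfile(fileext = ".tsv")
  ev <- export_glm_events(pk, ip, f)
  resp <- grepl("^resp_", ev$trial_type)
  expect_true(all(ev$duration[resp] == 0))
  expect_equal(sum(resp), nrow(pk))
  expect_equal(sum(ev$trial_type == "resp_plus") +
                 sum(ev$trial_type == "resp_minus"), nrow(pk))
  expect_false(is.unsorted(ev$onset))
  back <- read_events(f)
  expect_equal(back$onset, ev$onset, tolerance = 1e-3)
  expect_identical(back$trial_type, ev$trial_type)
})
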