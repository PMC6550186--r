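test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(n_subjects = -3), "n_subjects")
  expect_error(cohort_config(brady_atten = 1.2), "brady_atten")
  expect_error(cohort_config(brady_atten = 0), "brady_atten")
  expect_error(cohort_config(bradykinesia_prev_mean = 1.4), "prevalence")
  expect_error(cohort_config(duration_s = 3), "duration_s")
  expect_error(cohort_config(locations = "ankle"), "locations")
})

test_that("subject draws are deterministic and propensities stay in [0,1]", {
  cfg <- cohort_config(n_subjects = 60, rng_seed = 4)
  s1 <- draw_subject(cfg, 1)
  s2 <- draw_subject(cfg, 1)
  expect_identical(s1, s2)
  for (i in seq_len(60)) {
    s <- draw_subject(cfg, i)
    expect_within(s$propensity_tremor, 0, 1)
    expect_within(s$propensity_bradykinesia, 0, 1)
    expect_within(s$tremor_freq, 4, 6)
  }
  expect_error(draw_subject(cfg, 61), "index")
})

test_that("zero prevalence SD collapses propensities to the mean", {
  cfg <- cohort_config(n_subjects = 5, tremor_prev_sd = 0,
                       tremor_prev_mean = 0.3, rng_seed = 2)
  props <- vapply(1:5, function(i) draw_subject(cfg, i)$propensity_tremor, 0)
  expect_equal(props, rep(0.3, 5))
})

test_that("task signals reject sub-clip durations and respect sensor ranges", {
  cfg <- cohort_config(n_subjects = 2, rng_seed = 1)
  s <- draw_subject(cfg, 1)
  expect_error(
    simulate_task_signal(s, "walking", "functional", duration_s = 3,
                         config = cfg, seed = 1),
    "rejected"
  )
  rec <- simulate_task_signal(s, "walking", "functional",
                              c(bradykinesia = 2, tremor = 3),
                              duration_s = 8, config = cfg, seed = 1)
  expect_equal(nrow(rec$data), floor(8 * 62.5))
  expect_equal(ncol(rec$data), 6)
  expect_true(all(abs(rec$data[, 1:3]) <= 4))
  expect_true(all(abs(rec$data[, 4:6]) <= 1000))
})

test_that("severe tremor dominates the 4-6 Hz band of the gravity-free magnitude", {
  cfg <- cohort_config(n_subjects = 2, tremor_amp = 0.3, rng_seed = 8)
  s <- draw_subject(cfg, 1)
  rec <- simulate_task_signal(s, "finger_to_nose", "clinical",
                              c(bradykinesia = 0, tremor = 4),
                              duration_s = 10, config = cfg, seed = 5)
  mag <- gravity_free_magnitude(rec)
  dom <- dominant_frequency(mag, rec$sampling_rate)
  expect_within(dom, 4, 6)

  # symptom-free signal: no 4-6 Hz line above the baseline floor
  rec0 <- simulate_task_signal(s, "finger_to_nose", "clinical",
                               c(bradykinesia = 0, tremor = 0),
                               duration_s = 10, config = cfg, seed = 5)
  psd <- pdwear:::welch_psd(gravity_free_magnitude(rec0), rec0$sampling_rate)
  band <- psd$freq >= 4 & psd$freq <= 6
  ratio <- max(psd$power[band]) / stats::median(psd$power[psd$freq > 0.25])
  psd_t <- pdwear:::welch_psd(mag, rec$sampling_rate)
  ratio_t <- max(psd_t$power[band]) /
    stats::median(psd_t$power[psd_t$freq > 0.25])
  expect_lt(ratio, ratio_t / 10)
})

test_that("bradykinesia attenuates movement variance monotonically", {
  cfg <- cohort_config(n_subjects = 2, brady_atten = 0.5, rng_seed = 3)
  s <- draw_subject(cfg, 1)
  vs <- vapply(0:4, function(sev) {
    rec <- simulate_task_signal(s, "walking", "functional",
                                c(bradykinesia = sev, tremor = 0),
                                duration_s = 10, config = cfg, seed = 99)
    var(gravity_free_magnitude(rec))
  }, 0)
  expect_true(all(diff(vs) < 0))
  expect_lt(vs[5], vs[1])
})

test_that("cohort sizes follow the study structure", {
  cfg <- cohort_config(n_subjects = 2, tasks = default_tasks()[1:2, ],
                       n_sessions_day1 = 1, include_day2 = FALSE,
                       day2_subjects = 0, duration_s = 6,
                       locations = "hand", rng_seed = 1)
  co <- simulate_cohort(cfg)
  expect_length(co$recordings, 8)   # 2 subj x 2 tasks x 1 session x 2 sides
  expect_equal(nrow(co$annotations), 8)

  # full task battery: 13 x 6 day-1 + 13 day-2 annotations per subject per side
  cfg2 <- cohort_config(n_subjects = 2, n_sessions_day1 = 6,
                        include_day2 = TRUE, day2_subjects = 2, rng_seed = 1)
  co2 <- simulate_cohort(cfg2, signals = FALSE)
  per_side <- subset(co2$annotations,
                     subject == "S001" & side == "left")
  expect_equal(nrow(per_side), 13 * 6 + 13)
})

test_that("identical seed and config give byte-identical written cohorts", {
  cfg <- cohort_config(n_subjects = 2, tasks = default_tasks()[1:2, ],
                       n_sessions_day1 = 1, include_day2 = FALSE,
                       day2_subjects = 0, duration_s = 6,
                       locations = "hand", rng_seed = 77)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  sums1 <- tools::md5sum(file.path(d1, f1))
  sums2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(sums1) == unname(sums2)))

  back <- read_cohort(d1)
  expect_length(back$recordings, 8)
  expect_equal(back$annotations$tremor,
               simulate_cohort(cfg)$annotations$tremor)
})

test_that("tremor clips at severity >= 2 peak in the tremor band", {
  cfg <- cohort_config(n_subjects = 8, tasks = default_tasks()[3:4, ],
                       n_sessions_day1 = 3, include_day2 = FALSE,
                       day2_subjects = 0, duration_s = 10,
                       locations = "hand", rng_seed = 7)
  co <- simulate_cohort(cfg)
  ann <- co$annotations
  key <- paste(ann$subject, ann$day, ann$session, ann$task, ann$side)
  hits <- logical(0)
  for (r in co$recordings) {
    sc <- ann$tremor[match(paste(r$subject_id, r$day, r$session, r$task,
                                 r$side), key)]
    if (sc < 2) next
    for (w in segment_clips(r)) {
      d <- dominant_frequency(gravity_free_magnitude(w, r$sampling_rate),
                              r$sampling_rate)
      hits <- c(hits, d >= 4 && d <= 6)
    }
  }
  expect_gte(length(hits), 50)
  expect_gte(mean(hits), 0.95)
})

test_that("annotated prevalence recovers the configured population means", {
  cfg <- cohort_config(n_subjects = 200, include_day2 = FALSE,
                       day2_subjects = 0, rng_seed = 42)
  ann <- simulate_cohort(cfg, signals = FALSE)$annotations
  expect_lt(abs(mean(ann$tremor > 0) - 0.22), 0.03)
  expect_lt(abs(mean(ann$bradykinesia > 0) - 0.485), 0.03)
  expect_true(all(ann$tremor %in% 0:4))
  expect_true(all(ann$bradykinesia %in% 0:4))
})
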