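test_that("simulated segments hit their target mean norms", {
  params <- synth_params()
  set.seed(71)
  for (category in categories()) {
    sim <- simulate_segment(category, params)
    rec <- new_recording("S01", params$sample_rate_hz, sim$data)
    ms <- mean_speeds(rec, sim$segment)
    fv <- extract_features(rec, sim$segment)
    # empirical HR / FWR equal the drawn targets (rescaling is exact)
    expect_equal(fv$hr, sim$targets$hr, tolerance = 1e-3)
    expect_equal(fv$fwr_active, sim$targets$fwr_active, tolerance = 1e-3)
    expect_equal(fv$fwr_mean, sim$targets$fwr_mean, tolerance = 1e-3)
    expect_equal(unname(ms$wrist[sim$targets$active_hand]),
                 sim$targets$wrist_active, tolerance = 1e-3)
    expect_lte(sim$segment$t_end_s - sim$segment$t_start_s,
               params$max_duration_s)
  }
})

test_that("well-separated draws land in their category's feature region", {
  params <- synth_params()
  set.seed(72)
  for (k in 1:5) {
    uni <- simulate_segment("unimanual", params)
    rec <- new_recording("S01", 100, uni$data)
    expect_gt(extract_features(rec, uni$segment)$hr, 20)

    glob <- simulate_segment("bimanual_both_global", params)
    rec2 <- new_recording("S01", 100, glob$data)
    fv2 <- extract_features(rec2, glob$segment)
    expect_lt(fv2$hr, 4)
    expect_lt(fv2$fwr_mean, 2.2)
  }
})

test_that("zero-noise degenerate ranges reproduce targets exactly", {
  params <- synth_params(hr_range_both = c(2, 2),
                         fwr_range_global = c(1.5, 1.5),
                         wrist_speed_range = c(50, 50),
                         sigma_subject_speed = 0)
  set.seed(73)
  sim <- simulate_segment("bimanual_both_global", params)
  rec <- new_recording("S01", 100, sim$data)
  fv <- extract_features(rec, sim$segment)
  expect_equal(fv$hr, 2, tolerance = 1e-3)
  expect_equal(fv$fwr_mean, 1.5, tolerance = 1e-3)
})

test_that("simulate_dataset is deterministic and writes the documented layout", {
  params <- synth_params()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(d1, 2, 1, params, seed = 7)
  s2 <- simulate_dataset(d2, 2, 1, params, seed = 7)
  expect_setequal(basename(s1$paths),
                  c("recording_S01.csv", "recording_S02.csv",
                    "segments.csv", "manifest.json"))
  for (f in basename(s1$paths)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # 2 subjects x 5 categories x 1 rep = 10 segments
  expect_equal(nrow(read_segments(file.path(d1, "segments.csv"))), 10L)
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_dataset(d3, 2, 1, params, seed = 8)
  expect_false(identical(readLines(file.path(d1, "recording_S01.csv")),
                         readLines(file.path(d3, "recording_S01.csv"))))
})

test_that("the on-disk dialect feeds back through the full reader path", {
  params <- synth_params()
  d <- withr::local_tempdir()
  simulate_dataset(d, 2, 1, params, seed = 9)
  res <- evaluate_external_dataset(d, sample_rate_hz = 100)
  expect_equal(nrow(res$features), 10L)
  expect_s3_class(res$cutoffs, "cutoff_set")
  expect_equal(length(res$cv$folds), 2L)
  expect_error(evaluate_external_dataset(file.path(d, "nope")),
               "no dataset")
})

test_that("learned cutoffs fall inside the generator's inter-class gaps", {
  params <- synth_params()
  study <- simulate_study(4, 3, params, seed = 74)
  ft <- extract_feature_table(study$recordings, study$segments)
  cs <- learn_cutoffs(ft)
  gaps <- cutoff_gaps(study$manifest)
  expect_true(all(gaps$lower_max < gaps$upper_min))  # gaps are nonempty
  learned <- unlist(cs[gaps$boundary])
  expect_true(all(learned > gaps$lower_max - 1e-3 &
                  learned < gaps$upper_min + 1e-3))
})

test_that("invalid generator parameters are rejected", {
  expect_error(synth_params(hr_range_both = c(3, 1)), "increasing")
  expect_error(synth_params(fwr_range_global = c(-1, 2)), "positive")
  expect_error(synth_params(duration_range_s = c(3, 30)),
               "max_duration_s")
  expect_error(simulate_segment("Trimanual", synth_params()), "Trimanual")
})
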