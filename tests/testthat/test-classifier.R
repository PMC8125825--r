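ref_cutoffs <- cutoff_set(20.96, 4.67, 2.61, 2.26)

test_that("classify reproduces documented repetitions from the worked example", {
  expect_equal(classify(56.73, NA, NA, ref_cutoffs), "unimanual")
  expect_equal(classify(27.72, NA, NA, ref_cutoffs), "unimanual")
  expect_equal(classify(1.51, NA, 1.70, ref_cutoffs),
               "bimanual_both_global")
  expect_equal(classify(2.80, NA, 2.97, ref_cutoffs),
               "bimanual_both_finger")
  expect_equal(classify(1.0, NA, 1.0, ref_cutoffs),
               "bimanual_both_global")
  expect_equal(classify(7.63, 1.72, NA, ref_cutoffs),
               "bimanual_stab_global")
  expect_equal(classify(27.0, 2.80, NA, cutoff_set(30, 4.67, 2.61, 2.26)),
               "bimanual_stab_finger")
})

test_that("classify matches a hand-written truth table on an exhaustive grid", {
  cs <- cutoff_set(20, 5, 2.5, 2.2)
  truth <- function(hr, fwr_a, fwr_m) {
    if (hr > 20) return("unimanual")
    if (hr > 5) {
      if (fwr_a > 2.5) "bimanual_stab_finger" else "bimanual_stab_global"
    } else {
      if (fwr_m > 2.2) "bimanual_both_finger" else "bimanual_both_global"
    }
  }
  hr_grid <- c(0.5, 1, 3, 4.99, 5, 5.01, 10, 19.99, 20, 20.01, 50, Inf)
  fwr_grid <- c(0.1, 1, 2.19, 2.2, 2.21, 2.5, 2.51, 4, Inf)
  for (hr in hr_grid) {
    for (fa in fwr_grid) {
      for (fm in fwr_grid) {
        expect_equal(classify(hr, fa, fm, cs), truth(hr, fa, fm),
                     info = sprintf("hr=%g fa=%g fm=%g", hr, fa, fm))
      }
    }
  }
})

test_that("classify is monotone in hr toward unimanual", {
  cs <- cutoff_set(20, 5, 2.5, 2.2)
  rank_of <- c(bimanual_both_global = 1, bimanual_both_finger = 1,
               bimanual_stab_global = 2, bimanual_stab_finger = 2,
               unimanual = 3)
  for (fwr in c(1, 2.4, 3)) {
    hrs <- c(1, 2, 4, 6, 15, 19, 21, 40, 100)
    preds <- classify(hrs, rep(fwr, 9), rep(fwr, 9), cs)
    expect_true(all(diff(rank_of[preds]) >= 0))
  }
})

test_that("evaluate reproduces the worked example's green/red accounting", {
  ev <- evaluate(example_features(), example_cutoffs())
  aa <- ev$activity_accuracy
  get <- function(act) aa[aa$activity == act, ]

  spoon <- get("Using a spoon")
  expect_equal(spoon$step1, 1)
  expect_true(is.na(spoon$step2) && is.na(spoon$step3))
  expect_equal(spoon$overall, 1)

  pan <- get("Lifting a full pan")
  expect_equal(pan$step1, 1)
  expect_equal(pan$step2, 1)
  expect_equal(pan$step3, 1)
  expect_equal(pan$overall, 1)

  pr <- ev$per_repetition
  jar5 <- pr[pr$activity == "Opening a screw-topped jar" &
               pr$repetition == 5, ]
  expect_true(jar5$step1 && jar5$step2)
  expect_false(jar5$step3)          # FWR 2.43 > 2.26
  expect_false(jar5$overall_correct)

  can2 <- pr[pr$activity == "Opening a can with a can opener" &
               pr$repetition == 2, ]
  expect_false(can2$step3)          # FWR 2.67 > 2.61
  expect_equal(get("Opening a can with a can opener")$step3, 0.8)
})

test_that("criterion accounting agrees with routing when the tree is consistent", {
  # on repetitions whose true category the tree also reaches, overall
  # correctness per criteria equals predicted == true
  ev <- evaluate(example_features(), example_cutoffs())
  pr <- ev$per_repetition
  both_rows <- pr$true_category %in% c("bimanual_both_finger",
                                       "bimanual_both_global")
  expect_equal(pr$overall_correct[both_rows],
               (pr$predicted == pr$true_category)[both_rows])
})

test_that("an all-correct toy table evaluates to 100% everywhere", {
  cs <- cutoff_set(20, 5, 2.5, 2.2)
  ft <- data.frame(
    participant_id = "A", activity = categories(), repetition = 1L,
    true_category = categories(),
    hr = c(50, 10, 10, 2, 2),
    fwr_active = c(1, 3, 1.5, 3, 1.5),
    fwr_mean = c(1, 3, 1.5, 3, 1.5))
  ev <- evaluate(ft, cs)
  expect_equal(ev$overall_accuracy, 1)
  expect_true(all(ev$per_repetition$predicted == ft$true_category))
  expect_equal(sum(diag(ev$confusion)), 5L)
})

test_that("loso_cv partitions repetitions and matches fold counts", {
  set.seed(61)
  params <- synth_params()
  study <- simulate_study(3, 2, params, seed = 62)
  ft <- extract_feature_table(study$recordings, study$segments)
  cv <- loso_cv(ft)
  expect_length(cv$folds, 3L)
  # every repetition tested exactly once
  key <- function(df) paste(df$participant_id, df$activity, df$repetition)
  expect_setequal(key(cv$per_repetition), key(ft))
  expect_equal(nrow(cv$per_repetition), nrow(ft))
  expect_error(loso_cv(ft[ft$participant_id == "S01", ]), ">= 2")
})

test_that("identical participants yield identical fold cutoffs", {
  set.seed(63)
  base <- data.frame(
    participant_id = "A",
    activity = rep(categories(), each = 4),
    repetition = rep(1:4, times = 5),
    true_category = rep(categories(), each = 4),
    hr = rep(c(50, 10, 10, 2, 2), each = 4) * runif(20, 0.9, 1.1),
    fwr_active = rep(c(1.5, 3.5, 1.5, 3.5, 1.5), each = 4),
    fwr_mean = rep(c(1.5, 3.5, 1.5, 3.5, 1.5), each = 4))
  twin <- base
  twin$participant_id <- "B"
  cv <- loso_cv(rbind(base, twin))
  expect_equal(cv$folds[[1]]$cutoffs[1:4], cv$folds[[2]]$cutoffs[1:4])
})

test_that("a training split missing a category names the failing fold", {
  ft <- data.frame(
    participant_id = rep(c("A", "B"), each = 5),
    activity = rep(categories(), 2),
    repetition = 1L,
    true_category = rep(categories(), 2),
    hr = rep(c(50, 10, 10, 2, 2), 2),
    fwr_active = rep(c(1.5, 3.5, 1.5, 3.5, 1.5), 2),
    fwr_mean = rep(c(1.5, 3.5, 1.5, 3.5, 1.5), 2))
  # remove B's unimanual rows: the fold holding out A cannot train step 1
  ft <- ft[!(ft$participant_id == "B" & ft$true_category == "unimanual"), ]
  expect_error(loso_cv(ft), "participant A")
})
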