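test_that("roc_curve handles separable and non-separable toy cases", {
  r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  perfect <- r$sensitivity == 1 & r$one_minus_specificity == 0
  expect_true(any(perfect))
  expect_equal(auc(r), 1)
  expect_equal(optimal_cutoff(r), 2.5)  # midpoint convention

  r2 <- roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_false(any(r2$sensitivity == 1 & r2$one_minus_specificity == 0))
  # sensitivity non-increasing in threshold
  expect_true(all(diff(r2$sensitivity) <= 0))
  expect_true(all(r2$sensitivity >= 0 & r2$sensitivity <= 1))

  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "degenerate")
  expect_error(roc_curve(1:3, c(0, 1)), "equal length")
})

test_that("identical score distributions give AUC 1/2", {
  r <- roc_curve(rep(c(1, 2), 10), rep(c(0, 1), each = 10))
  expect_equal(auc(r), 0.5)
})

test_that("degenerate all-equal scores return a sentinel with a warning", {
  r <- roc_curve(rep(3, 6), c(0, 0, 0, 1, 1, 1))
  expect_warning(thr <- optimal_cutoff(r), "degenerate")
  expect_false(is.finite(thr))
})

test_that("roc_curve, auc and optimal_cutoff match brute-force oracles", {
  set.seed(51)
  for (k in 1:120) {
    n <- sample(8:200, 1)
    scores <- if (k %% 3 == 0) sample(1:12, n, replace = TRUE)  # many ties
              else round(rnorm(n, mean = 0, sd = 2), 2)
    labels <- integer(n)
    labels[sample(n, sample(1:(n - 1), 1))] <- 1L
    shift <- runif(1, 0, 3)  # informative scores, varying overlap
    scores <- scores + shift * labels
    r <- roc_curve(scores, labels)

    # every curve point's rates equal direct counting at its threshold
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    expect_equal(r$sensitivity,
                 vapply(r$threshold, function(t) mean(pos > t), numeric(1)))
    expect_equal(r$one_minus_specificity,
                 vapply(r$threshold, function(t) mean(neg > t), numeric(1)))

    # AUC equals the O(n^2) Mann-Whitney pairwise count exactly
    expect_equal(auc(r), auc_oracle_mw(scores, labels), tolerance = 1e-12)

    # the chosen cutoff attains the exhaustive-sweep maximum of Youden's J
    sweep <- roc_oracle_sweep(scores, labels)
    thr <- optimal_cutoff(r)
    j_at <- mean(pos > thr) + mean(neg <= thr) - 1
    expect_equal(j_at, max(sweep$j), tolerance = 1e-12)
  }
})

test_that("auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  for (k in 1:20) {
    n <- sample(20:120, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + 1.2 * labels
    r <- roc_curve(scores, labels)
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<")))
    expect_equal(auc(r), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(53)
  labels <- rbinom(80, 1, 0.5)
  labels[1:2] <- c(0L, 1L)
  scores <- rexp(80) + labels
  a0 <- auc(roc_curve(scores, labels))
  expect_equal(auc(roc_curve(log(scores), labels)), a0, tolerance = 1e-12)
  expect_equal(auc(roc_curve(scores^3, labels)), a0, tolerance = 1e-12)
  expect_equal(auc(roc_curve(100 * scores - 7, labels)), a0,
               tolerance = 1e-12)
})

test_that("learn_cutoffs separates well-separated synthetic feature draws", {
  set.seed(54)
  n_per <- 30L
  make_rows <- function(category, hr, fwr) {
    data.frame(participant_id = "X", activity = category,
               repetition = seq_along(hr), true_category = category,
               hr = hr, fwr_active = fwr, fwr_mean = fwr)
  }
  ft <- rbind(
    make_rows("unimanual", runif(n_per, 45, 55), runif(n_per, 1, 2)),
    make_rows("bimanual_stab_finger", runif(n_per, 8, 12),
              runif(n_per, 3, 5)),
    make_rows("bimanual_stab_global", runif(n_per, 8, 12),
              runif(n_per, 1.2, 2)),
    make_rows("bimanual_both_finger", runif(n_per, 1.5, 2.5),
              runif(n_per, 3, 5)),
    make_rows("bimanual_both_global", runif(n_per, 1.5, 2.5),
              runif(n_per, 1.2, 2)))
  cs <- learn_cutoffs(ft)
  expect_gt(cs$hr_unimanual, 15)
  expect_lt(cs$hr_unimanual, 45)
  expect_gt(cs$hr_stabilizing, 2.5)
  expect_lt(cs$hr_stabilizing, 8)
  expect_gt(cs$fwr_stab, 2)
  expect_lt(cs$fwr_stab, 3)
  expect_true(all(unlist(cs$auc) == 1))
  expect_gt(cs$hr_unimanual, cs$hr_stabilizing)

  # perfectly separated training data is classified without error
  pred <- classify(ft$hr, ft$fwr_active, ft$fwr_mean, cs)
  expect_equal(pred, ft$true_category)

  # a category missing from a nested subset is a named error
  expect_error(
    learn_cutoffs(ft[ft$true_category != "bimanual_stab_finger", ]),
    "fwr_stab")
})

test_that("cutoff sets round-trip through their JSON form", {
  cs <- cutoff_set(20.96, 4.67, 2.61, 2.26,
                   auc = list(hr_unimanual = 0.99))
  path <- withr::local_tempfile(fileext = ".json")
  write_cutoffs(cs, path)
  back <- read_cutoffs(path)
  expect_equal(back$hr_unimanual, cs$hr_unimanual)
  expect_equal(back$fwr_both, cs$fwr_both)
  expect_warning(cutoff_set(2, 5, 1, 1), "expected to exceed")
  expect_error(cutoff_set(-1, 5, 1, 1), "positive")
})
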