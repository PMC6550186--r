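# A small synthetic feature dataset where class separation is controlled
# directly; avoids simulation in pure evaluation tests.
make_feature_dataset <- function(n_subjects = 5, clips = 20, sep = 2,
                                 seed = 1, all_negative = integer(0)) {
  set.seed(seed)
  meta <- data.frame(
    subject = rep(sprintf("S%02d", seq_len(n_subjects)), each = clips),
    day = 1L, session = 1L, task = "t", task_group = "clinical",
    stringsAsFactors = FALSE
  )
  n <- nrow(meta)
  y <- rbinom(n, 1, 0.4)
  for (s in all_negative) y[meta$subject == sprintf("S%02d", s)] <- 0L
  # guarantee both classes for the rest
  for (s in setdiff(seq_len(n_subjects), all_negative)) {
    i <- which(meta$subject == sprintf("S%02d", s))
    y[i[1]] <- 0L
    y[i[2]] <- 1L
  }
  x <- cbind(f1 = rnorm(n) + sep * y, f2 = rnorm(n))
  meta$label_tremor <- y
  structure(list(x = x, meta = meta, symptom = "tremor"),
            class = "pd_dataset")
}

test_that("AUROC equals the pair-ordering statistic", {
  expect_equal(compute_auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auroc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(compute_auroc(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 1, 1)), 0.0)
  expect_true(is.na(compute_auroc(c(0.2, 0.4), c(1, 1))))

  set.seed(7)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(1:3, 1))     # coarse scores force ties
    expect_lt(abs(compute_auroc(s, y) - auroc_oracle(s, y)), 1e-12)
  }
})

test_that("paired comparisons handle identical, shifted and degenerate input", {
  a <- c(S1 = 0.7, S2 = 0.8, S3 = 0.9, S4 = 0.6)
  same <- paired_comparison(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(1)
  base <- runif(10, 0.5, 0.8)
  shift <- paired_comparison(base + 0.1, base)
  expect_lt(shift$p, 1e-6)
  expect_equal(shift$mean_diff, 0.1)

  exact <- paired_comparison(c(0.7, 0.8, 0.9), c(0.6, 0.7, 0.8))
  expect_true(is.infinite(exact$t) && exact$t > 0)
  expect_equal(exact$mean_diff, 0.1)

  few <- paired_comparison(c(0.7, 0.8), c(0.6, 0.7))
  expect_true(is.na(few$t) && is.na(few$p))

  # pairwise dropping by subject name
  b <- c(S1 = 0.6, S2 = 0.7, S3 = 0.8, S9 = 0.1)
  pc <- paired_comparison(a, b)
  expect_equal(pc$n, 3)
})

test_that("leave-one-subject-out averages per-subject AUROCs", {
  ds <- make_feature_dataset(n_subjects = 3, sep = 4)
  res <- loso_evaluate(ds, "rf", seed = 1)
  expect_s3_class(res, "eval_result")
  expect_equal(nrow(res$per_subject), 3)
  expect_equal(res$mean_auroc, mean(res$per_subject$auroc))
  expect_true(res$ci_lower <= res$mean_auroc &&
                res$mean_auroc <= res$ci_upper)
  expect_true(all(res$per_subject$auroc >= 0 & res$per_subject$auroc <= 1))
})

test_that("subjects without both classes are excluded and reported", {
  ds <- make_feature_dataset(n_subjects = 5, sep = 4, all_negative = 3)
  res <- loso_evaluate(ds, "rf", seed = 1)
  expect_equal(res$n_subjects_evaluated, 4)
  expect_equal(res$excluded$subject, "S03")
  expect_match(res$excluded$reason, "single-class")
  expect_false("S03" %in% res$per_subject$subject)
})

test_that("evaluation aborts on too few subjects or single-class training", {
  ds <- make_feature_dataset(n_subjects = 2)
  expect_error(loso_evaluate(ds, "rf"), ">= 3 subjects")
  ds2 <- make_feature_dataset(n_subjects = 3, all_negative = c(1, 2))
  expect_error(loso_evaluate(ds2, "rf"), "single class")
  # a stratum with fewer than 2 evaluable subjects is omitted with a warning
  ds3 <- make_feature_dataset(n_subjects = 4, sep = 4, all_negative = c(1, 2))
  sets <- list(all = rep(TRUE, nrow(ds3$meta)),
               none = ds3$meta$subject == "S01")
  expect_warning(res <- loso_evaluate(ds3, "rf", test_sets = sets),
                 "omitted")
  expect_named(res, "all")
})

test_that("results round-trip losslessly through JSON", {
  ds <- make_feature_dataset(n_subjects = 4, sep = 2, seed = 9)
  res <- loso_evaluate(ds, "rf", seed = 3)
  f <- tempfile(fileext = ".json")
  write_eval_results(res, f)
  back <- read_eval_results(f)
  expect_s3_class(back, "eval_result")
  expect_identical(back$mean_auroc, res$mean_auroc)
  expect_identical(back$per_subject$auroc, res$per_subject$auroc)
  expect_identical(back$per_subject$subject, res$per_subject$subject)
  expect_identical(back$ci_lower, res$ci_lower)
})

test_that("learning-curve subset draws are reproducible and guarded", {
  co <- fixture("lc_cohort", function() {
    simulate_cohort(cohort_config(
      n_subjects = 6, tasks = default_tasks()[c(1, 3, 8), ],
      n_sessions_day1 = 2, include_day2 = FALSE, day2_subjects = 0,
      duration_s = 10, locations = "hand", rng_seed = 13
    ))
  })
  lc1 <- learning_curve_experiment(co, "bradykinesia", sizes = c(3),
                                   n_repeats = 3, seed = 5)
  lc2 <- learning_curve_experiment(co, "bradykinesia", sizes = c(3),
                                   n_repeats = 3, seed = 5)
  expect_identical(lc1$per_repeat, lc2$per_repeat)
  expect_warning(
    learning_curve_experiment(co, "bradykinesia", sizes = c(3, 10),
                              n_repeats = 2, seed = 5),
    "skipped"
  )
})
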