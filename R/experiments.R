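# The four evaluation experiments: sensor combinations, activity groups,
# training-subject learning curve, and session/day transfer. All use
# leave-one-subject-out AUROC with identical subject splits within an
# experiment, and paired t tests between conditions.

# Assemble -> filter -> featurize (rf) or stack to an array (cnn).
prepare_dataset <- function(cohort, symptom, sensor_set, family) {
  cs <- assemble_dataset(cohort, sensor_set)
  cs <- filter_clips(cs, symptom)
  if (family == "rf") {
    extract_features(cs)
  } else {
    structure(list(x = clips_to_array(cs), meta = cs$meta, symptom = symptom,
                   fs = cs$fs), class = "pd_dataset")
  }
}

new_experiment <- function(name, symptom, family, results, comparisons,
                           extra = NULL) {
  structure(c(list(experiment = name, symptom = symptom, family = family,
                   results = results, comparisons = comparisons), extra),
            class = "pd_experiment")
}

#' @export
print.pd_experiment <- function(x, ...) {
  cat(sprintf("<pd_experiment> %s (%s, %s)\n", x$experiment, x$symptom,
              x$family))
  for (r in x$results) {
    if (inherits(r, "eval_result")) print(r)
  }
  if (is.data.frame(x$comparisons) && nrow(x$comparisons) > 0) {
    cat("comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

subject_aurocs <- function(res) {
  stats::setNames(res$per_subject$auroc, res$per_subject$subject)
}

#' Sensor-combination experiment
#'
#' Leave-one-subject-out AUROC for models trained on a single hand sensor
#' (side with dominant symptoms), both hands, or the unilateral
#' hand + forearm + thigh combination, with paired t tests of each multi-
#' sensor condition against the single hand.
#'
#' @param cohort a simulated cohort containing the required sensor locations.
#' @param symptom `"bradykinesia"` or `"tremor"`.
#' @param family model family, `"rf"` or `"cnn"`.
#' @param seed master seed shared by all three conditions, so subject splits
#'   are identical (LOSO folds are defined by subjects).
#' @param n_trees,cnn model hyperparameters.
#' @return A `pd_experiment` with one `eval_result` per available condition
#'   and a comparison table.
#' @export
sensor_combination_experiment <- function(cohort, symptom, family = "rf",
                                          seed = 1L, n_trees = 50,
                                          cnn = cnn_spec()) {
  conds <- c("hand", "hand_bi", "combo")
  locs <- unique(vapply(cohort$recordings, `[[`, "", "location"))
  needed <- list(hand = "hand", hand_bi = "hand",
                 combo = c("hand", "forearm", "thigh"))
  results <- list()
  for (cond in conds) {
    if (!all(needed[[cond]] %in% locs)) {
      warning("condition '", cond, "' skipped: sensor location(s) missing",
              call. = FALSE)
      next
    }
    ds <- prepare_dataset(cohort, symptom, cond, family)
    results[[cond]] <- loso_evaluate(ds, family, seed = seed,
                                     condition = cond, n_trees = n_trees,
                                     cnn = cnn)
  }
  comparisons <- NULL
  if ("hand" %in% names(results)) {
    ref <- subject_aurocs(results$hand)
    rows <- lapply(setdiff(names(results), "hand"), function(cond) {
      pc <- paired_comparison(subject_aurocs(results[[cond]]), ref)
      data.frame(a = cond, b = "hand", t = pc$t, p = pc$p,
                 mean_diff = pc$mean_diff, n = pc$n)
    })
    comparisons <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  new_experiment("sensor_combination", symptom, family, results, comparisons)
}

#' Activity-group experiment
#'
#' Models are trained on clips from all tasks; test clips of each held-out
#' subject are stratified by task group, yielding one `eval_result` per group
#' (groups form a partition of the test clips), with paired t tests of every
#' group against the clinical tasks.
#'
#' @inheritParams sensor_combination_experiment
#' @param sensor_set sensor set used (default `"hand"`).
#' @return A `pd_experiment`.
#' @export
activity_group_experiment <- function(cohort, symptom, family = "rf",
                                      seed = 1L, sensor_set = "hand",
                                      n_trees = 50, cnn = cnn_spec()) {
  ds <- prepare_dataset(cohort, symptom, sensor_set, family)
  groups <- sort(unique(ds$meta$task_group))
  test_sets <- lapply(groups, function(g) ds$meta$task_group == g)
  names(test_sets) <- groups
  results <- loso_evaluate(ds, family, seed = seed, test_sets = test_sets,
                           condition = "activity_group", n_trees = n_trees,
                           cnn = cnn)
  comparisons <- NULL
  if ("clinical" %in% names(results)) {
    ref <- subject_aurocs(results$clinical)
    rows <- lapply(setdiff(names(results), "clinical"), function(g) {
      pc <- paired_comparison(subject_aurocs(results[[g]]), ref)
      data.frame(a = g, b = "clinical", t = pc$t, p = pc$p,
                 mean_diff = pc$mean_diff, n = pc$n)
    })
    comparisons <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  new_experiment("activity_group", symptom, family, results, comparisons)
}

#' Training-subject learning curve
#'
#' For each training-set size, repeatedly draws a random subset of subjects,
#' trains a population model on their clips, and evaluates AUROC on every
#' left-out subject. The expected AUROC per size is the mean over
#' repeats x subjects with a t-based 95% CI; per-repeat means are kept for
#' paired comparisons between sizes.
#'
#' @inheritParams activity_group_experiment
#' @param sizes training-set sizes (default `3:(n_subjects - 1)`); sizes not
#'   below the number of subjects are skipped.
#' @param n_repeats random subsets drawn per size.
#' @return A `pd_experiment`; `results` has one `eval_result` per size (the
#'   per-unit table has one row per repeat x evaluable subject) and
#'   `per_repeat` is a data frame of per-repeat mean AUROCs.
#' @export
learning_curve_experiment <- function(cohort, symptom, sizes = NULL,
                                      n_repeats = 10, family = "rf",
                                      seed = 1L, sensor_set = "hand",
                                      n_trees = 50, cnn = cnn_spec()) {
  ds0 <- prepare_dataset(cohort, symptom, sensor_set, family)
  ds <- as_eval_dataset(ds0)
  subjects <- sort(unique(ds$meta$subject))
  n_sub <- length(subjects)
  sizes <- sizes %||% seq.int(3L, n_sub - 1L)
  drop <- sizes >= n_sub | sizes < 1
  if (any(drop)) {
    warning("size(s) ", paste(sizes[drop], collapse = ", "),
            " skipped (must be < number of subjects)", call. = FALSE)
    sizes <- sizes[!drop]
  }
  stopifnot(length(sizes) > 0)

  per_rows <- list()
  rep_rows <- list()
  for (r in seq_len(n_repeats)) {
    for (szi in seq_along(sizes)) {
      sz <- sizes[szi]
      # deterministic subset draw; redrawn (bounded) if the training pool
      # happens to contain a single class
      tr_sub <- NULL
      for (try in 1:25) {
        cand <- with_seed(derive_seed(seed, 7L, r, szi, try),
                          sample(subjects, sz))
        rows <- ds$meta$subject %in% cand
        if (length(unique(ds$y[rows])) == 2) {
          tr_sub <- cand
          break
        }
      }
      if (is.null(tr_sub)) next
      tr <- ds$meta$subject %in% tr_sub
      model <- fit_model(ds, tr, family, derive_seed(seed, 8L, r, szi),
                         n_trees, cnn)
      held <- setdiff(subjects, tr_sub)
      aucs <- c()
      for (s in held) {
        te <- which(ds$meta$subject == s)
        y_te <- ds$y[te]
        if (length(unique(y_te)) < 2) next
        auc <- compute_auroc(score_model(model, ds, te), y_te)
        per_rows[[length(per_rows) + 1]] <- data.frame(
          size = sz, repeat_idx = r, subject = s, auroc = auc,
          stringsAsFactors = FALSE)
        aucs <- c(aucs, auc)
      }
      if (length(aucs)) {
        rep_rows[[length(rep_rows) + 1]] <- data.frame(
          size = sz, repeat_idx = r, mean_auroc = mean(aucs),
          n_subjects = length(aucs))
      }
    }
  }
  if (length(per_rows) == 0) {
    stop("no evaluable left-out subjects in any repeat; cohort too small or ",
         "labels too degenerate for a learning curve", call. = FALSE)
  }
  per <- do.call(rbind, per_rows)
  per_repeat <- do.call(rbind, rep_rows)

  results <- list()
  for (sz in sizes) {
    sub <- per[per$size == sz, ]
    if (nrow(sub) < 2) next
    ps <- data.frame(subject = paste0("r", sub$repeat_idx, ":", sub$subject),
                     auroc = sub$auroc, n_pos = NA_integer_,
                     n_neg = NA_integer_, stringsAsFactors = FALSE)
    results[[as.character(sz)]] <- new_eval_result(
      sprintf("n_train_subjects=%d", sz), ps)
  }

  comparisons <- NULL
  if (length(sizes) >= 2) {
    s_lo <- as.character(min(sizes))
    rows <- lapply(setdiff(names(results), s_lo), function(s_hi) {
      a <- per_repeat[per_repeat$size == as.integer(s_hi), ]
      b <- per_repeat[per_repeat$size == as.integer(s_lo), ]
      m <- merge(a, b, by = "repeat_idx")
      pc <- paired_comparison(m$mean_auroc.x, m$mean_auroc.y,
                              alternative = "greater")
      data.frame(a = paste0("size_", s_hi), b = paste0("size_", s_lo),
                 t = pc$t, p_one_sided = pc$p, mean_diff = pc$mean_diff,
                 n = pc$n)
    })
    comparisons <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  new_experiment("learning_curve", symptom, family, results, comparisons,
                 extra = list(per_repeat = per_repeat, sizes = sizes,
                              n_repeats = n_repeats))
}

#' Session / day-transfer experiment
#'
#' Leave-one-subject-out models trained on day-1 data restricted to the first
#' session versus all day-1 sessions, each tested on the held-out subject's
#' day-1 clips and (when available) day-2 clips, with paired t tests of the
#' per-subject AUROC change from adding sessions.
#'
#' @inheritParams activity_group_experiment
#' @return A `pd_experiment`; `results` is a nested list
#'   `train condition -> test day -> eval_result`, and `train_sizes` records
#'   the training-pool clip counts (all-sessions is a strict superset of
#'   single-session).
#' @export
session_experiment <- function(cohort, symptom, family = "rf", seed = 1L,
                               sensor_set = "hand", n_trees = 50,
                               cnn = cnn_spec()) {
  ds0 <- prepare_dataset(cohort, symptom, sensor_set, family)
  meta <- ds0$meta
  train_conds <- list(
    single_session = meta$day == 1 & meta$session == 1,
    all_sessions = meta$day == 1
  )
  test_sets <- list(day1 = meta$day == 1)
  if (any(meta$day == 2)) {
    test_sets$day2 <- meta$day == 2
  } else {
    warning("no day-2 clips in cohort; day-2 arm skipped", call. = FALSE)
  }
  results <- list()
  for (nm in names(train_conds)) {
    results[[nm]] <- loso_evaluate(ds0, family, seed = seed,
                                   train_rows = train_conds[[nm]],
                                   test_sets = test_sets, condition = nm,
                                   n_trees = n_trees, cnn = cnn)
  }
  rows <- list()
  for (day in names(test_sets)) {
    if (is.null(results$all_sessions[[day]]) ||
        is.null(results$single_session[[day]])) next
    pc <- paired_comparison(subject_aurocs(results$all_sessions[[day]]),
                            subject_aurocs(results$single_session[[day]]))
    rows[[length(rows) + 1]] <- data.frame(
      a = paste0("all_sessions:", day), b = paste0("single_session:", day),
      t = pc$t, p = pc$p, mean_diff = pc$mean_diff, n = pc$n)
  }
  new_experiment("session_transfer", symptom, family, results,
                 if (length(rows)) do.call(rbind, rows) else NULL,
                 extra = list(train_sizes = vapply(train_conds, sum, 0L)))
}
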