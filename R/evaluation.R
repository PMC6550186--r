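# Evaluation: AUROC, leave-one-subject-out cross-validation, paired
# comparisons, and serializable results.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) score pairs ordered correctly, ties counted one half.
#'
#' @param scores numeric classifier scores (higher = more symptom-like).
#' @param labels binary labels (0/1) of the same length.
#' @return AUROC in `[0, 1]`; `NA` when only one class is present (the caller
#'   must exclude such sets).
#' @export
compute_auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired comparison of per-subject metrics
#'
#' Paired t test on the differences `a - b`; subjects missing in either arm
#' are dropped pairwise (vectors may be named by subject). Zero-variance
#' differences are handled in closed form (t of 0 or +-Inf).
#'
#' @param a,b numeric vectors of per-subject AUROCs, optionally named by
#'   subject.
#' @param alternative `"two.sided"` (default), `"greater"` (a > b) or
#'   `"less"`.
#' @return List with `t`, `df`, `p`, `mean_diff` (mean of a - b) and `n`
#'   pairs; all `NA` when fewer than 3 pairs remain.
#' @export
paired_comparison <- function(a, b, alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]
    b <- b[common]
  } else {
    stopifnot(length(a) == length(b))
  }
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]
  b <- b[keep]
  n <- length(a)
  if (n < 3) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_diff = if (n > 0) mean(a - b) else NA_real_, n = n))
  }
  d <- a - b
  md <- mean(d)
  sdd <- sd(d)
  if (sdd < 1e-15) {
    tstat <- if (abs(md) < 1e-15) 0 else sign(md) * Inf
  } else {
    tstat <- md / (sdd / sqrt(n))
  }
  p <- switch(alternative,
    two.sided = if (is.infinite(tstat)) 0 else if (tstat == 0 && sdd < 1e-15) 1
      else 2 * pt(-abs(tstat), n - 1),
    greater = if (is.infinite(tstat)) as.numeric(tstat < 0) else
      pt(tstat, n - 1, lower.tail = FALSE),
    less = if (is.infinite(tstat)) as.numeric(tstat > 0) else
      pt(tstat, n - 1)
  )
  list(t = tstat, df = n - 1, p = p, mean_diff = md, n = n)
}

# Aggregate per-unit AUROCs into a classed result with a t-based 95% CI.
new_eval_result <- function(condition, per_subject, excluded = NULL) {
  vals <- per_subject$auroc
  n <- length(vals)
  m <- mean(vals)
  ci <- if (n >= 2) {
    hw <- qt(0.975, n - 1) * sd(vals) / sqrt(n)
    c(m - hw, m + hw)
  } else {
    c(m, m)
  }
  structure(list(condition = condition, per_subject = per_subject,
                 mean_auroc = m, ci_lower = ci[1], ci_upper = ci[2],
                 n_subjects_evaluated = n,
                 excluded = excluded %||% data.frame(subject = character(0),
                                                     reason = character(0))),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: mean AUROC %.3f (95%% CI %.3f-%.3f), n = %d",
              x$condition, x$mean_auroc, x$ci_lower, x$ci_upper,
              x$n_subjects_evaluated))
  if (nrow(x$excluded) > 0) {
    cat(sprintf(" | %d excluded", nrow(x$excluded)))
  }
  cat("\n")
  invisible(x)
}

# Fit one model for the given training rows; dispatches on family.
fit_model <- function(dataset, rows, family, seed, n_trees = 50,
                      spec = NULL) {
  if (family == "rf") {
    pd_rf(dataset$x[rows, , drop = FALSE], dataset$y[rows],
          n_trees = n_trees, seed = seed)
  } else {
    sp <- spec %||% cnn_spec()
    sp$seed <- seed
    pd_cnn(dataset$x[rows, , , drop = FALSE], dataset$y[rows], sp)
  }
}

score_model <- function(model, dataset, rows) {
  if (inherits(model, "pd_rf")) {
    predict(model, dataset$x[rows, , drop = FALSE])
  } else {
    predict(model, dataset$x[rows, , , drop = FALSE])
  }
}

# Internal canonical form: list(x, y, meta) with y the active binary label.
as_eval_dataset <- function(dataset, symptom = NULL) {
  symptom <- symptom %||% dataset$symptom
  lab <- paste0("label_", symptom)
  stopifnot(lab %in% names(dataset$meta))
  list(x = dataset$x, y = dataset$meta[[lab]], meta = dataset$meta,
       symptom = symptom)
}

#' Leave-one-subject-out evaluation
#'
#' For each subject, a population model is trained on all other subjects'
#' clips and scored on the held-out subject; per-subject AUROCs are averaged
#' with a t-based 95% confidence interval. Subjects whose test labels contain
#' a single class (e.g. no tremor manifestation at all) are excluded from
#' that condition and reported.
#'
#' @param dataset a `pd_dataset` from [extract_features()] (for
#'   `family = "rf"`) or a list with a clip array `x` and `meta` (for
#'   `family = "cnn"`; see [clips_to_array()]), plus `symptom`.
#' @param family `"rf"` or `"cnn"`.
#' @param seed integer master seed (per-fold seeds are derived from it).
#' @param train_rows optional logical vector restricting the training pool
#'   (e.g. to day-1 session-1 clips).
#' @param test_sets optional named list of logical vectors defining test
#'   strata (e.g. task groups); default: all clips of the held-out subject.
#' @param condition label stored in the result.
#' @param n_trees random-forest size.
#' @param cnn convolutional spec used when `family = "cnn"`.
#' @return An `eval_result`, or a named list of them when several `test_sets`
#'   are given (strata with fewer than 2 evaluable subjects are omitted with
#'   a warning).
#' @export
loso_evaluate <- function(dataset, family = c("rf", "cnn"), seed = 1L,
                          train_rows = NULL, test_sets = NULL,
                          condition = "all", n_trees = 50,
                          cnn = cnn_spec()) {
  family <- match.arg(family)
  ds <- as_eval_dataset(dataset)
  n <- length(ds$y)
  subjects <- sort(unique(ds$meta$subject))
  if (length(subjects) < 3) {
    stop("leave-one-subject-out evaluation requires >= 3 subjects",
         call. = FALSE)
  }
  single <- is.null(test_sets)
  if (single) test_sets <- list(all = rep(TRUE, n))
  train_rows <- train_rows %||% rep(TRUE, n)

  per <- lapply(test_sets, function(s) list())
  exc <- lapply(test_sets, function(s) list())
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    tr <- train_rows & ds$meta$subject != s
    if (length(unique(ds$y[tr])) < 2) {
      stop("training pool has a single class after holding out subject ", s,
           call. = FALSE)
    }
    model <- fit_model(ds, tr, family, derive_seed(seed, si), n_trees, cnn)
    te_all <- which(ds$meta$subject == s)
    if (length(te_all) == 0) next
    sc_all <- score_model(model, ds, te_all)
    for (nm in names(test_sets)) {
      sel <- test_sets[[nm]][te_all]
      y_te <- ds$y[te_all][sel]
      if (sum(sel) == 0) {
        exc[[nm]][[length(exc[[nm]]) + 1]] <-
          data.frame(subject = s, reason = "no test clips")
        next
      }
      if (length(unique(y_te)) < 2) {
        exc[[nm]][[length(exc[[nm]]) + 1]] <-
          data.frame(subject = s, reason = "single-class test labels")
        next
      }
      auc <- compute_auroc(sc_all[sel], y_te)
      per[[nm]][[length(per[[nm]]) + 1]] <- data.frame(
        subject = s, auroc = auc, n_pos = sum(y_te == 1),
        n_neg = sum(y_te == 0), stringsAsFactors = FALSE)
    }
  }

  results <- list()
  for (nm in names(test_sets)) {
    ps <- if (length(per[[nm]])) do.call(rbind, per[[nm]]) else
      data.frame(subject = character(0), auroc = numeric(0),
                 n_pos = integer(0), n_neg = integer(0))
    ex <- if (length(exc[[nm]])) do.call(rbind, exc[[nm]]) else NULL
    if (nrow(ps) < 2) {
      if (single) {
        stop("fewer than 2 evaluable subjects; experiment aborted",
             call. = FALSE)
      }
      warning("condition '", nm, "' omitted: fewer than 2 evaluable subjects",
              call. = FALSE)
      next
    }
    cond <- if (single) condition else paste(condition, nm, sep = ":")
    results[[nm]] <- new_eval_result(cond, ps, ex)
  }
  if (single) results[["all"]] else results
}

# ---- result serialization ------------------------------------------------

result_to_list <- function(x) {
  if (inherits(x, "eval_result")) {
    list(.class = "eval_result", condition = x$condition,
         per_subject = x$per_subject, mean_auroc = x$mean_auroc,
         ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         n_subjects_evaluated = x$n_subjects_evaluated,
         excluded = x$excluded)
  } else if (inherits(x, "pd_experiment")) {
    c(list(.class = "pd_experiment"),
      lapply(unclass(x), result_to_list))
  } else if (is.list(x) && !is.data.frame(x)) {
    lapply(x, result_to_list)
  } else {
    x
  }
}

list_to_result <- function(x) {
  if (is.list(x) && identical(x$.class, "eval_result")) {
    ps <- as.data.frame(x$per_subject)
    ps$auroc <- as.numeric(ps$auroc)
    if ("n_pos" %in% names(ps)) {
      ps$n_pos <- as.integer(ps$n_pos)
      ps$n_neg <- as.integer(ps$n_neg)
    }
    ex <- as.data.frame(x$excluded)
    if (nrow(ex) == 0) ex <- data.frame(subject = character(0),
                                        reason = character(0))
    r <- new_eval_result(x$condition, ps, ex)
    return(r)
  }
  if (is.list(x) && identical(x$.class, "pd_experiment")) {
    out <- lapply(x[setdiff(names(x), ".class")], list_to_result)
    class(out) <- "pd_experiment"
    return(out)
  }
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, list_to_result))
  x
}

#' Write evaluation results to JSON
#'
#' Full-precision JSON serialization of `eval_result` / `pd_experiment`
#' objects; [read_eval_results()] restores them losslessly.
#'
#' @param x an `eval_result`, `pd_experiment`, or list of them.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_eval_results <- function(x, path) {
  jsonlite::write_json(result_to_list(x), path, auto_unbox = TRUE,
                       digits = I(17), dataframe = "columns", null = "null")
  invisible(path)
}

#' Read evaluation results written by [write_eval_results()]
#'
#' @param path JSON file path.
#' @return The restored object.
#' @export
read_eval_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list_to_result(x)
}
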