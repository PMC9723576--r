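# Threshold classifier on s-bar scores: stratified train/test split,
# rank-based c-statistic, sensitivity+specificity-optimal cutoff, the
# "s_bar < t => PISSB" decision rule, and the replication protocol.

POS_LABEL <- "PISSB"
NEG_LABEL <- "NISSB"

check_two_classes <- function(labels) {
  if (!all(labels %in% c(POS_LABEL, NEG_LABEL)))
    stop("labels must be PISSB or NISSB")
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
}

#' Stratified train/test split
#'
#' Splits score records by label: `round(frac * n)` records of each class go
#' to training, the rest to test. Reproducible under the seed.
#'
#' @param records data.frame with at least a `label` column
#'   (`"PISSB"`/`"NISSB"`).
#' @param frac training fraction (default 0.8).
#' @param seed integer seed.
#' @param stratify stratify by label (default `TRUE`).
#' @return List with `train` and `test` data.frames (a `.row` column tracks
#'   provenance).
#' @export
split_train_test <- function(records, frac = 0.8, seed = 1, stratify = TRUE) {
  stopifnot(frac > 0, frac < 1)
  check_two_classes(records$label)
  if (min(table(records$label)) < 2) stop("each class needs at least 2 records")
  records$.row <- seq_len(nrow(records))
  pick <- withr::with_seed(seed, {
    if (stratify) {
      unlist(lapply(split(records$.row, records$label), function(rows) {
        k <- round(frac * length(rows))
        rows[sample.int(length(rows), k)]
      }), use.names = FALSE)
    } else {
      sample.int(nrow(records), round(frac * nrow(records)))
    }
  })
  list(train = records[records$.row %in% pick, , drop = FALSE],
       test = records[!records$.row %in% pick, , drop = FALSE])
}

#' Concordance statistic (area under the ROC curve)
#'
#' The probability that a randomly chosen PISSB has a *lower* s-bar score
#' than a randomly chosen NISSB, ties counted one half — the rank
#' (Mann-Whitney) formulation of the AUC under the "lower score means
#' positive" orientation.
#'
#' @param scores numeric s-bar scores.
#' @param labels `"PISSB"`/`"NISSB"` per score.
#' @return Numeric in `[0, 1]`.
#' @export
c_statistic <- function(scores, labels) {
  check_two_classes(labels)
  pos <- scores[labels == POS_LABEL]
  neg <- scores[labels == NEG_LABEL]
  r <- rank(c(neg, pos))  # midranks handle ties
  u <- sum(r[seq_along(neg)]) - length(neg) * (length(neg) + 1) / 2
  u / (length(pos) * length(neg))
}

#' Train the optimal s-bar cutoff
#'
#' Candidate cutoffs are the midpoints between consecutive distinct sorted
#' scores, plus sentinels below the minimum and above the maximum. The
#' chosen `t` maximizes sensitivity (fraction of PISSB with `s_bar < t`)
#' plus specificity (fraction of NISSB with `s_bar >= t`); ties go to the
#' smallest `t`. A grid where every candidate attains the same objective
#' (e.g. all scores equal) is flagged degenerate.
#'
#' @param scores numeric training s-bar scores.
#' @param labels `"PISSB"`/`"NISSB"` per score.
#' @return A `threshold_model`: list with `t`, `train_sensitivity`,
#'   `train_specificity`, `candidate_grid`, `degenerate`,
#'   `orientation = "lower s_bar => PISSB"`.
#' @export
optimal_threshold <- function(scores, labels) {
  check_two_classes(labels)
  u <- sort(unique(scores))
  grid <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  pos <- scores[labels == POS_LABEL]
  neg <- scores[labels == NEG_LABEL]
  sens <- vapply(grid, function(t) mean(pos < t), 0)
  spec <- vapply(grid, function(t) mean(neg >= t), 0)
  J <- sens + spec
  best <- which.max(J)  # which.max takes the first (smallest t) on ties
  structure(list(t = grid[best], train_sensitivity = sens[best],
                 train_specificity = spec[best], candidate_grid = grid,
                 J = J, degenerate = max(J) - min(J) < .Machine$double.eps^0.5,
                 orientation = "lower s_bar => PISSB"),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model: t = %.4f (train sens %.3f, spec %.3f)%s>\n",
              x$t, x$train_sensitivity, x$train_specificity,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Classify a block by its s-bar score
#'
#' `PISSB` iff `s_bar < t`, strictly: a score exactly at the cutoff — and an
#' infinite score from the disconnected-pair policy — is classified `NISSB`.
#'
#' @param s_bar numeric score(s).
#' @param model a `threshold_model`.
#' @return Character vector of labels.
#' @export
classify <- function(s_bar, model) {
  ifelse(s_bar < model$t, POS_LABEL, NEG_LABEL)
}

#' Evaluate a threshold model on scored records
#'
#' @param model a `threshold_model`.
#' @param scores numeric s-bar scores.
#' @param labels true labels.
#' @return An `eval_report`: list with `c_statistic`, `sensitivity`,
#'   `specificity`, `confusion` (TP/FN/TN/FP), `n`.
#' @export
evaluate_threshold <- function(model, scores, labels) {
  check_two_classes(labels)
  pred <- classify(scores, model)
  tp <- sum(pred == POS_LABEL & labels == POS_LABEL)
  fn <- sum(pred == NEG_LABEL & labels == POS_LABEL)
  tn <- sum(pred == NEG_LABEL & labels == NEG_LABEL)
  fp <- sum(pred == POS_LABEL & labels == NEG_LABEL)
  structure(list(c_statistic = c_statistic(scores, labels),
                 sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
                 n = length(scores)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval: c = %.3f, sens = %.3f, spec = %.3f, n = %d>\n",
              x$c_statistic, x$sensitivity, x$specificity, x$n))
  invisible(x)
}

#' ROC curve points
#'
#' Sensitivity / one-minus-specificity at every candidate cutoff, under the
#' "lower score means positive" orientation.
#'
#' @param scores numeric scores.
#' @param labels `"PISSB"`/`"NISSB"`.
#' @return data.frame with `t`, `sensitivity`, `specificity`.
#' @export
roc_points <- function(scores, labels) {
  check_two_classes(labels)
  u <- sort(unique(scores))
  grid <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  pos <- scores[labels == POS_LABEL]; neg <- scores[labels == NEG_LABEL]
  data.frame(t = grid,
             sensitivity = vapply(grid, function(t) mean(pos < t), 0),
             specificity = vapply(grid, function(t) mean(neg >= t), 0))
}

#' Replicate a train/evaluate experiment over resampled score sets
#'
#' The replication protocol: in each trial a fresh set of NISSB counterpart
#' scores is drawn (via `draw_fn`), pooled with the fixed PISSB scores,
#' split 80/20 stratified, the threshold retrained, and the test c-statistic
#' recorded.
#'
#' @param draw_fn function `(trial_seed) -> data.frame(score, label)`
#'   producing one trial's labeled score records.
#' @param n_reps number of trials (default 50).
#' @param seed master seed; trial seeds are `seed + 1:n_reps`.
#' @param frac training fraction (default 0.8).
#' @return List with `trials` (data.frame: `trial`, `seed`, `t`,
#'   `train_c`, `test_c`) and `summary` (mean/sd of test c-statistic).
#' @export
replicate_experiment <- function(draw_fn, n_reps = 50, seed = 1, frac = 0.8) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    trial_seed <- seed + r
    rec <- draw_fn(trial_seed)
    sp <- split_train_test(rec, frac = frac, seed = trial_seed)
    model <- optimal_threshold(sp$train$score, sp$train$label)
    rows[[r]] <- data.frame(
      trial = r, seed = trial_seed, t = model$t,
      train_c = c_statistic(sp$train$score, sp$train$label),
      test_c = c_statistic(sp$test$score, sp$test$label))
  }
  trials <- do.call(rbind, rows)
  list(trials = trials,
       summary = list(n_reps = n_reps,
                      mean_test_c = mean(trials$test_c),
                      sd_test_c = stats::sd(trials$test_c),
                      mean_train_c = mean(trials$train_c),
                      mean_t = mean(trials$t)))
}
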