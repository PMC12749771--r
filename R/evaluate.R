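# Evaluation machinery: ROC/AUC, dual operating thresholds (balanced and
# F1-oriented), DeLong confidence intervals, permutation significance,
# one-sided fold comparisons, probability-level ensemble voting, and
# patient-level stratified cross-validation folds.
#
# Orientation convention throughout: the score is the probability of the
# positive (mutant) class, and a prediction is positive iff score >= the
# threshold.

check_two_classes <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) stop("labels must be logical TRUE/FALSE", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("degenerate-input error: both classes must be present", call. = FALSE)
  labels
}

# Rank-based AUC (Mann-Whitney probability, ties counted 1/2).
auc_value <- function(scores, labels) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve and AUC
#'
#' AUC equals the Mann-Whitney probability that a random positive outscores
#' a random negative, with ties counted one half.
#'
#' @param scores Numeric scores (probability of the positive class).
#' @param labels Logical, TRUE for the positive class; both classes must be
#'   present.
#' @return A list with `auc` and `roc`, a data.frame of operating points
#'   (threshold, fpr, tpr) as the threshold sweeps the observed scores from
#'   above the maximum downwards.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  pts <- vapply(thr, function(t) {
    pos_call <- scores >= t
    c(fpr = sum(pos_call & !labels) / n_neg, tpr = sum(pos_call & labels) / n_pos)
  }, numeric(2))
  list(auc = auc_value(scores, labels),
       roc = data.frame(threshold = thr, fpr = pts["fpr", ], tpr = pts["tpr", ]))
}

# Candidate thresholds: midpoints between adjacent distinct scores plus
# sentinels below and above the observed range.
candidate_thresholds <- function(scores) {
  s <- sort(unique(scores))
  if (length(s) == 1) return(c(s - 1, s + 1))
  c(s[1] - 1, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1)
}

confusion_metrics <- function(scores, labels, threshold) {
  pos_call <- scores >= threshold
  tp <- sum(pos_call & labels); fn <- sum(!pos_call & labels)
  fp <- sum(pos_call & !labels); tn <- sum(!pos_call & !labels)
  sen <- tp / (tp + fn); spe <- tn / (tn + fp)
  acc <- (tp + tn) / length(labels)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(acc = acc, sen = sen, spe = spe, f1 = f1)
}

#' Balanced (sensitivity/specificity) operating threshold
#'
#' Scans all candidate thresholds (midpoints of adjacent observed scores)
#' for the operating point balancing sensitivity and specificity. The
#' default criterion maximises Youden's J = SEN + SPE - 1; the alternative
#' `"min_diff"` mode minimises |SEN - SPE|. Ties take the lower threshold.
#'
#' @inheritParams roc_auc
#' @param mode `"youden"` or `"min_diff"`.
#' @return A list with `threshold`, `acc`, `sen`, `spe` and `j`.
#' @export
balanced_threshold <- function(scores, labels, mode = c("youden", "min_diff")) {
  mode <- match.arg(mode)
  labels <- check_two_classes(labels)
  cand <- candidate_thresholds(scores)
  crit <- vapply(cand, function(t) {
    m <- confusion_metrics(scores, labels, t)
    if (mode == "youden") m$sen + m$spe - 1 else -abs(m$sen - m$spe)
  }, numeric(1))
  best <- cand[which.max(crit)]  # which.max takes the first (lowest) on ties
  m <- confusion_metrics(scores, labels, best)
  list(threshold = best, acc = m$acc, sen = m$sen, spe = m$spe,
       j = m$sen + m$spe - 1)
}

#' F1-oriented operating threshold
#'
#' Maximises the F1 score of the positive class over candidate thresholds;
#' ties take the lower threshold.
#'
#' @inheritParams roc_auc
#' @return A list with `threshold` and `f1`.
#' @export
f1_threshold <- function(scores, labels) {
  labels <- check_two_classes(labels)
  cand <- candidate_thresholds(scores)
  f1s <- vapply(cand, function(t) confusion_metrics(scores, labels, t)$f1, numeric(1))
  best <- cand[which.max(f1s)]
  list(threshold = best, f1 = max(f1s))
}

#' DeLong confidence interval for an AUC
#'
#' Variance from DeLong's structural components, normal-quantile interval,
#' clipped to \[0, 1\].
#'
#' @inheritParams roc_auc
#' @param level Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- check_two_classes(labels)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("degenerate-input error: need at least 2 observations per class", call. = FALSE)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- pROC::ci.auc(r, conf.level = level, method = "delong")
  c(lower = max(0, as.numeric(ci[1])), upper = min(1, as.numeric(ci[3])))
}

#' Permutation p-value for an AUC
#'
#' Estimates significance against the chance-level AUC distribution obtained
#' by permuting the truth labels, with the add-one estimator
#' p = (1 + #\{AUC_perm >= AUC_obs\}) / (n_perm + 1). For cross-validation
#' results, apply it to the predictions and labels pooled over all folds.
#'
#' @inheritParams roc_auc
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutation stream.
#' @return One-sided p-value.
#' @export
permutation_pvalue <- function(scores, labels, n_perm = 1000L, seed = 1L) {
  labels <- check_two_classes(labels)
  obs <- auc_value(scores, labels)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) auc_value(scores, sample(labels)) >= obs, logical(1)))
  })
  (1 + exceed) / (n_perm + 1)
}

#' One-sided fold-AUC comparison between two models
#'
#' Welch (unequal-variance) two-sample t-test of mean(a) > mean(b) on
#' per-fold AUCs.
#'
#' @param fold_aucs_a,fold_aucs_b Numeric vectors of per-fold AUCs (>= 2
#'   each).
#' @return One-sided p-value.
#' @export
compare_models_ttest <- function(fold_aucs_a, fold_aucs_b) {
  if (length(fold_aucs_a) < 2 || length(fold_aucs_b) < 2)
    stop("need at least 2 fold AUCs per model", call. = FALSE)
  na <- length(fold_aucs_a); nb <- length(fold_aucs_b)
  va <- stats::var(fold_aucs_a); vb <- stats::var(fold_aucs_b)
  diff <- mean(fold_aucs_a) - mean(fold_aucs_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) return(if (diff > 0) 0 else if (diff < 0) 1 else 0.5)
  t_stat <- diff / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  stats::pt(t_stat, df, lower.tail = FALSE)
}

#' Probability-level majority voting
#'
#' Averages prediction probabilities across models (rows), slide by slide.
#'
#' @param prob_matrix Numeric matrix, models x slides (or a list of
#'   equal-length probability vectors).
#' @return Numeric vector of per-slide averaged probabilities.
#' @export
ensemble_vote <- function(prob_matrix) {
  if (is.list(prob_matrix)) {
    lens <- lengths(prob_matrix)
    if (length(unique(lens)) != 1)
      stop("shape error: all probability vectors must have the same length", call. = FALSE)
    prob_matrix <- do.call(rbind, prob_matrix)
  }
  if (!is.matrix(prob_matrix)) stop("shape error: expected a models x slides matrix", call. = FALSE)
  colMeans(prob_matrix)
}

#' Patient-level stratified cross-validation folds
#'
#' Partitions patients (never slides) into k folds, stratified by the
#' patient-level task label: per-fold positive counts and fold sizes each
#' differ by at most one. All slides of a patient share its fold.
#'
#' @param records Slide metadata data.frame with `patient_id` and the label
#'   column.
#' @param k Number of folds.
#' @param label_col Name of the logical task label column.
#' @param ratio Optional train:test ratio tag recorded in the plan (e.g.
#'   "9:1" for ten-fold).
#' @param seed Shuffling seed.
#' @return An object of class `fold_plan`: `folds` (list of patient-id
#'   vectors), `k`, `ratio`, `seed`.
#' @export
make_folds <- function(records, k, label_col, ratio = NULL, seed = 1L) {
  patients <- unique(records$patient_id)
  if (k > length(patients))
    stop("k = ", k, " exceeds the number of patients (", length(patients), ")",
         call. = FALSE)
  # patient-level label: constant across a patient's slides by construction
  plab <- vapply(patients, function(p)
    as.logical(records[[label_col]][records$patient_id == p][1]), logical(1))
  ordered <- with_seed(seed, {
    pos <- sample(patients[plab])
    neg <- sample(patients[!plab])
    c(pos, neg)
  })
  assignment <- rep_len(seq_len(k), length(ordered))
  folds <- lapply(seq_len(k), function(f) sort(ordered[assignment == f]))
  structure(list(folds = folds, k = k,
                 ratio = if (is.null(ratio)) sprintf("%d:1", k - 1) else ratio,
                 seed = seed, label_col = label_col),
            class = "fold_plan")
}

# Fold-spread CI: t-interval over per-fold AUCs.
fold_spread_ci <- function(fold_aucs, level = 0.95) {
  n <- length(fold_aucs)
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(fold_aucs) / sqrt(n)
  c(lower = max(0, mean(fold_aucs) - half), upper = min(1, mean(fold_aucs) + half))
}

#' Evaluation report for one prediction task
#'
#' Bundles the AUC with its confidence interval (t-interval over fold AUCs
#' when folds are available, DeLong otherwise), permutation significance,
#' and the two operating thresholds with their metrics.
#'
#' @inheritParams roc_auc
#' @param task Task name (gene or PA).
#' @param fold_aucs Optional numeric vector of per-fold AUCs; switches the
#'   CI to the fold-spread formula.
#' @param n_perm Permutations for the significance test.
#' @param seed Permutation seed.
#' @param fold Fold identifier or `"pooled"`.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(scores, labels, task = "task", fold_aucs = NULL,
                        n_perm = 1000L, seed = 1L, fold = "pooled") {
  labels <- check_two_classes(labels)
  pooled_auc <- auc_value(scores, labels)
  if (!is.null(fold_aucs) && length(fold_aucs) >= 2) {
    # report the fold-averaged AUC with its spread interval
    auc <- mean(fold_aucs)
    ci <- fold_spread_ci(fold_aucs)
    ci_method <- "fold-spread"
  } else {
    auc <- pooled_auc
    ci <- delong_ci(scores, labels)
    ci_method <- "DeLong"
  }
  bal <- balanced_threshold(scores, labels)
  f1 <- f1_threshold(scores, labels)
  structure(list(task = task, auc = auc, pooled_auc = pooled_auc,
                 ci = ci, ci_method = ci_method,
                 fold_aucs = fold_aucs,
                 permutation_p = permutation_pvalue(scores, labels, n_perm, seed),
                 balanced = bal, f1 = f1,
                 n_pos = sum(labels), n_neg = sum(!labels), fold = fold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s [%s]: AUC %.3f (%s CI %.3f-%.3f), perm p %.4g\n",
              x$task, x$fold, x$auc, x$ci_method, x$ci[1], x$ci[2], x$permutation_p))
  cat(sprintf("  balanced thr %.3f: ACC %.3f SEN %.3f SPE %.3f | F1 thr %.3f: F1 %.3f\n",
              x$balanced$threshold, x$balanced$acc, x$balanced$sen, x$balanced$spe,
              x$f1$threshold, x$f1$f1))
  cat(sprintf("  n+ %d / n- %d\n", x$n_pos, x$n_neg))
  invisible(x)
}
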