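# ROC/AUC, thresholds, CIs, permutation tests, fold machinery.

test_that("AUC handles perfect separation and complete ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "degenerate-input")
})

test_that("AUC equals the pairwise oracle, including on random sets", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.6)
  labels <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  expect_equal(roc_auc(scores, labels)$auc, oracle_auc_pairs(scores, labels))
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # force some ties
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc_pairs(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with the pROC implementation", {
  set.seed(5)
  scores <- runif(40)
  labels <- runif(40) < 0.4
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              levels = c(FALSE, TRUE),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("balanced threshold maximises Youden's J over all cut points", {
  res <- balanced_threshold(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$sen, 1); expect_equal(res$spe, 1)

  scores <- c(0.1, 0.2, 0.35, 0.4, 0.55, 0.6, 0.8, 0.9)
  labels <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  res <- balanced_threshold(scores, labels)
  # exhaustive oracle over a fine threshold sweep
  sweep_thr <- seq(-0.1, 1.1, by = 0.001)
  js <- vapply(sweep_thr, function(t) {
    sen <- mean(scores[labels] >= t); spe <- mean(scores[!labels] < t)
    sen + spe - 1
  }, numeric(1))
  expect_equal(res$j, max(js), tolerance = 1e-12)
  # orientation: positive iff score >= threshold
  expect_equal(res$sen, mean(scores[labels] >= res$threshold))
})

test_that("F1 threshold matches an exhaustive scan and may differ from balanced", {
  expect_equal(f1_threshold(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$f1, 1)

  scores <- c(0.05, 0.2, 0.3, 0.45, 0.5, 0.65, 0.7, 0.95)
  labels <- c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  res <- f1_threshold(scores, labels)
  sweep_thr <- seq(-0.1, 1.1, by = 0.001)
  f1s <- vapply(sweep_thr, function(t) {
    tp <- sum(scores >= t & labels); fp <- sum(scores >= t & !labels)
    fn <- sum(scores < t & labels)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  expect_equal(res$f1, max(f1s), tolerance = 1e-12)
  # an asymmetric set where the two operating points disagree
  bal <- balanced_threshold(scores, labels)
  expect_false(isTRUE(all.equal(bal$threshold, res$threshold)))
})

test_that("DeLong intervals bracket the AUC and clip at 1", {
  set.seed(2)
  scores <- c(rnorm(30), rnorm(30, 1))
  labels <- rep(c(FALSE, TRUE), each = 30)
  ci <- delong_ci(scores, labels)
  auc <- roc_auc(scores, labels)$auc
  expect_lte(ci[["lower"]], auc)
  expect_gte(ci[["upper"]], auc)

  perfect <- suppressWarnings(
    delong_ci(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3)))
  expect_equal(perfect[["upper"]], 1)
  expect_error(delong_ci(c(1, 2, 3), c(TRUE, FALSE, FALSE)), "degenerate-input")
})

test_that("permutation p-values hit the estimator floor and are reproducible", {
  scores <- c(0.1, 0.2, 0.3, 0.8, 0.9, 0.95)
  labels <- rep(c(FALSE, TRUE), each = 3)
  p <- permutation_pvalue(scores, labels, n_perm = 1000, seed = 3)
  # observed AUC = 1 can only be matched, never exceeded; permutations
  # reaching 1 exist but are rare for n = 6 (prob 1/20 per draw)
  expect_gte(p, 1 / 1001)
  expect_lt(p, 0.15)
  expect_identical(p, permutation_pvalue(scores, labels, n_perm = 1000, seed = 3))
  # a larger clean separation drives p to the floor
  scores2 <- c(seq(0.01, 0.2, length.out = 12), seq(0.8, 0.99, length.out = 12))
  labels2 <- rep(c(FALSE, TRUE), each = 12)
  expect_equal(permutation_pvalue(scores2, labels2, n_perm = 1000, seed = 4),
               1 / 1001)
})

test_that("permutation p-values shrink as the injected signal grows", {
  set.seed(12)
  labels <- rep(c(FALSE, TRUE), each = 20)
  meds <- vapply(c(0, 0.8, 2), function(delta) {
    ps <- vapply(1:20, function(i) {
      scores <- rnorm(40) + delta * labels
      permutation_pvalue(scores, labels, n_perm = 199, seed = i)
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("fold-AUC comparisons follow the one-sided Welch form", {
  a <- c(0.8, 0.82, 0.78, 0.81)
  expect_equal(compare_models_ttest(a, a), 0.5)

  set.seed(6)
  b <- runif(10, 0.6, 0.7)
  a2 <- b + 0.2
  p <- compare_models_ttest(a2, b)
  expect_lt(p, 0.01)
  # closed-form oracle via t.test
  expect_equal(p, t.test(a2, b, alternative = "greater")$p.value, tolerance = 1e-12)
  expect_equal(compare_models_ttest(b, a2), 1 - p, tolerance = 1e-9)
  expect_error(compare_models_ttest(0.5, c(0.4, 0.5)), "at least 2")
})

test_that("ensemble voting averages probabilities column-wise", {
  m <- matrix(0.42, 10, 4)
  expect_equal(ensemble_vote(m), rep(0.42, 4))
  hand <- rbind(c(0.1, 0.5, 0.9, 0.2),
                c(0.3, 0.7, 0.8, 0.4),
                c(0.2, 0.6, 1.0, 0.0))
  expect_equal(ensemble_vote(hand),
               c((0.1 + 0.3 + 0.2) / 3, (0.5 + 0.7 + 0.6) / 3,
                 (0.9 + 0.8 + 1.0) / 3, (0.2 + 0.4 + 0.0) / 3))
  expect_true(all(ensemble_vote(hand) >= 0 & ensemble_vote(hand) <= 1))
  expect_error(ensemble_vote(list(c(0.1, 0.2), c(0.3))), "shape error")
})

test_that("folds partition patients with stratified balance", {
  ch <- small_cohort(n_patients = 30, seed = 17)
  plan <- make_folds(ch$records, 10, "H3K27M", seed = 3)
  sizes <- lengths(plan$folds)
  expect_equal(sizes, rep(3L, 10))
  all_patients <- sort(unlist(plan$folds))
  expect_equal(all_patients, sort(unique(ch$records$patient_id)))

  per_patient <- ch$records[!duplicated(ch$records$patient_id), ]
  pos_per_fold <- vapply(plan$folds, function(f)
    sum(per_patient$H3K27M[match(f, per_patient$patient_id)]), numeric(1))
  n_pos <- sum(per_patient$H3K27M)
  expect_true(all(abs(pos_per_fold - n_pos / 10) <= 1))

  # determinism and error case
  expect_identical(plan$folds, make_folds(ch$records, 10, "H3K27M", seed = 3)$folds)
  expect_error(make_folds(ch$records, 31, "H3K27M"), "exceeds")
})

test_that("eval_report bundles the statistics coherently", {
  set.seed(20)
  scores <- c(runif(25, 0, 0.7), runif(25, 0.3, 1))
  labels <- rep(c(FALSE, TRUE), each = 25)
  rep1 <- eval_report(scores, labels, task = "demo", n_perm = 199, seed = 1)
  expect_equal(rep1$ci_method, "DeLong")
  expect_lte(rep1$ci[["lower"]], rep1$auc)
  expect_gte(rep1$ci[["upper"]], rep1$auc)
  expect_true(all(c(rep1$balanced$acc, rep1$balanced$sen, rep1$balanced$spe,
                    rep1$f1$f1) >= 0))

  fold_aucs <- c(0.81, 0.77, 0.84, 0.79, 0.8)
  rep2 <- eval_report(scores, labels, task = "demo", fold_aucs = fold_aucs,
                      n_perm = 199, seed = 1)
  expect_equal(rep2$ci_method, "fold-spread")
  expect_equal(rep2$auc, mean(fold_aucs))
  expect_lte(rep2$ci[["lower"]], rep2$auc)
  expect_gte(rep2$ci[["upper"]], rep2$auc)
})
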