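# Retrospective biopsy re-checking policy.

mk_stream <- function(id, status, truth, probs) {
  patient_stream(id, seq_along(status), status, truth,
                 matrix(probs, nrow = length(status),
                        dimnames = list(NULL, names(truth))))
}

GENES <- c("ATRX", "H3K27M", "TP53")
THR <- c(ATRX = 0.5, H3K27M = 0.5, TP53 = 0.5)

test_that("human biopsy counts follow the first-Pass rule with fallback", {
  t0 <- c(ATRX = FALSE, H3K27M = FALSE, TP53 = FALSE)
  expect_equal(human_biopsy_count(mk_stream("p", "Pass", t0, rep(0, 3))), 1)
  expect_equal(human_biopsy_count(
    mk_stream("p", c("No-Pass", "No-Pass", "Pass"), t0, rep(0, 9))), 3)
  expect_equal(human_biopsy_count(
    mk_stream("p", c("No-Pass", "No-Pass"), t0, rep(0, 6))), 2)
  expect_error(patient_stream("p", integer(0), character(0), t0,
                              matrix(numeric(0), 0, 3,
                                     dimnames = list(NULL, GENES))),
               "empty stream")
})

test_that("AI counts require gene-matched correct detection", {
  truth <- c(ATRX = FALSE, H3K27M = TRUE, TP53 = FALSE)
  probs <- rbind(c(0.2, 0.9, 0.1), c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))
  colnames(probs) <- GENES
  s <- patient_stream("p1", 1:3, c("No-Pass", "No-Pass", "Pass"), truth, probs)
  expect_equal(ai_biopsy_count(s, THR), 1)

  # wrong-gene positive call does not count in strict mode
  probs2 <- rbind(c(0.9, 0.2, 0.1), c(0.2, 0.2, 0.2), c(0.2, 0.9, 0.2))
  colnames(probs2) <- GENES
  s2 <- patient_stream("p2", 1:3, c("No-Pass", "No-Pass", "Pass"), truth, probs2)
  expect_equal(ai_biopsy_count(s2, THR, mode = "strict"), 3)
  expect_equal(ai_biopsy_count(s2, THR, mode = "lenient"), 1)

  # no mutant gene: AI cannot reduce, count = human count
  t0 <- c(ATRX = FALSE, H3K27M = FALSE, TP53 = FALSE)
  s3 <- mk_stream("p3", c("No-Pass", "No-Pass", "No-Pass", "Pass"), t0, rep(0.9, 12))
  expect_equal(ai_biopsy_count(s3, THR), 4)

  # mutant patient the model never flags is capped at the human count
  s4 <- mk_stream("p4", c("No-Pass", "Pass"), truth, rep(0.1, 6))
  expect_equal(ai_biopsy_count(s4, THR), 2)

  # cap = FALSE reports the raw late detection
  probs5 <- rbind(c(0.1, 0.1, 0.1), c(0.1, 0.1, 0.1), c(0.1, 0.9, 0.1))
  colnames(probs5) <- GENES
  s5 <- patient_stream("p5", 1:3, c("No-Pass", "Pass", "No-Pass"), truth, probs5)
  expect_equal(ai_biopsy_count(s5, THR, cap = TRUE), 2)
  expect_equal(ai_biopsy_count(s5, THR, cap = FALSE), 3)

  expect_error(ai_biopsy_count(s4, c(ATRX = 0.5)), "consistency error")
})

test_that("reduction summaries match hand arithmetic", {
  truth_mut <- c(ATRX = FALSE, H3K27M = TRUE, TP53 = FALSE)
  # engineered so human counts are (2, 1, 3) and AI counts (1, 1, 2)
  streams <- list(
    mk_stream("a", c("No-Pass", "Pass"), truth_mut,
              rbind(c(0.1, 0.9, 0.1), c(0.1, 0.9, 0.1))),
    mk_stream("b", "Pass", truth_mut, cbind(0.1, 0.9, 0.1)),
    mk_stream("c", c("No-Pass", "No-Pass", "Pass"), truth_mut,
              rbind(c(0.1, 0.1, 0.1), c(0.1, 0.9, 0.1), c(0.1, 0.9, 0.1))))
  res <- reduction_summary(streams, THR)
  expect_equal(res$per_patient$human_count, c(2, 1, 3))
  expect_equal(res$per_patient$ai_count, c(1, 1, 2))
  expect_equal(res$saved, 2)
  expect_equal(res$total_human, 6)
  expect_equal(res$reduction_ratio, 2 / 6)
  expect_equal(res$mean_human, 2)
  expect_equal(res$mean_ai, 4 / 3, tolerance = 1e-12)
  expect_true(res$p_value < 0.5)
  # dominance and conservation invariants
  expect_true(all(res$per_patient$ai_count <= res$per_patient$human_count))
  expect_equal(sum(res$sankey$n), 3)
  expect_equal(res$saved, res$total_human - res$total_ai)
})

test_that("published aggregate counts reproduce the printed summary statistics", {
  internal <- biopsy_reduction_totals(564, 326, 149)
  expect_equal(round(internal$mean_human, 2), 1.73)
  expect_equal(round(internal$mean_ai, 2), 1.27)
  expect_equal(round(internal$reduction_percent, 1), 26.4)

  consecutive <- biopsy_reduction_totals(143, 68, 38)
  expect_equal(round(consecutive$mean_human, 2), 2.10)
  expect_equal(round(consecutive$mean_ai, 2), 1.54)
  expect_equal(round(consecutive$reduction_percent, 1), 26.6)
})

test_that("sankey counts tally a hand cohort and conserve patients", {
  per <- data.frame(human_count = c(1, 2, 2, 3, 1),
                    ai_count    = c(1, 1, 2, 1, 1))
  sk <- sankey_counts(per)
  expect_equal(sum(sk$n), 5)
  expect_equal(sk$n[sk$key == "H1->A1"], 2)
  expect_equal(sk$n[sk$key == "H2->A1"], 1)
  expect_equal(sk$n[sk$key == "H2->A2"], 1)
  expect_equal(sk$n[sk$key == "H3->A1"], 1)

  all_11 <- data.frame(human_count = rep(1, 7), ai_count = rep(1, 7))
  sk2 <- sankey_counts(all_11)
  expect_equal(nrow(sk2), 1)
  expect_equal(sk2$n, 7)
})

test_that("perfect and never-firing detectors bound the policy", {
  set.seed(44)
  streams <- lapply(1:12, function(i) {
    truth <- stats::setNames(runif(3) < 0.5, GENES)
    n <- sample(1:4, 1)
    status <- c(rep("No-Pass", n - 1), "Pass")
    probs <- matrix(rep(as.numeric(truth), each = n), n,
                    dimnames = list(NULL, GENES))  # oracle detector
    patient_stream(sprintf("p%02d", i), 1:n, status, truth, probs)
  })
  res <- reduction_summary(streams, THR)
  mutant <- vapply(streams, function(s) any(s$truth), logical(1))
  expect_true(all(res$per_patient$ai_count[mutant] == 1))

  never <- lapply(streams, function(s) {
    s$probs[] <- 0
    s
  })
  res0 <- reduction_summary(never, THR)
  expect_equal(res0$saved, 0)
  expect_equal(res0$reduction_ratio, 0)
  expect_equal(res0$per_patient$ai_count, res0$per_patient$human_count)
})

test_that("early-biopsy metrics average the first two samplings", {
  truth_pos <- c(ATRX = FALSE, H3K27M = TRUE, TP53 = FALSE)
  truth_neg <- c(ATRX = FALSE, H3K27M = FALSE, TP53 = FALSE)
  streams <- list(
    mk_stream("a", c("No-Pass", "Pass"), truth_pos,
              rbind(c(0.1, 0.8, 0.1), c(0.1, 0.6, 0.1))),
    mk_stream("b", c("No-Pass", "Pass"), truth_neg,
              rbind(c(0.1, 0.3, 0.1), c(0.1, 0.1, 0.1))),
    mk_stream("c", c("No-Pass", "Pass"), truth_pos,
              rbind(c(0.1, 0.55, 0.1), c(0.1, 0.65, 0.1))),
    mk_stream("d", "Pass", truth_neg, cbind(0.1, 0.4, 0.1)))
  em <- early_biopsy_metrics(streams)
  expect_equal(em$H3K27M$one$n, 4)
  # patients with a single slide are excluded from the two-biopsy block
  expect_equal(em$H3K27M$two$n, 3)
  # arithmetic oracle for the averaged probabilities
  two_scores <- c(mean(c(0.8, 0.6)), mean(c(0.3, 0.1)), mean(c(0.55, 0.65)))
  expect_equal(em$H3K27M$two$auc,
               roc_auc(two_scores, c(TRUE, FALSE, TRUE))$auc)

  # identical second probabilities leave the AUC unchanged on that subset
  streams_same <- lapply(streams[1:3], function(s) { s$probs[2, ] <- s$probs[1, ]; s })
  em2 <- early_biopsy_metrics(streams_same)
  expect_equal(em2$H3K27M$two$auc, em2$H3K27M$one$auc)

  expect_warning(early_biopsy_metrics(list(streams[[4]], mk_stream(
    "e", "Pass", truth_pos, cbind(0.1, 0.9, 0.1)))), "two-biopsy")
})
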