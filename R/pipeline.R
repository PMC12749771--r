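# End-to-end experiment orchestration.
#
# Part I: per-gene ten-fold patient-level cross-validation on Pass slides.
# Part II: transfer of the Part-I fold models to No-Pass slides (with
# probability-level ensemble voting), and direct retraining on No-Pass
# slides. Part III: per-gene models over all slides feeding the
# retrospective biopsy re-checking simulation; optionally applied to a
# second ("consecutive-style") cohort with models trained on the full
# primary cohort. Dual validation: the same machinery at five folds on the
# pilocytic-astrocytoma label.

#' Experiment configuration
#'
#' @param cohort A cohort: either the list(records, bags) from
#'   [generate_cohort()], a directory path written by [write_cohort()], or a
#'   [cohort_config()] to generate at run time.
#' @param tasks Character vector of task label columns (gene names and/or
#'   `"pa_label"`).
#' @param subset Which slides to use: `"pass"`, `"nopass"` or `"all"`.
#' @param cv_k Number of cross-validation folds.
#' @param cv_seed Seed for fold assignment and per-fold model seeds.
#' @param hyperparams A [mil_hyperparams()]; its `feature_dim` must match
#'   the cohort.
#' @param n_perm Permutations for significance testing.
#' @param recheck_mode Detection mode for the re-checking simulation.
#' @param out_dir Optional run directory; when set, reports and a manifest
#'   are written there.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort, tasks = c("ATRX", "H3K27M", "TP53"),
                              subset = c("pass", "nopass", "all"),
                              cv_k = 10L, cv_seed = 1L,
                              hyperparams = mil_hyperparams(),
                              n_perm = 1000L, recheck_mode = "strict",
                              out_dir = NULL) {
  subset <- match.arg(subset)
  if (length(tasks) < 1) stop("configuration error: 'tasks' must be non-empty", call. = FALSE)
  structure(list(cohort = cohort, tasks = tasks, subset = subset,
                 cv_k = as.integer(cv_k), cv_seed = as.integer(cv_seed),
                 hyperparams = hyperparams, n_perm = as.integer(n_perm),
                 recheck_mode = recheck_mode, out_dir = out_dir),
            class = "experiment_config")
}

resolve_cohort <- function(cohort) {
  if (inherits(cohort, "cohort_config")) return(generate_cohort(cohort))
  if (is.character(cohort)) return(read_cohort(cohort))
  if (is.list(cohort) && !is.null(cohort$records) && !is.null(cohort$bags)) return(cohort)
  stop("configuration error: 'cohort' must be a cohort list, a directory, ",
       "or a cohort_config", call. = FALSE)
}

subset_records <- function(records, subset) {
  switch(subset,
         pass = records[records$pass_status == "Pass", , drop = FALSE],
         nopass = records[records$pass_status == "No-Pass", , drop = FALSE],
         all = records)
}

check_task <- function(records, task) {
  if (!task %in% names(records))
    stop("configuration error: no label column '", task, "' in the cohort records",
         call. = FALSE)
}

with_fold_seed <- function(hyperparams, seed) {
  hp <- unclass(hyperparams)
  hp$seed <- as.integer(seed)
  structure(hp, class = "mil_hyperparams")
}

#' Patient-level cross-validation for one task
#'
#' Trains one model per fold on the training patients' slides and predicts
#' the held-out fold; records per-fold AUCs, per-fold balanced thresholds
#' estimated on the training predictions, and the decisions these thresholds
#' produce on the held-out slides (thresholds estimated separately per fold,
#' thresholded decisions combined).
#'
#' @param records,bags A cohort (already subset to the slides in play).
#' @param task Label column name.
#' @param k Number of folds.
#' @param seed Fold-assignment seed; per-fold model seeds derive from it.
#' @param hyperparams A [mil_hyperparams()].
#' @param n_perm Permutations for the pooled significance test.
#' @param ratio Split-ratio tag recorded in the fold plan.
#' @return An object of class `cv_result`: `report` (pooled [eval_report()]
#'   with fold-spread CI), `fold_aucs`, `predictions` (slide_id, patient_id,
#'   fold, label, score, decision), `combined` (ACC/SEN/SPE of the combined
#'   per-fold-threshold decisions), `fold_models`, `fold_thresholds`,
#'   `fold_plan`.
#' @export
run_cv <- function(records, bags, task, k = 10L, seed = 1L,
                   hyperparams = mil_hyperparams(), n_perm = 1000L,
                   ratio = NULL) {
  check_task(records, task)
  plan <- make_folds(records, k, task, ratio = ratio, seed = seed)
  preds <- list()
  fold_models <- vector("list", k)
  fold_thresholds <- numeric(k)
  fold_aucs <- numeric(k)

  for (f in seq_len(k)) {
    test_patients <- plan$folds[[f]]
    train_rec <- records[!records$patient_id %in% test_patients, , drop = FALSE]
    test_rec <- records[records$patient_id %in% test_patients, , drop = FALSE]
    hp <- with_fold_seed(hyperparams, child_seed(seed, "fold", f))
    model <- train_classifier(bags[train_rec$slide_id],
                              train_rec[[task]], hp)
    fold_models[[f]] <- model

    train_scores <- predict(model, bags[train_rec$slide_id])$p_mutant
    fold_thresholds[f] <- balanced_threshold(train_scores, train_rec[[task]])$threshold

    test_pred <- predict(model, bags[test_rec$slide_id])
    fold_aucs[f] <- auc_value(test_pred$p_mutant, as.logical(test_rec[[task]]))
    preds[[f]] <- data.frame(slide_id = test_rec$slide_id,
                             patient_id = test_rec$patient_id,
                             fold = f, label = as.logical(test_rec[[task]]),
                             score = test_pred$p_mutant,
                             decision = test_pred$p_mutant >= fold_thresholds[f],
                             stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL

  report <- eval_report(predictions$score, predictions$label, task = task,
                        fold_aucs = fold_aucs, n_perm = n_perm,
                        seed = child_seed(seed, "perm"))
  combined <- list(
    acc = mean(predictions$decision == predictions$label),
    sen = mean(predictions$decision[predictions$label]),
    spe = mean(!predictions$decision[!predictions$label]))

  structure(list(report = report, fold_aucs = fold_aucs,
                 predictions = predictions, combined = combined,
                 fold_models = fold_models, fold_thresholds = fold_thresholds,
                 fold_plan = plan, task = task),
            class = "cv_result")
}

write_manifest <- function(config, stage, seeds, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  cfg$cohort <- if (is.character(config$cohort)) config$cohort else "<in-memory>"
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(stage = stage, config = unclass(cfg),
                   config_hash = unname(tools::md5sum(tmp)), seeds = seeds,
                   package_version = as.character(utils::packageVersion("cryomil")))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Part I: per-gene cross-validation on Pass slides
#'
#' @param config An [experiment_config()]; its `subset` is forced to
#'   `"pass"`.
#' @return Named list (one entry per task) of [run_cv()] results.
#' @export
run_part1 <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- resolve_cohort(config$cohort)
  records <- subset_records(cohort$records, "pass")
  out <- lapply(config$tasks, function(task)
    run_cv(records, cohort$bags, task, k = config$cv_k, seed = config$cv_seed,
           hyperparams = config$hyperparams, n_perm = config$n_perm))
  names(out) <- config$tasks
  write_manifest(config, "part1", list(cv_seed = config$cv_seed), config$out_dir)
  out
}

#' Part II: No-Pass slides — transfer and retrain
#'
#' Transfer mode applies every Part-I Pass-trained fold model to all No-Pass
#' slides and averages the prediction probabilities (probability-level
#' majority voting); retrain mode runs a fresh cross-validation on No-Pass
#' slides only.
#'
#' @param config An [experiment_config()].
#' @param part1 The [run_part1()] result on the same cohort (required for
#'   transfer mode).
#' @param mode `"transfer"`, `"retrain"`, or `"both"`.
#' @return A list with `transfer` (per task: `report` with DeLong CI,
#'   `scores`, `labels`) and/or `retrain` (per task: [run_cv()] result).
#' @export
run_part2 <- function(config, part1 = NULL, mode = c("both", "transfer", "retrain")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "experiment_config"))
  cohort <- resolve_cohort(config$cohort)
  records <- subset_records(cohort$records, "nopass")
  out <- list()

  if (mode %in% c("both", "transfer")) {
    if (is.null(part1))
      stop("dependency error: transfer mode requires the Part-I fold models", call. = FALSE)
    out$transfer <- lapply(config$tasks, function(task) {
      check_task(records, task)
      models <- part1[[task]]$fold_models
      prob_matrix <- do.call(rbind, lapply(models, function(m)
        predict(m, cohort$bags[records$slide_id])$p_mutant))
      scores <- ensemble_vote(prob_matrix)
      report <- eval_report(scores, records[[task]], task = task,
                            n_perm = config$n_perm,
                            seed = child_seed(config$cv_seed, "transfer", task))
      list(report = report, scores = scores, labels = as.logical(records[[task]]),
           slide_id = records$slide_id)
    })
    names(out$transfer) <- config$tasks
  }
  if (mode %in% c("both", "retrain")) {
    out$retrain <- lapply(config$tasks, function(task)
      run_cv(records, cohort$bags, task, k = config$cv_k, seed = config$cv_seed,
             hyperparams = config$hyperparams, n_perm = config$n_perm))
    names(out$retrain) <- config$tasks
  }
  write_manifest(config, "part2", list(cv_seed = config$cv_seed), config$out_dir)
  out
}

# Assemble per-patient streams from cohort records plus a wide table of
# per-gene slide probabilities.
build_patient_streams <- function(records, prob_table, genes) {
  idx <- match(records$slide_id, prob_table$slide_id)
  if (any(is.na(idx)))
    stop("consistency error: probabilities missing for some slides", call. = FALSE)
  lapply(split(seq_len(nrow(records)), records$patient_id), function(rows) {
    rows <- rows[order(records$biopsy_order[rows])]
    truth <- vapply(genes, function(g) as.logical(records[[g]][rows[1]]), logical(1))
    probs <- as.matrix(prob_table[idx[rows], genes, drop = FALSE])
    patient_stream(records$patient_id[rows[1]], records$biopsy_order[rows],
                   records$pass_status[rows], truth, probs)
  })
}

#' Part III: all-slide models and the biopsy re-checking simulation
#'
#' Runs per-gene cross-validation over all slides (Pass and No-Pass), keeps
#' the held-out probability of every slide, derives one decision threshold
#' per gene (the mean of the per-fold training-set balanced thresholds), and
#' replays each patient's biopsy sequence through [reduction_summary()].
#' When a consecutive-style cohort is supplied, one model per gene is
#' additionally trained on the full primary cohort and applied to the second
#' cohort's streams with the primary training thresholds.
#'
#' @param config An [experiment_config()]; its `subset` is forced to
#'   `"all"`.
#' @param consecutive_cohort Optional second cohort (same feature space) for
#'   the consecutive-style evaluation.
#' @return A list with `cv` (per-gene [run_cv()] results), `thresholds`,
#'   `recheck` (a `rebiopsy_result`), `early` (first/second-biopsy metrics)
#'   and, when requested, `consecutive` (reports, thresholds and
#'   `rebiopsy_result` for the second cohort).
#' @export
run_part3 <- function(config, consecutive_cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- resolve_cohort(config$cohort)
  records <- cohort$records
  genes <- config$tasks

  cv <- lapply(genes, function(task)
    run_cv(records, cohort$bags, task, k = config$cv_k, seed = config$cv_seed,
           hyperparams = config$hyperparams, n_perm = config$n_perm))
  names(cv) <- genes

  prob_table <- data.frame(slide_id = records$slide_id, stringsAsFactors = FALSE)
  for (g in genes) {
    p <- cv[[g]]$predictions
    prob_table[[g]] <- p$score[match(records$slide_id, p$slide_id)]
  }
  thresholds <- vapply(genes, function(g) mean(cv[[g]]$fold_thresholds), numeric(1))

  streams <- build_patient_streams(records, prob_table, genes)
  recheck <- reduction_summary(streams, thresholds, mode = config$recheck_mode)
  early <- early_biopsy_metrics(streams)

  out <- list(cv = cv, thresholds = thresholds, recheck = recheck,
              early = early, streams = streams)

  if (!is.null(consecutive_cohort)) {
    cons <- resolve_cohort(consecutive_cohort)
    cons_probs <- data.frame(slide_id = cons$records$slide_id,
                             stringsAsFactors = FALSE)
    cons_thresholds <- numeric(length(genes)); names(cons_thresholds) <- genes
    cons_reports <- list()
    for (g in genes) {
      hp <- with_fold_seed(config$hyperparams, child_seed(config$cv_seed, "full", g))
      model <- train_classifier(cohort$bags[records$slide_id], records[[g]], hp)
      train_scores <- predict(model, cohort$bags[records$slide_id])$p_mutant
      cons_thresholds[g] <- balanced_threshold(train_scores, records[[g]])$threshold
      scores <- predict(model, cons$bags[cons$records$slide_id])$p_mutant
      cons_probs[[g]] <- scores
      cons_reports[[g]] <- eval_report(scores, cons$records[[g]], task = g,
                                       n_perm = config$n_perm,
                                       seed = child_seed(config$cv_seed, "cons", g))
    }
    cons_streams <- build_patient_streams(cons$records, cons_probs, genes)
    out$consecutive <- list(reports = cons_reports, thresholds = cons_thresholds,
                            recheck = reduction_summary(cons_streams, cons_thresholds,
                                                        mode = config$recheck_mode),
                            streams = cons_streams)
  }
  write_manifest(config, "part3", list(cv_seed = config$cv_seed), config$out_dir)
  out
}

#' Dual validation: pilocytic-astrocytoma identification
#'
#' Five-fold patient-level cross-validation (8:2 train-test split) on the
#' PA label over Pass slides, with the same machinery as Part I.
#'
#' @param config An [experiment_config()]; `tasks` is replaced by
#'   `"pa_label"` and `cv_k` by 5 unless already 5.
#' @return A [run_cv()] result for the PA task.
#' @export
run_dual_validation <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- resolve_cohort(config$cohort)
  records <- subset_records(cohort$records, "pass")
  if (!"pa_label" %in% names(records))
    stop("configuration error: cohort has no 'pa_label' column", call. = FALSE)
  res <- run_cv(records, cohort$bags, "pa_label", k = 5L, seed = config$cv_seed,
                hyperparams = config$hyperparams, n_perm = config$n_perm,
                ratio = "8:2")
  res$task <- "PA"
  res$report$task <- "PA"
  write_manifest(config, "dual", list(cv_seed = config$cv_seed), config$out_dir)
  res
}
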