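# Retrospective biopsy re-checking simulation.
#
# For each patient, slides are replayed strictly in biopsy arrival order.
# The human biopsy count is the order of the first Pass slide (the pathologist
# keeps requesting tissue until a slide passes). The AI count is the order of
# the first slide at which the model correctly flags any truly mutant gene
# (probability >= that gene's training-derived threshold). Patients with no
# mutant gene — and, under the cap rule, mutant patients the model never
# flags — fall back to the human count, so the AI can only save biopsies,
# never add them. The analysis is optimistic by construction (ground-truth
# mutation status is unavailable intraoperatively) and reports carry that
# caveat.

#' Construct a patient biopsy stream
#'
#' @param patient_id Patient identifier.
#' @param biopsy_order Integer vector of arrival orders (strictly
#'   increasing).
#' @param pass_status Character vector, `"Pass"`/`"No-Pass"`, parallel to
#'   `biopsy_order`.
#' @param truth Named logical vector of per-gene ground-truth mutant status.
#' @param probs Matrix of predicted mutant probabilities, slides x genes
#'   (column names = gene names).
#' @return An object of class `patient_stream`.
#' @export
patient_stream <- function(patient_id, biopsy_order, pass_status, truth, probs) {
  if (length(biopsy_order) < 1) stop("empty stream for patient ", patient_id, call. = FALSE)
  if (any(diff(biopsy_order) <= 0))
    stop("biopsy_order must be strictly increasing", call. = FALSE)
  if (length(pass_status) != length(biopsy_order))
    stop("pass_status must be parallel to biopsy_order", call. = FALSE)
  probs <- as.matrix(probs)
  if (nrow(probs) != length(biopsy_order))
    stop("probs must have one row per biopsy", call. = FALSE)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (is.null(names(truth)) || is.null(colnames(probs)) ||
      !all(names(truth) %in% colnames(probs)))
    stop("consistency error: probs must cover every gene in truth", call. = FALSE)
  structure(list(patient_id = patient_id, biopsy_order = as.integer(biopsy_order),
                 pass_status = pass_status, truth = truth,
                 probs = probs[, names(truth), drop = FALSE]),
            class = "patient_stream")
}

#' Human biopsy count for one patient
#'
#' The 1-based order of the first Pass slide; when no slide passed, the
#' total number of biopsies taken.
#'
#' @param stream A [patient_stream()].
#' @return Integer count.
#' @export
human_biopsy_count <- function(stream) {
  stopifnot(inherits(stream, "patient_stream"))
  first_pass <- which(stream$pass_status == "Pass")
  if (length(first_pass)) first_pass[1] else length(stream$pass_status)
}

#' AI biopsy count for one patient
#'
#' The 1-based order of the first slide at which the model accurately flags
#' a mutant: in the default `"strict"` mode some gene must be both truly
#' mutant and predicted positive at its threshold; in `"lenient"` mode any
#' positive call counts (for mutant patients). Patients with no mutant gene
#' fall back to the human count; with `cap = TRUE` (default), mutant
#' patients never flagged are likewise capped at the human count.
#'
#' @param stream A [patient_stream()].
#' @param thresholds Named numeric vector of per-gene decision thresholds
#'   (estimated on training data, never refit on the stream being scored).
#' @param mode `"strict"` (gene-matched correctness) or `"lenient"`.
#' @param cap If FALSE, return the raw first-detection count, leaving mutant
#'   patients the model never flags at the human count but not truncating a
#'   late detection.
#' @return Integer count.
#' @export
ai_biopsy_count <- function(stream, thresholds, mode = c("strict", "lenient"),
                            cap = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(stream, "patient_stream"))
  genes <- names(stream$truth)
  if (is.null(names(thresholds)) || !all(genes %in% names(thresholds)))
    stop("consistency error: thresholds must cover gene(s) ",
         paste(setdiff(genes, names(thresholds)), collapse = ", "), call. = FALSE)
  human <- human_biopsy_count(stream)
  if (!any(stream$truth)) return(human)  # no mutant: AI cannot reduce

  hits <- sapply(genes, function(g) stream$probs[, g] >= thresholds[g])
  hits <- matrix(hits, nrow = nrow(stream$probs))
  relevant <- if (mode == "strict") hits[, stream$truth, drop = FALSE] else hits
  detected <- which(rowSums(relevant) > 0)
  if (!length(detected)) return(human)  # never flagged: cap at human count
  first <- detected[1]
  if (cap) min(first, human) else first
}

#' Summarise biopsy reduction across a cohort
#'
#' Computes per-patient human and AI biopsy counts, their totals and means,
#' the number of biopsies saved and the reduction ratio, a one-sided paired
#' t-test of human > AI, and the Sankey transition counts between human and
#' AI biopsy numbers.
#'
#' @param streams List of [patient_stream()]s.
#' @param thresholds Named per-gene decision thresholds.
#' @param mode Detection mode, see [ai_biopsy_count()].
#' @return An object of class `rebiopsy_result`: `per_patient` (data.frame
#'   patient_id, human_count, ai_count, ai_count_raw), `total_human`,
#'   `total_ai`, `saved`, `mean_human`, `mean_ai`, `reduction_ratio`,
#'   `t_statistic`, `df`, `p_value`, `sankey` (data.frame human_count,
#'   ai_count, key, n) and a `caveat` noting the optimistic design.
#' @export
reduction_summary <- function(streams, thresholds, mode = "strict") {
  per <- do.call(rbind, lapply(streams, function(s) data.frame(
    patient_id = s$patient_id,
    human_count = human_biopsy_count(s),
    ai_count = ai_biopsy_count(s, thresholds, mode = mode),
    ai_count_raw = ai_biopsy_count(s, thresholds, mode = mode, cap = FALSE),
    stringsAsFactors = FALSE)))
  rownames(per) <- NULL

  total_human <- sum(per$human_count)
  total_ai <- sum(per$ai_count)
  saved <- total_human - total_ai

  if (nrow(per) >= 2) {
    d <- per$human_count - per$ai_count
    if (stats::sd(d) == 0) {
      t_stat <- if (mean(d) > 0) Inf else 0
      p <- if (mean(d) > 0) 0 else 0.5
    } else {
      t_stat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
      p <- stats::pt(t_stat, length(d) - 1, lower.tail = FALSE)
    }
    df <- nrow(per) - 1L
  } else {
    warning("statistics error: fewer than 2 patients; paired test not computed")
    t_stat <- NA_real_; p <- NA_real_; df <- NA_integer_
  }

  structure(list(per_patient = per, total_human = total_human,
                 total_ai = total_ai, saved = saved,
                 mean_human = total_human / nrow(per),
                 mean_ai = total_ai / nrow(per),
                 reduction_ratio = saved / total_human,
                 t_statistic = t_stat, df = df, p_value = p,
                 sankey = sankey_counts(per),
                 caveat = paste("optimistic: assumes ground-truth mutation",
                                "status is known when scoring detections")),
            class = "rebiopsy_result")
}

#' @export
print.rebiopsy_result <- function(x, ...) {
  cat(sprintf("<rebiopsy_result> %d patients: human %d biopsies (mean %.2f), AI %d (mean %.2f)\n",
              nrow(x$per_patient), x$total_human, x$mean_human, x$total_ai, x$mean_ai))
  cat(sprintf("  saved %d (%.1f%%), one-sided paired t(%d) = %.2f, p = %.3g\n",
              x$saved, 100 * x$reduction_ratio, x$df, x$t_statistic, x$p_value))
  cat("  note:", x$caveat, "\n")
  invisible(x)
}

#' Sankey transition counts between human and AI biopsy numbers
#'
#' @param per_patient data.frame with `human_count` and `ai_count` columns
#'   (as in a [reduction_summary()] result), or a `rebiopsy_result`.
#' @return data.frame of human_count, ai_count, key (`"Hn->Am"`), n; the n
#'   column sums to the number of patients.
#' @export
sankey_counts <- function(per_patient) {
  if (inherits(per_patient, "rebiopsy_result")) per_patient <- per_patient$per_patient
  tab <- as.data.frame(table(human = per_patient$human_count,
                             ai = per_patient$ai_count),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  out <- data.frame(human_count = as.integer(tab$human),
                    ai_count = as.integer(tab$ai),
                    key = sprintf("H%s->A%s", tab$human, tab$ai),
                    n = tab$Freq, stringsAsFactors = FALSE)
  out <- out[order(out$human_count, out$ai_count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prediction metrics from the first one and two biopsies
#'
#' For each gene: the one-biopsy metrics use each patient's first-slide
#' mutant probability; the two-biopsy metrics use the elementwise mean of
#' the first and second slide probabilities over the patients with at least
#' two slides. AUC and balanced-threshold ACC/SEN/SPE come from the
#' evaluation module.
#'
#' @param streams List of [patient_stream()]s.
#' @return A named list per gene, each with `one` and (when any patient has
#'   two slides) `two`, holding `auc`, `acc`, `sen`, `spe`, `n`.
#' @export
early_biopsy_metrics <- function(streams) {
  genes <- names(streams[[1]]$truth)
  out <- list()
  has_two <- vapply(streams, function(s) length(s$biopsy_order) >= 2, logical(1))
  if (!any(has_two))
    warning("no patient has two biopsies; two-biopsy metrics omitted")
  for (g in genes) {
    labels <- vapply(streams, function(s) s$truth[[g]], logical(1))
    if (length(unique(labels)) < 2) {
      out[[g]] <- list(one = NULL, note = "single-class truth; metrics undefined")
      next
    }
    first <- vapply(streams, function(s) s$probs[1, g], numeric(1))
    bal1 <- balanced_threshold(first, labels)
    res <- list(one = list(auc = auc_value(first, labels), acc = bal1$acc,
                           sen = bal1$sen, spe = bal1$spe, n = length(first)))
    if (any(has_two)) {
      two_scores <- vapply(streams[has_two],
                           function(s) mean(s$probs[1:2, g]), numeric(1))
      two_labels <- labels[has_two]
      if (length(unique(two_labels)) == 2) {
        bal2 <- balanced_threshold(two_scores, two_labels)
        res$two <- list(auc = auc_value(two_scores, two_labels), acc = bal2$acc,
                        sen = bal2$sen, spe = bal2$spe, n = length(two_scores))
      }
    }
    out[[g]] <- res
  }
  out
}
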