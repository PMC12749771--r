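# Small reporting utilities for published-count worked examples: aggregate
# biopsy-reduction arithmetic from cohort totals, and adjudication fractions
# from pathologist patch/slide review counts.

#' Biopsy-reduction arithmetic from cohort totals
#'
#' Computes the summary statistics of a re-checking analysis directly from
#' aggregate counts: total human biopsies, number of patients, and the
#' number of biopsies the AI policy saves.
#'
#' @param total_human Total biopsies taken by the human workflow.
#' @param n_patients Number of patients.
#' @param saved Biopsies saved by the AI policy (total_human - total_ai).
#' @return A list with `mean_human`, `mean_ai`, `total_ai`,
#'   `reduction_ratio` and `reduction_percent`.
#' @export
biopsy_reduction_totals <- function(total_human, n_patients, saved) {
  if (saved < 0 || saved > total_human)
    stop("'saved' must be between 0 and total_human", call. = FALSE)
  if (n_patients < 1) stop("'n_patients' must be >= 1", call. = FALSE)
  total_ai <- total_human - saved
  list(mean_human = total_human / n_patients,
       mean_ai = total_ai / n_patients,
       total_ai = total_ai,
       reduction_ratio = saved / total_human,
       reduction_percent = 100 * saved / total_human)
}

#' Adjudication fractions from review counts
#'
#' Converts pathologist adjudication counts (e.g. of top predictive patches
#' grouped as malignant / uncertain / benign, or of slides with tumour cells
#' identified) into percentages of their total.
#'
#' @param counts Named numeric vector of category counts.
#' @param total Denominator; defaults to `sum(counts)`.
#' @return Named numeric vector of percentages.
#' @export
adjudication_fractions <- function(counts, total = sum(counts)) {
  if (any(counts < 0) || total <= 0)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  100 * counts / total
}
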