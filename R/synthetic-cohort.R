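# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: bags of
# patch feature vectors per slide, Pass/No-Pass verdicts along ordered biopsy
# sequences, per-patient gene mutation labels shared by all of the patient's
# slides, an optional pilocytic-astrocytoma label, and additive centre batch
# offsets. Mutant slides carry a configurable fraction of "signal" patches
# whose features are mean-shifted along a gene-specific unit direction;
# No-Pass slides carry sparser signal plus a weaker peritumoural shift in
# part of the background.

round_half_up <- function(x) floor(x + 0.5)

check_prob <- function(value, field) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0) || any(value > 1))
    stop("configuration error: '", field, "' must be a probability in [0, 1]", call. = FALSE)
  invisible(value)
}

check_count <- function(value, field, min = 1L) {
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) ||
      value != as.integer(value) || value < min)
    stop("configuration error: '", field, "' must be an integer >= ", min, call. = FALSE)
  invisible(as.integer(value))
}

#' Configuration for a synthetic cryosection cohort
#'
#' Defines the study conditions a generated cohort emulates: cohort size,
#' feature dimension, per-gene mutant prevalence, the fraction and magnitude
#' of signal patches in Pass and No-Pass slides of mutant patients, a weaker
#' peritumoural shift in No-Pass background patches, bag sizes, centre batch
#' effects, the order-dependent No-Pass rate governing biopsy sequences, and
#' the pilocytic-astrocytoma (PA) prevalence.
#'
#' Background patch features are standard multivariate normal; each gene (and
#' the PA label) owns a fixed unit direction, orthogonalised across genes, and
#' signal patches are shifted by `effect_size` along the directions of the
#' slide's mutant genes. The number of signal patches is
#' `round(fraction * bag size)` (half-up).
#'
#' @param n_patients Number of patients.
#' @param feature_dim Patch feature dimension (the foundation-model embedding
#'   width; 768 in the reference configuration).
#' @param genes Character vector of gene names.
#' @param prevalence Per-gene mutant prevalence; scalar or named vector.
#' @param signal_fraction_pass Fraction of signal patches in Pass slides of
#'   mutant patients.
#' @param signal_fraction_nopass Fraction in No-Pass slides; must not exceed
#'   `signal_fraction_pass`.
#' @param effect_size Mean-shift magnitude of signal patches along the gene
#'   direction, in units of the unit background standard deviation.
#' @param peritumoural_effect Weaker shift applied to a fraction of non-signal
#'   patches in No-Pass mutant slides (peritumoural morphology cue).
#' @param peritumoural_fraction Fraction of non-signal patches receiving the
#'   peritumoural shift in No-Pass mutant slides.
#' @param bag_size_range Length-2 integer vector, min/max patches per slide.
#' @param n_centres Number of centres; each centre contributes an additive
#'   feature offset.
#' @param centre_offset_scale Standard deviation of centre offset entries.
#' @param nopass_rate_by_order Probability that biopsy k of a patient is
#'   No-Pass, one entry per possible biopsy; its length caps the number of
#'   biopsies per patient. Should be non-increasing in k.
#' @param pa_prevalence Probability of the pilocytic-astrocytoma label.
#' @param seed Root seed; per-patient/slide child streams are derived from it
#'   by stable hashing, so content is independent of generation order.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [generate_feature_bag()]
#' @export
cohort_config <- function(n_patients,
                          feature_dim = 768L,
                          genes = c("ATRX", "H3K27M", "TP53"),
                          prevalence = 0.5,
                          signal_fraction_pass = 0.3,
                          signal_fraction_nopass = 0.1,
                          effect_size = 1.5,
                          peritumoural_effect = 0.5,
                          peritumoural_fraction = 0.2,
                          bag_size_range = c(24L, 64L),
                          n_centres = 3L,
                          centre_offset_scale = 0.1,
                          nopass_rate_by_order = c(0.45, 0.35, 0.25, 0.15, 0.10, 0),
                          pa_prevalence = 0.1,
                          seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients", min = 0L)
  feature_dim <- check_count(feature_dim, "feature_dim")
  if (!is.character(genes) || length(genes) < 1 || anyDuplicated(genes))
    stop("configuration error: 'genes' must be distinct gene names", call. = FALSE)
  if (length(prevalence) == 1) prevalence <- stats::setNames(rep(prevalence, length(genes)), genes)
  if (is.null(names(prevalence))) names(prevalence) <- genes
  if (!setequal(names(prevalence), genes))
    stop("configuration error: 'prevalence' names must match 'genes'", call. = FALSE)
  check_prob(prevalence, "prevalence")
  check_prob(signal_fraction_pass, "signal_fraction_pass")
  check_prob(signal_fraction_nopass, "signal_fraction_nopass")
  if (signal_fraction_nopass > signal_fraction_pass)
    stop("configuration error: 'signal_fraction_nopass' must not exceed 'signal_fraction_pass'",
         call. = FALSE)
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("configuration error: 'effect_size' must be >= 0", call. = FALSE)
  if (!is.numeric(peritumoural_effect) || peritumoural_effect < 0)
    stop("configuration error: 'peritumoural_effect' must be >= 0", call. = FALSE)
  check_prob(peritumoural_fraction, "peritumoural_fraction")
  if (length(bag_size_range) != 2 || bag_size_range[1] < 1 || bag_size_range[2] < bag_size_range[1])
    stop("configuration error: 'bag_size_range' must be c(min, max) with min >= 1", call. = FALSE)
  n_centres <- check_count(n_centres, "n_centres")
  if (!is.numeric(centre_offset_scale) || centre_offset_scale < 0)
    stop("configuration error: 'centre_offset_scale' must be >= 0", call. = FALSE)
  check_prob(nopass_rate_by_order, "nopass_rate_by_order")
  check_prob(pa_prevalence, "pa_prevalence")
  if (feature_dim < length(genes) + 1)
    stop("configuration error: 'feature_dim' must be >= number of genes + 1 ",
         "(orthogonal signal directions)", call. = FALSE)
  seed <- check_count(seed, "seed", min = 0L)

  structure(list(
    n_patients = n_patients, feature_dim = feature_dim, genes = genes,
    prevalence = prevalence[genes],
    signal_fraction_pass = signal_fraction_pass,
    signal_fraction_nopass = signal_fraction_nopass,
    effect_size = effect_size,
    peritumoural_effect = peritumoural_effect,
    peritumoural_fraction = peritumoural_fraction,
    bag_size_range = as.integer(bag_size_range),
    n_centres = n_centres, centre_offset_scale = centre_offset_scale,
    nopass_rate_by_order = nopass_rate_by_order,
    pa_prevalence = pa_prevalence, seed = seed
  ), class = "cohort_config")
}

# Orthonormal signal directions: one column per gene plus one for PA.
# Deterministic given the config seed.
signal_directions <- function(config) {
  k <- length(config$genes) + 1L
  with_seed(child_seed(config$seed, "directions"), {
    m <- matrix(rnorm(config$feature_dim * k), config$feature_dim, k)
    q <- qr.Q(qr(m))[, seq_len(k), drop = FALSE]
    colnames(q) <- c(config$genes, ".pa")
    q
  })
}

# Additive centre batch offsets, one row per centre.
centre_offsets <- function(config) {
  with_seed(child_seed(config$seed, "centres"), {
    matrix(rnorm(config$n_centres * config$feature_dim, sd = config$centre_offset_scale),
           config$n_centres, config$feature_dim)
  })
}

#' Construct a feature bag
#'
#' A feature bag is one slide's set of patch feature vectors (one row per
#' patch) together with the level-0 pixel coordinate of each patch's top-left
#' corner, and — for synthetic data only — a ground-truth mask of signal
#' patches.
#'
#' @param slide_id Slide identifier.
#' @param features Numeric matrix, patches x feature_dim; all entries finite.
#' @param patch_coords Integer matrix, patches x 2 (columns x, y).
#' @param signal_mask Optional logical vector marking ground-truth signal
#'   patches.
#' @return An object of class `feature_bag`.
#' @export
feature_bag <- function(slide_id, features, patch_coords, signal_mask = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 1) stop("feature bag must contain at least one patch", call. = FALSE)
  if (!all(is.finite(features))) stop("feature bag contains non-finite values", call. = FALSE)
  patch_coords <- as.matrix(patch_coords)
  if (nrow(patch_coords) != nrow(features) || ncol(patch_coords) != 2)
    stop("patch_coords must have one (x, y) row per patch", call. = FALSE)
  if (!is.null(signal_mask) && length(signal_mask) != nrow(features))
    stop("signal_mask length must equal the number of patches", call. = FALSE)
  colnames(patch_coords) <- c("x", "y")
  structure(list(slide_id = slide_id, features = features,
                 patch_coords = patch_coords, signal_mask = signal_mask),
            class = "feature_bag")
}

#' @export
print.feature_bag <- function(x, ...) {
  cat("<feature_bag> ", x$slide_id, ": ", nrow(x$features), " patches x ",
      ncol(x$features), " features", sep = "")
  if (!is.null(x$signal_mask)) cat(" (", sum(x$signal_mask), " signal)", sep = "")
  cat("\n")
  invisible(x)
}

# Default deterministic patch grid for synthetic bags: row-major square-ish
# grid with a 224 px stride.
synthetic_patch_grid <- function(n, patch = 224L) {
  per_row <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  cbind(x = (idx %% per_row) * patch, y = (idx %/% per_row) * patch)
}

#' Generate one synthetic feature bag
#'
#' Draws a bag of background-normal patch features and shifts a
#' `round(fraction * N)` subset (the signal patches) by `effect_size` along
#' the direction of every mutant gene; the applicable fraction depends on the
#' slide's Pass/No-Pass status. In No-Pass slides of mutant patients a
#' further `peritumoural_fraction` of the background patches is shifted by
#' the weaker `peritumoural_effect`. Finally the slide's centre offset is
#' added to all rows.
#'
#' @param gene_labels Named logical vector (TRUE = mutant), one entry per
#'   configured gene.
#' @param pass_status `"Pass"` or `"No-Pass"`.
#' @param config A [cohort_config()].
#' @param rng_seed Seed for this bag's private RNG stream.
#' @param slide_id Identifier stored in the bag.
#' @param pa_label Logical; if TRUE the PA direction is added to signal
#'   patches as well.
#' @param centre_id Integer centre index in `1:n_centres`.
#' @return A [feature_bag()] with `signal_mask` set.
#' @export
generate_feature_bag <- function(gene_labels, pass_status, config,
                                 rng_seed = config$seed, slide_id = "slide",
                                 pa_label = FALSE, centre_id = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (!pass_status %in% c("Pass", "No-Pass"))
    stop("pass_status must be 'Pass' or 'No-Pass'", call. = FALSE)
  if (is.null(names(gene_labels))) names(gene_labels) <- config$genes
  if (!setequal(names(gene_labels), config$genes))
    stop("gene_labels names must match the configured genes", call. = FALSE)
  gene_labels <- gene_labels[config$genes]
  if (centre_id < 1 || centre_id > config$n_centres)
    stop("centre_id out of range", call. = FALSE)

  dirs <- signal_directions(config)
  offs <- centre_offsets(config)

  with_seed(rng_seed, {
    n <- if (config$bag_size_range[1] == config$bag_size_range[2]) config$bag_size_range[1]
         else sample(config$bag_size_range[1]:config$bag_size_range[2], 1L)
    x <- matrix(rnorm(n * config$feature_dim), n, config$feature_dim)

    frac <- if (pass_status == "Pass") config$signal_fraction_pass else config$signal_fraction_nopass
    has_target <- any(gene_labels) || isTRUE(pa_label)
    n_sig <- if (has_target) round_half_up(frac * n) else 0L
    mask <- rep(FALSE, n)
    if (n_sig > 0) {
      sig_idx <- sample.int(n, n_sig)
      mask[sig_idx] <- TRUE
      shift <- numeric(config$feature_dim)
      for (g in config$genes[gene_labels]) shift <- shift + config$effect_size * dirs[, g]
      if (isTRUE(pa_label)) shift <- shift + config$effect_size * dirs[, ".pa"]
      x[sig_idx, ] <- sweep(x[sig_idx, , drop = FALSE], 2, shift, `+`)
    }

    if (pass_status == "No-Pass" && any(gene_labels) && config$peritumoural_fraction > 0) {
      bg_idx <- which(!mask)
      n_peri <- round_half_up(config$peritumoural_fraction * length(bg_idx))
      if (n_peri > 0) {
        peri_idx <- bg_idx[sample.int(length(bg_idx), n_peri)]
        pshift <- numeric(config$feature_dim)
        for (g in config$genes[gene_labels]) pshift <- pshift + config$peritumoural_effect * dirs[, g]
        x[peri_idx, ] <- sweep(x[peri_idx, , drop = FALSE], 2, pshift, `+`)
      }
    }

    x <- sweep(x, 2, offs[centre_id, ], `+`)
    feature_bag(slide_id, x, synthetic_patch_grid(n), mask)
  })
}

#' Generate a full synthetic cohort
#'
#' For each patient: draws per-gene mutant labels (independent Bernoulli at
#' the configured prevalence, identical across all of the patient's slides),
#' a PA label, a centre, and an ordered biopsy sequence — biopsy k is No-Pass
#' with probability `nopass_rate_by_order[k]` and the patient keeps biopsying
#' until a Pass slide is drawn or the configured maximum (the length of
#' `nopass_rate_by_order`) is reached. Each slide then receives a feature bag
#' from [generate_feature_bag()] under its own child RNG stream.
#'
#' @param config A [cohort_config()].
#' @return A list with `records` (a data.frame of slide metadata: slide_id,
#'   patient_id, biopsy_order, pass_status, one logical column per gene,
#'   pa_label, centre_id) and `bags` (a named list of [feature_bag()]s,
#'   parallel to `records`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  empty <- data.frame(slide_id = character(), patient_id = character(),
                      biopsy_order = integer(), pass_status = character(),
                      stringsAsFactors = FALSE)
  for (g in config$genes) empty[[g]] <- logical()
  empty$pa_label <- logical()
  empty$centre_id <- character()
  if (config$n_patients == 0) return(list(records = empty, bags = list()))

  rows <- vector("list", config$n_patients)
  bags <- list()
  max_biopsies <- length(config$nopass_rate_by_order)
  width <- max(3L, nchar(as.character(config$n_patients)))

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%0*d", width, i)
    meta <- with_seed(child_seed(config$seed, "patient", i), {
      labels <- stats::setNames(runif(length(config$genes)) < config$prevalence, config$genes)
      pa <- runif(1) < config$pa_prevalence
      centre <- sample.int(config$n_centres, 1L)
      status <- character(0)
      for (k in seq_len(max_biopsies)) {
        nopass <- runif(1) < config$nopass_rate_by_order[k]
        status <- c(status, if (nopass) "No-Pass" else "Pass")
        if (!nopass) break
      }
      list(labels = labels, pa = pa, centre = centre, status = status)
    })

    patient_rows <- vector("list", length(meta$status))
    for (k in seq_along(meta$status)) {
      sid <- sprintf("%s_S%d", pid, k)
      bag <- generate_feature_bag(
        meta$labels, meta$status[k], config,
        rng_seed = child_seed(config$seed, "slide", i, k),
        slide_id = sid, pa_label = meta$pa, centre_id = meta$centre
      )
      bags[[sid]] <- bag
      row <- data.frame(slide_id = sid, patient_id = pid, biopsy_order = k,
                        pass_status = meta$status[k], stringsAsFactors = FALSE)
      for (g in config$genes) row[[g]] <- unname(meta$labels[g])
      row$pa_label <- meta$pa
      row$centre_id <- sprintf("C%d", meta$centre)
      patient_rows[[k]] <- row
    }
    rows[[i]] <- do.call(rbind, patient_rows)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records, bags = bags)
}
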