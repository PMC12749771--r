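# On-disk cohort container: a directory holding
#   cohort.json    — schema version tag, feature dimension, gene names
#   metadata.csv   — one row per slide (records table)
#   features/<slide_id>.bin — per-slide array file: magic "CRYF", version,
#                    dims, features (doubles, column-major), coords, and an
#                    optional signal mask.
# Numeric storage is lossless (native doubles), so write/read round-trips
# feature matrices exactly.

COHORT_SCHEMA <- "cryomil-cohort-1"
FEATURE_MAGIC <- "CRYF"

write_feature_bin <- function(bag, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(FEATURE_MAGIC, con, nchars = 4, eos = NULL)
  writeBin(1L, con)
  writeBin(c(nrow(bag$features), ncol(bag$features)), con)
  writeBin(as.numeric(bag$features), con)
  writeBin(as.integer(bag$patch_coords), con)
  has_mask <- !is.null(bag$signal_mask)
  writeBin(as.integer(has_mask), con)
  if (has_mask) writeBin(as.integer(bag$signal_mask), con)
  invisible(path)
}

read_feature_bin <- function(path, slide_id) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, FEATURE_MAGIC))
    stop("I/O error: '", path, "' is not a cryomil feature file", call. = FALSE)
  version <- readBin(con, "integer", 1)
  if (!identical(version, 1L))
    stop("schema version mismatch: feature file version ", version,
         " not supported", call. = FALSE)
  dims <- readBin(con, "integer", 2)
  feats <- matrix(readBin(con, "numeric", dims[1] * dims[2]), dims[1], dims[2])
  coords <- matrix(readBin(con, "integer", dims[1] * 2L), dims[1], 2L)
  mask <- if (readBin(con, "integer", 1) == 1L)
    as.logical(readBin(con, "integer", dims[1])) else NULL
  feature_bag(slide_id, feats, coords, mask)
}

#' Write a cohort to a directory
#'
#' Stores the slide metadata table as CSV and each slide's feature bag as a
#' small binary array file; numeric round trips are lossless.
#'
#' @param records Slide metadata data.frame as produced by
#'   [generate_cohort()].
#' @param bags Named list of [feature_bag()]s covering every `slide_id` in
#'   `records`.
#' @param path Directory to create (must not exist or be empty).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, bags, path) {
  missing_bags <- setdiff(records$slide_id, names(bags))
  if (length(missing_bags))
    stop("no bag supplied for slide(s): ", paste(missing_bags, collapse = ", "), call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "features"), showWarnings = FALSE)
  feature_dim <- if (length(bags)) ncol(bags[[1]]$features) else NA_integer_
  genes <- setdiff(names(records), c("slide_id", "patient_id", "biopsy_order",
                                     "pass_status", "pa_label", "centre_id"))
  jsonlite::write_json(
    list(schema = COHORT_SCHEMA, feature_dim = feature_dim, genes = genes,
         n_slides = nrow(records)),
    file.path(path, "cohort.json"), auto_unbox = TRUE)
  utils::write.csv(records, file.path(path, "metadata.csv"), row.names = FALSE)
  for (sid in records$slide_id)
    write_feature_bin(bags[[sid]], file.path(path, "features", paste0(sid, ".bin")))
  invisible(path)
}

#' Read a cohort from a directory
#'
#' @param path Directory written by [write_cohort()].
#' @return A list with `records` and `bags`, as from [generate_cohort()].
#' @export
read_cohort <- function(path) {
  if (!dir.exists(path))
    stop("I/O error: cohort directory '", path, "' does not exist", call. = FALSE)
  meta_path <- file.path(path, "cohort.json")
  if (!file.exists(meta_path))
    stop("I/O error: '", path, "' has no cohort.json", call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema, COHORT_SCHEMA))
    stop("schema version mismatch: found '", meta$schema, "', expected '",
         COHORT_SCHEMA, "'", call. = FALSE)
  records <- utils::read.csv(file.path(path, "metadata.csv"), stringsAsFactors = FALSE)
  for (g in meta$genes) records[[g]] <- as.logical(records[[g]])
  if ("pa_label" %in% names(records)) records$pa_label <- as.logical(records$pa_label)
  bags <- stats::setNames(
    lapply(records$slide_id, function(sid)
      read_feature_bin(file.path(path, "features", paste0(sid, ".bin")), sid)),
    records$slide_id)
  list(records = records, bags = bags)
}
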