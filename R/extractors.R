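# Pluggable patch-feature extraction.
#
# The production pipeline uses external pre-trained components (a
# cryosection-to-FFPE generative translator followed by a pathology
# foundation model) to turn patch pixels into 768-d embeddings; those weights
# are out of scope here. This module isolates them behind a registry of named
# extractors so the rest of the pipeline is agnostic to where features come
# from. Bundled extractors: `identity` (pass a synthetic feature bag
# through) and `random_projection` (a seeded linear projection of flattened
# pixels, for image-path integration runs). Entries for the external
# adapters validate shapes but carry no weights.

.extractor_registry <- new.env(parent = emptyenv())

#' Describe a feature extractor
#'
#' @param name Registry key.
#' @param output_dim Embedding width produced per patch.
#' @param requires_images TRUE when the extractor consumes pixel blocks
#'   rather than an existing feature bag.
#' @param description Free-text description.
#' @param fun Implementation: `function(input, spec, ...) -> feature matrix`
#'   (or feature_bag for bag-to-bag extractors). NULL for declared-only
#'   external adapters.
#' @return An object of class `extractor_spec`.
#' @export
extractor_spec <- function(name, output_dim = 768L, requires_images = TRUE,
                           description = "", fun = NULL) {
  if (!is.na(output_dim) && output_dim < 1)
    stop("configuration error: 'output_dim' must be >= 1", call. = FALSE)
  structure(list(name = name, output_dim = as.integer(output_dim),
                 requires_images = requires_images,
                 description = description, fun = fun),
            class = "extractor_spec")
}

#' Register a feature extractor
#'
#' @param spec An [extractor_spec()].
#' @return The spec, invisibly.
#' @export
register_extractor <- function(spec) {
  stopifnot(inherits(spec, "extractor_spec"))
  assign(spec$name, spec, envir = .extractor_registry)
  invisible(spec)
}

#' Look up a registered extractor
#'
#' @param name Registry key.
#' @return The [extractor_spec()].
#' @export
get_extractor <- function(name) {
  if (!exists(name, envir = .extractor_registry, inherits = FALSE))
    stop("lookup error: no extractor registered under '", name, "'", call. = FALSE)
  get(name, envir = .extractor_registry, inherits = FALSE)
}

#' List registered extractor names
#' @return Character vector of registry keys.
#' @export
list_extractors <- function() sort(ls(.extractor_registry))

#' Extract per-patch features
#'
#' Runs the named extractor over patch pixel blocks (or an existing feature
#' bag for bag-to-bag extractors), returning one feature row per input patch
#' in input order.
#'
#' @param input A [feature_bag()] (for extractors with
#'   `requires_images = FALSE`) or a list with `blocks` (RGB patch arrays)
#'   and `coords` as returned by [extract_patches()].
#' @param extractor Registry name or an [extractor_spec()].
#' @param slide_id Slide identifier for the output bag (ignored for
#'   bag-to-bag extractors, which keep the input id).
#' @param ... Passed to the extractor implementation.
#' @return A [feature_bag()] with `output_dim` columns.
#' @export
extract_features <- function(input, extractor, slide_id = "slide", ...) {
  spec <- if (inherits(extractor, "extractor_spec")) extractor else get_extractor(extractor)
  if (is.null(spec$fun))
    stop("extractor '", spec$name, "' is a declared external adapter without ",
         "bundled weights; supply an implementation to run it", call. = FALSE)
  if (spec$requires_images) {
    if (is.null(input$blocks) || is.null(input$coords))
      stop("extractor '", spec$name, "' requires pixel blocks ",
           "(use extract_patches(..., return_blocks = TRUE))", call. = FALSE)
    feats <- spec$fun(input$blocks, spec, ...)
    if (nrow(feats) != length(input$blocks) || ncol(feats) != spec$output_dim)
      stop("consistency error: extractor '", spec$name, "' returned ",
           nrow(feats), " x ", ncol(feats), ", expected ",
           length(input$blocks), " x ", spec$output_dim, call. = FALSE)
    feature_bag(slide_id, feats, as.matrix(input$coords[, c("x", "y")]))
  } else {
    if (!inherits(input, "feature_bag"))
      stop("extractor '", spec$name, "' consumes a feature_bag", call. = FALSE)
    out <- spec$fun(input, spec, ...)
    if (!inherits(out, "feature_bag") || nrow(out$features) != nrow(input$features))
      stop("consistency error: extractor '", spec$name,
           "' must preserve patch count", call. = FALSE)
    out
  }
}

register_builtin_extractors <- function() {
  register_extractor(extractor_spec(
    "identity", output_dim = NA_integer_, requires_images = FALSE,
    description = "Pass an existing (synthetic) feature bag through unchanged.",
    fun = function(bag, spec, ...) bag))

  register_extractor(extractor_spec(
    "random_projection", output_dim = 768L, requires_images = TRUE,
    description = paste("Seeded fixed random linear projection of flattened,",
                        "mean-centred pixel values; a deterministic synthetic",
                        "stand-in for a learned embedding."),
    fun = function(blocks, spec, seed = 7L, ...) {
      n_px <- length(blocks[[1]])
      proj <- with_seed(seed, matrix(rnorm(n_px * spec$output_dim, sd = 1 / sqrt(n_px)),
                                     n_px, spec$output_dim))
      t(vapply(blocks, function(p) as.vector((as.vector(p) - mean(p)) %*% proj),
               numeric(spec$output_dim)))
    }))

  # External pre-trained adapters: interface entries only (no weights bundled).
  register_extractor(extractor_spec(
    "ffpe_translation_chief", output_dim = 768L, requires_images = TRUE,
    description = paste("Adapter slot for the external cryosection-to-FFPE",
                        "translation followed by the CHIEF pathology foundation",
                        "model (applied frozen, without tuning); weights are",
                        "not distributed with this package."),
    fun = NULL))
  invisible(NULL)
}

# identity extractor needs no fixed output_dim; NA means "whatever comes in"
.onLoad <- function(libname, pkgname) {
  register_builtin_extractors()
}
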