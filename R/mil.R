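# Single-block Transformer MIL classifier.
#
# A slide is a bag x of N_x patch feature rows. One single-head
# self-attention block:
#
#   K = x W_K, Q = x W_Q, V = x W_V            (feature_dim -> attention_dim)
#   A = softmax(K Q^T)                         (N_x x N_x, row-wise softmax)
#   y_sa  = LN(x + MLP_att(A V))               (MLP restores feature_dim)
#   y_MLP = LN(y_sa + MLP_blk(y_sa))
#
# followed by mean pooling over patches and a linear head with softmax into
# (wild-type, mutant) probabilities. There is no positional embedding, so
# the slide probability is invariant to patch order. Scores are used
# unscaled by default (no 1/sqrt(d) factor); an optional scaling flag is
# provided. Layer normalisation is applied after each residual (post-norm).

MIL_LN_EPS <- 1e-5

#' Hyperparameters of the MIL Transformer classifier
#'
#' Defaults are the reference training configuration: one attention head with
#' encoding dimension 64, MLP width 1024, 80 epochs of Adam at learning rate
#' 1e-4 with weight decay 5e-3, one bag per optimisation step, inverse
#' class-frequency weighted sampling, and cross-entropy loss.
#'
#' @param feature_dim Patch feature width consumed by the block.
#' @param attention_dim Attention encoding dimension.
#' @param mlp_dim Hidden width of both two-layer MLPs (ReLU in between).
#' @param n_heads Number of attention heads; this architecture is
#'   single-head.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Bags per optimisation step; the training loop is
#'   defined for one bag per step.
#' @param weight_decay L2 penalty coupled into the Adam update.
#' @param scale_scores If TRUE, divide attention scores by
#'   sqrt(attention_dim); defaults to FALSE (unscaled scores).
#' @param seed Seed for weight initialisation and the sampling stream;
#'   training is deterministic given it.
#' @return An object of class `mil_hyperparams`.
#' @export
mil_hyperparams <- function(feature_dim = 768L, attention_dim = 64L,
                            mlp_dim = 1024L, n_heads = 1L, epochs = 80L,
                            learning_rate = 1e-4, batch_size = 1L,
                            weight_decay = 5e-3, scale_scores = FALSE,
                            seed = 1L) {
  for (f in c("feature_dim", "attention_dim", "mlp_dim", "n_heads", "epochs",
              "batch_size")) {
    v <- get(f)
    if (!is.numeric(v) || v < 1)
      stop("configuration error: '", f, "' must be >= 1", call. = FALSE)
  }
  if (n_heads != 1L) stop("configuration error: this block is single-head", call. = FALSE)
  if (batch_size != 1L)
    stop("configuration error: the training loop is defined for batch_size = 1", call. = FALSE)
  if (learning_rate <= 0) stop("configuration error: 'learning_rate' must be > 0", call. = FALSE)
  if (weight_decay < 0) stop("configuration error: 'weight_decay' must be >= 0", call. = FALSE)
  structure(list(feature_dim = as.integer(feature_dim),
                 attention_dim = as.integer(attention_dim),
                 mlp_dim = as.integer(mlp_dim), n_heads = 1L,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = 1L, weight_decay = weight_decay,
                 scale_scores = isTRUE(scale_scores), seed = as.integer(seed)),
            class = "mil_hyperparams")
}

# Uniform fan-in initialisation, as used for dense layers.
init_dense <- function(fan_in, fan_out) {
  bound <- 1 / sqrt(fan_in)
  list(W = matrix(runif(fan_in * fan_out, -bound, bound), fan_in, fan_out),
       b = runif(fan_out, -bound, bound))
}

#' Initialise an untrained MIL model
#'
#' Weights are drawn under `hyperparams$seed` with uniform fan-in scaling;
#' layer-norm gains start at 1 and shifts at 0.
#'
#' @param hyperparams A [mil_hyperparams()].
#' @return An object of class `mil_model`.
#' @export
mil_init <- function(hyperparams) {
  stopifnot(inherits(hyperparams, "mil_hyperparams"))
  d <- hyperparams$feature_dim; a <- hyperparams$attention_dim
  m <- hyperparams$mlp_dim
  params <- with_seed(hyperparams$seed, {
    kqv_bound <- 1 / sqrt(d)
    att <- init_dense(a, m); att2 <- init_dense(m, d)
    blk <- init_dense(d, m); blk2 <- init_dense(m, d)
    head <- init_dense(d, 2L)
    list(
      Wk = matrix(runif(d * a, -kqv_bound, kqv_bound), d, a),
      Wq = matrix(runif(d * a, -kqv_bound, kqv_bound), d, a),
      Wv = matrix(runif(d * a, -kqv_bound, kqv_bound), d, a),
      W1 = att$W, b1 = att$b, W2 = att2$W, b2 = att2$b,
      g1 = rep(1, d), be1 = rep(0, d),
      W3 = blk$W, b3 = blk$b, W4 = blk2$W, b4 = blk2$b,
      g2 = rep(1, d), be2 = rep(0, d),
      Wh = head$W, bh = head$b
    )
  })
  structure(list(params = params, hyperparams = hyperparams,
                 training_log = numeric(0)),
            class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  hp <- x$hyperparams
  cat("<mil_model> single-block Transformer MIL: feature_dim=", hp$feature_dim,
      ", attention_dim=", hp$attention_dim, ", mlp_dim=", hp$mlp_dim,
      if (length(x$training_log)) paste0(", trained ", length(x$training_log), " epochs")
      else ", untrained", "\n", sep = "")
  invisible(x)
}

row_softmax <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

layernorm_forward <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv_sd <- 1 / sqrt(rowMeans(xc * xc) + MIL_LN_EPS)
  xhat <- xc * inv_sd
  list(y = sweep(xhat * gamma[col(xhat)], 2, beta, `+`), xhat = xhat, inv_sd = inv_sd)
}

as_bag_matrix <- function(x, model) {
  if (inherits(x, "feature_bag")) x <- x$features
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty-bag error: bag has no patches", call. = FALSE)
  if (ncol(x) != model$hyperparams$feature_dim)
    stop("consistency error: bag feature dimension ", ncol(x),
         " does not match model feature_dim ", model$hyperparams$feature_dim,
         call. = FALSE)
  x
}

# Full forward pass with every intermediate needed for backprop.
mil_forward <- function(x, model) {
  p <- model$params
  n <- nrow(x)
  K <- x %*% p$Wk; Q <- x %*% p$Wq; V <- x %*% p$Wv
  S <- K %*% t(Q)
  if (model$hyperparams$scale_scores) S <- S / sqrt(model$hyperparams$attention_dim)
  A <- row_softmax(S)
  Z <- A %*% V
  H1pre <- sweep(Z %*% p$W1, 2, p$b1, `+`)
  H1 <- pmax(H1pre, 0)
  M1 <- sweep(H1 %*% p$W2, 2, p$b2, `+`)
  R1 <- x + M1
  ln1 <- layernorm_forward(R1, p$g1, p$be1)
  y_sa <- ln1$y
  H2pre <- sweep(y_sa %*% p$W3, 2, p$b3, `+`)
  H2 <- pmax(H2pre, 0)
  M2 <- sweep(H2 %*% p$W4, 2, p$b4, `+`)
  R2 <- y_sa + M2
  ln2 <- layernorm_forward(R2, p$g2, p$be2)
  y_mlp <- ln2$y
  pooled <- colMeans(y_mlp)
  logits <- as.vector(pooled %*% p$Wh) + p$bh
  prob <- { e <- exp(logits - max(logits)); e / sum(e) }
  list(x = x, n = n, K = K, Q = Q, V = V, A = A, Z = Z,
       H1pre = H1pre, H1 = H1, ln1 = ln1, y_sa = y_sa,
       H2pre = H2pre, H2 = H2, ln2 = ln2, y_mlp = y_mlp,
       pooled = pooled, logits = logits, prob = prob)
}

#' Self-attention forward pass
#'
#' Computes the attention weight matrix and the post-attention,
#' layer-normalised patch representations for one bag.
#'
#' @param x A [feature_bag()] or a patches x feature_dim matrix.
#' @param model A [mil_model()][mil_init].
#' @return A list with `A` (N_x x N_x attention weights, rows summing to 1)
#'   and `y_sa` (N_x x feature_dim).
#' @export
attention_forward <- function(x, model) {
  stopifnot(inherits(model, "mil_model"))
  fw <- mil_forward(as_bag_matrix(x, model), model)
  list(A = fw$A, y_sa = fw$y_sa)
}

#' Full Transformer block forward pass
#'
#' @inheritParams attention_forward
#' @return A list with `A`, `y_sa` and `y_MLP` (N_x x feature_dim, the block
#'   output after the second residual and layer normalisation).
#' @export
transformer_block <- function(x, model) {
  stopifnot(inherits(model, "mil_model"))
  fw <- mil_forward(as_bag_matrix(x, model), model)
  list(A = fw$A, y_sa = fw$y_sa, y_MLP = fw$y_mlp)
}

#' Slide-level class probabilities for one bag
#'
#' Mean-pools the Transformer block output over patches and applies the
#' linear head with softmax.
#'
#' @param bag A [feature_bag()] or feature matrix.
#' @param model A [mil_model()][mil_init].
#' @param threshold Optional decision threshold on the mutant probability;
#'   when supplied, a predicted label is attached (mutant iff
#'   `prob["mutant"] >= threshold`).
#' @return A list with `slide_id`, `prob` (named probability pair, sums
#'   to 1) and optionally `label`.
#' @export
slide_logits <- function(bag, model, threshold = NULL) {
  stopifnot(inherits(model, "mil_model"))
  x <- as_bag_matrix(bag, model)
  fw <- mil_forward(x, model)
  out <- list(slide_id = if (inherits(bag, "feature_bag")) bag$slide_id else NA_character_,
              prob = stats::setNames(fw$prob, c("wildtype", "mutant")))
  if (!is.null(threshold))
    out$label <- ifelse(fw$prob[2] >= threshold, "mutant", "wildtype")
  out
}

#' Predict slide probabilities for a list of bags
#'
#' @param object A trained [mil_model()][mil_init].
#' @param bags List of [feature_bag()]s (or feature matrices).
#' @param ... Unused.
#' @return A data.frame with one row per bag, in input order: `slide_id`,
#'   `p_wildtype`, `p_mutant`.
#' @export
predict.mil_model <- function(object, bags, ...) {
  if (length(bags) == 0)
    return(data.frame(slide_id = character(0), p_wildtype = numeric(0),
                      p_mutant = numeric(0)))
  rows <- lapply(seq_along(bags), function(i) {
    pr <- slide_logits(bags[[i]], object)
    data.frame(slide_id = if (is.na(pr$slide_id)) sprintf("bag_%d", i) else pr$slide_id,
               p_wildtype = unname(pr$prob[1]), p_mutant = unname(pr$prob[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

MIL_MODEL_SCHEMA <- "cryomil-model-1"

#' Save a MIL model to a single JSON archive
#'
#' The archive carries a schema version tag, the hyperparameters and all
#' parameter arrays at full precision.
#'
#' @param model A [mil_model()][mil_init].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_mil_model <- function(model, path) {
  stopifnot(inherits(model, "mil_model"))
  payload <- list(schema = MIL_MODEL_SCHEMA,
                  hyperparams = unclass(model$hyperparams),
                  training_log = model$training_log,
                  params = lapply(model$params, function(p) {
                    if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
                    else list(dim = NULL, data = as.vector(p))
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a MIL model saved by [save_mil_model()]
#'
#' @param path Archive file.
#' @return A [mil_model()][mil_init].
#' @export
load_mil_model <- function(path) {
  if (!file.exists(path)) stop("I/O error: '", path, "' does not exist", call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, MIL_MODEL_SCHEMA))
    stop("schema version mismatch: found '", payload$schema, "', expected '",
         MIL_MODEL_SCHEMA, "'", call. = FALSE)
  hp <- do.call(mil_hyperparams, payload$hyperparams[
    setdiff(names(payload$hyperparams), character(0))])
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[1], p$dim[2]) else as.numeric(p$data)
  })
  structure(list(params = params, hyperparams = hp,
                 training_log = as.numeric(payload$training_log)),
            class = "mil_model")
}
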