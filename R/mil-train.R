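# Training: cross-entropy loss, full backpropagation through the block, and
# Adam with decoupled-from-nothing L2 weight decay folded into the gradient
# (the classical Adam + weight_decay coupling). One bag per step; class
# imbalance is handled by an inverse class-frequency weighted sampler drawing
# with replacement, epoch length equal to the training-set size.

layernorm_backward <- function(dy, ln, gamma) {
  dxhat <- dy * gamma[col(dy)]
  dgamma <- colSums(dy * ln$xhat)
  dbeta <- colSums(dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * ln$xhat)
  dx <- ln$inv_sd * (dxhat - m1 - ln$xhat * m2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Gradient of the cross-entropy loss of one bag w.r.t. every parameter.
# `label` is 0 (wild-type) or 1 (mutant).
mil_backward <- function(fw, model, label) {
  p <- model$params
  n <- fw$n
  target <- c(1 - label, label)
  dlogits <- fw$prob - target

  dWh <- outer(fw$pooled, dlogits)
  dbh <- dlogits
  dpooled <- as.vector(p$Wh %*% dlogits)
  dy_mlp <- matrix(dpooled / n, n, length(dpooled), byrow = TRUE)

  ln2b <- layernorm_backward(dy_mlp, fw$ln2, p$g2)
  dR2 <- ln2b$dx
  dW4 <- crossprod(fw$H2, dR2)
  db4 <- colSums(dR2)
  dH2pre <- (dR2 %*% t(p$W4)) * (fw$H2pre > 0)
  dW3 <- crossprod(fw$y_sa, dH2pre)
  db3 <- colSums(dH2pre)
  dy_sa <- dR2 + dH2pre %*% t(p$W3)

  ln1b <- layernorm_backward(dy_sa, fw$ln1, p$g1)
  dR1 <- ln1b$dx
  dW2 <- crossprod(fw$H1, dR1)
  db2 <- colSums(dR1)
  dH1pre <- (dR1 %*% t(p$W2)) * (fw$H1pre > 0)
  dW1 <- crossprod(fw$Z, dH1pre)
  db1 <- colSums(dH1pre)
  dZ <- dH1pre %*% t(p$W1)

  dA <- dZ %*% t(fw$V)
  dV <- crossprod(fw$A, dZ)
  dS <- fw$A * (dA - rowSums(dA * fw$A))
  if (model$hyperparams$scale_scores)
    dS <- dS / sqrt(model$hyperparams$attention_dim)
  dK <- dS %*% fw$Q
  dQ <- crossprod(dS, fw$K)

  list(Wk = crossprod(fw$x, dK), Wq = crossprod(fw$x, dQ), Wv = crossprod(fw$x, dV),
       W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       g1 = ln1b$dgamma, be1 = ln1b$dbeta,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4,
       g2 = ln2b$dgamma, be2 = ln2b$dbeta,
       Wh = dWh, bh = dbh)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the MIL Transformer classifier
#'
#' Runs `epochs` passes of single-bag Adam steps over the training set. Each
#' epoch draws `length(bags)` bags with replacement, with probability
#' inversely proportional to class frequency, and records the mean
#' cross-entropy loss. Initialisation and the sampling stream are both
#' governed by `hyperparams$seed`, so training is deterministic given the
#' seed.
#'
#' @param bags List of [feature_bag()]s (or feature matrices).
#' @param labels Logical/0-1 vector, one slide label per bag (TRUE = mutant
#'   / positive class).
#' @param hyperparams A [mil_hyperparams()].
#' @return A trained [mil_model()][mil_init] with `training_log` holding the
#'   per-epoch mean loss.
#' @export
train_classifier <- function(bags, labels, hyperparams = mil_hyperparams()) {
  stopifnot(inherits(hyperparams, "mil_hyperparams"))
  labels <- as.integer(as.logical(labels))
  if (length(bags) != length(labels))
    stop("one label per bag is required", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("class-coverage error: training set must contain both classes", call. = FALSE)

  model <- mil_init(hyperparams)
  xs <- lapply(bags, function(b) as_bag_matrix(b, model))

  n <- length(xs)
  class_n <- table(factor(labels, levels = c(0, 1)))
  sample_w <- 1 / as.numeric(class_n)[labels + 1L]

  params <- model$params
  state <- adam_init(params)
  log_loss <- numeric(hyperparams$epochs)

  with_seed(child_seed(hyperparams$seed, "training"), {
    for (epoch in seq_len(hyperparams$epochs)) {
      idx <- sample.int(n, n, replace = TRUE, prob = sample_w)
      losses <- numeric(n)
      for (j in seq_len(n)) {
        i <- idx[j]
        model$params <- params
        fw <- mil_forward(xs[[i]], model)
        losses[j] <- -log(max(fw$prob[labels[i] + 1L], 1e-12))
        grads <- mil_backward(fw, model, labels[i])
        upd <- adam_step(params, grads, state,
                         hyperparams$learning_rate, hyperparams$weight_decay)
        params <- upd$params
        state <- upd$state
      }
      log_loss[epoch] <- mean(losses)
    }
  })

  model$params <- params
  model$training_log <- log_loss
  model
}
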