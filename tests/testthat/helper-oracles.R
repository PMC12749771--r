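# Independent straight-line oracles used to validate the vectorised
# implementations. Deliberately written with explicit loops and without any
# cryomil code path.

# triple-loop matrix multiply
mm <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(b)))
      for (k in seq_len(ncol(a)))
        out[i, j] <- out[i, j] + a[i, k] * b[k, j]
  out
}

oracle_softmax_rows <- function(s) {
  out <- matrix(0, nrow(s), ncol(s))
  for (i in seq_len(nrow(s))) {
    e <- exp(s[i, ] - max(s[i, ]))
    out[i, ] <- e / sum(e)
  }
  out
}

oracle_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    mu <- mean(x[i, ])
    v <- mean((x[i, ] - mu)^2)
    out[i, ] <- gamma * (x[i, ] - mu) / sqrt(v + eps) + beta
  }
  out
}

oracle_mlp <- function(x, W1, b1, W2, b2) {
  h <- mm(x, W1)
  for (i in seq_len(nrow(h))) h[i, ] <- pmax(h[i, ] + b1, 0)
  out <- mm(h, W2)
  for (i in seq_len(nrow(out))) out[i, ] <- out[i, ] + b2
  out
}

# Full straight-line forward pass of the one-block Transformer MIL model.
oracle_forward <- function(x, p, scale_scores = FALSE, attention_dim = ncol(p$Wk)) {
  K <- mm(x, p$Wk); Q <- mm(x, p$Wq); V <- mm(x, p$Wv)
  S <- mm(K, t(Q))
  if (scale_scores) S <- S / sqrt(attention_dim)
  A <- oracle_softmax_rows(S)
  y_sa <- oracle_layernorm(x + oracle_mlp(mm(A, V), p$W1, p$b1, p$W2, p$b2),
                           p$g1, p$be1)
  y_mlp <- oracle_layernorm(y_sa + oracle_mlp(y_sa, p$W3, p$b3, p$W4, p$b4),
                            p$g2, p$be2)
  pooled <- numeric(ncol(y_mlp))
  for (j in seq_len(ncol(y_mlp))) pooled[j] <- mean(y_mlp[, j])
  logits <- as.vector(mm(matrix(pooled, 1), p$Wh)) + p$bh
  e <- exp(logits - max(logits))
  list(A = A, y_sa = y_sa, y_mlp = y_mlp, prob = e / sum(e))
}

# O(n^2) pairwise AUC with ties counted one half.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Tiny deterministic model with hand-set weights, small enough to reason
# about; a structured (non-random) filling so failures are reproducible.
hand_model <- function(d = 4L, a = 3L, m = 5L, scale_scores = FALSE) {
  hp <- cryomil::mil_hyperparams(feature_dim = d, attention_dim = a, mlp_dim = m,
                                 scale_scores = scale_scores, seed = 1L)
  model <- cryomil::mil_init(hp)
  fill <- function(nr, nc, start) matrix(seq(start, by = 0.01, length.out = nr * nc) *
                                           rep(c(1, -1), length.out = nr * nc), nr, nc)
  model$params <- list(
    Wk = fill(d, a, 0.05), Wq = fill(d, a, 0.10), Wv = fill(d, a, 0.15),
    W1 = fill(a, m, 0.02), b1 = seq(-0.02, by = 0.01, length.out = m),
    W2 = fill(m, d, 0.03), b2 = seq(0.01, by = 0.01, length.out = d),
    g1 = seq(0.9, by = 0.05, length.out = d), be1 = seq(-0.1, by = 0.05, length.out = d),
    W3 = fill(d, m, 0.04), b3 = seq(0.02, by = 0.01, length.out = m),
    W4 = fill(m, d, 0.05), b4 = seq(-0.01, by = 0.01, length.out = d),
    g2 = seq(1.1, by = -0.05, length.out = d), be2 = seq(0.05, by = 0.02, length.out = d),
    Wh = fill(d, 2, 0.06), bh = c(0.02, -0.02)
  )
  model
}

# A small well-separated cohort shared by several training tests.
small_cohort <- function(n_patients = 40, feature_dim = 16, effect_size = 3,
                         seed = 7, ...) {
  cryomil::generate_cohort(cryomil::cohort_config(
    n_patients = n_patients, feature_dim = feature_dim,
    effect_size = effect_size, seed = seed, ...))
}

tiny_hyperparams <- function(feature_dim = 16, epochs = 10, seed = 1, ...) {
  cryomil::mil_hyperparams(feature_dim = feature_dim, attention_dim = 8,
                           mlp_dim = 16, epochs = epochs, seed = seed, ...)
}
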