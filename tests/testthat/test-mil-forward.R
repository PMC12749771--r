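# Forward-pass contracts of the single-block Transformer MIL classifier.

test_that("attention of a single patch is exactly [[1]]", {
  model <- hand_model()
  out <- attention_forward(matrix(c(0.3, -0.2, 0.5, 0.1), 1, 4), model)
  expect_identical(out$A, matrix(1, 1, 1))
})

test_that("attention rows are probability distributions", {
  model <- hand_model()
  set.seed(11)
  x <- matrix(rnorm(7 * 4), 7, 4)
  out <- attention_forward(x, model)
  expect_lt(max(abs(rowSums(out$A) - 1)), 1e-6)
  expect_true(all(out$A > 0 & out$A <= 1))
})

test_that("the block matches the straight-line equation oracle within 1e-6", {
  for (n in c(2, 3, 5)) {
    model <- hand_model()
    set.seed(n)
    x <- matrix(rnorm(n * 4, sd = 0.8), n, 4)
    fw <- transformer_block(x, model)
    pr <- slide_logits(x, model)
    oracle <- oracle_forward(x, model$params)
    expect_lt(max(abs(fw$A - oracle$A)), 1e-6)
    expect_lt(max(abs(fw$y_sa - oracle$y_sa)), 1e-6)
    expect_lt(max(abs(fw$y_MLP - oracle$y_mlp)), 1e-6)
    expect_lt(max(abs(unname(pr$prob) - oracle$prob)), 1e-6)
  }
  # the optional score scaling is honoured
  model_s <- hand_model(scale_scores = TRUE)
  set.seed(2)
  x <- matrix(rnorm(3 * 4), 3, 4)
  oracle_s <- oracle_forward(x, model_s$params, scale_scores = TRUE)
  expect_lt(max(abs(attention_forward(x, model_s)$A - oracle_s$A)), 1e-6)
})

test_that("zero block-MLP weights reduce y_MLP to layer-normalised y_sa", {
  model <- hand_model()
  model$params$W3[] <- 0; model$params$b3[] <- 0
  model$params$W4[] <- 0; model$params$b4[] <- 0
  set.seed(4)
  x <- matrix(rnorm(4 * 4), 4, 4)
  fw <- transformer_block(x, model)
  expect_equal(fw$y_MLP,
               oracle_layernorm(fw$y_sa, model$params$g2, model$params$be2),
               tolerance = 1e-9)
  expect_equal(dim(fw$y_MLP), c(4L, 4L))
})

test_that("slide probabilities are permutation invariant and sum to one", {
  ch <- small_cohort(n_patients = 4)
  hp <- tiny_hyperparams()
  model <- mil_init(hp)
  for (bag in ch$bags[1:3]) {
    pr <- slide_logits(bag, model)
    expect_equal(sum(pr$prob), 1, tolerance = 1e-9)
    perm <- sample(nrow(bag$features))
    pr2 <- slide_logits(bag$features[perm, , drop = FALSE], model)
    expect_lt(max(abs(pr$prob - pr2$prob)), 1e-6)
  }
})

test_that("degenerate bags and dimension mismatches are rejected", {
  model <- hand_model()
  expect_error(slide_logits(matrix(numeric(0), 0, 4), model), "empty-bag")
  expect_error(slide_logits(matrix(1, 2, 7), model), "consistency error")
})

test_that("predict agrees with per-bag slide_logits and handles empty input", {
  ch <- small_cohort(n_patients = 4)
  model <- mil_init(tiny_hyperparams())
  bags <- ch$bags[1:5]
  preds <- predict(model, bags)
  expect_equal(nrow(preds), 5)
  expect_equal(preds$slide_id, names(bags))
  for (i in seq_along(bags)) {
    expect_lt(abs(preds$p_mutant[i] - slide_logits(bags[[i]], model)$prob["mutant"]),
              1e-7)
  }
  empty <- predict(model, list())
  expect_equal(nrow(empty), 0)
})

test_that("analytic gradients match finite differences on a tiny bag", {
  model <- hand_model()
  set.seed(6)
  x <- matrix(rnorm(3 * 4, sd = 0.5), 3, 4)
  label <- 1L
  loss_at <- function(params) {
    m <- model; m$params <- params
    fw <- cryomil:::mil_forward(x, m)
    -log(fw$prob[label + 1L])
  }
  fw <- cryomil:::mil_forward(x, model)
  grads <- cryomil:::mil_backward(fw, model, label)
  eps <- 1e-6
  for (nm in c("Wk", "Wq", "Wv", "W1", "b2", "g1", "W3", "be2", "Wh", "bh")) {
    p <- model$params
    target <- p[[nm]]
    # probe a handful of coordinates of each tensor
    for (idx in unique(pmin(length(target), c(1, 2, length(target))))) {
      up <- p; up[[nm]][idx] <- up[[nm]][idx] + eps
      dn <- p; dn[[nm]][idx] <- dn[[nm]][idx] - eps
      numeric_grad <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(grads[[nm]][idx], numeric_grad, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, idx))
    }
  }
})

test_that("model archives round-trip through JSON", {
  ch <- small_cohort(n_patients = 6)
  rec <- ch$records
  model <- train_classifier(ch$bags[rec$slide_id], rec$H3K27M,
                            tiny_hyperparams(epochs = 2))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_mil_model(model, path)
  back <- load_mil_model(path)
  expect_equal(back$params, model$params, tolerance = 1e-12)
  expect_equal(back$training_log, model$training_log, tolerance = 1e-12)
  p1 <- predict(model, ch$bags[1:3])
  p2 <- predict(back, ch$bags[1:3])
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(load_mil_model(tempfile()), "I/O error")
})
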