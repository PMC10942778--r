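small_cfg <- function(d = 6L, hidden = 10L) {
  cnn_head_config(in_channels = d, hidden_channels = hidden)
}

test_that("the two-layer CNN preserves sequence length for L = 1..64", {
  h <- build_head(small_cfg(), seed = 1)
  for (L in 1:64) {
    X <- matrix(rnorm(L * 6), L, 6)
    expect_equal(dim(head_forward(h, X)$logits), c(L, 21L))
  }
})

test_that("parameter count matches the closed form for the published shapes", {
  h <- build_head(cnn_head_config(), seed = 1)
  expect_identical(n_parameters(h), 2560L * 300L * 5L + 300L +
                     300L * 21L * 5L + 21L)
  expect_identical(n_parameters(h), 3871821L)
})

test_that("head initialization is seeded and deterministic", {
  X <- matrix(rnorm(8 * 6), 8, 6)
  a <- head_forward(build_head(small_cfg(), seed = 9), X)$logits
  b <- head_forward(build_head(small_cfg(), seed = 9), X)$logits
  c3 <- head_forward(build_head(small_cfg(), seed = 10), X)$logits
  expect_identical(a, b)
  expect_false(all(a == c3))
})

test_that("misconfigured kernels and mismatched inputs are rejected", {
  expect_error(cnn_head_config(paddings = c(2L, 1L)), "preserve")
  expect_error(cnn_head_config(class_weights = rep(1, 5)), "class")
  h <- build_head(small_cfg(), seed = 1)
  expect_error(head_forward(h, matrix(0, 4, 9)), "dimensionality")
  expect_error(predict_3di(h, matrix(0, 4, 9)), "dimensionality")
})

test_that("weighted cross-entropy matches its closed forms and a direct sum", {
  # all weights 1 -> plain mean cross-entropy
  set.seed(1)
  lg <- matrix(rnorm(8 * 21), 8, 21)
  tg <- sample(1:20, 8, replace = TRUE)
  plain <- mean(vapply(1:8, function(i)
    -log(exp(lg[i, tg[i]]) / sum(exp(lg[i, ]))), numeric(1)))
  expect_equal(weighted_cross_entropy(lg, tg, rep(1, 21)), plain)

  # two-class toy: probability 0.5 on a target of weight 2 -> 2 ln 2
  lg2 <- matrix(c(0, 0, rep(-1e9, 19)), 1, 21)
  expect_equal(weighted_cross_entropy(lg2, 1L, c(2, rep(1, 19), 0)),
               2 * log(2))

  # random case equals a position-by-position brute-force sum
  w <- c(runif(20, 0.5, 2), 0)
  tg2 <- sample(1:21, 8, replace = TRUE)
  keep <- tg2 != 21
  brute <- sum(vapply(which(keep), function(i)
    w[tg2[i]] * -log(exp(lg[i, tg2[i]]) / sum(exp(lg[i, ]))),
    numeric(1))) / sum(keep)
  expect_equal(weighted_cross_entropy(lg, tg2, w), brute)

  expect_error(weighted_cross_entropy(lg, rep(25L, 8), w), "range")
})

test_that("default class weights come from the substitution-matrix diagonal", {
  cfg <- cnn_head_config()
  expect_equal(cfg$class_weights,
               unname(c(0.1 * diag(read_substitution_matrix()), 0)))
  expect_equal(cfg$class_weights[21], 0)
})

test_that("loss is non-negative and zero only at certainty", {
  lg <- matrix(c(1e3, rep(-1e3, 20)), 3, 21, byrow = TRUE)
  expect_equal(weighted_cross_entropy(lg, rep(1L, 3), rep(1, 21)), 0)
  set.seed(2)
  for (i in 1:20) {
    lg <- matrix(rnorm(5 * 21), 5, 21)
    tg <- sample(1:21, 5, replace = TRUE)
    expect_gte(weighted_cross_entropy(lg, tg, c(runif(20), 0)), 0)
  }
})

test_that("the learning-rate schedule decays by gamma every 100 batches", {
  ds <- gen_embedding_3di_dataset(
    embedding_dataset_spec(n_sequences = 4, length_range = c(5L, 8L),
                           dimensionality = 3, seed = 1))
  h <- build_head(small_cfg(3L, 4L), seed = 1)
  fit <- train_head(h, ds, train_config(max_batches = 201, batch_size = 2,
                                        seed = 1))
  expect_equal(fit$history$learning_rate[1], 0.001)
  expect_equal(fit$history$learning_rate[100], 0.001)
  expect_equal(fit$history$learning_rate[101], 0.001 * 0.98)
  expect_equal(fit$history$learning_rate[201], 0.001 * 0.98^2)
})

test_that("the first recorded loss equals the loss of the initial model", {
  ds <- gen_embedding_3di_dataset(
    embedding_dataset_spec(n_sequences = 3, length_range = c(10L, 10L),
                           dimensionality = 4, seed = 2))
  h <- build_head(small_cfg(4L, 5L), seed = 3)
  fit <- train_head(h, ds, train_config(max_batches = 1, batch_size = 3,
                                        seed = 4))
  direct <- mean(vapply(ds, function(it)
    weighted_cross_entropy(head_forward(h, it$emb)$logits, it$targets,
                           h$config$class_weights), numeric(1)))
  expect_equal(fit$history$loss[1], direct)
})

test_that("training is deterministic under a fixed seed", {
  ds <- gen_embedding_3di_dataset(
    embedding_dataset_spec(n_sequences = 6, length_range = c(8L, 12L),
                           dimensionality = 4, seed = 5))
  h <- build_head(small_cfg(4L, 5L), seed = 6)
  f1 <- train_head(h, ds, train_config(max_batches = 20, seed = 7))
  f2 <- train_head(h, ds, train_config(max_batches = 20, seed = 7))
  expect_identical(f1$model$W1, f2$model$W1)
  expect_identical(f1$history, f2$history)
  expect_error(train_head(h, list(), train_config()), "empty")
})

test_that("3Di prediction is the per-position argmax over the 20 states", {
  h <- build_head(small_cfg(), seed = 2)
  for (L in c(1L, 7L, 120L)) {
    X <- matrix(rnorm(L * 6), L, 6)
    out <- predict_3di(h, X, id = "q")
    expect_equal(nchar(out$seq), L)
    logits <- head_forward(h, X)$logits
    oracle <- vapply(seq_len(L), function(i)
      as.character(alphabet("3Di"))[which.max(logits[i, 1:20])],
      character(1))
    expect_equal(out$seq, paste(oracle, collapse = ""))
  }
})

test_that("a trained head separates well-separated Gaussian state classes", {
  ds <- gen_embedding_3di_dataset(
    embedding_dataset_spec(n_sequences = 40, length_range = c(30L, 40L),
                           dimensionality = 16, mean_scale = 3,
                           noise_sd = 1, seed = 8))
  fit <- train_head(build_head(small_cfg(16L, 96L), seed = 9),
                    ds[1:30],
                    train_config(max_batches = 1000, seed = 10))
  held <- ds[31:40]
  acc <- mean(unlist(lapply(held, function(it) {
    strsplit(predict_3di(fit, it$emb)$seq, "")[[1]] ==
      strsplit(it$states, "")[[1]]
  })))
  expect_gte(acc, 0.95)
})

test_that("with coincident class means accuracy stays at chance", {
  ds <- gen_embedding_3di_dataset(
    embedding_dataset_spec(n_sequences = 30, length_range = c(30L, 40L),
                           dimensionality = 8, mean_scale = 0,
                           noise_sd = 1, seed = 11))
  fit <- train_head(build_head(small_cfg(8L, 12L), seed = 12),
                    ds[1:20], train_config(max_batches = 60, seed = 13))
  preds <- unlist(lapply(ds[21:30], function(it) {
    strsplit(predict_3di(fit, it$emb)$seq, "")[[1]] ==
      strsplit(it$states, "")[[1]]
  }))
  p_hat <- mean(preds)
  sigma <- sqrt(0.05 * 0.95 / length(preds))
  expect_lt(abs(p_hat - 0.05), 3 * sigma + 0.01)
})

test_that("length filtering is inclusive and splitting uses largest remainders", {
  seqs <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    seq = strrep("A", c(119, 120, 1000, 1001)))
  sp <- filter_and_split(seqs, seed = 1)
  expect_setequal(sp$kept$id, c("b", "c"))

  big <- tibble::tibble(id = sprintf("s%04d", 1:1000),
                        seq = strrep("A", sample(120:1000, 1000, TRUE)))
  sp2 <- filter_and_split(big, seed = 2)
  expect_equal(lengths(sp2[c("train", "validation", "test")]),
               c(train = 900L, validation = 50L, test = 50L))
  expect_setequal(c(sp2$train, sp2$validation, sp2$test), big$id)
  sp3 <- filter_and_split(big, seed = 2)
  expect_identical(sp2$train, sp3$train)
  expect_error(filter_and_split(big, proportions = c(0.5, 0.5, 0.5)),
               "sum to 1")
})
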