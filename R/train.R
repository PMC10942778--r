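#' Training configuration for the 3Di head
#'
#' Defaults follow the published recipe: AdamW with learning rate 0.001 and
#' weight decay 0.001, exponential decay of the learning rate by a factor of
#' 0.98 applied every 100 batches, batches of 15 randomly selected sequences.
#'
#' @param learning_rate,weight_decay AdamW hyperparameters.
#' @param gamma,decay_every Exponential learning-rate schedule: the rate is
#'   multiplied by `gamma` after every `decay_every` batches.
#' @param batch_size Sequences per batch.
#' @param max_batches Number of training batches.
#' @param seed Seed controlling batch selection (training is fully
#'   deterministic given the seed and the initial model).
#'
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.001,
                         gamma = 0.98, decay_every = 100L,
                         batch_size = 15L, max_batches = 1000L, seed = 1L) {
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 gamma = gamma, decay_every = as.integer(decay_every),
                 batch_size = as.integer(batch_size),
                 max_batches = as.integer(max_batches),
                 seed = as.integer(seed)),
            class = "train_config")
}

threedi_states_to_indices <- function(states) {
  idx <- symbol_index(strsplit(states, "")[[1]], alphabet("3Di"))
  if (anyNA(idx)) abort("3Di string contains symbols outside the 3Di alphabet")
  idx
}

indices_to_threedi <- function(idx) {
  paste(as.character(alphabet("3Di"))[idx], collapse = "")
}

# right-pad a batch of (embedding, target) pairs to the max length;
# padded positions get zero embeddings and the padding class as target
pad_batch <- function(items, in_channels, pad_class) {
  Lmax <- max(vapply(items, function(it) nrow(it$emb), integer(1)))
  lapply(items, function(it) {
    L <- nrow(it$emb)
    if (L == Lmax) return(it)
    list(emb = rbind(it$emb, matrix(0, Lmax - L, in_channels)),
         targets = c(it$targets, rep(pad_class, Lmax - L)))
  })
}

#' Train the 3Di head
#'
#' Runs AdamW with the exponential learning-rate schedule on batches of
#' randomly selected sequences, right-padded to the batch maximum length
#' with the padding class.  Per-batch loss, accuracy (non-padding positions
#' only) and learning rate are recorded in the history.  A
#' `unfreeze_hook(batch)` argument marks where a backbone-unfreezing stage
#' would slot in when the head sits on a real language model; the packaged
#' training is head-only and the default hook is a no-op.
#'
#' @param model A `threedi_head` from [build_head()].
#' @param dataset List of `list(emb = L x C matrix, states = 3Di string)`
#'   pairs (or `targets` as integer indices).
#' @param config A [train_config()].
#' @param unfreeze_hook Function of the batch number; no-op by default.
#'
#' @return A `threedi_head_fit`: list with the trained `model` and a
#'   `history` tibble (`batch`, `loss`, `accuracy`, `learning_rate`).
#' @export
train_head <- function(model, dataset, config = train_config(),
                       unfreeze_hook = function(batch) NULL) {
  stopifnot(inherits(model, "threedi_head"), inherits(config, "train_config"))
  if (length(dataset) == 0) abort("empty training dataset")
  cfg <- model$config
  pad_class <- cfg$out_channels
  dataset <- lapply(dataset, function(it) {
    if (is.null(it$targets)) it$targets <- threedi_states_to_indices(it$states)
    if (length(it$targets) != nrow(it$emb)) {
      abort("embedding and 3Di lengths differ within a training pair")
    }
    it
  })
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- c("W1", "b1", "W2", "b2")
  m <- lapply(params, function(p) model[[p]] * 0)
  v <- m
  names(m) <- names(v) <- params
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  history <- vector("list", config$max_batches)
  for (b in seq_len(config$max_batches)) {
    unfreeze_hook(b)
    lr <- config$learning_rate * config$gamma^((b - 1L) %/% config$decay_every)
    pick <- sample(length(dataset), min(config$batch_size, length(dataset)))
    batch <- pad_batch(dataset[pick], cfg$in_channels, pad_class)
    grads <- list(W1 = model$W1 * 0, b1 = model$b1 * 0,
                  W2 = model$W2 * 0, b2 = model$b2 * 0)
    loss <- 0; n_correct <- 0; n_pos <- 0
    for (it in batch) {
      fw <- head_forward(model, it$emb, keep_cache = TRUE)
      loss <- loss + weighted_cross_entropy(fw$logits, it$targets,
                                            cfg$class_weights)
      keep <- it$targets != pad_class
      pred <- max.col(fw$logits[, -pad_class, drop = FALSE])
      n_correct <- n_correct + sum(pred[keep] == it$targets[keep])
      n_pos <- n_pos + sum(keep)
      dL <- wce_grad(fw$logits, it$targets, cfg$class_weights)
      grads$W2 <- grads$W2 + t(fw$cache$Xc2) %*% dL
      grads$b2 <- grads$b2 + colSums(dL)
      dH <- conv1d_backward_input(dL %*% t(model$W2),
                                  nrow(fw$cache$pre1), cfg$hidden_channels,
                                  cfg$kernel_sizes[2], cfg$paddings[2])
      dH <- dH * (fw$cache$pre1 > 0)
      grads$W1 <- grads$W1 + t(fw$cache$Xc1) %*% dH
      grads$b1 <- grads$b1 + colSums(dH)
    }
    nb <- length(batch)
    for (p in params) {
      g <- grads[[p]] / nb
      m[[p]] <- beta1 * m[[p]] + (1 - beta1) * g
      v[[p]] <- beta2 * v[[p]] + (1 - beta2) * g^2
      mhat <- m[[p]] / (1 - beta1^b)
      vhat <- v[[p]] / (1 - beta2^b)
      # decoupled weight decay (AdamW); biases are not decayed
      decay <- if (p %in% c("W1", "W2")) config$weight_decay else 0
      model[[p]] <- model[[p]] - lr * (mhat / (sqrt(vhat) + eps) +
                                         decay * model[[p]])
    }
    history[[b]] <- tibble(batch = b, loss = loss / nb,
                           accuracy = n_correct / max(1, n_pos),
                           learning_rate = lr)
  }
  structure(list(model = model, config = config,
                 history = dplyr::bind_rows(history)),
            class = "threedi_head_fit")
}

#' @export
print.threedi_head_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat("<threedi_head_fit: ", n, " batches, final loss ",
      signif(x$history$loss[n], 4), ", final accuracy ",
      signif(x$history$accuracy[n], 4), ">\n", sep = "")
  invisible(x)
}

#' Predict a 3Di sequence from positional embeddings
#'
#' Runs the head forward and takes the argmax over the 20 state classes at
#' every position (the padding class is excluded from the argmax).
#'
#' @param model A `threedi_head` or `threedi_head_fit`.
#' @param embeddings L x C embedding matrix.
#' @param id Sequence id for the result.
#'
#' @return A tibble with columns `id` and `seq` (the 3Di string, length L).
#' @export
predict_3di <- function(model, embeddings, id = "query") {
  if (inherits(model, "threedi_head_fit")) model <- model$model
  logits <- head_forward(model, embeddings)$logits
  pad_class <- model$config$out_channels
  idx <- max.col(logits[, -pad_class, drop = FALSE])
  tibble(id = id, seq = indices_to_threedi(idx))
}

#' Filter sequences by length and split into train/validation/test
#'
#' Keeps sequences whose length lies in the inclusive range `bounds`
#' (defaults 120..1000), then randomly partitions the retained ids by
#' `proportions` using largest-remainder rounding, so a 1000-sequence input
#' under the default 90/5/5 split yields exactly 900/50/50.
#'
#' @param seqs Tibble with columns `id`, `seq`.
#' @param bounds Inclusive keep-range of sequence lengths.
#' @param proportions Train/validation/test proportions (sum to 1).
#' @param seed Seed for the random partition.
#'
#' @return A `dataset_split`: list of character id vectors `train`,
#'   `validation`, `test`, plus the retained tibble `kept`.
#' @export
filter_and_split <- function(seqs, bounds = c(120L, 1000L),
                             proportions = c(0.90, 0.05, 0.05), seed = 1L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  if (abs(sum(proportions) - 1) > 1e-9) abort("`proportions` must sum to 1")
  len <- nchar(seqs$seq)
  kept <- seqs[len >= bounds[1] & len <= bounds[2], ]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ids <- sample(kept$id)
  n <- length(ids)
  sizes <- floor(proportions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- proportions * n - sizes
    sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  bounds_idx <- cumsum(sizes)
  structure(list(train = ids[seq_len(sizes[1])],
                 validation = ids[seq(sizes[1] + 1, length.out = sizes[2])],
                 test = ids[seq(bounds_idx[2] + 1, length.out = sizes[3])],
                 kept = kept),
            class = "dataset_split")
}
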