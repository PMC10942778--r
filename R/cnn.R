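# 1D convolution via im2col: X is L x C_in, W is (k*C_in) x C_out with
# W[(c-1)*k + j, o] the weight for input channel c, tap j, output channel o.

conv1d_im2col <- function(X, k, pad) {
  L <- nrow(X); C <- ncol(X)
  Xp <- rbind(matrix(0, pad, C), X, matrix(0, pad, C))
  Lout <- L + 2L * pad - k + 1L
  Xc <- matrix(0, Lout, k * C)
  for (j in seq_len(k)) {
    idx <- seq(j, k * C, by = k)
    Xc[, idx] <- Xp[j:(j + Lout - 1L), , drop = FALSE]
  }
  Xc
}

conv1d_forward <- function(X, W, b, k, pad) {
  Xc <- conv1d_im2col(X, k, pad)
  Y <- Xc %*% W
  Y <- sweep(Y, 2, b, "+")
  list(Y = Y, Xc = Xc)
}

# gradient wrt input given dXc (chain through im2col by scatter-add)
conv1d_backward_input <- function(dXc, L, C, k, pad) {
  Lout <- nrow(dXc)
  dXp <- matrix(0, L + 2L * pad, C)
  for (j in seq_len(k)) {
    idx <- seq(j, k * C, by = k)
    rows <- j:(j + Lout - 1L)
    dXp[rows, ] <- dXp[rows, ] + dXc[, idx, drop = FALSE]
  }
  dXp[(pad + 1L):(pad + L), , drop = FALSE]
}

#' Configuration of the 3Di convolutional head
#'
#' The head is a two-layer 1D CNN mapping per-position embeddings to 3Di
#' states.  Defaults follow the published architecture: layer 1 has 2560
#' input channels (the embedding width of a large protein language model),
#' 300 output channels, kernel 5, stride 1, padding 3; layer 2 has 300 input
#' and 21 output channels (20 3Di states plus one padding class), kernel 5,
#' stride 1, padding 1.  The padding arithmetic preserves length:
#' L -> L + 2 -> L.  A ReLU sits between the layers.
#'
#' @param in_channels Embedding width (default 2560).
#' @param hidden_channels Hidden width (default 300).
#' @param out_channels Output classes (default 21 = 20 states + padding).
#' @param kernel_sizes,paddings Integer pairs for the two layers.
#' @param class_weights Length-`out_channels` loss weights; default
#'   0.1 x the diagonal of the packaged 3Di substitution matrix for the 20
#'   state classes and 0 for the padding class.
#'
#' @return A `cnn_head_config` list.
#' @export
cnn_head_config <- function(in_channels = 2560L, hidden_channels = 300L,
                            out_channels = 21L, kernel_sizes = c(5L, 5L),
                            paddings = c(3L, 1L), class_weights = NULL) {
  if (is.null(class_weights)) {
    class_weights <- unname(c(0.1 * diag(read_substitution_matrix()), 0))
  }
  if (length(class_weights) != out_channels) {
    abort("`class_weights` must have one entry per output class")
  }
  length_shift <- sum(2L * paddings - kernel_sizes + 1L)
  if (length_shift != 0L) {
    abort("kernel/padding configuration does not preserve sequence length")
  }
  structure(list(in_channels = as.integer(in_channels),
                 hidden_channels = as.integer(hidden_channels),
                 out_channels = as.integer(out_channels),
                 kernel_sizes = as.integer(kernel_sizes),
                 strides = c(1L, 1L),
                 paddings = as.integer(paddings),
                 class_weights = class_weights),
            class = "cnn_head_config")
}

#' Build the 3Di convolutional head
#'
#' Initializes both convolution layers with seeded He-scaled Gaussian weights
#' and zero biases.
#'
#' @param config A [cnn_head_config()].
#' @param seed Integer seed for the initialization.
#'
#' @return A `threedi_head` model object.
#' @examples
#' head <- build_head(cnn_head_config(in_channels = 8), seed = 1)
#' n_parameters(head)
#' @export
build_head <- function(config = cnn_head_config(), seed = 1L) {
  stopifnot(inherits(config, "cnn_head_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  k <- config$kernel_sizes
  init <- function(fan_in, n) matrix(rnorm(fan_in * n, sd = sqrt(2 / fan_in)),
                                     fan_in, n)
  structure(list(
    config = config,
    W1 = init(k[1] * config$in_channels, config$hidden_channels),
    b1 = numeric(config$hidden_channels),
    W2 = init(k[2] * config$hidden_channels, config$out_channels),
    b2 = numeric(config$out_channels),
    seed = as.integer(seed)
  ), class = "threedi_head")
}

#' @export
print.threedi_head <- function(x, ...) {
  cat("<threedi_head: ", x$config$in_channels, " -> ",
      x$config$hidden_channels, " -> ", x$config$out_channels,
      " channels, ", n_parameters(x), " parameters>\n", sep = "")
  invisible(x)
}

#' @rdname build_head
#' @param model A `threedi_head`.
#' @export
n_parameters <- function(model) {
  length(model$W1) + length(model$b1) + length(model$W2) + length(model$b2)
}

head_forward <- function(model, X, keep_cache = FALSE) {
  cfg <- model$config
  if (ncol(X) != cfg$in_channels) {
    abort(paste0("embedding dimensionality ", ncol(X),
                 " does not match head input channels ", cfg$in_channels))
  }
  l1 <- conv1d_forward(X, model$W1, model$b1, cfg$kernel_sizes[1], cfg$paddings[1])
  H <- pmax(l1$Y, 0)
  l2 <- conv1d_forward(H, model$W2, model$b2, cfg$kernel_sizes[2], cfg$paddings[2])
  out <- list(logits = l2$Y)
  if (keep_cache) out$cache <- list(Xc1 = l1$Xc, pre1 = l1$Y, Xc2 = l2$Xc)
  out
}

#' Weighted cross-entropy over 3Di positions
#'
#' Mean over non-padding positions of
#' `weight[target] * (-log softmax(logits)[target])`.  With all weights 1
#' this is the ordinary mean cross-entropy.  The default weights (see
#' [cnn_head_config()]) up-weight 3Di states with large self-substitution
#' scores -- conserved, information-rich structural states -- and give the
#' padding class weight 0 so padded positions never contribute.
#'
#' @param logits L x 21 matrix.
#' @param targets Length-L integer class indices (1..21; 21 = padding).
#' @param weights Length-21 non-negative weights.
#'
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(logits, targets,
                                   weights = cnn_head_config()$class_weights) {
  stopifnot(is.matrix(logits), length(targets) == nrow(logits),
            length(weights) == ncol(logits))
  if (any(targets < 1 | targets > ncol(logits))) {
    abort("target class index out of range")
  }
  pad_class <- length(weights)
  keep <- targets != pad_class
  if (!any(keep)) return(0)
  lp <- logits - apply(logits, 1, max)
  lse <- log(rowSums(exp(lp)))
  nll <- lse - lp[cbind(seq_len(nrow(logits)), targets)]
  sum(weights[targets[keep]] * nll[keep]) / sum(keep)
}

# gradient of weighted_cross_entropy wrt logits (same reduction)
wce_grad <- function(logits, targets, weights) {
  pad_class <- length(weights)
  keep <- targets != pad_class
  P <- softmax_rows(logits)
  G <- P
  G[cbind(seq_len(nrow(logits)), targets)] <-
    G[cbind(seq_len(nrow(logits)), targets)] - 1
  G <- G * (weights[targets] * keep) / max(1, sum(keep))
  G
}
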