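#' Embedder contract
#'
#' Profile prediction is written against a pluggable embedder: any object that
#' maps a masked protein sequence to per-position logits over the 20 canonical
#' amino acids and per-position embedding vectors.  A real protein language
#' model can be plugged in through this interface; the packaged
#' [toy_embedder()] is a deterministic stand-in used by all tests.
#'
#' An embedder is a list with class `"posembed_embedder"` holding:
#' \describe{
#'   \item{dimensionality}{positive integer, width of the embedding vectors.}
#'   \item{fn}{`function(chars, masked)` where `chars` is the sequence as a
#'     character vector and `masked` a logical vector of the same length;
#'     returns `list(logits = L x 20 matrix, embeddings = L x d matrix)`.}
#' }
#'
#' Contract invariants: the operation is deterministic, and the logits and
#' embeddings returned at a masked position must not depend on the residue
#' identity at that position (the model sees only the context).
#'
#' @param dimensionality Positive integer.
#' @param fn The mapping function described above.
#'
#' @return A `posembed_embedder`.
#' @export
new_embedder <- function(dimensionality, fn) {
  stopifnot(is.numeric(dimensionality), dimensionality >= 1, is.function(fn))
  structure(list(dimensionality = as.integer(dimensionality), fn = fn),
            class = "posembed_embedder")
}

run_embedder <- function(embedder, chars, masked) {
  stopifnot(inherits(embedder, "posembed_embedder"))
  out <- embedder$fn(chars, masked)
  if (!is.matrix(out$logits) || ncol(out$logits) != 20 ||
      nrow(out$logits) != length(chars)) {
    abort("embedder contract violation: logits must be an L x 20 matrix")
  }
  if (!is.matrix(out$embeddings) ||
      ncol(out$embeddings) != embedder$dimensionality ||
      nrow(out$embeddings) != length(chars)) {
    abort(paste0("embedder contract violation: embeddings must be L x ",
                 embedder$dimensionality))
  }
  out
}

#' Deterministic toy embedder
#'
#' A seeded, fully deterministic embedder satisfying the embedder contract.
#' Logits and embeddings at each position are arithmetic hashes of the local
#' context window (radius 3) with the centre residue blanked out, so outputs
#' at any position never depend on that position's own residue -- the
#' mask-independence the contract requires of a masked language model.
#'
#' @param seed Integer seed folded into the hash.
#' @param dimensionality Embedding width (default 2560, the width of a large
#'   protein language model's positional embeddings).
#'
#' @return A `posembed_embedder`.
#' @examples
#' emb <- toy_embedder(seed = 1, dimensionality = 8)
#' out <- emb$fn(strsplit("ACDEF", "")[[1]], rep(FALSE, 5))
#' dim(out$logits)
#' @export
toy_embedder <- function(seed = 0L, dimensionality = 2560L) {
  seed <- as.integer(seed)
  d <- as.integer(dimensionality)
  radius <- 3L
  fn <- function(chars, masked) {
    L <- length(chars)
    chars[masked] <- "#"
    codes <- utf8ToInt(paste(chars, collapse = ""))
    # context hash per position: weighted sum over the window, centre blanked
    h <- numeric(L)
    w <- (-radius):radius
    mult <- 31^(w + radius)          # distinct weight per offset
    mult[radius + 1L] <- 0           # centre residue never contributes
    for (k in seq_along(w)) {
      idx <- seq_len(L) + w[k]
      ok <- idx >= 1 & idx <= L
      h[ok] <- h[ok] + mult[k] * codes[idx[ok]]
    }
    h <- h + 1e-3 * seed
    logits <- outer(h, seq_len(20), function(hh, a)
      3 * sin(hh * 0.137 * a + 0.61 * a + 0.011 * seed))
    embeddings <- outer(h, seq_len(d), function(hh, j)
      sin(hh * 0.0113 * j + 0.37 * j + 0.017 * seed))
    list(logits = logits, embeddings = embeddings)
  }
  new_embedder(d, fn)
}

#' Check an embedder against the contract
#'
#' Runs a small battery: determinism (two identical calls agree bitwise) and
#' mask-independence (substituting the residue under a mask leaves the output
#' at that position unchanged).
#'
#' @param embedder A `posembed_embedder`.
#' @param n_trials Number of randomized trials.
#' @param seed Seed for the trial sequences.
#'
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_embedder_contract <- function(embedder, n_trials = 5, seed = 1) {
  ab <- as.character(alphabet())
  set.seed(seed)
  for (t in seq_len(n_trials)) {
    L <- sample(5:30, 1)
    chars <- sample(ab, L, replace = TRUE)
    masked <- seq_len(L) %in% sample(L, max(1, L %/% 5))
    a <- run_embedder(embedder, chars, masked)
    b <- run_embedder(embedder, chars, masked)
    if (!identical(a, b)) abort("embedder contract violation: not deterministic")
    pos <- sample(which(masked), 1)
    chars2 <- chars
    chars2[pos] <- sample(setdiff(ab, chars[pos]), 1)
    c2 <- run_embedder(embedder, chars2, masked)
    if (!isTRUE(all.equal(a$logits[pos, ], c2$logits[pos, ])) ||
        !isTRUE(all.equal(a$embeddings[pos, ], c2$embeddings[pos, ]))) {
      abort("embedder contract violation: output at a masked position depends on the masked residue")
    }
  }
  invisible(TRUE)
}
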