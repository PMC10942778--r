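#' Positional amino-acid probability profiles
#'
#' A positional profile stores, for one protein sequence, a probability
#' distribution over the 20 canonical amino acids at every position -- the
#' smallest profile-HMM-style embedding the package produces.
#'
#' @param sequence_id Sequence identifier.
#' @param probs Numeric L x 20 matrix of row-stochastic match probabilities,
#'   columns in the canonical amino-acid order.
#' @param source `"predicted"` or `"msa-derived"`.
#'
#' @return A `positional_profile` object.
#' @export
new_positional_profile <- function(sequence_id, probs,
                                   source = c("predicted", "msa-derived")) {
  source <- match.arg(source)
  if (!is.matrix(probs) || ncol(probs) != 20 || nrow(probs) < 1) {
    abort("`probs` must be an L x 20 matrix with L >= 1")
  }
  if (any(probs < 0) || any(probs > 1) ||
      any(abs(rowSums(probs) - 1) > 1e-6)) {
    abort("profile rows must be probabilities summing to 1 (tolerance 1e-6)")
  }
  colnames(probs) <- as.character(alphabet())
  structure(list(sequence_id = sequence_id, length = nrow(probs),
                 probs = probs, source = source),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("<positional_profile ", x$sequence_id, ": ", x$length,
      " positions, source ", x$source, ">\n", sep = "")
  invisible(x)
}

#' @rdname new_positional_profile
#' @param x A `positional_profile`.
#' @param ... Unused.
#' @method tidy positional_profile
#' @export
tidy.positional_profile <- function(x, ...) {
  tibble(
    sequence_id = x$sequence_id,
    position = rep(seq_len(x$length), each = 20L),
    residue = rep(as.character(alphabet()), times = x$length),
    probability = as.vector(t(x$probs))
  )
}

#' @rdname new_positional_profile
#' @param object A `positional_profile`.
#' @method autoplot positional_profile
#' @export
autoplot.positional_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$position,
                                  factor(.data$residue,
                                         levels = rev(as.character(alphabet()))),
                                  fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "position", y = "residue",
                  title = object$sequence_id) +
    ggplot2::theme_minimal()
}

#' Predict a positional profile by multi-pass masked inference
#'
#' Implements the multi-pass masked-marginal algorithm: the sequence is
#' prepended with `M` (language models trained on full proteins carry a
#' strong prior that position 1 is a methionine, which would distort the
#' first column of a domain-level profile), positions of the extended
#' sequence are partitioned into `stride` stride-separated mask sets, the
#' embedder is run once per non-empty pass with that pass's positions
#' masked, the 20 amino-acid logits at each masked position are collected
#' from the pass that owns it, and a softmax converts each position's logits
#' into probabilities.  The row for the prepended residue is dropped, so the
#' profile covers exactly the original positions.
#'
#' The prepended `M` occupies model position 1 and takes part in the masking
#' schedule; the first original residue is model position 2.
#'
#' @param seq Protein sequence: a single string (ambiguity codes X/B/Z/U/O
#'   are passed through to the embedder unchanged).
#' @param embedder A `posembed_embedder` (see [new_embedder()]).
#' @param stride Number of masking passes (default 7).
#' @param id Sequence id recorded in the profile.
#'
#' @return A `positional_profile` of the same length as `seq`.
#' @examples
#' p <- predict_profile("ACDEFGHIK", toy_embedder(1, 8), id = "demo")
#' p$length
#' @export
predict_profile <- function(seq, embedder, stride = 7L, id = "query") {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    abort("`seq` must be a single non-empty string")
  }
  chars <- strsplit(seq, "")[[1]]
  allowed <- c(as.character(alphabet()), AMBIGUITY_CODES)
  if (!all(chars %in% allowed)) {
    abort(paste0("residues outside the amino-acid alphabet: ",
                 paste(unique(setdiff(chars, allowed)), collapse = ", ")))
  }
  ext <- c("M", chars)                       # model position 1 = prepended M
  sched <- build_masking_schedule(length(ext), stride)
  logits <- matrix(NA_real_, length(ext), 20L)
  for (pass in sched$passes) {
    if (length(pass) == 0) next              # short sequences: skip empty passes
    masked <- seq_along(ext) %in% pass
    out <- run_embedder(embedder, ext, masked)
    logits[pass, ] <- out$logits[pass, , drop = FALSE]
  }
  probs <- softmax_rows(logits[-1L, , drop = FALSE])
  new_positional_profile(id, probs, source = "predicted")
}

#' Predict profiles for a set of sequences
#'
#' Tidy front end to [predict_profile()].
#'
#' @param seqs Tibble with columns `id` and `seq` (e.g. from [read_fasta()]).
#' @inheritParams predict_profile
#'
#' @return The input tibble with a list-column `profile` of
#'   `positional_profile` objects.
#' @export
predict_profiles <- function(seqs, embedder, stride = 7L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  dplyr::mutate(seqs, profile = purrr::map2(
    .data$seq, .data$id,
    function(s, i) predict_profile(s, embedder, stride = stride, id = i)))
}
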