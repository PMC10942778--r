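#' Build a stride-separated masking schedule
#'
#' Partitions positions `1..length` into passes: pass `p` holds the positions
#' congruent to `p` modulo `stride` (so with the default stride of 7, pass 1
#' masks positions 1, 8, 15, ... and the masks shift one position to the
#' right on each subsequent pass).  Every position is masked in exactly one
#' pass; the number of non-empty passes is `min(stride, length)`.
#'
#' @param length Sequence length (positive integer).
#' @param stride Mask spacing; also the number of passes (default 7).
#'
#' @return A `masking_schedule` object: a list with `stride`, `length` and
#'   `passes` (a list of `stride` integer vectors of 1-based positions, some
#'   possibly empty).
#' @examples
#' build_masking_schedule(14)
#' tidy(build_masking_schedule(10, stride = 3))
#' @export
build_masking_schedule <- function(length, stride = 7L) {
  if (!is.numeric(length) || length(length) != 1 || is.na(length) ||
      length < 1 || length != floor(length)) {
    abort("`length` must be a positive integer")
  }
  if (!is.numeric(stride) || length(stride) != 1 || is.na(stride) ||
      stride < 1 || stride != floor(stride)) {
    abort("`stride` must be a positive integer")
  }
  length <- as.integer(length); stride <- as.integer(stride)
  passes <- lapply(seq_len(stride), function(p) {
    if (p > length) integer(0) else seq.int(p, length, by = stride)
  })
  structure(list(stride = stride, length = length, passes = passes),
            class = "masking_schedule")
}

#' @export
print.masking_schedule <- function(x, ...) {
  cat("<masking_schedule: length ", x$length, ", stride ", x$stride, ", ",
      sum(lengths(x$passes) > 0), " non-empty passes>\n", sep = "")
  invisible(x)
}

#' @rdname build_masking_schedule
#' @param x A `masking_schedule`.
#' @param ... Unused.
#' @method tidy masking_schedule
#' @export
tidy.masking_schedule <- function(x, ...) {
  tibble(
    pass = rep.int(seq_along(x$passes), lengths(x$passes)),
    position = unlist(x$passes, use.names = FALSE)
  )
}

#' Convert logits to a probability distribution
#'
#' Numerically stable softmax over a vector of logits (temperature 1).
#'
#' @param logits Finite numeric vector.
#'
#' @return A non-negative vector of the same length summing to 1.
#' @examples
#' logits_to_probabilities(rep(0, 20))
#' @export
logits_to_probabilities <- function(logits) {
  if (!is.numeric(logits) || any(!is.finite(logits))) {
    abort("`logits` must be a finite numeric vector")
  }
  z <- exp(logits - max(logits))
  z / sum(z)
}

# row-wise stable softmax over a matrix
softmax_rows <- function(m) {
  z <- exp(m - apply(m, 1, max))
  z / rowSums(z)
}
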