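#' Percent identity from an affine-gap global alignment
#'
#' Aligns two sequences globally (Gotoh three-state dynamic programming,
#' BLOSUM62 scores, gap cost `open + extension * length` -- the same cost
#' convention as `Biostrings::pairwiseAlignment`) and returns
#' `100 * identical aligned pairs / alignment columns` (gap columns count in
#' the denominator).  The traceback tie-break is fixed (match/mismatch over
#' gap-in-second over gap-in-first), making the value deterministic and
#' symmetric.
#'
#' @param a,b Protein sequences (single strings).
#' @param matrix Substitution matrix with residue dimnames (default
#'   BLOSUM62).
#' @param gap_open,gap_extension Affine gap parameters (default 10 and 1).
#'
#' @return Percent identity in `[0, 100]`.
#' @examples
#' percent_identity("ACDEFGHIK", "ACDEFGHIK")
#' @export
percent_identity <- function(a, b, matrix = blosum62(),
                             gap_open = 10, gap_extension = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  aln <- align_global(a, b, matrix, gap_open, gap_extension)
  pa <- strsplit(aln$a, "")[[1]]
  pb <- strsplit(aln$b, "")[[1]]
  100 * sum(pa == pb & pa != "-") / length(pa)
}

#' @rdname percent_identity
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Gotoh global alignment with affine gaps.  Gap of length k costs
# open + k * extension.  Returns the aligned strings and the optimal score.
align_global <- function(a, b, matrix, gap_open, gap_extension) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- gap_open + gap_extension; ge <- gap_extension
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # aligned pair ends at (i, j)
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (A[i] over '-') ends at (i, j)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  X[2:(n + 1), 1] <- -(go + ge * (seq_len(n) - 1))
  Y[1, 2:(m + 1)] <- -(go + ge * (seq_len(m) - 1))
  for (i in 2:(n + 1)) {
    s_row <- matrix[A[i - 1], B]
    for (j in 2:(m + 1)) {
      best_prev <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- best_prev + s_row[j - 1]
      X[i, j] <- max(M[i - 1, j] - go, X[i - 1, j] - ge, Y[i - 1, j] - go)
      Y[i, j] <- max(M[i, j - 1] - go, Y[i, j - 1] - ge, X[i, j - 1] - go)
    }
  }
  # traceback with fixed preference M > X > Y
  ra <- character(0); rb <- character(0)
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  score <- c(M[i, j], X[i, j], Y[i, j])[state]
  while (i > 1 || j > 1) {
    if (state == 1) {
      ra <- c(A[i - 1], ra); rb <- c(B[j - 1], rb)
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      target <- M[i, j] - matrix[A[i - 1], B[j - 1]]
      i <- i - 1; j <- j - 1
      state <- which(abs(prev - target) < 1e-9)[1]
      if (i == 1 && j == 1) break
    } else if (state == 2) {
      ra <- c(A[i - 1], ra); rb <- c("-", rb)
      cand <- c(M[i - 1, j] - go, X[i - 1, j] - ge, Y[i - 1, j] - go)
      i <- i - 1
      state <- which(abs(cand - X[i + 1, j]) < 1e-9)[1]
    } else {
      ra <- c("-", ra); rb <- c(B[j - 1], rb)
      cand <- c(M[i, j - 1] - go, Y[i, j - 1] - ge, X[i, j - 1] - go)
      j <- j - 1
      st <- which(abs(cand - Y[i, j + 1]) < 1e-9)[1]
      state <- c(1L, 3L, 2L)[st]
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = score)
}
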