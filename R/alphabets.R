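#' Residue alphabets
#'
#' The package works with two 20-letter alphabets: the canonical amino-acid
#' alphabet in the fixed HMMER column order, and the 3Di structure alphabet
#' (the 20 states Foldseek uses to encode the tertiary interactions of each
#' residue, written with the same 20 letters).  The 3Di letter order is fixed
#' to the row order of the packaged substitution matrix.
#'
#' @param kind `"amino-acid"` or `"3Di"`.
#'
#' @return A character vector of 20 single-letter symbols with class
#'   `"posembed_alphabet"` and a `kind` attribute.
#' @examples
#' alphabet("amino-acid")
#' @export
alphabet <- function(kind = c("amino-acid", "3Di")) {
  kind <- match.arg(kind)
  sym <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  structure(sym, kind = kind, class = "posembed_alphabet")
}

#' @export
print.posembed_alphabet <- function(x, ...) {
  cat("<", attr(x, "kind"), " alphabet: ", paste(unclass(x), collapse = ""),
      ">\n", sep = "")
  invisible(x)
}

# ambiguity / unknown residue codes passed through to embedders but never
# counted in 20-symbol distributions
AMBIGUITY_CODES <- c("X", "B", "Z", "U", "O")
GAP_CHARS <- c("-", ".")

symbol_index <- function(chars, ab = alphabet()) {
  match(chars, as.character(ab))
}

#' Read a 20x20 substitution matrix
#'
#' Parses a whitespace-delimited square substitution matrix with a header row
#' of symbols and one labelled row per symbol (the layout used for 3Di and
#' BLOSUM-style matrices).  Lines starting with `#` are comments.
#'
#' @param path Path to the matrix file.  Defaults to the packaged synthetic
#'   3Di-style matrix.
#'
#' @return A symmetric numeric matrix with symbol dimnames.
#' @examples
#' m <- read_substitution_matrix()
#' diag(m)
#' @export
read_substitution_matrix <- function(path = threedi_matrix_path()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  n <- length(header)
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (any(lengths(rows) != n + 1)) {
    abort("malformed substitution matrix: ragged rows")
  }
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(m) <- vapply(rows, `[[`, character(1), 1)
  colnames(m) <- header
  if (!isTRUE(all.equal(m, t(m)))) abort("substitution matrix is not symmetric")
  m
}

#' @rdname read_substitution_matrix
#' @export
threedi_matrix_path <- function() {
  system.file("extdata", "mat3di_synthetic.out", package = "posembed",
              mustWork = TRUE)
}
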