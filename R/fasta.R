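#' Read and write FASTA sequence sets
#'
#' Thin tidy wrappers around [Biostrings::readBStringSet()] /
#' [Biostrings::writeXStringSet()].  Sequence ids are the first
#' whitespace-delimited token of the header line.
#'
#' @param path File path.
#' @param seqs A tibble with columns `id` and `seq`.
#' @param width Line width for wrapping on write.
#'
#' @return `read_fasta()` returns a tibble with columns `id` (character) and
#'   `seq` (character); `write_fasta()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' write_fasta(tibble::tibble(id = "s1", seq = "ACDEF"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids)) abort("duplicate sequence ids in FASTA")
  tibble(id = ids, seq = unname(as.character(ss)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  ss <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
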