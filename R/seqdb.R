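#' Write paired amino-acid / 3Di sequences as a search-engine database
#'
#' Serializes matched amino-acid and 3Di FASTA sets into the MMseqs2-style
#' data/index/dbtype triple layout consumed by structure search engines:
#' three file sets (`<name>` amino-acid payloads, `<name>_ss` 3Di payloads,
#' `<name>_h` headers).  Each data file holds null-terminated entries
#' (`payload "\n" "\0"`); each `.index` is tab-separated
#' `key <TAB> offset <TAB> length` with length counting the payload, newline
#' and null byte; `.dbtype` is a 4-byte tag (first byte 0 = amino acid,
#' 1 = 3Di states, 12 = generic header; remaining bytes 0).
#'
#' Entries are written in the order of `aa`; keys are 0-based.
#'
#' @param aa Tibble (`id`, `seq`) of amino-acid sequences.
#' @param tdi Tibble (`id`, `seq`) of 3Di sequences; must contain exactly the
#'   ids of `aa`, each with matching sequence length.
#' @param out_dir Output directory (created if needed).
#' @param name Database base name.
#'
#' @return Invisibly, the database base path `file.path(out_dir, name)`.
#' @export
write_paired_sequence_db <- function(aa, tdi, out_dir, name = "db") {
  stopifnot(all(c("id", "seq") %in% names(aa)), all(c("id", "seq") %in% names(tdi)))
  missing_ids <- setdiff(aa$id, tdi$id)
  extra_ids <- setdiff(tdi$id, aa$id)
  if (length(missing_ids) || length(extra_ids)) {
    abort(paste0("id mismatch between amino-acid and 3Di inputs: ",
                 paste(c(missing_ids, extra_ids), collapse = ", ")))
  }
  tdi <- tdi[match(aa$id, tdi$id), ]
  bad <- aa$id[nchar(aa$seq) != nchar(tdi$seq)]
  if (length(bad)) {
    abort(paste0("length mismatch between amino-acid and 3Di sequence for id: ",
                 paste(bad, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(payloads, base, type_byte) {
    data_path <- file.path(out_dir, base)
    con <- file(data_path, open = "wb")
    offset <- 0
    idx <- character(length(payloads))
    for (i in seq_along(payloads)) {
      raw <- c(charToRaw(payloads[[i]]), charToRaw("\n"), as.raw(0L))
      writeBin(raw, con)
      idx[i] <- sprintf("%d\t%d\t%d", i - 1L, offset, length(raw))
      offset <- offset + length(raw)
    }
    close(con)
    writeLines(idx, paste0(data_path, ".index"))
    writeBin(as.raw(c(type_byte, 0L, 0L, 0L)), paste0(data_path, ".dbtype"))
  }
  write_one(aa$seq, name, 0L)
  write_one(tdi$seq, paste0(name, "_ss"), 1L)
  write_one(aa$id, paste0(name, "_h"), 12L)
  invisible(file.path(out_dir, name))
}

#' Read back a paired sequence database
#'
#' Inverse of [write_paired_sequence_db()]; payloads are recovered from the
#' index offsets/lengths, so read-back also validates index consistency.
#'
#' @param out_dir Directory holding the database files.
#' @param name Database base name.
#'
#' @return A list with tibbles `aa` and `tdi` (columns `id`, `seq`), in
#'   stored entry order.
#' @export
read_paired_sequence_db <- function(out_dir, name = "db") {
  read_one <- function(base) {
    data_path <- file.path(out_dir, base)
    idx <- read.delim(paste0(data_path, ".index"), header = FALSE,
                      col.names = c("key", "offset", "length"))
    bytes <- readBin(data_path, what = "raw", n = file.info(data_path)$size)
    vapply(seq_len(nrow(idx)), function(i) {
      span <- bytes[(idx$offset[i] + 1):(idx$offset[i] + idx$length[i])]
      if (tail(span, 1) != as.raw(0L)) abort("corrupt entry: missing null terminator")
      rawToChar(span[seq_len(length(span) - 2L)])
    }, character(1))
  }
  ids <- read_one(paste0(name, "_h"))
  list(aa = tibble(id = ids, seq = read_one(name)),
       tdi = tibble(id = ids, seq = read_one(paste0(name, "_ss"))))
}
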