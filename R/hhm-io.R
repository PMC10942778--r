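#' Write a positional profile as an HH-suite `.hhm` file
#'
#' Emission fields store `round(-1000 * log2(p))` with `*` for p = 0 (the
#' hhm integer encoding); this quantization bounds round-trip relative error
#' by about `2^(5e-4) - 1`, i.e. under 5e-4.  Transition and Neff fields come
#' from `defaults` and are written on every position's second line.
#'
#' @inheritParams write_hmmer3_profile
#'
#' @return `path` invisibly (or lines if `path = NULL`).
#' @export
write_hhsuite_hhm <- function(profile, path, defaults = profile_defaults()) {
  stopifnot(inherits(profile, "positional_profile"))
  if (profile$length < 1) abort("zero-length profile")
  ab <- as.character(alphabet())
  enc <- function(p) {
    out <- rep("*", length(p))
    pos <- p > 0
    val <- round(-1000 * log2(p[pos]))
    val[val == 0] <- 0                   # avoid "-0" for p = 1
    out[pos] <- sprintf("%.0f", val)
    out
  }
  tr <- defaults$transitions
  tr_fields <- paste(c(enc(c(tr[["mm"]], tr[["mi"]], tr[["md"]], tr[["im"]],
                             tr[["ii"]], tr[["dm"]], tr[["dd"]])),
                       "1000", "1000", "1000"), collapse = "\t")
  null_line <- paste(enc(rep(0.05, 20)), collapse = "\t")
  lines <- c(
    "HHsearch 1.5",
    sprintf("NAME  %s", profile$sequence_id),
    sprintf("LENG  %d match states", profile$length),
    paste0("NULL   ", null_line),
    paste0("HMM    ", paste(ab, collapse = "\t")),
    paste0("       ", paste(c("M->M", "M->I", "M->D", "I->M", "I->I",
                              "D->M", "D->D", "Neff", "Neff_I", "Neff_D"),
                            collapse = "\t")),
    paste0("       ", paste(c("0", "*", "*", "0", "*", "*", "*",
                              "1000", "0", "0"), collapse = "\t"))
  )
  body <- character(3L * profile$length)
  for (i in seq_len(profile$length)) {
    cons <- ab[which.max(profile$probs[i, ])]
    body[3 * i - 2] <- paste(c(paste(cons, i), enc(profile$probs[i, ]), i),
                             collapse = "\t")
    body[3 * i - 1] <- paste0("       ", tr_fields)
    body[3 * i] <- ""
  }
  lines <- c(lines, body, "//")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read an HH-suite `.hhm` profile
#'
#' Companion reader for [write_hhsuite_hhm()]: decodes emission integers as
#' `2^(-value / 1000)` and `*` as probability 0.
#'
#' @param path File path or character vector of lines.
#'
#' @return A list with `name`, `length` and `match` (L x 20 probability
#'   matrix; rows renormalized are not applied -- values are the decoded
#'   quantized probabilities).
#' @export
read_hhsuite_hhm <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  if (length(lines) == 0) abort("empty hhm stream")
  if (!grepl("^HHsearch", lines[[1]])) abort("parse error: missing HHsearch header")
  name <- trimws(sub("^NAME\\s+", "", lines[grep("^NAME\\s", lines)[1]]))
  L <- as.integer(strsplit(trimws(sub("^LENG\\s+", "",
        lines[grep("^LENG\\s", lines)[1]])), "\\s+")[[1]][1])
  hmm_at <- grep("^HMM\\s", lines)[1]
  i <- hmm_at + 3L                    # skip column header, transition header, begin line
  dec <- function(tok) {
    out <- numeric(length(tok))
    num <- tok != "*"
    out[num] <- 2^(-as.numeric(tok[num]) / 1000)
    out
  }
  match <- matrix(NA_real_, L, 20)
  node <- 0L
  while (i <= length(lines) && trimws(lines[[i]]) != "//") {
    ln <- trimws(lines[[i]])
    if (nzchar(ln) && grepl("^[A-Z-] \\d", ln)) {
      t1 <- strsplit(ln, "\\s+")[[1]]
      node <- node + 1L
      if (node > L) abort("parse error: more match lines than LENG")
      match[node, ] <- dec(t1[3:22])
    }
    i <- i + 1L
  }
  if (node != L) abort(paste0("parse error: LENG ", L, " but ", node, " match lines"))
  colnames(match) <- as.character(alphabet())
  list(name = name, length = L, match = match)
}
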