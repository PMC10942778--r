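#' Default insert emissions and state transitions for written profiles
#'
#' Profile prediction yields match emissions only; insertion and deletion
#' behaviour is not predicted, so written profiles carry fixed defaults: a
#' high match-to-match probability with small, equal match-to-insert and
#' match-to-delete, standard insert/delete self-transitions, and flat insert
#' emissions over the 20 symbols.
#'
#' @param mm,mi,md Match transitions (must sum to 1).
#' @param im,ii Insert transitions (sum to 1).
#' @param dm,dd Delete transitions (sum to 1).
#' @param insert_emissions Length-20 probability vector for insert states.
#'
#' @return A list used as the `defaults` argument of the profile writers.
#' @export
profile_defaults <- function(mm = 0.95, mi = 0.025, md = 0.025,
                             im = 0.8, ii = 0.2, dm = 0.8, dd = 0.2,
                             insert_emissions = rep(0.05, 20)) {
  stopifnot(abs(mm + mi + md - 1) < 1e-5, abs(im + ii - 1) < 1e-5,
            abs(dm + dd - 1) < 1e-5, length(insert_emissions) == 20,
            abs(sum(insert_emissions) - 1) < 1e-5)
  list(transitions = c(mm = mm, mi = mi, md = md, im = im, ii = ii,
                       dm = dm, dd = dd),
       insert_emissions = insert_emissions)
}

# -ln(p) encoded to 5 decimals, '*' for p == 0 (the HMMER3 ascii convention)
fmt_nlog <- function(p) {
  out <- rep("      *", length(p))
  pos <- p > 0
  val <- -log(p[pos])
  val[val == 0] <- 0                     # avoid printing "-0.00000"
  out[pos] <- sprintf("%8.5f", val)
  out
}

parse_nlog <- function(tok) {
  out <- numeric(length(tok))
  num <- tok != "*"
  out[num] <- exp(-as.numeric(tok[num]))
  out
}

#' Write a positional profile as a HMMER3 ASCII `.hmm` file
#'
#' Serializes the profile's match emissions, plus the configured insert
#' emissions and transitions, in the HMMER3/f text format readable by stock
#' `hmmsearch`/`hmmscan`.  Match-emission fields store the negative natural
#' log of the probability; zero probability is written as `*`.  E-value
#' calibration (STATS) lines are deliberately omitted: downstream users who
#' need calibrated E-values can rebuild via `hmmbuild` on a sampled MSA
#' (see [sample_msa()]).
#'
#' @param profile A `positional_profile`.
#' @param path Output file path, or `NULL` to return the lines.
#' @param defaults Transition/insert configuration from [profile_defaults()].
#'
#' @return `path` invisibly (or the character vector of lines if
#'   `path = NULL`).
#' @examples
#' p <- new_positional_profile("toy", matrix(0.05, 4, 20))
#' lines <- write_hmmer3_profile(p, NULL)
#' head(lines, 4)
#' @export
write_hmmer3_profile <- function(profile, path, defaults = profile_defaults()) {
  stopifnot(inherits(profile, "positional_profile"))
  if (profile$length < 1) abort("zero-length profile")
  ab <- as.character(alphabet())
  L <- profile$length
  tr <- defaults$transitions
  ins_line <- paste(fmt_nlog(defaults$insert_emissions), collapse = " ")
  # last node: M->D and D->D are impossible (no delete state after the end)
  tr_line <- function(last = FALSE) {
    v <- c(tr[["mm"]], tr[["mi"]], if (last) 0 else tr[["md"]],
           tr[["im"]], tr[["ii"]], 1, if (last) 0 else tr[["dd"]])
    p <- fmt_nlog(v)
    if (last) { p[3] <- "      *"; p[7] <- "      *" }
    # renormalize printed m-> block for the last node: mm+mi must absorb md
    if (last) {
      mm2 <- tr[["mm"]] / (tr[["mm"]] + tr[["mi"]])
      mi2 <- tr[["mi"]] / (tr[["mm"]] + tr[["mi"]])
      p[1] <- fmt_nlog(mm2); p[2] <- fmt_nlog(mi2)
    } else {
      p[6] <- fmt_nlog(tr[["dm"]])
    }
    paste(p, collapse = " ")
  }
  compo <- colMeans(profile$probs)
  lines <- c(
    "HMMER3/f [posembed | profile writer]",
    sprintf("NAME  %s", profile$sequence_id),
    sprintf("LENG  %d", L),
    "ALPH  amino",
    "RF    no",
    "MM    no",
    "CONS  yes",
    "CS    no",
    "MAP   yes",
    paste0("HMM      ", paste(sprintf("%8s", ab), collapse = " ")),
    paste0("         ", paste(sprintf("%8s",
      c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
      collapse = " ")),
    paste0("  COMPO   ", paste(fmt_nlog(compo), collapse = " ")),
    paste0("          ", ins_line),
    paste0("          ", paste(c(fmt_nlog(c(tr[["mm"]], tr[["mi"]], tr[["md"]],
                                            tr[["im"]], tr[["ii"]], 1)),
                                 "      *"), collapse = " "))
  )
  body <- character(3L * L)
  for (i in seq_len(L)) {
    cons <- ab[which.max(profile$probs[i, ])]
    body[3 * i - 2] <- paste0(sprintf("%7d   ", i),
                              paste(fmt_nlog(profile$probs[i, ]), collapse = " "),
                              sprintf(" %6d %s - - -", i, tolower(cons)))
    body[3 * i - 1] <- paste0("          ", ins_line)
    body[3 * i]     <- paste0("          ", tr_line(last = i == L))
  }
  lines <- c(lines, body, "//")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a HMMER3 ASCII `.hmm` profile
#'
#' Parses the text profile format written by [write_hmmer3_profile()] (and by
#' `hmmbuild`), recovering probabilities by exponentiating the negated stored
#' values; `*` decodes to probability 0.
#'
#' @param path File path, or a character vector of lines.
#'
#' @return A `profile_file_model`: list with `name`, `length`, `match`
#'   (L x 20 probability matrix), `insert` (L x 20) and `transitions`
#'   (L x 7 matrix with columns mm, mi, md, im, ii, dm, dd).
#' @export
read_hmmer3_profile <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  if (length(lines) == 0) abort("empty profile stream")
  if (!grepl("^HMMER3", lines[[1]])) {
    abort("parse error at line 1: missing HMMER3 format header")
  }
  grab <- function(key) {
    i <- grep(paste0("^", key, "\\s"), lines)
    if (length(i) == 0) abort(paste0("parse error: missing ", key, " line"))
    trimws(sub(paste0("^", key, "\\s+"), "", lines[[i[1]]]))
  }
  name <- grab("NAME")
  L <- as.integer(grab("LENG"))
  alph <- grab("ALPH")
  if (!tolower(alph) %in% c("amino", "amino-acid")) {
    abort(paste0("parse error at line ", grep("^ALPH", lines)[1],
                 ": unsupported alphabet '", alph, "'"))
  }
  hmm_at <- grep("^HMM\\s", lines)[1]
  if (is.na(hmm_at)) abort("parse error: missing HMM header line")
  i <- hmm_at + 2L                    # skip the m->m transition header line
  toks <- function(j) strsplit(trimws(lines[[j]]), "\\s+")[[1]]
  if (toks(i)[1] == "COMPO") i <- i + 1L
  i <- i + 2L                         # node-0 insert and transition lines
  match <- matrix(NA_real_, L, 20)
  insert <- matrix(NA_real_, L, 20)
  trans <- matrix(NA_real_, L, 7)
  colnames(trans) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  node <- 0L
  while (i <= length(lines) && trimws(lines[[i]]) != "//") {
    t1 <- toks(i)
    node <- node + 1L
    if (node > L) {
      abort(paste0("parse error at line ", i, ": more nodes than LENG ", L))
    }
    if (suppressWarnings(as.integer(t1[1])) != node) {
      abort(paste0("parse error at line ", i, ": expected node ", node))
    }
    match[node, ] <- parse_nlog(t1[2:21])
    insert[node, ] <- parse_nlog(toks(i + 1L)[1:20])
    trans[node, ] <- parse_nlog(toks(i + 2L)[1:7])
    i <- i + 3L
  }
  if (node != L) {
    abort(paste0("parse error: LENG ", L, " but found ", node, " nodes"))
  }
  colnames(match) <- colnames(insert) <- as.character(alphabet())
  structure(list(name = name, length = L, match = match, insert = insert,
                 transitions = trans),
            class = "profile_file_model")
}
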