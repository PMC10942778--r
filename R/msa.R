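#' Multiple sequence alignments as tidy tables
#'
#' An MSA is a tibble with columns `id` and `seq` (equal-length aligned
#' strings, gap character `-`) carrying class `posembed_msa` and an
#' `alphabet` attribute.
#'
#' @param rows Tibble or data frame with columns `id`, `seq`.
#' @param alphabet An [alphabet()].
#'
#' @return A `posembed_msa` tibble.
#' @export
new_msa <- function(rows, alphabet = posembed::alphabet()) {
  rows <- as_tibble(rows)
  stopifnot(all(c("id", "seq") %in% names(rows)))
  if (length(unique(nchar(rows$seq))) > 1) abort("MSA rows must have equal length")
  if (anyDuplicated(rows$id)) abort("MSA ids must be unique")
  structure(rows, alphabet = alphabet,
            class = c("posembed_msa", class(rows)))
}

#' Sample an MSA from a positional profile
#'
#' Draws `n` ungapped sequences, sampling each column independently from the
#' profile's per-position distribution -- the sampled alignment a downstream
#' `hmmbuild` run (with or without its Dirichlet priors, see `apply_priors`
#' on the search orchestration side) consumes to produce a calibrated
#' profile.
#'
#' @param profile A `positional_profile`.
#' @param n Number of sequences (default 40).
#' @param seed Integer seed; sampling is fully reproducible.
#'
#' @return A `posembed_msa` with `n` rows of length `profile$length`.
#' @examples
#' p <- new_positional_profile("toy", matrix(0.05, 6, 20))
#' sample_msa(p, n = 3, seed = 1)
#' @export
sample_msa <- function(profile, n = 40L, seed = 1L) {
  stopifnot(inherits(profile, "positional_profile"))
  if (!is.numeric(n) || n < 1) abort("`n` must be a positive integer")
  n <- as.integer(n)
  ab <- as.character(alphabet())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  cols <- vapply(seq_len(profile$length), function(i) {
    sample(ab, n, replace = TRUE, prob = profile$probs[i, ])
  }, character(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  seqs <- apply(cols, 1, paste, collapse = "")
  new_msa(tibble(id = sprintf("%s_sample_%d", profile$sequence_id, seq_len(n)),
                 seq = seqs))
}

#' Build a calibrated profile from a sampled MSA with hmmbuild
#'
#' Orchestrates the external `hmmbuild` step of the sampled-MSA route: write
#' the MSA, run `hmmbuild` with default settings (Dirichlet priors applied)
#' or with priors disabled (`apply_priors = FALSE`, the `--pnone` option),
#' producing a calibrated `.hmm` for the sampled profile.
#'
#' @param msa A `posembed_msa` (e.g. from [sample_msa()]).
#' @param out_hmm Output profile path.
#' @param apply_priors Apply the engine's Dirichlet priors (default `TRUE`).
#' @param run Execute the command (requires `hmmbuild` on the PATH); if
#'   `FALSE`, only the command line is returned.
#' @param hmmbuild Name or path of the hmmbuild executable.
#'
#' @return The command line as a character vector (invisibly when run).
#' @export
build_profile_from_msa <- function(msa, out_hmm, apply_priors = TRUE,
                                   run = FALSE, hmmbuild = "hmmbuild") {
  stopifnot(inherits(msa, "posembed_msa"))
  msa_path <- tempfile(fileext = ".fasta")
  write_fasta(msa, msa_path)
  args <- c(if (!apply_priors) "--pnone", out_hmm, msa_path)
  cmd <- c(hmmbuild, args)
  if (!run) return(cmd)
  status <- system2(hmmbuild, args, stdout = FALSE)
  if (status != 0) abort(paste0("hmmbuild failed with status ", status))
  invisible(cmd)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
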