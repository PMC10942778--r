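#' Bin test sequences by nearest-train percent identity
#'
#' For every test sequence, finds the maximum [percent_identity()] to any
#' training sequence of the same family and assigns an identity bin.  This
#' mirrors clustered-split benchmarks where search difficulty is graded by a
#' query's distance to its closest training relative.
#'
#' @param test,train Tibbles with columns `id`, `seq`, `family`.
#' @param edges Bin edges over `[0, 100]` (default 2-point bins).
#' @param ... Passed to [percent_identity()].
#'
#' @return An `identity_binning` tibble: `id`, `family`, `nearest_identity`,
#'   `bin` (factor over the edge intervals), with the edges as an attribute.
#' @export
bin_by_identity <- function(test, train, edges = seq(0, 100, by = 2), ...) {
  stopifnot(all(c("id", "seq", "family") %in% names(test)),
            all(c("id", "seq", "family") %in% names(train)))
  missing_fams <- setdiff(test$family, train$family)
  if (length(missing_fams)) {
    abort(paste0("test families absent from train: ",
                 paste(missing_fams, collapse = ", ")))
  }
  nearest <- vapply(seq_len(nrow(test)), function(i) {
    pool <- train$seq[train$family == test$family[i]]
    max(vapply(pool, function(s) percent_identity(test$seq[i], s, ...),
               numeric(1)))
  }, numeric(1))
  out <- tibble(id = test$id, family = test$family,
                nearest_identity = nearest,
                bin = cut(nearest, breaks = edges, include.lowest = TRUE,
                          right = FALSE))
  structure(out, edges = edges,
            class = c("identity_binning", class(out)))
}

#' Run a two-iteration homology search
#'
#' First iteration runs the engine with default flags; queries that return
#' zero hits are re-searched with a relaxed flag set that trades speed for
#' sensitivity.  Hits are tagged with the iteration that produced them.  The
#' engine is any function `(queries, targets, flags) -> tibble(query,
#' target, bits)`, so external programs and test mocks plug in identically.
#'
#' @param queries,targets Tibbles with at least `id` (and usually `seq`).
#' @param engine The search contract described above.
#' @param relaxed_flags Flags for the second iteration; the default mirrors
#'   the maximize-sensitivity settings of profile-HMM tools.
#' @param default_flags Flags for the first iteration.
#'
#' @return Tibble `query`, `target`, `bits`, `iteration` (1 or 2).
#' @export
two_iteration_search <- function(queries, targets, engine,
                                 relaxed_flags = c("--max", "-Z", "1",
                                                   "--domZ", "1",
                                                   "-E", "1000000",
                                                   "--domE", "1000000"),
                                 default_flags = character(0)) {
  hits1 <- engine(queries, targets, default_flags)
  req <- c("query", "target", "bits")
  if (!all(req %in% names(hits1))) abort("engine must return query/target/bits")
  no_hit <- setdiff(queries$id, hits1$query)
  hits1$iteration <- 1L
  if (length(no_hit) == 0) return(as_tibble(hits1[c(req, "iteration")]))
  hits2 <- tryCatch(
    engine(queries[queries$id %in% no_hit, , drop = FALSE], targets,
           relaxed_flags),
    error = function(e) abort(paste0("search engine failed on relaxed pass (",
                                     length(no_hit), " queries): ",
                                     conditionMessage(e))))
  hits2$iteration <- 2L
  dplyr::bind_rows(as_tibble(hits1[c(req, "iteration")]),
                   as_tibble(hits2[c(req, "iteration")]))
}

# deterministic hit ranking: bitscore descending, target id as tie-break
rank_hits <- function(hits) {
  dplyr::arrange(hits, dplyr::desc(.data$bits), .data$target)
}

#' Identity-binned top-hit accuracy at family and clan level
#'
#' Each query is annotated with the family of its highest-bitscore hit (ties
#' broken by target id).  Family accuracy is the fraction of queries per
#' identity bin whose predicted family is correct; clan accuracy is computed
#' over only the queries that have a clan label, counting a prediction
#' correct when the predicted family's clan matches.  Queries with no hits
#' count as incorrect.
#'
#' @param hits Tibble `query`, `target`, `bits` (e.g. from
#'   [two_iteration_search()] or [read_hits_tsv()]).
#' @param labels Tibble `id`, `family` and optionally `clan` (NA = no clan),
#'   covering every query and target.
#' @param binning An [bin_by_identity()] result covering every query.
#'
#' @return A tibble `level` ("family"/"clan"), `bin`, `n`, `n_correct`,
#'   `accuracy`, one row per non-empty bin and level.
#' @export
tophit_accuracy <- function(hits, labels, binning) {
  stopifnot(all(c("query", "target", "bits") %in% names(hits)),
            all(c("id", "family") %in% names(labels)))
  if (!"clan" %in% names(labels)) labels$clan <- NA_character_
  unknown <- setdiff(hits$target, labels$id)
  if (length(unknown)) {
    abort(paste0("hits reference unlabeled targets: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (!all(binning$id %in% labels$id)) abort("binning contains unlabeled queries")
  top <- rank_hits(hits)
  top <- top[!duplicated(top$query), c("query", "target")]
  lab <- labels[, c("id", "family", "clan")]
  per_query <- dplyr::left_join(
    tibble(id = binning$id, bin = binning$bin,
           family = binning$family), top, by = c(id = "query"))
  per_query <- dplyr::left_join(per_query, setNames(lab, c("target",
      "pred_family", "pred_clan")), by = "target")
  per_query <- dplyr::left_join(per_query,
      setNames(lab[c("id", "clan")], c("id", "clan")), by = "id")
  fam <- per_query |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_correct = sum(!is.na(.data$pred_family) &
                        .data$pred_family == .data$family),
      .groups = "drop") |>
    dplyr::mutate(level = "family", accuracy = .data$n_correct / .data$n)
  clan <- per_query |>
    dplyr::filter(!is.na(.data$clan)) |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_correct = sum(!is.na(.data$pred_clan) & .data$pred_clan == .data$clan),
      .groups = "drop") |>
    dplyr::mutate(level = "clan", accuracy = .data$n_correct / .data$n)
  out <- dplyr::bind_rows(fam, clan)[, c("level", "bin", "n", "n_correct",
                                         "accuracy")]
  structure(out, class = c("tophit_accuracy", class(out)))
}

# ---- sensitivity to the first false positive -------------------------------

scop_relation <- function(query_lab, target_lab, level) {
  same_fam <- target_lab$family == query_lab$family
  same_sf <- target_lab$superfamily == query_lab$superfamily
  same_fold <- target_lab$fold == query_lab$fold
  tp <- switch(level,
    family = same_fam,
    superfamily = same_sf & !same_fam,
    fold = same_fold & !same_sf)
  ifelse(tp, "TP", ifelse(!same_fold, "FP", "ignore"))
}

#' Which queries are eligible for sensitivity scoring
#'
#' A query qualifies only if it has at least one possible true positive at
#' every level: another member of its family, another family in its
#' superfamily, and another superfamily in its fold.
#'
#' @param labels Tibble `id`, `family`, `superfamily`, `fold`.
#'
#' @return Logical vector along `labels$id`.
#' @export
scop_eligible <- function(labels) {
  vapply(seq_len(nrow(labels)), function(i) {
    l <- labels[i, ]; o <- labels[-i, ]
    any(o$family == l$family) &&
      any(o$superfamily == l$superfamily & o$family != l$family) &&
      any(o$fold == l$fold & o$superfamily != l$superfamily)
  }, logical(1))
}

#' Per-query sensitivity up to the first false positive
#'
#' Walks each eligible query's bitscore-ranked hit list (self-hits removed).
#' At a given level a hit is a true positive per the level rule (family:
#' same family; superfamily: same superfamily but different family; fold:
#' same fold but different superfamily), a false positive iff it comes from
#' a different fold, and ignored otherwise.  Sensitivity is the number of
#' true positives seen before the first false positive divided by the number
#' of possible true positives for that query at that level.
#'
#' @param hits Tibble `query`, `target`, `bits` over all queries.
#' @param labels Tibble `id`, `family`, `superfamily`, `fold` covering every
#'   query and target.
#' @param levels Levels to score.
#'
#' @return Tibble `query_id`, `level`, `sensitivity`.  Eligible queries with
#'   no hits are skipped with a warning.
#' @export
sensitivity_to_first_fp <- function(hits, labels,
                                    levels = c("family", "superfamily",
                                               "fold")) {
  stopifnot(all(c("id", "family", "superfamily", "fold") %in% names(labels)))
  unknown <- setdiff(unique(c(hits$query, hits$target)), labels$id)
  if (length(unknown)) {
    abort(paste0("hits reference unlabeled sequences: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  eligible <- labels$id[scop_eligible(labels)]
  no_hit <- setdiff(eligible, hits$query)
  if (length(no_hit)) {
    warn(paste0(length(no_hit),
                " eligible queries had no hits and were skipped"))
  }
  ranked <- rank_hits(hits)
  out <- list()
  for (q in intersect(eligible, unique(ranked$query))) {
    qlab <- labels[labels$id == q, ]
    h <- ranked[ranked$query == q & ranked$target != q, ]
    tlab <- labels[match(h$target, labels$id), ]
    olab <- labels[labels$id != q, ]
    for (lv in levels) {
      rel <- scop_relation(qlab, tlab, lv)
      possible <- sum(scop_relation(qlab, olab, lv) == "TP")
      first_fp <- match("FP", rel)
      upto <- if (is.na(first_fp)) rel else rel[seq_len(first_fp - 1L)]
      out[[length(out) + 1L]] <- tibble(
        query_id = q, level = lv,
        sensitivity = sum(upto == "TP") / possible)
    }
  }
  res <- dplyr::bind_rows(out)
  structure(res, class = c("sensitivity_result", class(res)))
}

#' Summarise per-query sensitivities
#'
#' Cumulative distribution (number of queries attaining sensitivity at least
#' `s` over a grid of `s`) and the arithmetic mean, per level.
#'
#' @param results A [sensitivity_to_first_fp()] tibble.
#' @param grid Sensitivity grid (default 0 to 1 by 0.01).
#'
#' @return A `sensitivity_summary`: list with `curve` (tibble `level`, `s`,
#'   `n_queries`) and `means` (tibble `level`, `mean_sensitivity`, `n`).
#' @export
sensitivity_summary <- function(results, grid = seq(0, 1, by = 0.01)) {
  if (nrow(results) == 0) abort("no sensitivity results to summarise")
  curve <- dplyr::bind_rows(lapply(split(results, results$level), function(d) {
    tibble(level = d$level[1], s = grid,
           n_queries = vapply(grid, function(g)
             sum(d$sensitivity >= g), integer(1)))
  }))
  means <- results |>
    dplyr::group_by(level = .data$level) |>
    dplyr::summarise(mean_sensitivity = mean(.data$sensitivity),
                     n = dplyr::n(), .groups = "drop")
  structure(list(curve = curve, means = means),
            class = "sensitivity_summary")
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat("<sensitivity_summary>\n")
  print(x$means)
  invisible(x)
}

#' Read search hits from a TSV file
#'
#' Accepts the three-column `query target bits` dialect written by
#' `convertalis`-style exporters, and HMMER `--tblout` tables (first, third
#' and sixth whitespace-separated fields).  Comment lines (`#`) are skipped.
#'
#' @param path File path.
#' @param format `"tsv"` or `"tblout"`.
#'
#' @return Tibble `query`, `target`, `bits`.
#' @export
read_hits_tsv <- function(path, format = c("tsv", "tblout")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(tibble(query = character(0),
                                        target = character(0),
                                        bits = numeric(0)))
  toks <- strsplit(trimws(lines), "\\s+")
  if (format == "tsv") {
    tibble(query = vapply(toks, `[[`, character(1), 1),
           target = vapply(toks, `[[`, character(1), 2),
           bits = as.numeric(vapply(toks, `[[`, character(1), 3)))
  } else {
    tibble(query = vapply(toks, `[[`, character(1), 3),
           target = vapply(toks, `[[`, character(1), 1),
           bits = as.numeric(vapply(toks, `[[`, character(1), 6)))
  }
}
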