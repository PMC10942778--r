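aa20 <- as.character(alphabet())

test_that("percent identity handles the boundary cases", {
  expect_equal(percent_identity("ACDEFGHIK", "ACDEFGHIK"), 100)
  expect_equal(percent_identity("AAAA", "WWWW"), 0)
  expect_equal(percent_identity("ACDE", "ACDE"),
               percent_identity("ACDE", "ACDE"))
  expect_error(percent_identity("", "ACD"), "non-empty")
})

test_that("percent identity equals an independent DP oracle and is symmetric", {
  set.seed(21)
  for (i in 1:12) {
    a <- paste(sample(aa20, sample(5:12, 1), TRUE), collapse = "")
    b <- paste(sample(aa20, sample(5:12, 1), TRUE), collapse = "")
    expect_equal(percent_identity(a, b), oracle_percent_identity(a, b),
                 info = paste(a, b))
  }
  for (i in 1:6) {
    a <- paste(sample(aa20, 20, TRUE), collapse = "")
    b <- paste(c(sample(aa20, 5, TRUE), strsplit(a, "")[[1]][6:20]),
               collapse = "")
    expect_equal(percent_identity(a, b), percent_identity(b, a))
  }
})

test_that("alignment scores match Biostrings pairwiseAlignment exactly", {
  set.seed(22)
  for (i in 1:8) {
    a <- paste(sample(aa20, sample(15:35, 1), TRUE), collapse = "")
    b <- paste(sample(aa20, sample(15:35, 1), TRUE), collapse = "")
    g <- posembed:::align_global(a, b, blosum62(), 10, 1)
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1, type = "global"))
    expect_equal(g$score, ref)
  }
})

test_that("identity binning finds the nearest training relative per family", {
  fams <- gen_families(family_spec(n_families = 3, n_train = 3, n_test = 1,
                                   length_range = c(40L, 50L),
                                   identity_range = c(40, 80), seed = 31))
  binning <- bin_by_identity(fams$test, fams$train)
  # nearest-neighbour identity equals an exhaustive same-family scan
  for (i in seq_len(nrow(fams$test))) {
    pool <- fams$train[fams$train$family == fams$test$family[i], ]
    brute <- max(vapply(pool$seq, function(s)
      percent_identity(fams$test$seq[i], s), numeric(1)))
    expect_equal(binning$nearest_identity[i], brute)
  }
  expect_equal(nrow(binning), nrow(fams$test))   # partition: one bin each
  expect_false(anyNA(binning$bin))

  # a test sequence identical to a train member lands in the top bin
  dup_test <- fams$train[1, ]; dup_test$id <- "dup"
  b2 <- bin_by_identity(dup_test, fams$train)
  expect_equal(b2$nearest_identity, 100)
  expect_equal(as.character(b2$bin), "[98,100]")

  orphan <- tibble::tibble(id = "x", seq = "ACDEF", family = "NOFAM")
  expect_error(bin_by_identity(orphan, fams$train), "NOFAM")
})

test_that("two-iteration search only re-searches zero-hit queries", {
  queries <- tibble::tibble(id = c("q1", "q2", "q3"))
  targets <- tibble::tibble(id = c("t1", "t2"))
  calls <- list()
  engine <- function(q, t, flags) {
    calls[[length(calls) + 1]] <<- list(ids = q$id, flags = flags)
    if (length(flags) == 0) {
      tibble::tibble(query = c("q1", "q3"), target = "t1", bits = c(50, 40))
    } else {
      tibble::tibble(query = q$id, target = "t2", bits = 5)
    }
  }
  hits <- two_iteration_search(queries, targets, engine)
  expect_equal(length(calls), 2)
  expect_equal(calls[[2]]$ids, "q2")                  # only the no-hit query
  expect_true(all(c("--max", "-E") %in% calls[[2]]$flags))
  expect_equal(hits$iteration[hits$query == "q2"], 2L)
  expect_equal(hits$iteration[hits$query == "q1"], 1L)

  # all queries hit in iteration 1 -> engine called once
  calls <- list()
  engine_all <- function(q, t, flags) {
    calls[[length(calls) + 1]] <<- flags
    tibble::tibble(query = q$id, target = "t1", bits = 1)
  }
  h2 <- two_iteration_search(queries, targets, engine_all)
  expect_equal(length(calls), 1)
  expect_true(all(h2$iteration == 1L))
})

test_that("randomized two-iteration runs match a protocol oracle", {
  set.seed(33)
  for (rep in 1:20) {
    qids <- sprintf("q%d", 1:8)
    hit1 <- sample(qids, sample(0:8, 1))
    hit2 <- sample(qids, sample(0:8, 1))
    engine <- function(q, t, flags) {
      pool <- if (length(flags) == 0) hit1 else hit2
      ok <- intersect(q$id, pool)
      tibble::tibble(query = ok, target = "t", bits = seq_along(ok) + 0)
    }
    hits <- two_iteration_search(tibble::tibble(id = qids),
                                 tibble::tibble(id = "t"), engine)
    # oracle: iteration 1 = hit1; iteration 2 = hit2 minus hit1
    expect_setequal(hits$query[hits$iteration == 1], hit1)
    expect_setequal(hits$query[hits$iteration == 2], setdiff(hit2, hit1))
  }
})

test_that("top-hit accuracy follows the worked examples", {
  labels <- tibble::tibble(id = c(sprintf("q%d", 1:4), "tA", "tB"),
                           family = c(rep("famA", 4), "famA", "famB"),
                           clan = c(rep("cl1", 4), "cl1", "cl2"))
  binning <- structure(
    tibble::tibble(id = sprintf("q%d", 1:4), family = "famA",
                   nearest_identity = 50,
                   bin = factor(rep("[50,52)", 4))),
    class = c("identity_binning", "tbl_df", "tbl", "data.frame"))
  hits_all <- tibble::tibble(query = sprintf("q%d", 1:4), target = "tA",
                             bits = 10)
  acc <- tophit_accuracy(hits_all, labels, binning)
  expect_equal(acc$accuracy[acc$level == "family"], 1.0)

  hits_one_wrong <- hits_all
  hits_one_wrong$target[2] <- "tB"
  acc2 <- tophit_accuracy(hits_one_wrong, labels, binning)
  expect_equal(acc2$accuracy[acc2$level == "family"], 0.75)
  expect_equal(acc2$accuracy[acc2$level == "clan"], 0.75)

  expect_error(tophit_accuracy(
    tibble::tibble(query = "q1", target = "nosuch", bits = 1),
    labels, binning), "unlabeled")
})

test_that("top-hit accuracy equals a brute-force recount on random instances", {
  set.seed(34)
  for (rep in 1:30) {
    n_fam <- 3
    fams <- sprintf("fam%d", 1:n_fam)
    clans <- c("clA", "clB", NA)
    targets <- tibble::tibble(id = sprintf("t%d", 1:6),
                              family = rep(fams, 2))
    queries <- tibble::tibble(id = sprintf("q%d", 1:8),
                              family = sample(fams, 8, TRUE))
    labels <- dplyr::bind_rows(targets, queries)
    labels$clan <- clans[match(labels$family, fams)]
    binning <- structure(
      tibble::tibble(id = queries$id, family = queries$family,
                     nearest_identity = runif(8, 0, 100)),
      class = c("identity_binning", "tbl_df", "tbl", "data.frame"))
    binning$bin <- cut(binning$nearest_identity, c(0, 50, 100),
                       include.lowest = TRUE, right = FALSE)
    n_hits <- sample(5:20, 1)
    hits <- tibble::tibble(
      query = sample(queries$id, n_hits, TRUE),
      target = sample(targets$id, n_hits, TRUE),
      bits = sample(1:5, n_hits, TRUE) + 0)   # ties on purpose
    got <- tophit_accuracy(hits, labels, binning)
    want <- oracle_tophit(hits, labels, binning)
    merged <- merge(as.data.frame(got), want, by = c("level", "bin"))
    expect_gt(nrow(merged), 0)
    expect_equal(merged$accuracy.x, merged$accuracy.y)
    expect_equal(merged$n.x, merged$n.y)
  }
})

test_that("sensitivity walker follows the level rules and worked example", {
  labels <- tibble::tibble(
    id = c("q", "famMate", "sf1", "sf2", "decoy", "foldMate"),
    family = c("a.1.1", "a.1.1", "a.1.2", "a.1.3", "b.1.1", "a.2.1"),
    superfamily = c("a.1", "a.1", "a.1", "a.1", "b.1", "a.2"),
    fold = c("a", "a", "a", "a", "b", "a"))
  # ranking: same-family, sameSF-diffFam, diff-fold, sameSF-diffFam
  hits <- tibble::tibble(query = "q",
                         target = c("famMate", "sf1", "decoy", "sf2"),
                         bits = c(40, 30, 20, 10))
  res <- suppressWarnings(sensitivity_to_first_fp(hits, labels))
  expect_equal(res$sensitivity[res$level == "superfamily"], 0.5)
  expect_equal(res$sensitivity[res$level == "family"], 1.0)

  # first-ranked hit from a different fold -> 0 at every level
  hits0 <- tibble::tibble(query = "q", target = c("decoy", "famMate"),
                          bits = c(99, 1))
  res0 <- suppressWarnings(sensitivity_to_first_fp(hits0, labels))
  expect_true(all(res0$sensitivity == 0))

  # all possible TPs found with no FP -> 1 at every level
  hits1 <- tibble::tibble(query = "q",
                          target = c("famMate", "sf1", "sf2", "foldMate"),
                          bits = c(4, 3, 2, 1))
  res1 <- suppressWarnings(sensitivity_to_first_fp(hits1, labels))
  expect_true(all(res1$sensitivity == 1))

  expect_error(sensitivity_to_first_fp(
    tibble::tibble(query = "q", target = "unknown", bits = 1), labels),
    "unlabeled")
})

test_that("eligibility requires a possible TP at every level", {
  labels <- tibble::tibble(
    id = c("q", "famMate", "sfMate", "foldMate", "lonely"),
    family = c("a.1.1", "a.1.1", "a.1.2", "a.2.1", "c.9.9"),
    superfamily = c("a.1", "a.1", "a.1", "a.2", "c.9"),
    fold = c("a", "a", "a", "a", "c"))
  elig <- scop_eligible(labels)
  expect_true(elig[1])                  # q has all three relations
  expect_false(elig[5])                 # lonely has none
  hits <- tibble::tibble(query = c("q", "lonely"),
                         target = c("famMate", "q"), bits = c(2, 1))
  res <- suppressWarnings(sensitivity_to_first_fp(hits, labels))
  expect_false("lonely" %in% res$query_id)
})

test_that("sensitivity agrees with a brute-force walker on random instances", {
  set.seed(35)
  n_checked <- 0
  for (rep in 1:30) {
    labels <- random_scop_labels(12)
    elig <- scop_eligible(labels)
    n_hits <- sample(10:40, 1)
    hits <- tibble::tibble(
      query = sample(labels$id, n_hits, TRUE),
      target = sample(labels$id, n_hits, TRUE),
      bits = sample(1:8, n_hits, TRUE) + 0)
    hits <- dplyr::distinct(hits, query, target, .keep_all = TRUE)
    res <- suppressWarnings(sensitivity_to_first_fp(hits, labels))
    for (i in seq_len(nrow(res))) {
      want <- oracle_sensitivity(res$query_id[i], hits, labels, res$level[i])
      expect_equal(res$sensitivity[i], want,
                   info = paste(rep, res$query_id[i], res$level[i]))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)
})

test_that("sensitivity summaries compute cumulative curves and means", {
  res <- structure(tibble::tibble(
    query_id = sprintf("q%d", 1:3), level = "superfamily",
    sensitivity = c(0, 0.5, 1)),
    class = c("sensitivity_result", "tbl_df", "tbl", "data.frame"))
  s <- sensitivity_summary(res)
  expect_equal(s$means$mean_sensitivity, 0.5)
  expect_equal(s$curve$n_queries[s$curve$s == 0], 3L)
  expect_equal(s$curve$n_queries[s$curve$s == 1], 1L)
  expect_true(all(diff(s$curve$n_queries) <= 0))   # monotone non-increasing

  all_one <- res; all_one$sensitivity <- 1
  s1 <- sensitivity_summary(all_one)
  expect_true(all(s1$curve$n_queries == 3L))
  expect_equal(s1$means$mean_sensitivity, 1)

  set.seed(36)
  r <- res[rep(1, 50), ]; r$sensitivity <- runif(50)
  s2 <- sensitivity_summary(r)
  expect_equal(s2$means$mean_sensitivity, mean(r$sensitivity))
})

test_that("hit tables parse from TSV and tblout dialects", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "q1\tt1\t52.3", "q2\tt2\t11.0"), f)
  h <- read_hits_tsv(f)
  expect_equal(h$query, c("q1", "q2"))
  expect_equal(h$bits, c(52.3, 11.0))
  f2 <- withr::local_tempfile()
  writeLines(c("#                                  --- full sequence ----",
               "t1  -  q1  -  1e-30  99.9  0.1  ..."), f2)
  h2 <- read_hits_tsv(f2, format = "tblout")
  expect_equal(h2, tibble::tibble(query = "q1", target = "t1", bits = 99.9))
})
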