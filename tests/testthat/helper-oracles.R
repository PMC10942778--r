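# Independent oracles used to validate package computations.  Each is a
# deliberately naive implementation (recursion, direct loops, Monte Carlo)
# kept separate from the package's code paths.

# affine-gap global alignment by memoized recursion; same scoring and
# tie-break convention (aligned pair > gap-in-b > gap-in-a) as the package
oracle_align <- function(a, b, mat = posembed::blosum62(),
                         gap_open = 10, gap_extension = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- gap_open + gap_extension; ge <- gap_extension
  memo <- new.env(parent = emptyenv())
  # best score of an alignment of A[1..i], B[1..j] ending in `state`
  sc <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (state == "M") {
      if (i == 0 && j == 0) 0
      else if (i == 0 || j == 0) -Inf
      else max(sc(i - 1, j - 1, "M"), sc(i - 1, j - 1, "X"),
               sc(i - 1, j - 1, "Y")) + mat[A[i], B[j]]
    } else if (state == "X") {          # A[i] over a gap
      if (i == 0) -Inf
      else max(sc(i - 1, j, "M") - go, sc(i - 1, j, "X") - ge,
               sc(i - 1, j, "Y") - go)
    } else {                            # gap over B[j]
      if (j == 0) -Inf
      else max(sc(i, j - 1, "M") - go, sc(i, j - 1, "Y") - ge,
               sc(i, j - 1, "X") - go)
    }
    memo[[key]] <- val
    val
  }
  states <- c("M", "X", "Y")
  finals <- vapply(states, function(s) sc(n, m, s), numeric(1))
  state <- states[which.max(finals)]
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (state == "M") {
      ra <- c(A[i], ra); rb <- c(B[j], rb)
      target <- sc(i, j, "M") - mat[A[i], B[j]]
      prev <- vapply(states, function(s) sc(i - 1, j - 1, s), numeric(1))
      i <- i - 1; j <- j - 1
      state <- states[which(abs(prev - target) < 1e-9)[1]]
    } else if (state == "X") {
      ra <- c(A[i], ra); rb <- c("-", rb)
      cand <- c(sc(i - 1, j, "M") - go, sc(i - 1, j, "X") - ge,
                sc(i - 1, j, "Y") - go)
      target <- sc(i, j, "X")
      i <- i - 1
      state <- states[which(abs(cand - target) < 1e-9)[1]]
    } else {
      ra <- c("-", ra); rb <- c(B[j], rb)
      cand <- c(sc(i, j - 1, "M") - go, sc(i, j - 1, "Y") - ge,
                sc(i, j - 1, "X") - go)
      target <- sc(i, j, "Y")
      j <- j - 1
      state <- c("M", "Y", "X")[which(abs(cand - target) < 1e-9)[1]]
    }
    if (i == 0 && j == 0) break
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = max(finals))
}

oracle_percent_identity <- function(a, b, ...) {
  aln <- oracle_align(a, b, ...)
  pa <- strsplit(aln$a, "")[[1]]; pb <- strsplit(aln$b, "")[[1]]
  100 * sum(pa == pb & pa != "-") / length(pa)
}

# direct recount of per-bin top-hit accuracy with explicit loops
oracle_tophit <- function(hits, labels, binning) {
  lab_of <- function(id, col) labels[[col]][match(id, labels$id)]
  res <- list()
  for (lv in c("family", "clan")) {
    ids <- binning$id
    if (lv == "clan") ids <- ids[!is.na(lab_of(ids, "clan"))]
    for (bn in levels(binning$bin)) {
      in_bin <- ids[as.character(binning$bin[match(ids, binning$id)]) == bn]
      if (length(in_bin) == 0) next
      ok <- 0
      for (q in in_bin) {
        h <- hits[hits$query == q, ]
        if (nrow(h) == 0) next
        h <- h[order(-h$bits, h$target), ]
        pred_fam <- lab_of(h$target[1], "family")
        if (lv == "family") {
          ok <- ok + (pred_fam == lab_of(q, "family"))
        } else {
          pc <- labels$clan[match(pred_fam, labels$family)]
          ok <- ok + (!is.na(pc) && pc == lab_of(q, "clan"))
        }
      }
      res[[length(res) + 1L]] <- data.frame(level = lv, bin = bn,
                                            n = length(in_bin),
                                            n_correct = ok,
                                            accuracy = ok / length(in_bin))
    }
  }
  do.call(rbind, res)
}

# explicit walker for sensitivity up to the first false positive
oracle_sensitivity <- function(q, hits, labels, level) {
  lab <- function(id) labels[match(id, labels$id), ]
  ql <- lab(q)
  is_tp <- function(tl) {
    if (level == "family") tl$family == ql$family
    else if (level == "superfamily") tl$superfamily == ql$superfamily &&
      tl$family != ql$family
    else tl$fold == ql$fold && tl$superfamily != ql$superfamily
  }
  possible <- 0
  for (id in setdiff(labels$id, q)) if (is_tp(lab(id))) possible <- possible + 1
  h <- hits[hits$query == q & hits$target != q, ]
  h <- h[order(-h$bits, h$target), ]
  found <- 0
  for (t in h$target) {
    tl <- lab(t)
    if (is_tp(tl)) found <- found + 1
    else if (tl$fold != ql$fold) break
  }
  found / possible
}

# Monte-Carlo estimate of E[prod_a p_a^{c_a}] under a Dirichlet mixture,
# returned with its standard error
oracle_mc_marginal <- function(counts, mixture, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  A <- length(counts)
  comp <- sample.int(mixture$K, n_draws, replace = TRUE, prob = mixture$q)
  shapes <- t(mixture$alpha[comp, , drop = FALSE])   # A x n_draws
  G <- matrix(rgamma(A * n_draws, shape = shapes), A, n_draws)
  P <- sweep(G, 2, colSums(G), "/")
  w <- exp(as.vector(counts %*% log(P)))
  list(mean = mean(w), se = sd(w) / sqrt(n_draws))
}

# random row-stochastic profile
random_profile <- function(L, id = "rand", concentrated = FALSE) {
  g <- matrix(rgamma(L * 20, shape = if (concentrated) 0.3 else 1), L, 20)
  posembed::new_positional_profile(id, g / rowSums(g))
}

random_scop_labels <- function(n, n_folds = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(sprintf("fold%d", seq_len(n_folds)), n, replace = TRUE)
  sf <- paste0(fold, ".", sample(1:2, n, replace = TRUE))
  fam <- paste0(sf, ".", sample(1:2, n, replace = TRUE))
  tibble::tibble(id = sprintf("d%03d", seq_len(n)),
                 family = fam, superfamily = sf, fold = fold)
}
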