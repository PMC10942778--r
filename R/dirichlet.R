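#' Collect residue counts from structure-alphabet MSA columns
#'
#' Tallies, for every alignment column deep enough to be informative, how
#' many times each of the 20 alphabet symbols occurs.  A column is retained
#' when it has more than `min_rows` non-gap symbols (with a constant-depth
#' alignment the row count itself would make the rule vacuous, so depth is
#' counted per column over non-gap residues).  Gaps (`-`, `.`) and unknown
#' residues (X/B/Z/U/O) are excluded from the counts; columns whose retained
#' count is zero after exclusion are dropped.
#'
#' @param msas A `posembed_msa` or list of them.
#' @param min_rows Minimum column depth; a column is kept iff its non-gap
#'   count exceeds this (default 10).
#'
#' @return An N x 20 integer matrix of column counts (one row per retained
#'   column), columns in alphabet order, with a `source` attribute naming
#'   the MSA and column of each row.
#' @export
collect_column_counts <- function(msas, min_rows = 10L) {
  if (inherits(msas, "posembed_msa")) msas <- list(msas)
  ab <- as.character(alphabet("3Di"))
  out <- list(); src <- character(0)
  for (mi in seq_along(msas)) {
    msa <- msas[[mi]]
    chars <- do.call(rbind, strsplit(msa$seq, ""))
    bad <- setdiff(unique(as.vector(chars)), c(ab, GAP_CHARS, AMBIGUITY_CODES))
    if (length(bad)) {
      abort(paste0("symbol outside alphabet in MSA ", mi, ": ",
                   paste(bad, collapse = ", ")))
    }
    for (j in seq_len(ncol(chars))) {
      col <- chars[, j]
      nongap <- col[!col %in% GAP_CHARS]
      if (length(nongap) <= min_rows) next
      counts <- tabulate(match(nongap, ab), nbins = 20L)
      if (sum(counts) == 0) next
      out[[length(out) + 1L]] <- counts
      src <- c(src, sprintf("msa%d_col%d", mi, j))
    }
  }
  if (length(out) == 0) {
    m <- matrix(integer(0), 0, 20, dimnames = list(NULL, ab))
    return(structure(m, source = character(0)))
  }
  m <- do.call(rbind, out)
  colnames(m) <- ab
  structure(m, source = src)
}

#' Estimate background symbol frequencies from column counts
#'
#' Pools all counts, adds a pseudocount to every symbol, and normalizes.
#'
#' @param counts N x 20 count matrix (e.g. from [collect_column_counts()]).
#' @param pseudocount Additive smoothing per symbol (default 1).
#'
#' @return A length-20 probability vector summing to 1.
#' @export
estimate_background <- function(counts, pseudocount = 1) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (nrow(counts) == 0) abort("no column counts to pool")
  pooled <- colSums(counts) + pseudocount
  p <- pooled / sum(pooled)
  names(p) <- as.character(alphabet("3Di"))
  p
}

#' Mixture-of-Dirichlets objects
#'
#' @param q Length-K mixture coefficients on the simplex.
#' @param alpha K x 20 matrix of strictly positive concentration parameters.
#'
#' @return A `dirichlet_mixture`.
#' @export
new_dirichlet_mixture <- function(q, alpha) {
  if (is.null(dim(alpha))) alpha <- matrix(alpha, nrow = 1)
  stopifnot(length(q) == nrow(alpha))
  if (abs(sum(q) - 1) > 1e-8 || any(q < 0)) abort("`q` must lie on the simplex")
  if (any(alpha <= 0)) abort("Dirichlet concentrations must be strictly positive")
  structure(list(K = length(q), q = as.numeric(q), alpha = unname(alpha)),
            class = "dirichlet_mixture")
}

#' @export
print.dirichlet_mixture <- function(x, ...) {
  cat("<dirichlet_mixture: ", x$K, " components over ", ncol(x$alpha),
      " symbols>\n", sep = "")
  invisible(x)
}

# per-column, per-component Dirichlet-multinomial log marginals
# (ordered-draw convention: the multinomial coefficient, constant in the
# parameters, is excluded).  counts: N x A matrix.
dm_component_loglik <- function(counts, alpha_k) {
  n <- rowSums(counts)
  a0 <- sum(alpha_k)
  lgamma(a0) - lgamma(n + a0) +
    rowSums(lgamma(sweep(counts, 2, alpha_k, "+"))) - sum(lgamma(alpha_k))
}

#' Log marginal likelihood of counts under a Dirichlet mixture
#'
#' Computes `log sum_k q_k * DirMult(counts | alpha_k)` per count vector via
#' log-sum-exp.  The multinomial coefficient is excluded (ordered-draw
#' convention): it is constant in the parameters, so objective values are
#' comparable across mixtures but not across conventions.
#'
#' @param counts A length-20 count vector or N x 20 matrix.
#' @param mixture A `dirichlet_mixture`.
#'
#' @return Numeric vector of per-column log marginals.
#' @examples
#' mix <- new_dirichlet_mixture(1, rep(1, 20))
#' dirichlet_multinomial_logmarginal(c(1, rep(0, 19)), mix)  # log(1/20)
#' @export
dirichlet_multinomial_logmarginal <- function(counts, mixture) {
  stopifnot(inherits(mixture, "dirichlet_mixture"))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (ncol(counts) != ncol(mixture$alpha)) {
    abort("counts and mixture have different alphabet sizes")
  }
  ll <- vapply(seq_len(mixture$K), function(k)
    dm_component_loglik(counts, mixture$alpha[k, ]), numeric(nrow(counts)))
  if (nrow(counts) == 1) ll <- matrix(ll, nrow = 1)
  ll <- sweep(ll, 2, log(mixture$q), "+")
  mx <- apply(ll, 1, max)
  mx + log(rowSums(exp(ll - mx)))
}

#' Fit a maximum-likelihood mixture of Dirichlets to column counts
#'
#' Expectation-maximization on the Dirichlet-multinomial mixture marginal:
#' the E-step computes per-column component responsibilities, the M-step
#' updates mixture weights in closed form and each component's concentration
#' vector by the standard fixed-point iteration for the Polya distribution
#' (a minorize-maximize step, so the objective never decreases).  The best
#' of `restarts` seeded initializations is returned.
#'
#' @param counts N x 20 (or N x A) count matrix.
#' @param K Number of mixture components (default 9).
#' @param seed Base seed for initialization (default 17).
#' @param restarts Number of random restarts (default 5).
#' @param tolerance Stop when the objective gain per EM iteration falls
#'   below this (default 1e-6).
#' @param max_iter Maximum EM iterations per restart.
#' @param alpha_floor Lower bound on concentrations, guarding degenerate
#'   (single-symbol) data; hitting it triggers a warning.
#'
#' @return A `dirichlet_mixture_fit`: list with `mixture`
#'   (a [new_dirichlet_mixture()]), `loglik` (final objective),
#'   `trace` (objective per EM iteration of the winning restart),
#'   `converged`, and `n_columns`.
#' @export
fit_mixture_dirichlet <- function(counts, K = 9L, seed = 17L, restarts = 5L,
                                  tolerance = 1e-6, max_iter = 200L,
                                  alpha_floor = 1e-4) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  N <- nrow(counts); A <- ncol(counts)
  if (N < K) abort("need at least K count vectors to fit K components")
  n_i <- rowSums(counts)
  freq <- sweep(counts, 1, pmax(n_i, 1), "/")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  best <- NULL
  floored <- FALSE
  for (r in seq_len(restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    # moment-flavoured init: component means from perturbed random columns
    centers <- freq[sample(N, K), , drop = FALSE] + 0.1
    centers <- sweep(centers, 1, rowSums(centers), "/")
    alpha <- sweep(centers, 1, exp(runif(K, log(1), log(20))), "*")
    alpha <- pmax(alpha, alpha_floor)
    q <- rep(1 / K, K)
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      ll <- vapply(seq_len(K), function(k)
        dm_component_loglik(counts, alpha[k, ]), numeric(N))
      if (N == 1) ll <- matrix(ll, nrow = 1)
      ll <- sweep(ll, 2, log(q), "+")
      mx <- apply(ll, 1, max)
      obj <- sum(mx + log(rowSums(exp(ll - mx))))
      trace <- c(trace, obj)
      if (iter > 1 && obj - prev < tolerance) { converged <- TRUE; break }
      prev <- obj
      resp <- exp(ll - mx)
      resp <- resp / rowSums(resp)
      q <- pmax(colSums(resp) / N, 1e-12)
      q <- q / sum(q)
      for (k in seq_len(K)) {
        w <- resp[, k]
        if (sum(w) < 1e-10) next
        a <- alpha[k, ]
        for (inner in 1:25) {
          a0 <- sum(a)
          num <- colSums(w * digamma(sweep(counts, 2, a, "+"))) -
            sum(w) * digamma(a)
          den <- sum(w * digamma(n_i + a0)) - sum(w) * digamma(a0)
          if (den <= 0) break
          a_new <- pmax(a * num / den, alpha_floor)
          if (any(a_new == alpha_floor)) floored <- TRUE
          if (max(abs(a_new - a)) < 1e-8) { a <- a_new; break }
          a <- a_new
        }
        alpha[k, ] <- a
      }
    }
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- list(mixture = new_dirichlet_mixture(q, alpha),
                   loglik = trace[length(trace)], trace = trace,
                   converged = converged)
    }
  }
  if (floored) {
    warn("some Dirichlet concentrations hit the lower floor (degenerate counts)")
  }
  structure(c(best, list(n_columns = N, K = K)),
            class = "dirichlet_mixture_fit")
}

#' @export
print.dirichlet_mixture_fit <- function(x, ...) {
  cat("<dirichlet_mixture_fit: K = ", x$K, ", n = ", x$n_columns,
      ", logLik ", signif(x$loglik, 6),
      if (x$converged) ", converged" else "", ">\n", sep = "")
  invisible(x)
}

#' Export a Dirichlet-mixture prior file
#'
#' Writes a plain-text prior block: one `Q k value` line per mixture
#' coefficient, one `ALPHA k v1..v20` line per component, and a final
#' `BACKGROUND` line -- the artifact substituted into a profile-HMM engine
#' in place of its amino-acid priors.
#'
#' @param mixture A `dirichlet_mixture` (or `dirichlet_mixture_fit`).
#' @param background A length-20 probability vector.
#' @param path Output path, or `NULL` for lines.
#'
#' @return `path` invisibly (or lines).
#' @export
export_priors <- function(mixture, background, path = NULL) {
  if (inherits(mixture, "dirichlet_mixture_fit")) mixture <- mixture$mixture
  stopifnot(inherits(mixture, "dirichlet_mixture"))
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  fmt <- function(x) sprintf("%.10g", x)
  lines <- c(
    "# posembed structure-alphabet prior file",
    sprintf("ALPHABET %s", paste(as.character(alphabet("3Di")), collapse = "")),
    sprintf("K %d", mixture$K),
    sprintf("Q %d %s", seq_len(mixture$K), fmt(mixture$q)),
    vapply(seq_len(mixture$K), function(k)
      sprintf("ALPHA %d %s", k, paste(fmt(mixture$alpha[k, ]), collapse = " ")),
      character(1)),
    paste0("BACKGROUND ", paste(fmt(background), collapse = " "))
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_priors
#' @export
read_priors <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[!grepl("^#", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  key <- vapply(toks, `[[`, character(1), 1)
  K <- as.integer(toks[[which(key == "K")]][2])
  q <- numeric(K); alpha <- matrix(NA_real_, K, 20)
  for (t in toks[key == "Q"]) q[as.integer(t[2])] <- as.numeric(t[3])
  for (t in toks[key == "ALPHA"]) {
    alpha[as.integer(t[2]), ] <- as.numeric(t[-(1:2)])
  }
  background <- as.numeric(toks[[which(key == "BACKGROUND")]][-1])
  list(mixture = new_dirichlet_mixture(q, alpha), background = background)
}
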