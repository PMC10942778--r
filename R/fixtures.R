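#' Specification of a synthetic protein-family benchmark
#'
#' Describes how to generate families of related sequences with controlled
#' identity structure, emulating clustered train/test splits where each test
#' sequence sits at a known percent identity from its closest training
#' relative.
#'
#' @param n_families Number of families.
#' @param n_train,n_test Members per family in each split.
#' @param length_range Ancestor length range (substitution-only evolution,
#'   so all members share the ancestor's length).
#' @param identity_range Target range for each test member's nearest-train
#'   identity, in percent (achieved within about +/- 5 points).
#' @param clan_size Families per clan; families beyond full clans get no
#'   clan label.
#' @param seed Seed; generation is fully deterministic.
#'
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_families = 6L, n_train = 4L, n_test = 2L,
                        length_range = c(60L, 80L),
                        identity_range = c(20, 90), clan_size = 2L,
                        seed = 1L) {
  stopifnot(identity_range[1] >= 0, identity_range[2] <= 100,
            identity_range[1] <= identity_range[2], all(length_range >= 10))
  structure(list(n_families = as.integer(n_families),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 length_range = as.integer(length_range),
                 identity_range = identity_range,
                 clan_size = as.integer(clan_size), seed = as.integer(seed)),
            class = "family_spec")
}

# sample() treats a scalar first argument as 1:n; guard degenerate ranges
sample_range <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1)

mutate_seq <- function(chars, n_sub, ab) {
  pos <- sample(length(chars), min(n_sub, length(chars)))
  for (p in pos) chars[p] <- sample(setdiff(ab, chars[p]), 1)
  chars
}

#' Generate synthetic protein families with controlled identity
#'
#' Each family grows from a random ancestor by seeded point substitutions
#' (no indels, so identity arithmetic stays exact).  Train members are mild
#' variants of the ancestor; each test member is mutated away from a train
#' member until its nearest-train [percent_identity()] falls inside the
#' requested range (iterative mutate-measure calibration, tolerance about
#' 5 points; unattainable ranges raise an error).
#'
#' @param spec A [family_spec()].
#'
#' @return List with tibbles `train` and `test` (`id`, `seq`, `family`) and
#'   `labels` (`id`, `family`, `clan`; clan `NA` where unassigned).
#' @export
gen_families <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  ab <- as.character(alphabet())
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  train <- list(); test <- list()
  for (f in seq_len(spec$n_families)) {
    fam <- sprintf("FAM%03d", f)
    L <- sample_range(spec$length_range[1], spec$length_range[2])
    ancestor <- sample(ab, L, replace = TRUE)
    members <- lapply(seq_len(spec$n_train), function(k) {
      if (k == 1) ancestor else mutate_seq(ancestor, ceiling(0.08 * L), ab)
    })
    train[[f]] <- tibble(
      id = sprintf("%s_train%02d", fam, seq_len(spec$n_train)),
      seq = vapply(members, paste, character(1), collapse = ""),
      family = fam)
    test[[f]] <- dplyr::bind_rows(lapply(seq_len(spec$n_test), function(k) {
      target <- runif(1, spec$identity_range[1], spec$identity_range[2])
      parent <- members[[sample(spec$n_train, 1)]]
      chars <- parent
      nearest <- function(ch) {
        s <- paste(ch, collapse = "")
        max(vapply(train[[f]]$seq, function(tr) percent_identity(s, tr),
                   numeric(1)))
      }
      cur <- nearest(chars)
      tries <- 0L
      while (cur > target + 5 && tries < 40 * L) {
        step <- max(1L, ceiling((cur - target) / 100 * L / 4))
        cand <- mutate_seq(chars, step, ab)
        cand_id <- nearest(cand)
        if (cand_id >= target - 5) { chars <- cand; cur <- cand_id }
        tries <- tries + 1L
      }
      if (cur > target + 5 || cur < target - 5) {
        abort(sprintf(
          "could not calibrate identity %.1f for length %d (reached %.1f)",
          target, L, cur))
      }
      tibble(id = sprintf("%s_test%02d", fam, k),
             seq = paste(chars, collapse = ""), family = fam)
    }))
  }
  train <- dplyr::bind_rows(train); test <- dplyr::bind_rows(test)
  fams <- sprintf("FAM%03d", seq_len(spec$n_families))
  clan_of <- ifelse(seq_along(fams) <= (length(fams) %/% spec$clan_size) *
                      spec$clan_size,
                    sprintf("CL%03d", (seq_along(fams) - 1L) %/%
                              spec$clan_size + 1L),
                    NA_character_)
  fam_tbl <- tibble(family = fams, clan = clan_of)
  labels <- dplyr::bind_rows(train, test) |>
    dplyr::left_join(fam_tbl, by = "family") |>
    dplyr::select("id", "family", "clan")
  list(train = train, test = test, labels = labels)
}

#' Specification of a synthetic embedding-to-3Di dataset
#'
#' Emulates the positional class structure a language model's embeddings
#' carry about local structure: each position's 3Di state is drawn
#' uniformly, and its embedding is the state's mean vector plus isotropic
#' Gaussian noise.  Far-apart means with small noise give a separable
#' dataset; coincident means make the classes indistinguishable.
#'
#' @param n_sequences Number of sequences.
#' @param length_range Per-sequence length range.
#' @param dimensionality Embedding width.
#' @param mean_scale Distance scale of the per-state mean vectors (0 makes
#'   all means coincide).
#' @param noise_sd Isotropic noise standard deviation.
#' @param seed Seed.
#'
#' @return An `embedding_dataset_spec` list.
#' @export
embedding_dataset_spec <- function(n_sequences = 60L,
                                   length_range = c(40L, 60L),
                                   dimensionality = 16L, mean_scale = 3,
                                   noise_sd = 1, seed = 1L) {
  stopifnot(dimensionality >= 1, noise_sd >= 0, mean_scale >= 0)
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 dimensionality = as.integer(dimensionality),
                 mean_scale = mean_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "embedding_dataset_spec")
}

#' Generate paired embedding / 3Di training data
#'
#' @param spec An [embedding_dataset_spec()].
#'
#' @return List of `list(id, emb = L x d matrix, states = 3Di string,
#'   targets = integer indices)`, plus attributes `means` (20 x d state
#'   means) and `spec`.
#' @export
gen_embedding_3di_dataset <- function(spec = embedding_dataset_spec()) {
  stopifnot(inherits(spec, "embedding_dataset_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  d <- spec$dimensionality
  means <- matrix(rnorm(20 * d), 20, d) * spec$mean_scale
  items <- lapply(seq_len(spec$n_sequences), function(i) {
    L <- sample_range(spec$length_range[1], spec$length_range[2])
    states <- sample.int(20L, L, replace = TRUE)
    emb <- means[states, , drop = FALSE] +
      matrix(rnorm(L * d, sd = spec$noise_sd), L, d)
    list(id = sprintf("emb%04d", i), emb = emb,
         states = indices_to_threedi(states), targets = states)
  })
  attr(items, "means") <- means
  attr(items, "spec") <- spec
  items
}

#' Sample column counts from a known Dirichlet mixture
#'
#' The generative model matched by [fit_mixture_dirichlet()]: per column,
#' draw a component from the mixture weights, a symbol distribution from
#' that component's Dirichlet, and counts from a multinomial.
#'
#' @param mixture A [new_dirichlet_mixture()].
#' @param n_columns Number of columns.
#' @param counts_per_column Multinomial total per column.
#' @param seed Seed.
#'
#' @return An `n_columns` x A count matrix with a `component` attribute
#'   recording the generating component of each column.
#' @export
gen_mixture_counts <- function(mixture, n_columns, counts_per_column,
                               seed = 1L) {
  stopifnot(inherits(mixture, "dirichlet_mixture"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  A <- ncol(mixture$alpha)
  comp <- sample.int(mixture$K, n_columns, replace = TRUE, prob = mixture$q)
  counts <- t(vapply(seq_len(n_columns), function(i) {
    g <- rgamma(A, shape = mixture$alpha[comp[i], ])
    p <- g / sum(g)
    as.integer(rmultinom(1, counts_per_column, p))
  }, integer(A)))
  structure(counts, component = comp)
}
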