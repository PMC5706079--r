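# Shared fixture builders. Everything is generated in code; no binary or
# stored data.

# random integer .hhm-style record, optionally with `*` sentinels
random_hhm_record <- function(L, seed, id = paste0("rec", seed),
                              sentinel_frac = 0) {
  set.seed(seed)
  scores <- matrix(sample.int(9999, L * 20, replace = TRUE) - 1L, nrow = L)
  if (sentinel_frac > 0) {
    hit <- which(stats::runif(L * 20) < sentinel_frac)
    scores[hit] <- NA_integer_
  }
  colnames(scores) <- profgram:::AA_ALPHABET
  profgram:::new_hmm_profile(
    id, sample(profgram:::AA_ALPHABET, L, replace = TRUE), scores)
}

random_pssm_record <- function(L, seed, id = paste0("pssm", seed)) {
  set.seed(seed)
  lo <- matrix(sample(-12L:12L, L * 20, replace = TRUE), nrow = L)
  colnames(lo) <- profgram:::AA_ALPHABET
  profgram:::new_pssm_profile(
    id, sample(profgram:::AA_ALPHABET, L, replace = TRUE), lo)
}

random_profile_matrix <- function(L, seed, id = paste0("pm", seed),
                                  origin = "HMM", row_stochastic = FALSE) {
  set.seed(seed)
  m <- matrix(stats::runif(L * 20), nrow = L)
  if (row_stochastic) m <- m / rowSums(m)
  new_profile_matrix(m, id, origin)
}

# independent naive-loop oracles for the feature definitions
oracle_monogram <- function(m) {
  L <- nrow(m)
  out <- numeric(20)
  for (j in 1:20) {
    s <- 0
    for (i in 1:L) s <- s + m[i, j]
    out[j] <- s / L
  }
  out
}

oracle_bigram <- function(m) {
  L <- nrow(m)
  out <- numeric(400)
  for (j in 1:20) {
    for (k in 1:20) {
      s <- 0
      for (i in 1:(L - 1)) s <- s + m[i, j] * m[i + 1, k]
      out[(j - 1) * 20 + k] <- s / (L - 1)
    }
  }
  out
}

# pairwise-concordance oracle for auROC: P(score_pos > score_neg) + 0.5 ties
oracle_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# two linearly separable 2-d clusters for classifier sanity checks
separable_toy <- function(n = 20, seed = 5, d = 2, gap = 4) {
  set.seed(seed)
  n1 <- n %/% 2
  x <- rbind(matrix(rnorm(n1 * d), ncol = d) + gap,
             matrix(rnorm((n - n1) * d), ncol = d) - gap)
  colnames(x) <- paste0("f", seq_len(d))
  tbl <- tibble::tibble(instance_id = paste0("t", seq_len(n)),
                        label = rep(c(1L, 0L), c(n1, n - n1)))
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(x))
  profgram:::as_labeled_dataset(tbl, "TOY", "HMM")
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_pos = 10, n_neg = 10, length_range = c(10, 20),
         effect = 0.8, concentration = 50, seed = 3),
    list(...))
  do.call(synthetic_config, args)
}
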