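#' Configure the synthetic profile generator
#'
#' The generator emulates the L x 20 substitution-probability profiles
#' that iterative profile searches produce, with a controllable
#' DNA-binding signal. Each profile row is a Dirichlet draw around a base
#' composition: negatives use a shared amino-acid background; positives
#' use the background with a fraction `0.3 * effect` of its mass shifted
#' onto arginine and lysine (the composition bias typical of DNA-binding
#' domains), and additionally carry an adjacent-position R->K motif
#' injected at per-position rate `0.15 * effect`, so monogram and bigram
#' features each carry signal independently. At `effect = 0` the two
#' classes are exchangeable in distribution.
#'
#' @param n_pos,n_neg Number of positive / negative profiles.
#' @param length_range Integer pair `c(L_min, L_max)`, `L_min >= 2`;
#'   profile lengths are uniform on this range.
#' @param effect Class-separation strength in \[0, 1\].
#' @param concentration Positive Dirichlet sharpness of per-position
#'   rows; larger values give rows closer to the base composition.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_pos = 100, n_neg = 100,
                             length_range = c(50, 150),
                             effect = 0.8, concentration = 50, seed = 1L) {
  if (n_pos < 1 || n_neg < 1) {
    abort("n_pos and n_neg must be positive", class = "profgram_invalid_input")
  }
  if (length(length_range) != 2 || length_range[1] < 2 ||
      length_range[2] < length_range[1]) {
    abort("length_range must be c(L_min, L_max) with 2 <= L_min <= L_max",
          class = "profgram_invalid_input")
  }
  if (effect < 0 || effect > 1) {
    abort("effect must lie in [0, 1]", class = "profgram_invalid_input")
  }
  if (concentration <= 0) {
    abort("concentration must be positive", class = "profgram_invalid_input")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 effect = effect, concentration = concentration,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Background amino-acid composition (approximate natural frequencies).
AA_BACKGROUND <- c(
  A = 0.0788, C = 0.0157, D = 0.0535, E = 0.0668, F = 0.0397,
  G = 0.0696, H = 0.0229, I = 0.0590, K = 0.0595, L = 0.0966,
  M = 0.0238, N = 0.0414, P = 0.0484, Q = 0.0395, R = 0.0541,
  S = 0.0683, T = 0.0541, V = 0.0673, W = 0.0109, Y = 0.0299
)

SIGNAL_COLUMNS <- c("R", "K")      # compositional signal target
MOTIF_FROM <- "R"                  # adjacent-position motif: R -> K
MOTIF_TO <- "K"

rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Generate labeled synthetic profiles
#'
#' @param config A [synthetic_config()].
#' @param origin Tag the generated matrices as `"HMM"` or `"PSSM"`
#'   profiles (affects only downstream bookkeeping; the generative model
#'   is the same).
#' @return A list with `profiles` (list of `profile_matrix`), `labels`
#'   (binary vector, positives first) and `config`.
#' @export
generate_profiles <- function(config = synthetic_config(),
                              origin = c("HMM", "PSSM")) {
  stopifnot(inherits(config, "synthetic_config"))
  origin <- match.arg(origin)
  set.seed(config$seed)
  bg <- AA_BACKGROUND / sum(AA_BACKGROUND)
  shift <- 0.3 * config$effect
  base_pos <- (1 - shift) * bg
  base_pos[SIGNAL_COLUMNS] <- base_pos[SIGNAL_COLUMNS] +
    shift / length(SIGNAL_COLUMNS)
  motif_rate <- 0.15 * config$effect
  motif_from_base <- 0.1 * bg; motif_from_base[MOTIF_FROM] <- 0.9
  motif_to_base <- 0.1 * bg; motif_to_base[MOTIF_TO] <- 0.9
  motif_from_base <- motif_from_base / sum(motif_from_base)
  motif_to_base <- motif_to_base / sum(motif_to_base)

  n <- config$n_pos + config$n_neg
  labels <- rep(c(1L, 0L), c(config$n_pos, config$n_neg))
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 n, replace = TRUE)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]
    base <- if (labels[i] == 1) base_pos else bg
    rows <- rdirichlet_rows(L, config$concentration * base)
    if (labels[i] == 1 && motif_rate > 0 && L >= 2) {
      starts <- which(stats::runif(L - 1) < motif_rate)
      # drop overlapping motif starts so each position belongs to one motif
      keep <- starts[c(TRUE, diff(starts) > 1)[seq_along(starts)]]
      for (s in keep) {
        rows[s, ] <- rdirichlet_rows(1, config$concentration * motif_from_base)
        rows[s + 1, ] <- rdirichlet_rows(1, config$concentration * motif_to_base)
      }
    }
    id <- sprintf("syn_%s_%04d", if (labels[i] == 1) "pos" else "neg", i)
    profiles[[i]] <- new_profile_matrix(rows, id, origin)
  }
  list(profiles = profiles, labels = labels, config = config)
}

#' Generate a ready-to-train labeled feature table
#'
#' Convenience wrapper: [generate_profiles()] followed by
#' [featurize_profiles()].
#'
#' @inheritParams generate_profiles
#' @param group Feature group passed to [featurize_profiles()].
#' @return A `labeled_dataset` tibble.
#' @export
generate_dataset <- function(config = synthetic_config(),
                             group = "COMBINED", origin = "HMM") {
  g <- generate_profiles(config, origin = origin)
  featurize_profiles(g$profiles, g$labels, group = group)
}

#' Convert a probability matrix back to integer score records
#'
#' Inverts the profile conversions so fixture files can be written:
#' `.hhm` scores use `N = round(-1000 * log2(p))` with `p = 0` mapped to
#' the `*` sentinel; PSSM log-odds use the rounded logit. Residue letters
#' are taken as each row's most probable amino acid. The `.hhm` direction
#' loses at most half a score unit, i.e. relative probability error below
#' `2^0.0005 - 1`.
#'
#' @param M A `profile_matrix`.
#' @return An `hmm_profile` / `pssm_profile` record.
#' @export
profile_to_hhm_record <- function(M) {
  M <- as_probability_matrix(M)
  scores <- round(-1000 * log2(unclass(M)))
  scores[is.infinite(scores)] <- NA  # p = 0 -> sentinel
  mode(scores) <- "integer"
  colnames(scores) <- AA_ALPHABET
  new_hmm_profile(attr(M, "sequence_id"),
                  AA_ALPHABET[max.col(unclass(M), ties.method = "first")],
                  scores)
}

#' @rdname profile_to_hhm_record
#' @export
profile_to_pssm_record <- function(M) {
  M <- as_probability_matrix(M)
  p <- pmin(pmax(unclass(M), 1e-7), 1 - 1e-7)
  lo <- round(stats::qlogis(p))
  mode(lo) <- "integer"
  colnames(lo) <- AA_ALPHABET
  new_pssm_profile(attr(M, "sequence_id"),
                   AA_ALPHABET[max.col(unclass(M), ties.method = "first")],
                   lo)
}

#' Write parser-compatible profile fixture files
#'
#' Emits text that [read_hhm()] / [read_pssm()] parse back to an
#' identical record. The `.hhm` fixture carries a minimal-but-valid
#' header (NAME, LENG, NULL model, HMM tag, transition labels) so
#' third-party readers also accept it; `NA` scores are written as the
#' literal `*`.
#'
#' @param record An `hmm_profile` / `pssm_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hhm_fixture <- function(record, path) {
  stopifnot(inherits(record, "hmm_profile"))
  L <- nrow(record$scores)
  fmt <- function(v) ifelse(is.na(v), "*", format(v, scientific = FALSE))
  lines <- c(
    "HHsearch 1.5",
    paste0("NAME  ", record$sequence_id),
    paste0("LENG  ", L, " match states, ", L, " columns in multiple alignment"),
    "FILT  synthetic fixture profile",
    paste0("NULL   ", paste(rep("3000", 20), collapse = "\t")),
    paste0("HMM    ", paste(AA_ALPHABET, collapse = "\t")),
    paste0("       ", paste(c("M->M", "M->I", "M->D", "I->M", "I->I",
                              "D->M", "D->D", "Neff", "Neff_I", "Neff_D"),
                            collapse = "\t")),
    paste0("       ", paste(c("0", "*", "*", "0", "*", "0", "*",
                              "1000", "0", "0"), collapse = "\t"))
  )
  for (i in seq_len(L)) {
    lines <- c(lines,
      paste(c(record$residues[i], i, fmt(record$scores[i, ]), i),
            collapse = "\t"),
      paste0("       ", paste(c("0", "*", "*", "0", "*", "0", "*",
                                "1000", "0", "0"), collapse = "\t")),
      "")
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' @rdname write_hhm_fixture
#' @export
write_pssm_fixture <- function(record, path) {
  stopifnot(inherits(record, "pssm_profile"))
  L <- nrow(record$log_odds)
  lo <- record$log_odds[, PSSM_ALPHABET, drop = FALSE]  # file column order
  lines <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapped matches to pseudocounts"),
    paste0("            ", paste(c(PSSM_ALPHABET, PSSM_ALPHABET),
                                 collapse = "   "))
  )
  for (i in seq_len(L)) {
    lines <- c(lines, paste(
      c(sprintf("%5d %s", i, record$residues[i]),
        sprintf("%3d", lo[i, ]), sprintf("%3d", rep(0L, 20)),
        " 0.00", " 0.00"),
      collapse = " "))
  }
  lines <- c(lines, "", "                      K         Lambda",
             "Standard Ungapped    0.1337     0.3113")
  writeLines(lines, path)
  invisible(path)
}

#' Write a label table as TSV
#'
#' @param ids Instance identifiers.
#' @param labels Binary labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(ids, labels, path) {
  readr::write_tsv(tibble::tibble(instance_id = ids,
                                  label = as.integer(labels)),
                   path, progress = FALSE)
  invisible(path)
}
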