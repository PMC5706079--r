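#' Read an HHblits `.hhm` profile file
#'
#' Parses the text `.hhm` format emitted by HHblits/HHsearch: header lines
#' through the `HMM` tag, a transition-label line, then one block per
#' residue holding a match-emission line (residue, position, 20 integer
#' score fields) and an insert/transition line, terminated by `//`. Only
#' the 20 match-emission scores per position are retained; transition,
#' insert-state and null-model lines are read and discarded, because the
#' profile used downstream is exactly the L x 20 match-emission matrix.
#'
#' Scores are the HHsuite encoding `N = -1000 * log2(p)`; the literal `*`
#' field (probability zero) is stored as `NA`.
#'
#' @param path Path to a `.hhm` file.
#' @return An object of class `hmm_profile`: a list with `sequence_id`,
#'   `residues` (character vector of length L), `scores` (L x 20 integer
#'   matrix, canonical column order, `NA` for `*`), and `source_path`.
#' @seealso [as_probability_matrix()] for the score-to-probability
#'   conversion, [write_hhm_fixture()] for the inverse writer.
#' @export
#' @examples
#' cfg <- synthetic_config(n_pos = 1, n_neg = 1, seed = 1)
#' prof <- generate_profiles(cfg)$profiles[[1]]
#' f <- tempfile(fileext = ".hhm")
#' write_hhm_fixture(profile_to_hhm_record(prof), f)
#' rec <- read_hhm(f)
#' dim(rec$scores)
read_hhm <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such .hhm file: ", path), class = "profgram_io_error")
  }
  parse_hhm(readLines(path, warn = FALSE), path = path)
}

parse_hhm <- function(lines, path = "<text>") {
  hmm_at <- which(vapply(lines, function(l) {
    identical(first_token(l), "HMM")
  }, logical(1)))
  if (length(hmm_at) == 0) {
    abort(paste0("malformed .hhm file ", path, ": missing 'HMM' tag"),
          class = "profgram_parse_error")
  }
  hmm_at <- hmm_at[[1]]
  end_at <- which(trimws(lines) == "//")
  if (length(end_at) == 0 || max(end_at) <= hmm_at) {
    abort(paste0("malformed .hhm file ", path, ": missing '//' terminator"),
          class = "profgram_parse_error")
  }
  end_at <- end_at[end_at > hmm_at][[1]]

  sequence_id <- basename_no_ext(path)
  for (l in lines[seq_len(hmm_at - 1)]) {
    toks <- tokenize(l)
    if (length(toks) >= 2 && toks[[1]] == "NAME") sequence_id <- toks[[2]]
  }

  residues <- character(0)
  rows <- list()
  # skip the transition-label line immediately after the HMM tag; the
  # begin-state transition line and per-residue transition lines are
  # recognised (first token not residue+position) and skipped below.
  body <- lines[seq(hmm_at + 2, end_at - 1)]
  for (l in body) {
    toks <- tokenize(l)
    if (length(toks) == 0) next
    if (!is_emission_line(toks)) next
    pos <- length(residues) + 1L
    if (length(toks) < 22) {
      abort(paste0("malformed .hhm row at position ", pos, " in ", path,
                   ": expected 20 score fields, found ", length(toks) - 2),
            class = "profgram_parse_error")
    }
    score_toks <- toks[3:22]
    scores <- suppressWarnings(as.integer(score_toks))
    bad <- which(is.na(scores) & score_toks != "*")
    if (length(bad) > 0) {
      abort(paste0("malformed .hhm row at position ", pos, " in ", path,
                   ": non-integer score field '", score_toks[bad[[1]]], "'"),
            class = "profgram_parse_error")
    }
    if (any(scores < 0, na.rm = TRUE)) {
      abort(paste0("malformed .hhm row at position ", pos, " in ", path,
                   ": negative score"),
            class = "profgram_parse_error")
    }
    residues[[pos]] <- toks[[1]]
    rows[[pos]] <- scores
  }
  if (length(rows) == 0) {
    abort(paste0("malformed .hhm file ", path, ": no match-emission rows"),
          class = "profgram_parse_error")
  }
  scores <- do.call(rbind, rows)
  colnames(scores) <- AA_ALPHABET
  new_hmm_profile(sequence_id, residues, scores, path)
}

new_hmm_profile <- function(sequence_id, residues, scores, source_path = NA_character_) {
  stopifnot(nrow(scores) == length(residues), ncol(scores) == 20)
  structure(
    list(sequence_id = sequence_id, residues = residues,
         scores = scores, source_path = source_path),
    class = "hmm_profile"
  )
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: two header lines, a column-label
#' line carrying 40 amino-acid letters, then one data row per residue
#' (position, residue, 20 log-odds integers, 20 weighted-percentage
#' integers, two trailing floats), then footer statistics. Only the first
#' 20-column log-odds block is kept. The PSSM column order
#' (A R N D C Q E G H I L K M F P S T W V Y) is re-mapped to the canonical
#' alphabetical order on load so that features extracted from PSSM and HMM
#' profiles are directly comparable.
#'
#' @param path Path to an ASCII PSSM file.
#' @return An object of class `pssm_profile`: a list with `sequence_id`,
#'   `residues`, `log_odds` (L x 20 integer matrix, canonical column
#'   order) and `source_path`.
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such PSSM file: ", path), class = "profgram_io_error")
  }
  parse_pssm(readLines(path, warn = FALSE), path = path)
}

parse_pssm <- function(lines, path = "<text>") {
  header_at <- 0L
  for (i in seq_along(lines)) {
    toks <- tokenize(lines[[i]])
    if (length(toks) >= 40 && all(nchar(toks[1:40]) == 1)) {
      header_at <- i
      break
    }
  }
  if (header_at == 0L) {
    abort(paste0("malformed PSSM file ", path,
                 ": missing 40-letter column-label line"),
          class = "profgram_parse_error")
  }
  residues <- character(0)
  rows <- list()
  for (l in lines[seq(header_at + 1, length(lines))]) {
    toks <- tokenize(l)
    if (length(toks) == 0) break  # blank line separates body from footer
    if (is.na(suppressWarnings(as.integer(toks[[1]])))) break  # footer
    pos <- length(residues) + 1L
    if (length(toks) < 22) {
      abort(paste0("malformed PSSM row at position ", pos, " in ", path,
                   ": expected at least 22 fields, found ", length(toks)),
            class = "profgram_parse_error")
    }
    vals <- suppressWarnings(as.integer(toks[3:22]))
    if (anyNA(vals)) {
      abort(paste0("malformed PSSM row at position ", pos, " in ", path,
                   ": non-integer log-odds field"),
            class = "profgram_parse_error")
    }
    residues[[pos]] <- toks[[2]]
    rows[[pos]] <- vals
  }
  if (length(rows) == 0) {
    abort(paste0("malformed PSSM file ", path, ": empty body"),
          class = "profgram_parse_error")
  }
  log_odds <- do.call(rbind, rows)
  colnames(log_odds) <- PSSM_ALPHABET
  log_odds <- log_odds[, AA_ALPHABET, drop = FALSE]
  new_pssm_profile(basename_no_ext(path), residues, log_odds, path)
}

new_pssm_profile <- function(sequence_id, residues, log_odds,
                             source_path = NA_character_) {
  stopifnot(nrow(log_odds) == length(residues), ncol(log_odds) == 20)
  structure(
    list(sequence_id = sequence_id, residues = residues,
         log_odds = log_odds, source_path = source_path),
    class = "pssm_profile"
  )
}

#' Convert a parsed profile record to a linear-probability matrix
#'
#' The common currency for feature extraction is an L x 20 matrix of
#' linear substitution probabilities. HHblits `.hhm` scores `N` are
#' converted with `p = 2^(-N/1000)`; the `*` sentinel (stored as `NA`)
#' maps to probability 0, since `*` encodes `-1000 * log2(0)`. PSSM
#' log-odds `x` are mapped through the logistic transform
#' `1 / (1 + exp(-x))`, the standard squashing used in the PSSM-bigram
#' literature (the conversion is strictly increasing in `x`).
#'
#' @param x An `hmm_profile` or `pssm_profile` record, or a bare numeric
#'   matrix already holding probabilities.
#' @param ... Unused.
#' @return A `profile_matrix`: an L x 20 numeric matrix with entries in
#'   \[0, 1\], canonical column names, and attributes `sequence_id` and
#'   `origin` (`"HMM"` or `"PSSM"`).
#' @export
as_probability_matrix <- function(x, ...) {
  UseMethod("as_probability_matrix")
}

#' @rdname as_probability_matrix
#' @export
as_probability_matrix.hmm_profile <- function(x, ...) {
  p <- 2^(-x$scores / 1000)
  p[is.na(x$scores)] <- 0
  new_profile_matrix(p, x$sequence_id, "HMM")
}

#' @rdname as_probability_matrix
#' @export
as_probability_matrix.pssm_profile <- function(x, ...) {
  new_profile_matrix(stats::plogis(x$log_odds), x$sequence_id, "PSSM")
}

#' @rdname as_probability_matrix
#' @export
as_probability_matrix.profile_matrix <- function(x, ...) x

new_profile_matrix <- function(values, sequence_id, origin = c("HMM", "PSSM")) {
  origin <- match.arg(origin)
  values <- as.matrix(values)
  if (ncol(values) != 20 || nrow(values) < 1) {
    abort("a profile matrix must have at least 1 row and exactly 20 columns",
          class = "profgram_invalid_input")
  }
  if (any(values < 0 | values > 1)) {
    abort("profile matrix entries must lie in [0, 1]",
          class = "profgram_invalid_input")
  }
  dimnames(values) <- list(NULL, AA_ALPHABET)
  structure(values, sequence_id = sequence_id, origin = origin,
            class = c("profile_matrix", "matrix", "array"))
}

#' @export
print.hmm_profile <- function(x, ...) {
  cat("<hmm_profile> ", x$sequence_id, ": L = ", nrow(x$scores),
      ", ", sum(is.na(x$scores)), " sentinel score(s)\n", sep = "")
  invisible(x)
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("<pssm_profile> ", x$sequence_id, ": L = ", nrow(x$log_odds), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", attr(x, "sequence_id"), " (", attr(x, "origin"),
      "): L = ", nrow(x), "\n", sep = "")
  print(utils::head(unclass(x), 3))
  if (nrow(x) > 3) cat("... (", nrow(x) - 3, " more rows)\n", sep = "")
  invisible(x)
}

# --- helpers ----------------------------------------------------------------

tokenize <- function(line) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1]]
  toks[nzchar(toks)]
}

first_token <- function(line) {
  toks <- tokenize(line)
  if (length(toks) == 0) "" else toks[[1]]
}

# match-emission lines start with a single residue letter followed by a
# 1-based position integer; transition/null/begin lines do not.
is_emission_line <- function(toks) {
  length(toks) >= 2 &&
    nchar(toks[[1]]) == 1 &&
    grepl("^[A-Za-z-]$", toks[[1]]) &&
    grepl("^[0-9]+$", toks[[2]])
}

basename_no_ext <- function(path) {
  sub("\\.[^.]*$", "", basename(path))
}
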