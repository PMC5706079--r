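#' Monogram features of a profile matrix
#'
#' The monogram summary of an L x 20 probability matrix H is the
#' length-normalised column sum: entry j equals
#' `(1/L) * sum_i H[i, j]`, a 20-dimensional composition-like vector.
#'
#' @param M A `profile_matrix` (or coercible record).
#' @return A named numeric `feature_vector` of length 20
#'   (names `m_A` ... `m_Y`) with attributes `instance_id`, `group`
#'   (`"MONOGRAM"`) and `origin`.
#' @export
#' @examples
#' M <- new_profile_matrix(matrix(1 / 20, 5, 20), "toy", "HMM")
#' monogram(M)
monogram <- function(M) {
  M <- as_probability_matrix(M)
  v <- colMeans(M)
  names(v) <- MONOGRAM_NAMES
  new_feature_vector(v, attr(M, "sequence_id"), "MONOGRAM", attr(M, "origin"))
}

#' Bigram features of a profile matrix
#'
#' The bigram summary captures adjacent-position transitions between
#' profile columns: entry (j, k) equals
#' `(1/(L-1)) * sum_{i=1}^{L-1} H[i, j] * H[i+1, k]`,
#' flattened row-major as b(1,1), b(1,2), ..., b(1,20), b(2,1), ...,
#' b(20,20) into a 400-dimensional vector.
#'
#' @param M A `profile_matrix` with at least 2 rows.
#' @return A named numeric `feature_vector` of length 400
#'   (names `b_A_A` ... `b_Y_Y`, first letter = column at position i).
#' @export
bigram <- function(M) {
  M <- as_probability_matrix(M)
  L <- nrow(M)
  if (L < 2) {
    abort(paste0("bigram features need L >= 2 rows; instance '",
                 attr(M, "sequence_id"), "' has L = ", L),
          class = "profgram_invalid_input")
  }
  B <- crossprod(M[-L, , drop = FALSE], M[-1, , drop = FALSE]) / (L - 1)
  v <- as.vector(t(B))  # row-major: (j, k) with j varying slowest
  names(v) <- BIGRAM_NAMES
  new_feature_vector(v, attr(M, "sequence_id"), "BIGRAM", attr(M, "origin"))
}

#' Concatenate monogram and bigram features
#'
#' Produces the combined 420-dimensional representation, monogram block
#' first. The order is fixed (and recorded in the column names) because
#' trained models depend on it.
#'
#' @param mono A MONOGRAM `feature_vector`.
#' @param bi A BIGRAM `feature_vector` for the same instance and origin.
#' @return A COMBINED `feature_vector` of length 420.
#' @export
combine_features <- function(mono, bi) {
  stopifnot(inherits(mono, "feature_vector"), inherits(bi, "feature_vector"))
  if (attr(mono, "group") != "MONOGRAM" || attr(bi, "group") != "BIGRAM") {
    abort("combine_features() expects a MONOGRAM and a BIGRAM vector",
          class = "profgram_invalid_input")
  }
  if (!identical(attr(mono, "instance_id"), attr(bi, "instance_id")) ||
      !identical(attr(mono, "origin"), attr(bi, "origin"))) {
    abort(paste0("inconsistent inputs: monogram is '",
                 attr(mono, "instance_id"), "'/", attr(mono, "origin"),
                 " but bigram is '", attr(bi, "instance_id"), "'/",
                 attr(bi, "origin")),
          class = "profgram_invalid_input")
  }
  new_feature_vector(c(unclass_fv(mono), unclass_fv(bi)),
                     attr(mono, "instance_id"), "COMBINED",
                     attr(mono, "origin"))
}

#' Extract a feature vector of a given group
#'
#' @param M A `profile_matrix`.
#' @param group `"MONOGRAM"`, `"BIGRAM"` or `"COMBINED"`.
#' @return A `feature_vector` of length 20, 400 or 420.
#' @export
profile_features <- function(M, group = c("COMBINED", "MONOGRAM", "BIGRAM")) {
  group <- match.arg(toupper(group), c("COMBINED", "MONOGRAM", "BIGRAM"))
  switch(group,
    MONOGRAM = monogram(M),
    BIGRAM = bigram(M),
    COMBINED = combine_features(monogram(M), bigram(M))
  )
}

new_feature_vector <- function(values, instance_id, group, origin) {
  stopifnot(all(is.finite(values)))
  structure(values, instance_id = instance_id, group = group,
            origin = origin, class = "feature_vector")
}

unclass_fv <- function(x) {
  attributes(x) <- list(names = names(x))
  x
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> ", attr(x, "instance_id"), " (", attr(x, "origin"),
      "/", attr(x, "group"), "), length ", length(x), "\n", sep = "")
  print(utils::head(unclass_fv(x), 6))
  invisible(x)
}

#' Build a labeled feature table from a list of profiles
#'
#' Converts each profile to the requested feature group and assembles the
#' classifier's input: one row per protein with its identifier, binary
#' label (1 = DNA-binding, 0 = non-binding) and feature columns. Row order
#' follows input order.
#'
#' @param profiles List of `profile_matrix` objects (one origin).
#' @param labels Binary vector (0/1), one per profile.
#' @param group Feature group, as in [profile_features()].
#' @return A tibble of class `labeled_dataset`: columns `instance_id`,
#'   `label`, then 20/400/420 feature columns; attributes `feature_group`
#'   and `origin`.
#' @export
featurize_profiles <- function(profiles, labels,
                               group = c("COMBINED", "MONOGRAM", "BIGRAM")) {
  group <- match.arg(toupper(group), c("COMBINED", "MONOGRAM", "BIGRAM"))
  if (length(profiles) == 0) {
    abort("cannot featurize an empty profile list",
          class = "profgram_invalid_input")
  }
  if (length(profiles) != length(labels)) {
    abort("profiles and labels must have equal length",
          class = "profgram_invalid_input")
  }
  if (!all(labels %in% c(0, 1))) {
    abort("labels must be binary (0 = non-binding, 1 = DNA-binding)",
          class = "profgram_invalid_input")
  }
  profiles <- lapply(profiles, as_probability_matrix)
  origins <- unique(vapply(profiles, attr, character(1), "origin"))
  if (length(origins) != 1) {
    abort("all profiles in a dataset must share one origin (HMM or PSSM)",
          class = "profgram_invalid_input")
  }
  fvs <- lapply(profiles, profile_features, group = group)
  mat <- do.call(rbind, lapply(fvs, unclass_fv))
  ids <- vapply(profiles, attr, character(1), "sequence_id")
  out <- tibble::as_tibble(as.data.frame(mat, optional = TRUE))
  out <- dplyr::bind_cols(
    tibble::tibble(instance_id = ids, label = as.integer(labels)), out
  )
  as_labeled_dataset(out, group, origins)
}

as_labeled_dataset <- function(tbl, feature_group, origin) {
  structure(tbl,
            feature_group = feature_group, origin = origin,
            class = c("labeled_dataset", class(tibble::as_tibble(tbl))))
}

#' Extract the numeric feature matrix from a labeled dataset
#' @param dataset A `labeled_dataset` tibble.
#' @return A numeric matrix with instance identifiers as row names.
#' @export
feature_matrix <- function(dataset) {
  cols <- setdiff(names(dataset), c("instance_id", "label"))
  m <- as.matrix(dataset[cols])
  rownames(m) <- dataset$instance_id
  m
}

#' Write / read a labeled feature table as TSV
#'
#' Plain tab-separated text: `instance_id`, `label`, then the canonical
#' feature columns (`m_A` ... `m_Y`, `b_A_A` ... `b_Y_Y`). Values are
#' serialised with 17 significant digits so write-then-read round-trips
#' are bit-stable.
#'
#' @param dataset A `labeled_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly (writer); a `labeled_dataset` (reader).
#' @export
write_feature_table <- function(dataset, path) {
  tbl <- tibble::as_tibble(dataset)
  num <- setdiff(names(tbl), c("instance_id", "label"))
  tbl[num] <- lapply(tbl[num], function(x) sprintf("%.17g", x))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  # feature columns are read as text and parsed with strtod (correctly
  # rounded), so the 17-significant-digit serialisation round-trips bit-stably
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           instance_id = readr::col_character(),
                           label = readr::col_integer(),
                           .default = readr::col_character()))
  num <- setdiff(names(tbl), c("instance_id", "label"))
  tbl[num] <- lapply(tbl[num], as.numeric)
  if (!all(c("instance_id", "label") %in% names(tbl))) {
    abort(paste0("feature table ", path,
                 " must have 'instance_id' and 'label' columns"),
          class = "profgram_io_error")
  }
  d <- ncol(tbl) - 2L
  group <- feature_group_for_dim(d)
  as_labeled_dataset(tbl, group, guess_origin_from_path(path))
}

feature_group_for_dim <- function(d) {
  switch(as.character(d),
         "20" = "MONOGRAM", "400" = "BIGRAM", "420" = "COMBINED",
         abort(paste0("feature dimension ", d,
                      " is not one of 20 / 400 / 420"),
               class = "profgram_invalid_input"))
}

guess_origin_from_path <- function(path) {
  if (grepl("pssm", tolower(basename(path)))) "PSSM" else "HMM"
}
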