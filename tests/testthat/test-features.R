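test_that("feature vectors have the documented dimensions and tags", {
  M <- random_profile_matrix(L = 12, seed = 1)
  mono <- monogram(M)
  bi <- bigram(M)
  comb <- combine_features(mono, bi)
  expect_length(mono, 20)
  expect_length(bi, 400)
  expect_length(comb, 420)
  expect_identical(attr(mono, "group"), "MONOGRAM")
  expect_identical(attr(bi, "group"), "BIGRAM")
  expect_identical(attr(comb, "group"), "COMBINED")
  expect_identical(names(comb)[1:20], profgram:::MONOGRAM_NAMES)
  expect_identical(names(comb)[21:420], profgram:::BIGRAM_NAMES)
})

test_that("monogram matches closed-form cases and the naive-loop oracle", {
  ones <- new_profile_matrix(matrix(1, 7, 20), "ones", "HMM")
  expect_equal(as.numeric(monogram(ones)), rep(1, 20))
  single <- random_profile_matrix(L = 1, seed = 2)
  expect_equal(as.numeric(monogram(single)), as.numeric(single[1, ]))

  M <- random_profile_matrix(L = 30, seed = 11)
  expect_equal(as.numeric(monogram(M)), oracle_monogram(unclass(M)),
               tolerance = 1e-12)
})

test_that("bigram matches closed-form cases and the naive-loop oracle", {
  # L = 2, one-hot rows: a single transition lights one entry
  m <- matrix(0, 2, 20)
  a <- 4; b <- 17
  m[1, a] <- 1; m[2, b] <- 1
  bi <- bigram(new_profile_matrix(m, "onehot", "HMM"))
  expect_equal(unname(bi[(a - 1) * 20 + b]), 1.0)
  expect_equal(sum(bi), 1.0)

  # constant matrix: every entry c^2
  cm <- bigram(new_profile_matrix(matrix(0.3, 9, 20), "const", "HMM"))
  expect_equal(as.numeric(cm), rep(0.09, 400), tolerance = 1e-12)

  M <- random_profile_matrix(L = 30, seed = 11)
  expect_equal(as.numeric(bigram(M)), oracle_bigram(unclass(M)),
               tolerance = 1e-12)

  expect_error(bigram(random_profile_matrix(L = 1, seed = 1)),
               class = "profgram_invalid_input")
})

test_that("features match naive-loop oracles across many random matrices", {
  for (s in 1:50) {
    M <- random_profile_matrix(L = 5 + (s %% 20), seed = 1000 + s)
    expect_equal(as.numeric(monogram(M)), oracle_monogram(unclass(M)),
                 tolerance = 1e-12)
    expect_equal(as.numeric(bigram(M)), oracle_bigram(unclass(M)),
                 tolerance = 1e-12)
  }
})

test_that("row-stochastic input conserves total feature mass", {
  for (s in 1:5) {
    M <- random_profile_matrix(L = 10 + s, seed = 200 + s,
                               row_stochastic = TRUE)
    expect_equal(sum(monogram(M)), 1, tolerance = 1e-9)
    expect_equal(sum(bigram(M)), 1, tolerance = 1e-9)
  }
})

test_that("features are in [0,1] for [0,1] inputs and equivariant to column permutation", {
  M <- random_profile_matrix(L = 15, seed = 42)
  expect_true(all(monogram(M) >= 0 & monogram(M) <= 1))
  expect_true(all(bigram(M) >= 0 & bigram(M) <= 1))

  set.seed(9)
  perm <- sample(20)
  Mp <- new_profile_matrix(unclass(M)[, perm], "pm42", "HMM")
  expect_equal(as.numeric(monogram(Mp)), as.numeric(monogram(M))[perm])
  bi <- matrix(as.numeric(bigram(M)), 20, 20, byrow = TRUE)
  bip <- matrix(as.numeric(bigram(Mp)), 20, 20, byrow = TRUE)
  expect_equal(bip, bi[perm, perm])
})

test_that("combine_features enforces consistency and ordering", {
  M1 <- random_profile_matrix(L = 10, seed = 1, id = "a")
  M2 <- random_profile_matrix(L = 10, seed = 2, id = "b")
  expect_error(combine_features(monogram(M1), bigram(M2)),
               class = "profgram_invalid_input")
  expect_error(combine_features(bigram(M1), bigram(M1)),
               class = "profgram_invalid_input")
  comb <- combine_features(monogram(M1), bigram(M1))
  expect_equal(as.numeric(comb)[1:20], as.numeric(monogram(M1)))
  expect_equal(as.numeric(comb)[21:420], as.numeric(bigram(M1)))
})

test_that("featurize_profiles assembles labeled tables row-by-row", {
  g <- generate_profiles(small_config(seed = 3))
  ds <- featurize_profiles(g$profiles, g$labels, group = "COMBINED")
  expect_s3_class(ds, "labeled_dataset")
  expect_equal(dim(ds), c(20, 422))
  expect_identical(attr(ds, "feature_group"), "COMBINED")
  expect_identical(attr(ds, "origin"), "HMM")
  # row i equals the per-instance operation on profile i
  for (i in c(1, 7, 20)) {
    fv <- profile_features(g$profiles[[i]], "COMBINED")
    expect_equal(as.numeric(ds[i, -(1:2)]), as.numeric(fv))
  }
  mono_ds <- featurize_profiles(g$profiles[1:4], g$labels[1:4], "MONOGRAM")
  expect_equal(dim(mono_ds), c(4, 22))

  expect_error(featurize_profiles(list(), integer(0)),
               class = "profgram_invalid_input")
  expect_error(featurize_profiles(g$profiles, g$labels[-1]),
               class = "profgram_invalid_input")
})

test_that("feature tables round-trip through TSV bit-stably", {
  ds <- generate_dataset(small_config(seed = 5), "MONOGRAM")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ds, f)
  back <- read_feature_table(f)
  expect_identical(attr(back, "feature_group"), "MONOGRAM")
  expect_equal(feature_matrix(back), feature_matrix(ds), tolerance = 0)
  expect_equal(back$label, ds$label)
})
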