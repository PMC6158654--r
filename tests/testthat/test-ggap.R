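test_that("dipeptide_index is the row-major alphabetical bijection", {
  expect_equal(dipeptide_index("A", "A"), 1L)
  expect_equal(dipeptide_index("Y", "Y"), 400L)
  expect_equal(dipeptide_index("A", "C"), 2L)
  expect_equal(dipeptide_index("C", "A"), 21L)
  grid <- expand.grid(second = AA_ALPHABET, first = AA_ALPHABET,
                      stringsAsFactors = FALSE)
  all_idx <- dipeptide_index(grid$first, grid$second)
  expect_setequal(all_idx, 1:400)
  expect_error(dipeptide_index("A", "X"), class = "aodeep_domain_error")
})

test_that("g-gap counting matches hand-worked examples", {
  c0 <- ggap_counts("AAA", 0)
  expect_equal(unname(c0[dipeptide_index("A", "A")]), 2L)
  expect_equal(sum(c0), 2L)

  c1 <- ggap_counts("ACA", 1)
  expect_equal(unname(c1[dipeptide_index("A", "A")]), 1L)
  expect_equal(sum(c1), 1L)

  cx <- ggap_counts("ACDEFACD", 0)
  expected <- c(AC = 2L, CD = 2L, DE = 1L, EF = 1L, FA = 1L)
  for (dp in names(expected))
    expect_equal(unname(cx[dp]), expected[[dp]], label = dp)
  expect_equal(sum(cx), 7L)
  expect_equal(unname(ggap_frequencies("ACDEFACD", 0)["AC"]), 2 / 7)
  expect_equal(unname(ggap_frequencies("AAA", 0)[1]), 1)
})

test_that("counts equal the naive double-loop oracle across random sequences and gaps", {
  set.seed(101)
  for (rep in 1:40) {
    L <- sample(12:300, 1)
    s <- random_sequence(L)
    for (g in sample(0:9, 3)) {
      expect_identical(unname(ggap_counts(s, g)), oracle_ggap_counts(s, g))
      f <- ggap_frequencies(s, g)
      expect_equal(sum(f), 1, tolerance = 1e-12)
      expect_equal(sum(ggap_counts(s, g)), L - g - 1)
    }
  }
})

test_that("reversing a sequence transposes its dipeptide counts", {
  set.seed(5)
  for (rep in 1:10) {
    s <- random_sequence(sample(20:100, 1))
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    for (g in c(0, 1, 3)) {
      cs <- matrix(ggap_counts(s, g), 20, 20, byrow = TRUE)
      cr <- matrix(ggap_counts(r, g), 20, 20, byrow = TRUE)
      expect_identical(cs, t(cr))
    }
  }
})

test_that("short sequences raise an informative error rather than zero vectors", {
  expect_error(ggap_counts("AC", 1, id = "tiny"), "tiny",
               class = "aodeep_short_sequence_error")
  expect_error(mixed_feature_vector("AC"), class = "aodeep_short_sequence_error")
  recs <- tibble::tibble(id = c("ok", "bad"), sequence = c("ACDEF", "AC"))
  expect_error(featurize(recs), "bad", class = "aodeep_short_sequence_error")
})

test_that("the mixed vector concatenates the 0-gap and 1-gap profiles", {
  v <- mixed_feature_vector("AAAA")
  expect_length(v, 800)
  idx <- dipeptide_index("A", "A")
  expect_equal(unname(v[idx]), 1)
  expect_equal(unname(v[400 + idx]), 1)
  expect_equal(sum(v), 2)

  v2 <- mixed_feature_vector("ACDEF")
  expect_equal(unname(v2[1:400]), unname(ggap_frequencies("ACDEF", 0)))
  expect_equal(unname(v2[401:800]), unname(ggap_frequencies("ACDEF", 1)))
})

test_that("featurize preserves order, names columns stably and matches the per-row oracle", {
  set.seed(33)
  recs <- random_records(20, c(5, 60))
  feats <- featurize(recs)
  expect_equal(dim(feats), c(20L, 801L))
  expect_equal(feats$id, recs$id)
  expect_equal(names(feats)[2], "g0_AA")
  expect_equal(names(feats)[801], "g1_YY")
  x <- feature_matrix(feats)$x
  expect_equal(unname(rowSums(x[, 1:400])), rep(1, 20), tolerance = 1e-12)
  expect_equal(unname(rowSums(x[, 401:800])), rep(1, 20), tolerance = 1e-12)
  for (k in c(1, 7, 20)) {
    ora <- c(oracle_ggap_counts(recs$sequence[k], 0) / (nchar(recs$sequence[k]) - 1),
             oracle_ggap_counts(recs$sequence[k], 1) / (nchar(recs$sequence[k]) - 2))
    expect_equal(unname(x[k, ]), ora, tolerance = 1e-15)
  }
  perm <- sample(20)
  expect_equal(featurize(recs[perm, ])$id, recs$id[perm])
  expect_equal(as.matrix(featurize(recs[perm, ])[, -1]),
               as.matrix(feats[perm, -1]), ignore_attr = TRUE)
})
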