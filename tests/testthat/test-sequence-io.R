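test_that("read_fasta parses valid records with ids, descriptions and lengths", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1 sod family", "ACDEF", ">p2", "WWWW"), fa)
  res <- read_fasta(fa)
  expect_equal(res$records$id, c("p1", "p2"))
  expect_equal(res$records$description, c("sod family", ""))
  expect_equal(res$records$length, c(5L, 4L))
  expect_equal(res$rejected, character(0))
})

test_that("records with non-standard letters are rejected and reported by id", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p3", "ACXDE", ">p4", "ACDE"), fa)
  res <- read_fasta(fa)
  expect_equal(res$records$id, "p4")
  expect_equal(res$rejected, "p3")
  expect_error(read_fasta(fa, strict = TRUE), class = "aodeep_validation_error")
})

test_that("rejection is exactly the complement of the 20-letter alphabet", {
  set.seed(7)
  invalid <- c("B", "X", "Z", "U", "O", "J", "*", "-")
  fa <- withr::local_tempfile(fileext = ".fa")
  n <- 40
  has_bad <- logical(n)
  lines <- character(0)
  for (k in seq_len(n)) {
    pool_bad <- runif(1) < 0.5
    chars <- sample(AA_ALPHABET, 12, replace = TRUE)
    if (pool_bad) chars[sample(12, 1)] <- sample(invalid, 1)
    has_bad[k] <- pool_bad
    lines <- c(lines, sprintf(">s%02d", k), paste(chars, collapse = ""))
  }
  writeLines(lines, fa)
  res <- read_fasta(fa)
  expect_setequal(res$rejected, sprintf("s%02d", which(has_bad)))
  expect_setequal(res$records$id, sprintf("s%02d", which(!has_bad)))
})

test_that("lowercase residues are uppercased before validation", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1", "acdEF"), fa)
  expect_equal(read_fasta(fa)$records$sequence, "ACDEF")
})

test_that("malformed and degenerate inputs give typed errors", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACDEF", ">p1", "ACDEF"), fa)
  expect_error(read_fasta(fa), "line 1", class = "aodeep_parse_error")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa), class = "aodeep_empty_input_error")
  writeLines(c(">only_bad", "XXXX"), fa)
  expect_error(read_fasta(fa), class = "aodeep_empty_input_error")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")),
               class = "aodeep_io_error")
})

test_that("duplicate ids are kept but flagged with a warning", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">dup", "ACDEF", ">dup", "WWWW"), fa)
  expect_warning(res <- read_fasta(fa), "dup")
  expect_equal(nrow(res$records), 2L)
})

test_that("write_fasta round-trips ids and residues, wrapping long sequences", {
  set.seed(11)
  recs <- random_records(3)
  recs$description <- c("alpha", "", "gamma d")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, fa)
  back <- read_fasta(fa)$records
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$description, recs$description)

  long <- tibble::tibble(id = "long1", sequence = random_sequence(600))
  write_fasta(long, fa)
  lines <- readLines(fa)
  expect_true(all(nchar(lines[-1]) <= 60))
  expect_equal(read_fasta(fa)$records$sequence, long$sequence)

  write_fasta(tibble::tibble(id = character(), sequence = character()), fa)
  expect_error(read_fasta(fa), class = "aodeep_empty_input_error")
})

test_that("label files round-trip and reject non-binary labels", {
  lab <- tibble::tibble(id = c("a", "b", "c"), label = c(1L, 0L, 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labels(lab, path)
  expect_equal(read_labels(path), lab)
  writeLines("a\t2", path)
  expect_error(read_labels(path), class = "aodeep_validation_error")
})

test_that("attach_labels joins by id and names missing records", {
  recs <- tibble::tibble(id = c("a", "b"), sequence = c("ACDEF", "WWWW"))
  lab <- tibble::tibble(id = "a", label = 1L)
  expect_error(attach_labels(recs, lab), "b", class = "aodeep_validation_error")
  lab2 <- tibble::tibble(id = c("b", "a"), label = c(0L, 1L))
  expect_equal(attach_labels(recs, lab2)$label, c(1L, 0L))
})
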