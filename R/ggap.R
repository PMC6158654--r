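#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetically ordered (`A < C < D < ... < Y`). This ordering fixes the
#' dipeptide indexing used throughout the package, so feature columns are
#' portable across models and sessions.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residues -> integer codes 1..20, NA for anything outside the alphabet
aa_codes <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  match(chars, AA_ALPHABET)
}

#' Index of an ordered dipeptide
#'
#' Maps an ordered pair of standard amino-acid letters to its 1-based position
#' in the 400-dimensional dipeptide composition vector. The map is the
#' row-major bijection `20 * rank(first) + rank(second)` with ranks taken in
#' alphabetical order, so `("A","A")` is 1 and `("Y","Y")` is 400.
#'
#' @param first,second Single amino-acid letters (vectorised).
#' @return Integer index in `[1, 400]`.
#' @examples
#' dipeptide_index("A", "C")
#' @export
dipeptide_index <- function(first, second) {
  i <- match(first, AA_ALPHABET)
  j <- match(second, AA_ALPHABET)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(first[is.na(i)], second[is.na(j)]))
    abort(sprintf("Invalid amino-acid letter(s): %s", paste(bad, collapse = ", ")),
          class = "aodeep_domain_error")
  }
  20L * (i - 1L) + j
}

#' Names of the 400 ordered dipeptides
#'
#' @param g Optional gap value; when given, names are prefixed `g<g>_`.
#' @return Character vector of length 400 in `dipeptide_index()` order.
#' @export
dipeptide_names <- function(g = NULL) {
  nm <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  if (!is.null(g)) nm <- paste0("g", g, "_", nm)
  nm
}

check_gap <- function(g) {
  if (length(g) != 1L || !is.numeric(g) || g != as.integer(g) || g < 0 || g > 9)
    abort("`g` must be a single integer gap in 0..9.", class = "aodeep_domain_error")
  as.integer(g)
}

#' Count g-gap dipeptides in one sequence
#'
#' A g-gap dipeptide is an ordered residue pair separated by exactly `g`
#' intervening residues; a sequence of length `L` contains `L - g - 1` such
#' pairs. Requires `L > g + 1`.
#'
#' @param sequence A validated amino-acid string over the 20-letter alphabet.
#' @param g Gap, an integer in 0..9 (0 = ordinary adjacent dipeptide).
#' @param id Record id used in error messages.
#' @return Named integer vector of length 400 summing to `L - g - 1`.
#' @export
ggap_counts <- function(sequence, g = 0, id = "<sequence>") {
  g <- check_gap(g)
  codes <- aa_codes(sequence)
  if (anyNA(codes))
    abort(sprintf("Sequence '%s' contains letters outside the 20-letter alphabet.", id),
          class = "aodeep_domain_error")
  L <- length(codes)
  if (L <= g + 1L)
    abort(sprintf("Sequence '%s' has length %d but gap g=%d requires length >= %d.",
                  id, L, g, g + 2L),
          class = "aodeep_short_sequence_error")
  idx <- 20L * (codes[seq_len(L - g - 1L)] - 1L) + codes[seq.int(g + 2L, L)]
  counts <- tabulate(idx, nbins = 400L)
  names(counts) <- dipeptide_names()
  counts
}

#' g-gap dipeptide frequencies of one sequence
#'
#' Normalises `ggap_counts()` by the number of pairs, `L - g - 1`, so the 400
#' frequencies sum to one.
#'
#' @inheritParams ggap_counts
#' @return Named numeric vector of length 400 summing to 1.
#' @export
ggap_frequencies <- function(sequence, g = 0, id = "<sequence>") {
  counts <- ggap_counts(sequence, g, id)
  counts / sum(counts)
}

#' Mixed g-gap feature vector of one sequence
#'
#' Concatenates the per-gap frequency profiles (default gaps 0 and 1) into the
#' model's input vector: 800 dimensions for the default mixed configuration.
#'
#' @inheritParams ggap_counts
#' @param gaps Integer vector of gap values; default `c(0, 1)`.
#' @return Named numeric vector of length `400 * length(gaps)`; each per-gap
#'   block sums to 1.
#' @export
mixed_feature_vector <- function(sequence, gaps = c(0, 1), id = "<sequence>") {
  stopifnot(length(gaps) >= 1)
  out <- lapply(gaps, function(g) {
    f <- ggap_frequencies(sequence, g, id)
    names(f) <- dipeptide_names(g)
    f
  })
  unlist(out)
}

#' Encode a set of protein records as mixed g-gap features
#'
#' Takes the record tibble produced by [read_fasta()] or [simulate_proteins()]
#' (columns `id` and `sequence`; other columns are ignored) and returns one
#' row per record: the id followed
#' by `400 * length(gaps)` frequency columns named `g0_AA ... g1_YY`.
#' Row order preserves input order.
#'
#' @param records A data frame with columns `id` and `sequence`.
#' @param gaps Integer vector of gap values; default `c(0, 1)` gives the
#'   800-dimensional mixed vector.
#' @return A tibble with `nrow(records)` rows: `id` plus the feature columns.
#' @examples
#' recs <- tibble::tibble(id = c("a", "b"), sequence = c("ACDEF", "MKLVW"))
#' featurize(recs)[, 1:4]
#' @export
featurize <- function(records, gaps = c(0, 1)) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  lens <- nchar(records$sequence)
  min_len <- max(gaps) + 2L
  short <- records$id[lens < min_len]
  if (length(short) > 0)
    abort(sprintf("Sequences too short for gaps {%s} (need length >= %d): %s",
                  paste(gaps, collapse = ","), min_len, paste(short, collapse = ", ")),
          class = "aodeep_short_sequence_error")
  mat <- t(vapply(seq_len(nrow(records)),
                  function(k) mixed_feature_vector(records$sequence[k], gaps, records$id[k]),
                  numeric(400L * length(gaps))))
  out <- as_tibble(mat)
  dplyr::bind_cols(tibble(id = records$id), out)
}

#' Split a feature tibble into a numeric matrix and its ids
#'
#' @param features A tibble from [featurize()] (`id` column plus numeric
#'   feature columns).
#' @return A list with `x` (numeric matrix, rownames = ids) and `ids`.
#' @export
feature_matrix <- function(features) {
  stopifnot(is.data.frame(features), "id" %in% names(features))
  x <- as.matrix(features[setdiff(names(features), "id")])
  storage.mode(x) <- "double"
  rownames(x) <- features$id
  list(x = x, ids = features$id)
}
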