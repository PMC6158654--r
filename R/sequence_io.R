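#' Read and validate protein sequences from a FASTA file
#'
#' Parses a multi-record protein FASTA file and validates every sequence
#' against the 20 standard amino-acid letters. Lowercase residues are
#' uppercased before validation (lowercase is commonly soft-masking, not a
#' different residue). Records containing any other character — ambiguity
#' codes B/X/Z, the rare letters U/O/J, stops `*`, gaps — are rejected: the
#' fixed 20 x 20 dipeptide feature space has no slot for them.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE`, any invalid record aborts the run; if `FALSE`
#'   (default) invalid records are dropped and reported in `rejected`.
#' @return A list with `records` (tibble: `id`, `description`, `sequence`,
#'   `length`) and `rejected` (character vector of rejected record ids).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 demo", "ACDEF", ">p2", "WWWW"), fa)
#' read_fasta(fa)$records
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path))
    abort(sprintf("FASTA file not found: %s", path), class = "aodeep_io_error")

  # Biostrings accepts some malformed input silently; pre-scan for sequence
  # data appearing before any '>' header so the error can carry a line number.
  head_lines <- readLines(path, n = 1000L, warn = FALSE)
  nonempty <- which(nzchar(trimws(head_lines)))
  if (length(nonempty) > 0 && !startsWith(trimws(head_lines[nonempty[1]]), ">"))
    abort(sprintf("Malformed FASTA: sequence data before any header at line %d of %s",
                  nonempty[1], path),
          class = "aodeep_parse_error")

  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    abort(sprintf("Failed to parse FASTA file %s: %s",
                                  path, conditionMessage(e)),
                          class = "aodeep_parse_error"))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(toupper(as.character(set)))

  if (anyDuplicated(ids))
    warn(sprintf("Duplicate record ids in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))

  ok <- !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs) &
    nzchar(seqs)
  rejected <- ids[!ok]
  if (strict && length(rejected) > 0)
    abort(sprintf("Records with non-standard letters (strict mode): %s",
                  paste(rejected, collapse = ", ")),
          class = "aodeep_validation_error")
  if (!any(ok))
    abort(sprintf("No valid protein records in %s.", path),
          class = "aodeep_empty_input_error")

  records <- tibble(id = ids[ok], description = desc[ok],
                    sequence = seqs[ok], length = nchar(seqs[ok]))
  list(records = records, rejected = rejected)
}

#' Write protein records to a FASTA file
#'
#' Output is wrapped at 60 columns and round-trips through [read_fasta()]
#' with identical ids and sequences.
#'
#' @param records Tibble with columns `id` and `sequence` (optionally
#'   `description`, appended to the header after a space).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  hdr <- records$id
  if ("description" %in% names(records)) {
    has_desc <- !is.na(records$description) & nzchar(records$description)
    hdr[has_desc] <- paste(records$id[has_desc], records$description[has_desc])
  }
  names(set) <- hdr
  tryCatch(Biostrings::writeXStringSet(set, path, width = 60L),
           error = function(e)
             abort(sprintf("Cannot write FASTA to %s: %s", path, conditionMessage(e)),
                   class = "aodeep_io_error"))
  invisible(path)
}

#' Read a two-column label file
#'
#' Tab-separated text, `record_id<TAB>label` with label 1 = antioxidant
#' (positive class) and 0 = non-antioxidant. No header row.
#'
#' @param path Path to the label file.
#' @return Tibble with columns `id` (character) and `label` (integer 0/1).
#' @export
read_labels <- function(path) {
  if (!file.exists(path))
    abort(sprintf("Label file not found: %s", path), class = "aodeep_io_error")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer"),
                          col.names = c("id", "label"))
  if (!all(df$label %in% c(0L, 1L)))
    abort("Labels must be 0 (non-antioxidant) or 1 (antioxidant).",
          class = "aodeep_validation_error")
  as_tibble(df)
}

#' Write a two-column label file
#'
#' @param labels Tibble with columns `id` and `label`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("id", "label") %in% names(labels)))
  utils::write.table(labels[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
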