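#' Read protein sequences from a FASTA file
#'
#' Reads a protein FASTA file into a tibble of sequence records, the unit
#' that flows through curation, clustering and phylogeny. Sequences are
#' uppercased and a single terminal stop character (`*`) is stripped;
#' record order follows the file.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param source Provenance tag stored with every record; defaults to the
#'   file name.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `sequence` (uppercase amino-acid string) and `source`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKVL", ">b", "mpga*"), fa)
#' read_fasta(fa)
read_fasta <- function(path, source = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  first_content <- which(nzchar(trimws(lines)))[1]
  if (is.na(first_content)) {
    abort(paste0("empty FASTA file: ", path))
  }
  if (!startsWith(trimws(lines[first_content]), ">")) {
    abort(paste0(
      "malformed FASTA at line ", first_content,
      ": expected a '>' header, got '", substr(lines[first_content], 1, 30), "'"
    ))
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA ids: ", paste(dup, collapse = ", ")))
  }
  seq_chr <- toupper(as.character(seqs))
  seq_chr <- sub("\\*$", "", seq_chr)
  tibble(id = ids, sequence = unname(seq_chr), source = source)
}

#' Write protein records to a FASTA file
#'
#' @param records Tibble with `id` and `sequence` columns (gapped sequences
#'   are allowed, so alignments round-trip too).
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  check_records(records)
  x <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# Shared validation for record tibbles.
check_records <- function(records, require_nonempty = FALSE) {
  if (!is.data.frame(records) ||
      !all(c("id", "sequence") %in% names(records))) {
    abort("`records` must be a data frame with `id` and `sequence` columns")
  }
  if (require_nonempty && nrow(records) == 0) {
    abort("`records` must contain at least one sequence")
  }
  if (anyDuplicated(records$id)) {
    abort(paste0(
      "duplicate record ids: ",
      paste(unique(records$id[duplicated(records$id)]), collapse = ", ")
    ))
  }
  if (nrow(records) > 0 && any(!nzchar(records$sequence))) {
    abort("records contain empty sequences")
  }
  invisible(records)
}
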