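#' Curation settings
#'
#' Bundles the thresholds used by the sequence-curation funnel: the open
#' length interval, the minimum fraction of the bait/reference sequence
#' that a candidate's best local alignment must cover, and the residue
#' alphabet outside which a call counts as ambiguous.
#'
#' @param min_length,max_length Exclusive length bounds in residues;
#'   retained sequences satisfy `min_length < l < max_length`.
#' @param min_coverage Minimum aligned fraction of the reference, in
#'   `[0, 1]`.
#' @param allowed_alphabet Character vector of allowed residues (default
#'   the 20 canonical amino acids).
#' @return A list of class `curation_config`.
#' @export
#' @examples
#' curation_config()
curation_config <- function(min_length = 300L, max_length = 700L,
                            min_coverage = 0.5,
                            allowed_alphabet = NULL) {
  allowed_alphabet <- allowed_alphabet %||% CANONICAL_AA
  if (!(min_length > 0 && min_length < max_length)) {
    abort("need 0 < min_length < max_length")
  }
  if (min_coverage < 0 || min_coverage > 1) {
    abort("`min_coverage` must be in [0, 1]")
  }
  structure(
    list(
      min_length = min_length, max_length = max_length,
      min_coverage = min_coverage, allowed_alphabet = allowed_alphabet
    ),
    class = "curation_config"
  )
}

#' Filter sequences by length
#'
#' Retains records whose length `l` lies strictly inside the configured
#' open interval (`min_length < l < max_length`); boundary lengths are
#' removed. Aimed at dropping truncated fragments and fusion proteins.
#'
#' @param records Tibble with `id` and `sequence` columns.
#' @param config A [curation_config()].
#' @return List with `retained` and `removed` tibbles.
#' @export
filter_by_length <- function(records, config = curation_config()) {
  check_records(records)
  l <- nchar(records$sequence)
  keep <- l > config$min_length & l < config$max_length
  list(retained = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Filter sequences with ambiguous residue calls
#'
#' Removes any record whose sequence contains a character outside the
#' allowed alphabet (by default B, J, Z, X, U, O, `*` and `-` all
#' disqualify).
#'
#' @inheritParams filter_by_length
#' @return List with `retained` and `removed` tibbles.
#' @export
filter_ambiguous <- function(records, config = curation_config()) {
  check_records(records)
  allowed <- paste0("^[", paste(config$allowed_alphabet, collapse = ""), "]*$")
  keep <- grepl(allowed, records$sequence)
  list(retained = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Filter sequences by local-alignment coverage of a reference
#'
#' Aligns each candidate locally against a single bait/reference record
#' and retains it iff the aligned span on the reference covers at least
#' `min_coverage` of the reference length. This removes aberrant hits
#' (remote homologs, false positives) that only share a short segment
#' with the bait.
#'
#' @inheritParams filter_by_length
#' @param reference One-row tibble (or list) with a `sequence` field: the
#'   bait the candidates were mined with.
#' @return List with `retained`, `removed`, and a `coverage` tibble
#'   (`id`, `coverage`).
#' @export
filter_by_coverage <- function(records, reference,
                               config = curation_config()) {
  check_records(records)
  ref_seq <- reference$sequence
  if (length(ref_seq) != 1 || !nzchar(ref_seq)) {
    abort("`reference` must carry exactly one non-empty sequence")
  }
  cov <- purrr::map_dbl(records$sequence, function(s) {
    al <- local_align(s, ref_seq)
    (al$ref_end - al$ref_start + 1) / nchar(ref_seq)
  })
  keep <- cov >= config$min_coverage
  list(
    retained = records[keep, , drop = FALSE],
    removed = records[!keep, , drop = FALSE],
    coverage = tibble(id = records$id, coverage = cov)
  )
}

#' Collapse records with identical sequences
#'
#' Non-redundancy at exact string identity (after the reader's uppercase
#' normalization): the first-seen record survives and absorbs the ids of
#' later duplicates into its `synonyms` list-column. Survivor order
#' follows the input.
#'
#' @param records Tibble with `id` and `sequence` columns.
#' @return Tibble of unique-sequence records with a `synonyms` list-column.
#' @export
deduplicate <- function(records) {
  check_records(records)
  if (nrow(records) == 0) {
    return(dplyr::mutate(records, synonyms = list()))
  }
  key <- records$sequence
  survivors <- which(!duplicated(key))
  syn <- lapply(survivors, function(i) {
    records$id[key == key[i] & seq_along(key) != i]
  })
  out <- records[survivors, , drop = FALSE]
  out$synonyms <- syn
  out
}

#' Run the full sequence-curation funnel
#'
#' Applies the curation filters in a fixed order -- length, ambiguity,
#' reference coverage, exact-identity deduplication -- so each removed
#' record is attributed to exactly one (first-triggered) stage. The
#' attached report records the per-stage funnel.
#'
#' @inheritParams filter_by_coverage
#' @return A tibble of retained, deduplicated records carrying a
#'   `curation_report` attribute; retrieve it with [curation_report()].
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   id = c("a", "b"),
#'   sequence = c(strrep("MKVLAGDERT", 35), "MKV")
#' )
#' ref <- tibble::tibble(id = "bait", sequence = strrep("MKVLAGDERT", 35))
#' curated <- curate(recs, ref)
#' curation_report(curated)$counts
curate <- function(records, reference, config = curation_config()) {
  check_records(records)
  n_in <- nrow(records)
  reasons <- tibble(
    id = character(), stage_removed = character(), reason = character()
  )
  note <- function(removed, stage, reason) {
    if (nrow(removed) == 0) return(NULL)
    tibble(id = removed$id, stage_removed = stage, reason = reason)
  }

  st1 <- filter_by_length(records, config)
  reasons <- dplyr::bind_rows(reasons, note(
    st1$removed, "length",
    sprintf("length outside (%d, %d)", config$min_length, config$max_length)
  ))
  st2 <- filter_ambiguous(st1$retained, config)
  reasons <- dplyr::bind_rows(reasons, note(
    st2$removed, "ambiguity", "non-canonical residue present"
  ))
  st3 <- filter_by_coverage(st2$retained, reference, config)
  reasons <- dplyr::bind_rows(reasons, note(
    st3$removed, "coverage",
    sprintf("reference alignment coverage < %.2f", config$min_coverage)
  ))
  out <- deduplicate(st3$retained)
  dup_removed <- setdiff(st3$retained$id, out$id)
  if (length(dup_removed) > 0) {
    reasons <- dplyr::bind_rows(reasons, tibble(
      id = dup_removed, stage_removed = "deduplication",
      reason = "identical to an earlier sequence"
    ))
  }

  counts <- tibble(
    stage = c("length", "ambiguity", "coverage", "deduplication"),
    removed = c(
      nrow(st1$removed), nrow(st2$removed), nrow(st3$removed),
      length(dup_removed)
    )
  )
  report <- list(
    input = n_in, retained = nrow(out),
    counts = counts, reasons = reasons
  )
  stopifnot(report$input == report$retained + sum(counts$removed))
  attr(out, "curation_report") <- report
  out
}

#' Retrieve the report attached by [curate()]
#'
#' @param curated The tibble returned by [curate()].
#' @return List with `input`, `retained`, per-stage `counts`, and
#'   per-record removal `reasons`.
#' @export
curation_report <- function(curated) {
  rep <- attr(curated, "curation_report")
  if (is.null(rep)) {
    abort("no curation report attached; was this produced by curate()?")
  }
  rep
}
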