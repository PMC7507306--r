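#' @noRd
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

check_alphabet_in_matrix <- function(seqs, mat) {
  residues <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  missing <- setdiff(residues, rownames(mat))
  if (length(missing) > 0) {
    abort(paste0(
      "residue(s) not covered by the substitution matrix: ",
      paste(missing, collapse = ", ")
    ))
  }
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman-style local alignment with affine gaps (a gap of length
#' `L` costs `gap_open + L * gap_extend`), scored with BLOSUM62 by default
#' to mirror protein-BLAST defaults. Used by the curation step to measure
#' how much of a bait/reference sequence a candidate covers.
#'
#' @param query,reference Non-empty amino-acid strings.
#' @param substitution_matrix Square scoring matrix covering both alphabets
#'   (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A one-row tibble: `score` (>= 0), and 1-based inclusive spans
#'   `query_start`, `query_end`, `ref_start`, `ref_end`. When no residue
#'   pair scores positive the alignment is empty: score 0 and zero-width
#'   spans (`start = 1`, `end = 0`).
#' @export
#' @examples
#' local_align("MKVLAG", "MKVLAG")
local_align <- function(query, reference,
                        substitution_matrix = NULL,
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(reference)) {
    abort("both `query` and `reference` must be non-empty")
  }
  mat <- substitution_matrix %||% blosum62()
  check_alphabet_in_matrix(c(query, reference), mat)
  pa <- Biostrings::pairwiseAlignment(
    query, reference,
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  s <- Biostrings::score(pa)
  p <- Biostrings::pattern(pa)
  r <- Biostrings::subject(pa)
  if (s <= 0 || Biostrings::width(p) == 0) {
    return(tibble(
      score = 0, query_start = 1L, query_end = 0L,
      ref_start = 1L, ref_end = 0L
    ))
  }
  tibble(
    score = s,
    query_start = Biostrings::start(p), query_end = Biostrings::end(p),
    ref_start = Biostrings::start(r), ref_end = Biostrings::end(r)
  )
}

# Global (Needleman-Wunsch) alignment returning the two gapped strings.
global_align_strings <- function(a, b, gap_open = 10, gap_extend = 0.5,
                                 substitution_matrix = NULL) {
  mat <- substitution_matrix %||% blosum62()
  check_alphabet_in_matrix(c(a, b), mat)
  pa <- Biostrings::pairwiseAlignment(
    a, b,
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  c(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa))
  )
}

#' Global percent identity between two protein sequences
#'
#' Aligns the pair globally (BLOSUM62, affine gaps) and reports the
#' fraction of matching columns. By default the denominator is the number
#' of alignment columns after terminal (leading/trailing) gap columns are
#' discarded; `denominator = "shorter"` divides matches by the shorter
#' sequence length instead.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param denominator `"alignment"` (terminal-gap-trimmed columns, default)
#'   or `"shorter"` (length of the shorter sequence).
#' @param gap_open,gap_extend Affine gap penalties for the global alignment.
#' @return Identity fraction in `[0, 1]`; exactly 1 iff the sequences are
#'   identical.
#' @export
#' @examples
#' global_identity("ACDEFGHIKL", "ACDEFGHIKV")
global_identity <- function(a, b, denominator = c("alignment", "shorter"),
                            gap_open = 10, gap_extend = 0.5) {
  denominator <- match.arg(denominator)
  if (!nzchar(a) || !nzchar(b)) {
    abort("both sequences must be non-empty")
  }
  if (identical(a, b)) {
    return(1)
  }
  al <- global_align_strings(a, b, gap_open, gap_extend)
  ca <- strsplit(al[1], "")[[1]]
  cb <- strsplit(al[2], "")[[1]]
  # drop terminal gap columns: any column inside the leading/trailing run
  # of gaps of either row
  interior <- function(x) {
    ng <- which(x != "-")
    seq(min(ng), max(ng))
  }
  keep <- intersect(interior(ca), interior(cb))
  ca <- ca[keep]
  cb <- cb[keep]
  matches <- sum(ca == cb & ca != "-")
  denom <- switch(denominator,
    alignment = length(keep),
    shorter = min(nchar(a), nchar(b))
  )
  matches / denom
}
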