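standard_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble(codon = names(gc), aa = unname(gc))
}

sense_codons <- function() {
  code <- standard_code()
  code[code$aa != "*", , drop = FALSE]
}

codon_gc_count <- function(codons) {
  vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")), integer(1))
}

#' Relative adaptiveness of each sense codon
#'
#' Sharp-Li relative adaptiveness: within each synonymous family, a
#' codon's weight `w` is its usage frequency divided by the family
#' maximum, so the preferred codon of every family has `w = 1`.
#' Zero-count codons receive a pseudo-weight of 0.01 times the family
#' maximum so the geometric mean stays defined.
#'
#' @param usage Data frame with `codon` (DNA, e.g. `"AAA"`) and `count`
#'   (non-negative) columns covering all 61 sense codons.
#' @return Tibble (`codon`, `aa`, `w`) with `0 < w <= 1` and max `w = 1`
#'   in every family.
#' @export
#' @examples
#' relative_adaptiveness(toy_usage_table())
relative_adaptiveness <- function(usage) {
  if (!all(c("codon", "count") %in% names(usage))) {
    abort("`usage` needs `codon` and `count` columns")
  }
  usage$codon <- toupper(gsub("U", "T", usage$codon))
  code <- sense_codons()
  missing <- setdiff(code$codon, usage$codon)
  if (length(missing) > 0) {
    abort(paste0(
      "usage table is missing sense codon(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  tab <- dplyr::inner_join(code, usage[c("codon", "count")], by = "codon")
  if (any(tab$count < 0)) abort("codon counts must be non-negative")
  tab <- dplyr::group_by(tab, .data$aa)
  tab <- dplyr::mutate(
    tab,
    fam_max = max(.data$count),
    w = ifelse(.data$count > 0, .data$count / .data$fam_max, 0.01)
  )
  tab <- dplyr::ungroup(tab)
  if (any(tab$fam_max == 0)) {
    fams <- unique(tab$aa[tab$fam_max == 0])
    abort(paste0(
      "synonymous family with all-zero counts: ", paste(fams, collapse = ", ")
    ))
  }
  tab[c("codon", "aa", "w")]
}

#' Codon adaptation index of a coding sequence
#'
#' Geometric mean of the relative adaptiveness `w` over codons, excluding
#' single-codon families (ATG, TGG) and stop codons (Sharp & Li 1987). A
#' terminal stop codon is tolerated and excluded from the mean; an
#' internal stop is an error.
#'
#' @param nt_sequence Coding DNA string, length divisible by 3.
#' @param usage Usage table as in [relative_adaptiveness()], or a
#'   precomputed weight tibble from that function.
#' @return CAI in `(0, 1]`.
#' @export
cai <- function(nt_sequence, usage) {
  w_tab <- if ("w" %in% names(usage)) usage else relative_adaptiveness(usage)
  nt_sequence <- toupper(nt_sequence)
  if (nchar(nt_sequence) %% 3 != 0 || nchar(nt_sequence) == 0) {
    abort("sequence length must be a positive multiple of 3")
  }
  codons <- substring(
    nt_sequence,
    seq(1, nchar(nt_sequence), 3), seq(3, nchar(nt_sequence), 3)
  )
  code <- setNames(standard_code()$aa, standard_code()$codon)
  aa <- code[codons]
  if (anyNA(aa)) {
    abort(paste0("invalid codon(s): ", paste(codons[is.na(aa)], collapse = ", ")))
  }
  stops <- unname(which(aa == "*"))
  if (length(stops) > 0) {
    if (length(stops) > 1 || stops != length(codons)) {
      abort("internal stop codon in coding sequence")
    }
    codons <- codons[-stops]
    aa <- aa[-stops]
  }
  keep <- !(codons %in% c("ATG", "TGG"))
  if (!any(keep)) {
    abort("CAI undefined: sequence has only single-codon-family codons")
  }
  w <- setNames(w_tab$w, w_tab$codon)[codons[keep]]
  exp(mean(log(w)))
}

#' GC content of a nucleotide sequence
#'
#' @param nt_sequence Non-empty string over A, C, G, T.
#' @return Fraction of G + C in `[0, 1]`.
#' @export
gc_content <- function(nt_sequence) {
  nt_sequence <- toupper(nt_sequence)
  chars <- strsplit(nt_sequence, "")[[1]]
  if (length(chars) == 0) abort("sequence must be non-empty")
  bad <- setdiff(unique(chars), c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    abort(paste0("non-ACGT character(s): ", paste(bad, collapse = ", ")))
  }
  mean(chars %in% c("G", "C"))
}

translate_dna <- function(nt_sequence) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(toupper(nt_sequence))
  ))
}

#' Reverse-translate a protein under GC and CAI constraints
#'
#' Deterministic codon optimization for heterologous expression: every
#' position starts at the highest-adaptiveness codon (CAI-optimal); while
#' the GC content exceeds `gc_max`, the synonymous swap costing the least
#' CAI among all GC-reducing swaps is applied (ties broken by codon, then
#' position, in lexicographic order). Fails informatively when the
#' constraint pair cannot be met for this protein and usage table.
#'
#' @param protein Amino-acid string over the 20 canonical residues.
#' @param usage Usage table or weight tibble (see [cai()]).
#' @param gc_max Maximum allowed GC fraction (default 0.60).
#' @param cai_min Minimum allowed CAI (default 0.60).
#' @return List with `sequence` (DNA), `gc`, and `cai`; the sequence
#'   translates back to `protein`.
#' @export
#' @examples
#' g <- reverse_translate("MKVLAG", toy_usage_table(), gc_max = 1, cai_min = 0)
#' g$sequence
reverse_translate <- function(protein, usage, gc_max = 0.60, cai_min = 0.60) {
  protein <- toupper(protein)
  residues <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(residues), CANONICAL_AA)
  if (length(bad) > 0 || length(residues) == 0) {
    abort(paste0(
      "protein must be non-empty over the canonical alphabet; offending: ",
      paste(bad, collapse = ", ")
    ))
  }
  w_tab <- if ("w" %in% names(usage)) usage else relative_adaptiveness(usage)
  w_tab <- w_tab[order(w_tab$codon), , drop = FALSE]
  fam <- split(w_tab, w_tab$aa)
  # start CAI-optimal: max-w codon per family, lexicographic tie-break
  pick_best <- vapply(fam, function(f) f$codon[which.max(f$w)], character(1))
  codons <- unname(pick_best[residues])
  gc_per <- setNames(codon_gc_count(w_tab$codon), w_tab$codon)
  w_of <- setNames(w_tab$w, w_tab$codon)
  n_nt <- 3 * length(residues)
  gc_now <- sum(gc_per[codons])

  while (gc_now / n_nt > gc_max) {
    # enumerate GC-reducing synonymous swaps; keep the cheapest in CAI
    best <- NULL
    for (p in seq_along(residues)) {
      f <- fam[[residues[p]]]
      cur <- codons[p]
      cand <- f[gc_per[f$codon] < gc_per[cur], , drop = FALSE]
      if (nrow(cand) == 0) next
      loss <- log(w_of[cur]) - log(cand$w)
      for (k in seq_len(nrow(cand))) {
        key <- c(loss[k], match(cand$codon[k], w_tab$codon), p)
        if (is.null(best) || lex_less(key, best$key)) {
          best <- list(key = key, p = p, codon = cand$codon[k])
        }
      }
    }
    if (is.null(best)) {
      break # GC cannot be reduced further
    }
    gc_now <- gc_now - gc_per[codons[best$p]] + gc_per[best$codon]
    codons[best$p] <- best$codon
  }

  seq_nt <- paste(codons, collapse = "")
  gc_val <- gc_now / n_nt
  cai_val <- tryCatch(cai(seq_nt, w_tab), error = function(e) NA_real_)
  if (gc_val > gc_max || (!is.na(cai_val) && cai_val < cai_min)) {
    abort(sprintf(
      paste0(
        "constraints infeasible for this protein/usage: best achievable ",
        "frontier point GC = %.3f, CAI = %.3f (required GC <= %.2f, ",
        "CAI >= %.2f)"
      ),
      gc_val, cai_val, gc_max, cai_min
    ))
  }
  list(sequence = seq_nt, gc = gc_val, cai = cai_val)
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Codon-optimize a set of protein records
#'
#' Data-frame-first wrapper around [reverse_translate()].
#'
#' @param records Tibble with `id` and `sequence` (protein) columns.
#' @inheritParams reverse_translate
#' @return Tibble (`id`, `nt_sequence`, `gc`, `cai`).
#' @export
optimize_genes <- function(records, usage, gc_max = 0.60, cai_min = 0.60) {
  check_records(records)
  w_tab <- if ("w" %in% names(usage)) usage else relative_adaptiveness(usage)
  res <- purrr::map(records$sequence, reverse_translate,
    usage = w_tab, gc_max = gc_max, cai_min = cai_min
  )
  tibble(
    id = records$id,
    nt_sequence = purrr::map_chr(res, "sequence"),
    gc = purrr::map_dbl(res, "gc"),
    cai = purrr::map_dbl(res, "cai")
  )
}

#' A synthetic codon-usage table for examples and tests
#'
#' Deterministic toy counts (not a real organism's usage): within each
#' synonymous family the lexicographically first codon gets the largest
#' count and each subsequent codon half of the previous one. Real
#' analyses should supply a measured host usage table (codon, count).
#'
#' @return Tibble (`codon`, `count`) over the 61 sense codons.
#' @export
toy_usage_table <- function() {
  code <- sense_codons()
  code <- code[order(code$aa, code$codon), , drop = FALSE]
  counts <- unlist(lapply(
    split(code$codon, code$aa),
    function(cods) 64 / (2^(seq_along(cods) - 1))
  ), use.names = FALSE)
  tibble(codon = code$codon[order(code$codon)]) |>
    dplyr::left_join(
      tibble(codon = code$codon, count = counts),
      by = "codon"
    )
}

#' Read a codon-usage table from a TSV file
#'
#' @param path Tab-separated file with `codon` and `count` columns.
#' @return Tibble (`codon`, `count`).
#' @export
read_usage_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "count") %in% names(tab))) {
    abort("usage table must have `codon` and `count` columns")
  }
  as_tibble(tab[c("codon", "count")])
}
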