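#' Construct a protein multiple alignment object
#'
#' @param sequences Named character vector of equal-length gapped
#'   (`-`) sequences.
#' @return An object of class `protein_msa`.
#' @export
as_msa <- function(sequences) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$id)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    abort("alignment rows must have unique names")
  }
  w <- nchar(sequences)
  if (length(unique(w)) != 1) {
    abort("alignment rows must all have equal length")
  }
  structure(sequences, class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(
    "protein alignment:", length(x), "rows x",
    nchar(x[[1]]), "columns\n"
  )
  invisible(x)
}

# character matrix view (rows = sequences, cols = alignment columns)
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(m) <- names(msa)
  m
}

# drop gaps from one row
degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Center-star multiple alignment
#'
#' Progressive multiple alignment built from pairwise global alignments
#' against a center sequence -- the record with the largest summed
#' pairwise identity to all others. Gaps introduced for one sequence are
#' kept for all ("once a gap, always a gap"). A deterministic,
#' desk-scale alternative to heuristic aligners; externally produced
#' alignments can be supplied anywhere a `protein_msa` is accepted (see
#' [as_msa()]).
#'
#' @param records Tibble with `id` and `sequence` columns; at least two
#'   rows.
#' @return A `protein_msa` whose rows degap back to the input sequences,
#'   with the center id in attribute `"center"`.
#' @export
star_align <- function(records) {
  check_records(records, require_nonempty = TRUE)
  n <- nrow(records)
  if (n < 2) {
    abort("star_align needs >= 2 records; pass single sequences through unchanged")
  }
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      idm[i, j] <- idm[j, i] <-
        global_identity(records$sequence[i], records$sequence[j])
    }
  }
  center <- which.max(rowSums(idm))
  center_chars <- strsplit(records$sequence[center], "")[[1]]
  rows <- list(center_chars)
  names(rows) <- records$id[center]
  col_of <- seq_along(center_chars) # master column of each center residue
  for (i in setdiff(seq_len(n), center)) {
    al <- global_align_strings(records$sequence[center], records$sequence[i])
    gc <- strsplit(al[1], "")[[1]]
    gs <- strsplit(al[2], "")[[1]]
    new_row <- rep("-", length(rows[[1]]))
    k <- 0L # center residues consumed
    last_pos <- 0L # master column of the last placed character
    for (j in seq_along(gc)) {
      if (gc[j] != "-") {
        k <- k + 1L
        new_row[col_of[k]] <- gs[j]
        last_pos <- col_of[k]
      } else {
        # insertion relative to the center: open a fresh master column
        rows <- lapply(rows, function(r) append(r, "-", after = last_pos))
        new_row <- append(new_row, gs[j], after = last_pos)
        col_of[col_of > last_pos] <- col_of[col_of > last_pos] + 1L
        last_pos <- last_pos + 1L
      }
    }
    rows[[records$id[i]]] <- new_row
  }
  out <- vapply(rows, paste, character(1), collapse = "")
  out <- out[records$id] # restore input row order
  msa <- as_msa(out)
  attr(msa, "center") <- records$id[center]
  msa
}

#' Trim poorly occupied alignment columns
#'
#' Keeps only columns whose non-gap occupancy across rows strictly
#' exceeds `min_occupancy` (default 0.95, i.e. positions present in more
#' than 95 % of the sequences). Column order is preserved.
#'
#' @param msa A `protein_msa`.
#' @param min_occupancy Strict lower bound on the non-gap fraction.
#' @return A trimmed `protein_msa`.
#' @export
trim_alignment <- function(msa, min_occupancy = 0.95) {
  m <- msa_matrix(msa)
  occ <- colMeans(m != "-")
  keep <- occ > min_occupancy
  if (!any(keep)) {
    abort("trimming removed every column; lower `min_occupancy`")
  }
  m <- m[, keep, drop = FALSE]
  out <- as_msa(apply(m, 1, paste, collapse = ""))
  attr(out, "center") <- attr(msa, "center")
  out
}

#' Pairwise p-distances from an alignment
#'
#' Uncorrected distances: for each row pair, the fraction of mismatching
#' columns among columns where neither row has a gap (pairwise
#' deletion).
#'
#' @param msa A (typically trimmed) `protein_msa`.
#' @return Symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, dimnames = row ids.
#' @export
p_distances <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        abort(paste0(
          "no comparable columns between ", rownames(m)[i],
          " and ", rownames(m)[j]
        ))
      }
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Wraps [ape::nj()]; on additive distances the reconstructed path
#' lengths reproduce the inputs exactly. Negative branch lengths (which
#' NJ can produce on noisy distances) are clamped to zero with a
#' warning.
#'
#' @param distances Symmetric distance matrix with >= 3 labelled taxa.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(distances) {
  if (!is.matrix(distances) || nrow(distances) < 3) {
    abort("neighbor-joining needs a distance matrix over >= 3 taxa")
  }
  tree <- ape::nj(stats::as.dist(distances))
  if (any(tree$edge.length < 0)) {
    warn(sprintf(
      "%d negative NJ branch length(s) clamped to 0",
      sum(tree$edge.length < 0)
    ))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

# leaf (tip index) sets under each node of a phylo tree
tips_under_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(edges))) {
    p <- edges[r, 1]
    c <- edges[r, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  desc
}

#' Propagate curated form labels across a tree
#'
#' Every curated leaf keeps its label. Each uncurated leaf inherits the
#' unanimous label of the smallest clade (either side of an internal
#' edge's bipartition of the unrooted tree) that contains it together
#' with at least one curated leaf. Clades whose curated members
#' disagree -- or ties between equally small clades with different
#' labels -- yield `"unknown"`, marking an ambiguous phylogenetic
#' affiliation.
#'
#' @param tree A `phylo` tree whose tip labels are record ids.
#' @param curated_labels Tibble with `id` and `form` columns; ids must
#'   appear in the tree and forms must come from [rubisco_forms()].
#' @return Tibble (`id`, `form`) covering every leaf of the tree.
#' @export
propagate_forms <- function(tree, curated_labels) {
  tips <- tree$tip.label
  if (!all(c("id", "form") %in% names(curated_labels))) {
    abort("`curated_labels` needs `id` and `form` columns")
  }
  bad_form <- setdiff(curated_labels$form, rubisco_forms())
  if (length(bad_form) > 0) {
    abort(paste0("unrecognised form label(s): ", paste(bad_form, collapse = ", ")))
  }
  curated_labels <- curated_labels[curated_labels$id %in% tips, , drop = FALSE]
  if (nrow(curated_labels) == 0) {
    abort("no curated leaf is present in the tree")
  }
  lab_of <- setNames(curated_labels$form, curated_labels$id)
  curated_tip <- match(curated_labels$id, tips)

  n_tip <- length(tips)
  desc <- tips_under_nodes(tree)
  # candidate clades: both sides of every edge's bipartition
  sides <- list()
  for (r in seq_len(nrow(tree$edge))) {
    a <- desc[[tree$edge[r, 2]]]
    sides[[length(sides) + 1]] <- a
    sides[[length(sides) + 1]] <- setdiff(seq_len(n_tip), a)
  }
  sides <- unique(lapply(sides, sort))
  sides <- sides[vapply(sides, function(s) any(s %in% curated_tip), logical(1))]
  side_size <- lengths(sides)

  form <- character(n_tip)
  for (u in seq_len(n_tip)) {
    if (u %in% curated_tip) {
      form[u] <- lab_of[[tips[u]]]
      next
    }
    containing <- which(vapply(sides, function(s) u %in% s, logical(1)))
    if (length(containing) == 0) {
      form[u] <- "unknown"
      next
    }
    smallest <- containing[side_size[containing] == min(side_size[containing])]
    verdicts <- vapply(smallest, function(k) {
      inside <- intersect(sides[[k]], curated_tip)
      labs <- unique(unname(lab_of[tips[inside]]))
      if (length(labs) == 1) labs else "unknown"
    }, character(1))
    form[u] <- if (length(unique(verdicts)) == 1) verdicts[1] else "unknown"
  }
  tibble(id = tips, form = form)
}

#' Remove non-carboxylating (form-IV) sequences
#'
#' Form-IV rubisco-like proteins are homologous to rubisco but lack
#' carboxylating activity; they are dropped before kinetic prospecting.
#' Records labelled `"unknown"` are retained.
#'
#' @param records Tibble with `id` and `sequence` columns.
#' @param labels Tibble (`id`, `form`) covering every record.
#' @return The records not labelled `"IV"`.
#' @export
drop_form_iv <- function(records, labels) {
  check_records(records)
  lab <- labels$form[match(records$id, labels$id)]
  if (anyNA(lab)) {
    abort(paste0(
      "unlabelled record(s): ",
      paste(records$id[is.na(lab)], collapse = ", ")
    ))
  }
  out <- records[lab != "IV", , drop = FALSE]
  if (nrow(out) == 0) {
    warn("all records were form IV; returning an empty set")
  }
  out
}
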