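test_that("star alignment of two sequences equals their pairwise alignment", {
  recs <- tibble::tibble(id = c("a", "b"), sequence = c("MKVLAG", "MKVAG"))
  msa <- star_align(recs)
  expect_equal(nchar(msa[["a"]]), nchar(msa[["b"]]))
  expect_equal(gsub("-", "", msa[["a"]]), "MKVLAG")
  expect_equal(gsub("-", "", msa[["b"]]), "MKVAG")
  expect_equal(sum(strsplit(msa[["b"]], "")[[1]] == "-"), 1)
})

test_that("aligning a substring places gaps only around the short row", {
  recs <- tibble::tibble(
    id = c("full1", "full2", "short"),
    sequence = c("MKVLAGDERT", "MKVLAGDERT", "VLAGDE")
  )
  msa <- star_align(recs)
  expect_equal(nchar(msa[["full1"]]), 10)
  expect_false(grepl("-", msa[["full1"]]))
  expect_false(grepl("-", msa[["full2"]]))
  expect_match(msa[["short"]], "^-+VLAGDE-+$")
})

test_that("star alignment rows degap to their inputs on random fixtures", {
  fam <- gen_sequence_family(2, 4, length = 80, seed = 701)
  msa <- star_align(fam$records)
  expect_equal(
    unname(gsub("-", "", unclass(msa)[fam$records$id])),
    fam$records$sequence
  )
  expect_error(star_align(fam$records[1, ]), ">= 2")
})

test_that("trimming applies the strict occupancy rule", {
  # 20 rows; column 2 has exactly one gap (occupancy 0.95 -> removed),
  # column 3 all gaps, columns 1 and 4 full
  rows <- setNames(rep("AK-V", 20), sprintf("r%02d", 1:20))
  rows[1] <- "A--V"
  msa <- as_msa(rows)
  trimmed <- trim_alignment(msa, min_occupancy = 0.95)
  expect_equal(unname(unclass(trimmed)[1]), "AV")
  expect_equal(nchar(trimmed[[2]]), 2)
  expect_error(trim_alignment(msa, min_occupancy = 1), "every column")
})

test_that("p-distances use pairwise-complete columns", {
  msa <- as_msa(c(
    a = "ACDEFGHIKL",
    b = "ACDEFGHIVV", # 2 mismatches in 10 comparable columns
    c = "ACDEFGHIK-" # gap: 9 comparable columns vs a, all equal
  ))
  d <- p_distances(msa)
  expect_equal(d["a", "b"], 0.2)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  gappy <- as_msa(c(x = "AA--", y = "--AA", z = "AAAA"))
  expect_error(p_distances(gappy), "no comparable columns")
})

test_that("three-taxon NJ matches the closed-form three-point solution", {
  d <- matrix(
    c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  tree <- nj_tree(d)
  pl <- ape::cophenetic.phylo(tree)
  expect_equal(pl[rownames(d), colnames(d)], d, tolerance = 1e-10)
  # branch lengths: a = (3+4-5)/2 = 1, b = 2, c = 3
  lens <- sort(tree$edge.length)
  expect_equal(lens, c(1, 2, 3), tolerance = 1e-10)
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3")
})

test_that("NJ is exact on additive distances up to 8 taxa", {
  withr::local_seed(702)
  for (n in c(4, 5, 6, 8)) {
    src <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(src)
    tree <- nj_tree(d)
    pl <- ape::cophenetic.phylo(tree)
    expect_equal(pl[rownames(d), colnames(d)], d, tolerance = 1e-8)
  }
})

test_that("ultrametric four-taxon distances pair the closest leaves", {
  taxa <- c("a", "b", "c", "d")
  d <- matrix(0.8, 4, 4, dimnames = list(taxa, taxa))
  d["a", "b"] <- d["b", "a"] <- 0.2
  d["c", "d"] <- d["d", "c"] <- 0.4
  diag(d) <- 0
  tree <- ape::unroot(nj_tree(d))
  # a,b must be sisters: the split {a,b} | {c,d} is in the tree
  parts <- ape::prop.part(tree)
  splits <- lapply(parts, function(p) sort(tree$tip.label[p]))
  expect_true(
    list(c("a", "b")) %in% splits || list(c("c", "d")) %in% splits
  )
})

test_that("curated labels propagate to the smallest informative clade", {
  # caterpillar-ish 6-leaf tree: ((a,b),(c,d),(e,f)) unrooted
  tree <- ape::read.tree(
    text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);"
  )
  labs <- propagate_forms(
    tree, tibble::tibble(id = c("a", "c"), form = c("II", "IIIb"))
  )
  got <- setNames(labs$form, labs$id)
  expect_equal(got[["a"]], "II")
  expect_equal(got[["b"]], "II")
  expect_equal(got[["c"]], "IIIb")
  expect_equal(got[["d"]], "IIIb")
  # e and f: smallest informative clade contains both II and IIIb -> unknown
  expect_equal(got[["e"]], "unknown")
  expect_equal(got[["f"]], "unknown")
})

test_that("a curated leaf keeps its own label regardless of neighbors", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  labs <- propagate_forms(
    tree, tibble::tibble(id = c("a", "b"), form = c("IV", "II"))
  )
  got <- setNames(labs$form, labs$id)
  expect_equal(got[["a"]], "IV")
  expect_equal(got[["b"]], "II")
  expect_error(
    propagate_forms(tree, tibble::tibble(id = "zz", form = "II")),
    "no curated leaf"
  )
})

test_that("label propagation is invariant to rerooting", {
  fam <- gen_sequence_family(3, 3, length = 120, seed = 703)
  msa <- star_align(fam$records)
  tree <- nj_tree(p_distances(msa))
  labs1 <- propagate_forms(tree, fam$curated_labels)
  rerooted <- ape::unroot(ape::root(tree, outgroup = tree$tip.label[5]))
  labs2 <- propagate_forms(rerooted, fam$curated_labels)
  m <- merge(labs1, labs2, by = "id")
  expect_equal(m$form.x, m$form.y)
})

test_that("form-IV records are removed, unknown retained", {
  recs <- tibble::tibble(
    id = sprintf("r%d", 1:10),
    sequence = replicate(10, {
      paste(sample(c("M", "K", "V", "L"), 30, replace = TRUE), collapse = "")
    })
  )
  labels <- tibble::tibble(
    id = recs$id,
    form = c(rep("II", 5), "IV", "IV", "unknown", "IIIa", "Ia")
  )
  out <- drop_form_iv(recs, labels)
  expect_equal(nrow(out), 8)
  expect_false(any(c("r6", "r7") %in% out$id))
  expect_true("r8" %in% out$id)
  expect_warning(
    drop_form_iv(recs, dplyr::mutate(labels, form = "IV")),
    "form IV"
  )
  expect_error(drop_form_iv(recs, labels[-1, ]), "unlabelled")
})
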