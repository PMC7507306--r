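test_that("Q10 adjustment scales exponentially with temperature", {
  expect_equal(q10_adjust(5, 25, 25), 5)
  expect_equal(q10_adjust(1, 25, 35), 2.2)
  expect_equal(q10_adjust(3.3, 25, 30), 3.3 * sqrt(2.2))
  # round trip is exact
  expect_equal(q10_adjust(q10_adjust(7.1, 18, 30), 30, 18), 7.1)
  expect_error(q10_adjust(-1, 25, 30), ">= 0")
})

test_that("carboxylation efficiency converts units correctly", {
  expect_equal(carbox_efficiency(22.2, 276), 80.4, tolerance = 1e-3)
  expect_equal(carbox_efficiency(14.3, 143), 100)
  expect_equal(carbox_efficiency(1, 1000), 1)
  expect_error(carbox_efficiency(1, 0), "> 0")
})

test_that("crossover analysis agrees with rate orderings", {
  # fast high-KM vs slower lower-KM: no positive crossover, dominance
  dom <- crossover_concentration(c(22.2, 276), c(11.7, 200))
  expect_equal(dom$verdict, "dominance")
  expect_equal(dom$dominant, "a")
  for (s in c(1, 10, 50, 200, 1000)) {
    expect_gt(mm_rate(22.2, 276, s), mm_rate(11.7, 200, s))
  }
  # fast bacterial vs plant-like: crossover near 28.5 uM
  cx <- crossover_concentration(c(22.2, 276), c(3.1, 14))
  expect_equal(cx$verdict, "crossover")
  expect_equal(cx$crossover_uM, (22.2 * 14 - 3.1 * 276) / (3.1 - 22.2),
    tolerance = 1e-12
  )
  cstar <- cx$crossover_uM
  expect_lt(mm_rate(22.2, 276, 0.9 * cstar), mm_rate(3.1, 14, 0.9 * cstar))
  expect_gt(mm_rate(22.2, 276, 1.1 * cstar), mm_rate(3.1, 14, 1.1 * cstar))
  expect_equal(
    mm_rate(22.2, 276, cstar), mm_rate(3.1, 14, cstar),
    tolerance = 1e-12
  )
  # equal kcat: lower KM dominates with no crossover
  eq <- crossover_concentration(c(10, 100), c(10, 300))
  expect_equal(eq$verdict, "dominance")
  expect_equal(eq$dominant, "a")
  expect_equal(
    crossover_concentration(c(10, 100), c(10, 100))$verdict, "identical"
  )
})

test_that("kinetic similarity ratios enumerate unordered pairs", {
  recs <- tibble::tibble(id = c("a", "b"), kcat_per_s = c(10, 5))
  expect_equal(kinetic_similarity_pairs(recs)$ratio, 2)
  expect_equal(
    kinetic_similarity_pairs(
      tibble::tibble(id = c("a", "b"), kcat_per_s = c(4, 4))
    )$ratio, 1
  )
  trio <- tibble::tibble(id = c("a", "b", "c"), kcat_per_s = c(8, 4, 2))
  pr <- kinetic_similarity_pairs(trio)
  expect_equal(sort(pr$ratio), c(2, 2, 4))
  expect_equal(mean(pr$ratio), 8 / 3)
  # scale invariance
  pr10 <- kinetic_similarity_pairs(
    dplyr::mutate(trio, kcat_per_s = kcat_per_s * 10)
  )
  expect_equal(pr10$ratio, pr$ratio)
  expect_warning(
    kinetic_similarity_pairs(
      tibble::tibble(id = c("a", "b", "c"), kcat_per_s = c(8, 0, 2))
    ),
    "zero"
  )
})

test_that("identity-binned similarity means match hand arithmetic", {
  pairs <- tibble::tibble(
    id_i = letters[1:4], id_j = letters[5:8],
    identity = c(0.95, 0.85, 0.60, 0.40),
    ratio = c(1.2, 2.0, 1.5, 3.0)
  )
  out <- similarity_by_identity_bin(pairs, threshold = 0.80)
  expect_equal(out$mean_high_identity, mean(c(1.2, 2.0)))
  expect_equal(out$mean_all, mean(pairs$ratio))
  expect_equal(out$n_high_identity, 2)
  # permutation invariance
  out2 <- similarity_by_identity_bin(pairs[c(3, 1, 4, 2), ], threshold = 0.80)
  expect_equal(out2$mean_all, out$mean_all)
  # all pairs above the cut: both means coincide
  hi <- dplyr::mutate(pairs, identity = 0.9)
  both <- similarity_by_identity_bin(hi)
  expect_equal(both$mean_high_identity, both$mean_all)
  none <- dplyr::mutate(pairs, identity = 0.1)
  expect_true(is.na(similarity_by_identity_bin(none)$mean_high_identity))
})

test_that("rate summaries use activity-gated type-7 quantiles", {
  expect_equal(
    summarize_rates(tibble::tibble(kcat_per_s = c(1, 2, 3)))$median_kcat, 2
  )
  single <- summarize_rates(tibble::tibble(kcat_per_s = 4.2))
  expect_equal(single$median_kcat, 4.2)
  expect_equal(single$iqr_kcat, 0)
  mixed <- summarize_rates(
    tibble::tibble(kcat_per_s = c(0.2, 0.5, 5, 10))
  )
  expect_equal(mixed$n_active, 3)
  expect_error(
    summarize_rates(tibble::tibble(kcat_per_s = 0.1)),
    "no active"
  )
})
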