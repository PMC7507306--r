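#' Q10 temperature adjustment of a rate
#'
#' Scales a rate measured at one temperature to another assuming an
#' exponential temperature response: `k * q10^((t_to - t_from)/10)`.
#' The default Q10 of 2.2 is a common assumption for rubisco
#' carboxylation.
#'
#' @param k Rate(s), >= 0.
#' @param t_from_C,t_to_C Measurement and target temperatures in Celsius.
#' @param q10 Fold change per 10 C (default 2.2).
#' @return Adjusted rate(s).
#' @export
#' @examples
#' q10_adjust(3.3, 25, 30) # one half-decade step of 2.2
q10_adjust <- function(k, t_from_C, t_to_C, q10 = 2.2) {
  if (any(k < 0)) abort("rates must be >= 0")
  k * q10^((t_to_C - t_from_C) / 10)
}

#' Carboxylation efficiency kcat/KM
#'
#' @param kcat_per_s Turnover number in s^-1.
#' @param km_uM Michaelis constant for CO2 in uM.
#' @return Efficiency in s^-1 mM^-1.
#' @export
#' @examples
#' carbox_efficiency(22.2, 276)
carbox_efficiency <- function(kcat_per_s, km_uM) {
  if (any(km_uM <= 0)) abort("`km_uM` must be > 0")
  kcat_per_s / (km_uM / 1000)
}

#' Michaelis-Menten rate at a substrate concentration
#'
#' @param kcat Turnover number.
#' @param km Michaelis constant (same units as `S`).
#' @param S Substrate concentration(s).
#' @return `kcat * S / (km + S)`.
#' @export
mm_rate <- function(kcat, km, S) {
  kcat * S / (km + S)
}

#' Crossover concentration of two Michaelis-Menten curves
#'
#' Two saturation curves `v = kcat S/(KM + S)` intersect (apart from the
#' origin) at `C* = (kcat_a KM_b - kcat_b KM_a) / (kcat_b - kcat_a)`.
#' A positive, finite `C*` means each enzyme is faster on one side of it;
#' otherwise one enzyme dominates at every concentration.
#'
#' @param params_a,params_b Length-2 vectors or lists `c(kcat, km)` with
#'   positive entries.
#' @return A list: `verdict` (`"crossover"`, `"dominance"`, or
#'   `"identical"`), `crossover_uM` (NA unless a crossover exists), and
#'   `dominant` (`"a"` or `"b"`, NA for crossover/identical).
#' @export
#' @examples
#' crossover_concentration(c(22.2, 276), c(3.1, 14))
crossover_concentration <- function(params_a, params_b) {
  a <- as.numeric(unlist(params_a))
  b <- as.numeric(unlist(params_b))
  if (length(a) != 2 || length(b) != 2 || any(c(a, b) <= 0)) {
    abort("each parameter pair must be two positive numbers (kcat, km)")
  }
  if (isTRUE(all.equal(a, b))) {
    return(list(verdict = "identical", crossover_uM = NA_real_,
                dominant = NA_character_))
  }
  if (a[1] == b[1]) {
    # equal kcat: the lower-KM enzyme is faster everywhere
    return(list(
      verdict = "dominance", crossover_uM = NA_real_,
      dominant = if (a[2] < b[2]) "a" else "b"
    ))
  }
  cstar <- (a[1] * b[2] - b[1] * a[2]) / (b[1] - a[1])
  if (is.finite(cstar) && cstar > 0) {
    return(list(verdict = "crossover", crossover_uM = cstar,
                dominant = NA_character_))
  }
  # no positive crossover: compare anywhere, e.g. at S -> infinity
  list(
    verdict = "dominance", crossover_uM = NA_real_,
    dominant = if (a[1] > b[1]) "a" else "b"
  )
}

#' All-pairs kinetic similarity
#'
#' For every unordered pair of variants the kinetic-similarity ratio is
#' the larger turnover divided by the smaller (always >= 1), paired with
#' the global sequence identity of the two variants. Pairs involving a
#' zero rate are skipped with a warning.
#'
#' @param kinetic_records Data frame with `id` and `kcat_per_s` columns.
#' @param identity_fn Function of two ids returning their sequence
#'   identity in `[0, 1]` (e.g. a closure over [global_identity()] and a
#'   sequence table), or `NULL` to skip identities.
#' @return Tibble (`id_i`, `id_j`, `identity`, `ratio`).
#' @export
kinetic_similarity_pairs <- function(kinetic_records, identity_fn = NULL) {
  if (!all(c("id", "kcat_per_s") %in% names(kinetic_records))) {
    abort("`kinetic_records` needs `id` and `kcat_per_s` columns")
  }
  recs <- as_tibble(kinetic_records)
  if (nrow(recs) < 2) abort("need >= 2 kinetic records")
  zero <- recs$kcat_per_s <= 0 | is.na(recs$kcat_per_s)
  if (any(zero)) {
    warn(sprintf("skipping %d record(s) with zero/missing rate", sum(zero)))
    recs <- recs[!zero, , drop = FALSE]
  }
  n <- nrow(recs)
  if (n < 2) abort("fewer than 2 records with positive rates")
  pairs <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) |>
    dplyr::filter(.data$i < .data$j)
  out <- tibble(
    id_i = recs$id[pairs$i],
    id_j = recs$id[pairs$j],
    identity = NA_real_,
    ratio = pmax(recs$kcat_per_s[pairs$i], recs$kcat_per_s[pairs$j]) /
      pmin(recs$kcat_per_s[pairs$i], recs$kcat_per_s[pairs$j])
  )
  if (!is.null(identity_fn)) {
    out$identity <- purrr::map2_dbl(out$id_i, out$id_j, identity_fn)
  }
  out
}

#' Mean kinetic similarity, overall and among close homologs
#'
#' Compares the average kinetic-similarity ratio of high-identity pairs
#' (sequence identity strictly above the threshold) with the average
#' over all pairs; similar values indicate that close homologs are
#' kinetically almost as diverse as the full set.
#'
#' @param pairs Tibble from [kinetic_similarity_pairs()] with non-NA
#'   identities.
#' @param threshold Identity cut (default 0.80).
#' @param mean_type `"arithmetic"` (default) or `"geometric"`.
#' @return One-row tibble: `mean_high_identity` (NA when no pair exceeds
#'   the threshold), `mean_all`, `n_high_identity`, `n_all`.
#' @export
similarity_by_identity_bin <- function(pairs, threshold = 0.80,
                                       mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (nrow(pairs) == 0) abort("`pairs` must be non-empty")
  avg <- function(x) {
    if (length(x) == 0) return(NA_real_)
    if (mean_type == "arithmetic") mean(x) else exp(mean(log(x)))
  }
  high <- pairs$ratio[!is.na(pairs$identity) & pairs$identity > threshold]
  tibble(
    mean_high_identity = avg(high),
    mean_all = avg(pairs$ratio),
    n_high_identity = length(high),
    n_all = nrow(pairs)
  )
}

#' Summarize turnover rates of active variants
#'
#' Median and interquartile range (linear-interpolation, type-7
#' quantiles) of `kcat` over records passing the activity threshold.
#'
#' @param kinetic_records Data frame with a `kcat_per_s` column.
#' @param activity_threshold_per_s Minimum rate to count as active
#'   (default 0.5 s^-1, boundary inclusive).
#' @return One-row tibble: `median_kcat`, `iqr_kcat`, `q25`, `q75`,
#'   `n_active`.
#' @export
#' @examples
#' summarize_rates(tibble::tibble(kcat_per_s = c(1, 2, 3, 0.2)))
summarize_rates <- function(kinetic_records,
                            activity_threshold_per_s = 0.5) {
  if (!"kcat_per_s" %in% names(kinetic_records)) {
    abort("`kinetic_records` needs a `kcat_per_s` column")
  }
  k <- kinetic_records$kcat_per_s
  k <- k[!is.na(k) & k >= activity_threshold_per_s]
  if (length(k) == 0) abort("no active records to summarize")
  q <- quantile(k, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(
    median_kcat = q[2], iqr_kcat = q[3] - q[1],
    q25 = q[1], q75 = q[3], n_active = length(k)
  )
}
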