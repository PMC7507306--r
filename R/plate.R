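#' Spectrophotometric assay settings
#'
#' Parameters of the NADH-coupled plate assay. The effective extinction
#' coefficient has no default: it is instrument- and path-length-specific
#' (multi-well plates do not have a 1 cm path) and must be determined
#' empirically for the plate reader in use.
#'
#' @param epsilon_eff Effective NADH extinction coefficient, absorbance
#'   units per molar of NADH at 340 nm in the instrument's geometry.
#' @param enzyme_nominal_conc_nM Nominal enzyme concentration in the well
#'   (default 50 nM).
#' @param cabp_series_nM CABP inhibitor series; the duplicate zero
#'   follows the assay protocol (default `c(0, 0, 10, 20, 30, 90)` nM).
#' @param nadh_per_carboxylation NADH oxidized per carboxylation: one
#'   carboxylation yields two 3PG, each consuming one NADH downstream,
#'   hence 2.
#' @param activity_threshold_per_s Per-site rate at or above which a
#'   variant is called active (default 0.5 s^-1).
#' @param fit_window_s Two-element `c(start, end)` window, in seconds,
#'   for the linear slope fit; the default skips a 30 s mixing dead time
#'   and uses the next 300 s.
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(epsilon_eff,
                         enzyme_nominal_conc_nM = 50,
                         cabp_series_nM = c(0, 0, 10, 20, 30, 90),
                         nadh_per_carboxylation = 2,
                         activity_threshold_per_s = 0.5,
                         fit_window_s = c(30, 330)) {
  if (missing(epsilon_eff) || !is.numeric(epsilon_eff) || epsilon_eff <= 0) {
    abort("`epsilon_eff` (absorbance per molar NADH) is required and must be > 0")
  }
  if (activity_threshold_per_s <= 0) abort("`activity_threshold_per_s` must be > 0")
  if (length(fit_window_s) != 2 || fit_window_s[1] >= fit_window_s[2]) {
    abort("`fit_window_s` must be c(start, end) with start < end")
  }
  structure(
    list(
      epsilon_eff = epsilon_eff,
      enzyme_nominal_conc_nM = enzyme_nominal_conc_nM,
      cabp_series_nM = cabp_series_nM,
      nadh_per_carboxylation = nadh_per_carboxylation,
      activity_threshold_per_s = activity_threshold_per_s,
      fit_window_s = fit_window_s
    ),
    class = "assay_config"
  )
}

# summary.lm warns on zero-residual fits; noise-free synthetic traces are
# legitimate inputs here, so that specific warning is muffled
quiet_lm_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Fit the initial-rate slope of an A340 trace
#'
#' Ordinary least-squares regression of absorbance on time over the
#' configured fit window. Points whose residual exceeds 5 residual
#' standard deviations are reported as gross artifacts (message) but not
#' removed.
#'
#' @param trace Data frame with `time_s` and `a340` columns for one well.
#' @param config An [assay_config()].
#' @return One-row tibble: `slope` (absorbance / s), `slope_se`,
#'   `n_points`, `r_squared`.
#' @export
fit_slope <- function(trace, config) {
  if (!all(c("time_s", "a340") %in% names(trace))) {
    abort("`trace` needs `time_s` and `a340` columns")
  }
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing")
  }
  win <- trace[trace$time_s >= config$fit_window_s[1] &
    trace$time_s <= config$fit_window_s[2], , drop = FALSE]
  if (nrow(win) < 10) {
    abort(sprintf(
      "only %d points inside the fit window [%g, %g] s; need >= 10",
      nrow(win), config$fit_window_s[1], config$fit_window_s[2]
    ))
  }
  fit <- lm(a340 ~ time_s, data = win)
  res <- stats::residuals(fit)
  sigma <- stats::sd(res)
  if (sigma > 0 && any(abs(res) > 5 * sigma)) {
    inform(sprintf(
      "%d gross artifact point(s) (|residual| > 5 sigma) in slope fit",
      sum(abs(res) > 5 * sigma)
    ))
  }
  sm <- quiet_lm_summary(fit)
  tibble(
    slope = unname(coef(fit)[2]),
    slope_se = sm$coefficients["time_s", "Std. Error"],
    n_points = nrow(win),
    r_squared = sm$r.squared
  )
}

#' Convert an A340 slope to a carboxylation rate
#'
#' NADH consumption dims A340, so slopes are expected to be <= 0. The
#' NADH oxidation rate `-slope / epsilon_eff` (molar per second) is
#' divided by the NADH:carboxylation stoichiometry (2, since each
#' carboxylation yields two 3PG) and expressed in nM/s. A positive slope
#' beyond 3 standard errors triggers a warning and the rate is clamped
#' to 0.
#'
#' @param slope A340 slope in absorbance per second (scalar, or the
#'   tibble from [fit_slope()]).
#' @param config An [assay_config()].
#' @return Carboxylation rate in nM per second (>= 0).
#' @export
slope_to_carbox_rate <- function(slope, config) {
  se <- 0
  if (is.data.frame(slope)) {
    se <- slope$slope_se %||% 0
    slope <- slope$slope
  }
  if (slope > 0) {
    if (slope > 3 * se) {
      warn("positive A340 slope beyond noise tolerance; rate clamped to 0")
    }
    return(0)
  }
  nadh_M_per_s <- -slope / config$epsilon_eff
  (nadh_M_per_s / config$nadh_per_carboxylation) * 1e9
}

#' Active-site titration from a CABP dilution series
#'
#' CABP binds rubisco active sites stoichiometrically and essentially
#' irreversibly, so the carboxylation rate falls linearly with inhibitor
#' until all sites are blocked. A least-squares line through rate versus
#' CABP concentration gives the active-site concentration `[E]` as the
#' x-intercept and the uninhibited rate `Vmax` as the y-intercept;
#' `kcat = Vmax / [E]`. Duplicate rates at the same CABP level are
#' averaged first. Saturated points -- CABP above the estimated `[E]`
#' with rate below 5 % of the uninhibited rate -- bias the line, so one
#' guarded refit excludes them.
#'
#' @param rates_by_cabp Data frame with `cabp_nM` and `rate_nM_s`
#'   columns (one row per well).
#' @param config An [assay_config()].
#' @return An object of class `titration_fit` with fields `vmax_nM_s`,
#'   `active_sites_nM`, `kcat_per_s`, `r_squared`, `active`,
#'   `quantifiable`, `n_points_used`, and the (possibly reduced) points.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   cabp_nM = c(0, 10, 20, 30),
#'   rate_nM_s = c(500, 400, 300, 200)
#' )
#' fit <- titration_fit(pts, assay_config(epsilon_eff = 5000))
#' glance(fit)
titration_fit <- function(rates_by_cabp, config) {
  if (!all(c("cabp_nM", "rate_nM_s") %in% names(rates_by_cabp))) {
    abort("`rates_by_cabp` needs `cabp_nM` and `rate_nM_s` columns")
  }
  pts <- dplyr::summarise(
    dplyr::group_by(as_tibble(rates_by_cabp), .data$cabp_nM),
    rate_nM_s = mean(.data$rate_nM_s), .groups = "drop"
  )
  if (nrow(pts) < 3) {
    abort("need >= 3 distinct CABP concentrations")
  }
  zero_rate <- pts$rate_nM_s[pts$cabp_nM == 0]
  zero_rate <- if (length(zero_rate) > 0) zero_rate[1] else max(pts$rate_nM_s)

  result <- function(quantifiable, vmax = NA_real_, sites = NA_real_,
                     kcat = NA_real_, r2 = NA_real_, used = pts) {
    structure(
      list(
        vmax_nM_s = vmax, active_sites_nM = sites, kcat_per_s = kcat,
        r_squared = r2,
        active = isTRUE(kcat >= config$activity_threshold_per_s),
        quantifiable = quantifiable, n_points_used = nrow(used),
        points = used, all_points = pts
      ),
      class = "titration_fit"
    )
  }

  if (all(pts$rate_nM_s <= 0)) {
    return(result(quantifiable = FALSE))
  }

  line_fit <- function(p) {
    fit <- lm(rate_nM_s ~ cabp_nM, data = p)
    a <- unname(coef(fit)[1])
    b <- unname(coef(fit)[2])
    list(a = a, b = b, r2 = quiet_lm_summary(fit)$r.squared)
  }

  f1 <- line_fit(pts)
  if (!is.finite(f1$b) || f1$b >= 0) {
    return(result(quantifiable = FALSE))
  }
  e_hat <- -f1$a / f1$b
  saturated <- pts$cabp_nM > e_hat & pts$rate_nM_s < 0.05 * zero_rate
  used <- pts
  f <- f1
  if (any(saturated) && sum(!saturated) >= 3) {
    used <- pts[!saturated, , drop = FALSE]
    f <- line_fit(used)
    if (!is.finite(f$b) || f$b >= 0) {
      return(result(quantifiable = FALSE))
    }
    e_hat <- -f$a / f$b
  }
  if (e_hat <= 0 || e_hat > 2 * max(pts$cabp_nM)) {
    return(result(quantifiable = FALSE, r2 = f$r2, used = used))
  }
  result(
    quantifiable = TRUE, vmax = f$a, sites = e_hat,
    kcat = f$a / e_hat, r2 = f$r2, used = used
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  if (x$quantifiable) {
    cat(sprintf(
      "CABP titration: kcat = %.3g /s, [E] = %.3g nM, Vmax = %.3g nM/s, r2 = %.4f (%d points)\n",
      x$kcat_per_s, x$active_sites_nM, x$vmax_nM_s, x$r_squared,
      x$n_points_used
    ))
  } else {
    cat("CABP titration: not quantifiable (flat, rising, or out-of-range fit)\n")
  }
  invisible(x)
}

#' @export
tidy.titration_fit <- function(x, ...) {
  tibble(
    term = c("vmax_nM_s", "active_sites_nM", "kcat_per_s"),
    estimate = c(x$vmax_nM_s, x$active_sites_nM, x$kcat_per_s)
  )
}

#' @export
glance.titration_fit <- function(x, ...) {
  tibble(
    kcat_per_s = x$kcat_per_s, active_sites_nM = x$active_sites_nM,
    vmax_nM_s = x$vmax_nM_s, r_squared = x$r_squared,
    active = x$active, quantifiable = x$quantifiable,
    n_points_used = x$n_points_used
  )
}

#' @export
autoplot.titration_fit <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$all_points,
    ggplot2::aes(x = .data$cabp_nM, y = .data$rate_nM_s)
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "[CABP] (nM)", y = "carboxylation rate (nM/s)",
      title = "Active-site titration"
    )
  if (object$quantifiable) {
    p <- p + ggplot2::geom_abline(
      intercept = object$vmax_nM_s,
      slope = -object$vmax_nM_s / object$active_sites_nM,
      linetype = 2
    )
  }
  p
}

#' Call a variant active or inactive
#'
#' Boundary-inclusive: a per-site rate equal to the threshold counts as
#' active.
#'
#' @param kcat Per-site turnover in s^-1 (NA for unquantifiable
#'   variants).
#' @param config An [assay_config()].
#' @return Logical.
#' @export
call_active <- function(kcat, config) {
  !is.na(kcat) & kcat >= config$activity_threshold_per_s
}

#' Analyze a plate of assay traces
#'
#' Runs the full spectrophotometric pipeline on a long-format trace
#' table: per-well slope fit, conversion to carboxylation rate, and a
#' CABP titration fit per variant.
#'
#' @param traces Long data frame with columns `variant`, `well`,
#'   `cabp_nM`, `time_s`, `a340` (a `batch` column is carried through if
#'   present).
#' @param config An [assay_config()].
#' @return Tibble with one row per variant: `kcat_per_s`,
#'   `active_sites_nM`, `vmax_nM_s`, `r_squared`, `active`,
#'   `quantifiable`.
#' @export
analyze_plate <- function(traces, config) {
  needed <- c("variant", "well", "cabp_nM", "time_s", "a340")
  if (!all(needed %in% names(traces))) {
    abort(paste0(
      "`traces` needs columns: ", paste(needed, collapse = ", ")
    ))
  }
  rates <- traces |>
    dplyr::group_by(.data$variant, .data$well, .data$cabp_nM) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      fit_slope(df, config)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      rate_nM_s = purrr::map2_dbl(
        .data$slope, .data$slope_se,
        function(s, e) {
          slope_to_carbox_rate(tibble(slope = s, slope_se = e), config)
        }
      )
    )
  rates |>
    dplyr::group_by(.data$variant) |>
    dplyr::group_modify(function(df, key) {
      glance(titration_fit(df, config))
    }) |>
    dplyr::ungroup()
}

#' Check the internal reference variant across batches
#'
#' Each measurement batch carries a reference enzyme of known turnover
#' (the assay's internal standard); a batch whose reference deviates
#' from the expected value by more than the tolerance fraction is
#' flagged. The running mean and standard error of the reference across
#' batches are reported.
#'
#' @param batch_results Data frame with `batch`, `variant`, and
#'   `kcat_per_s` columns.
#' @param reference_variant Id of the reference variant.
#' @param expected_kcat Expected reference turnover (s^-1).
#' @param tolerance_fraction Maximum tolerated relative deviation
#'   (default 0.25).
#' @return List with `batches` (tibble: batch, reference kcat, relative
#'   deviation, flagged) and `summary` (tibble: n_batches, mean_kcat,
#'   se_kcat).
#' @export
batch_reference_check <- function(batch_results, reference_variant,
                                  expected_kcat,
                                  tolerance_fraction = 0.25) {
  needed <- c("batch", "variant", "kcat_per_s")
  if (!all(needed %in% names(batch_results))) {
    abort(paste0("`batch_results` needs columns: ", paste(needed, collapse = ", ")))
  }
  ref <- batch_results[batch_results$variant == reference_variant, , drop = FALSE]
  if (nrow(ref) == 0) {
    abort(paste0("reference variant '", reference_variant, "' missing"))
  }
  missing_batches <- setdiff(unique(batch_results$batch), unique(ref$batch))
  if (length(missing_batches) > 0) {
    abort(paste0(
      "reference missing from batch(es): ",
      paste(missing_batches, collapse = ", ")
    ))
  }
  batches <- ref |>
    dplyr::group_by(.data$batch) |>
    dplyr::summarise(kcat_per_s = mean(.data$kcat_per_s), .groups = "drop") |>
    dplyr::mutate(
      relative_deviation = abs(.data$kcat_per_s - expected_kcat) / expected_kcat,
      flagged = .data$relative_deviation > tolerance_fraction
    )
  n <- nrow(batches)
  list(
    batches = batches,
    summary = tibble(
      n_batches = n,
      mean_kcat = mean(batches$kcat_per_s),
      se_kcat = if (n > 1) sd(batches$kcat_per_s) / sqrt(n) else NA_real_
    )
  )
}
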