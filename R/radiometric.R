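#' Dissolved CO2 from a bicarbonate concentration
#'
#' Henderson-Hasselbalch equilibrium: at the assay pH the dissolved CO2
#' is `hco3 * 10^(pKa_app - pH)`. The apparent pKa default of 6.10
#' reproduces the usual mM-bicarbonate to uM-CO2 correspondence of
#' carbonic-anhydrase-equilibrated assay buffers at pH 8.0 (e.g. 4 mM ->
#' ~50 uM, 55 mM -> ~690 uM).
#'
#' @param hco3_mM Bicarbonate concentration in mM (vectorized).
#' @param pH Assay pH, in (5, 11).
#' @param pKa_app Apparent first pKa of carbonic acid (default 6.10).
#' @return Dissolved CO2 in uM.
#' @export
#' @examples
#' co2_from_bicarbonate(55, pH = 8.0)
co2_from_bicarbonate <- function(hco3_mM, pH, pKa_app = 6.10) {
  if (any(hco3_mM < 0)) abort("`hco3_mM` must be >= 0")
  if (pH <= 5 || pH >= 11) abort("`pH` must lie in (5, 11)")
  hco3_mM * 1000 * 10^(pKa_app - pH)
}

# inverse of the above; used by the synthetic generator
bicarbonate_from_co2 <- function(co2_uM, pH, pKa_app = 6.10) {
  (co2_uM / 1000) * 10^(pH - pKa_app)
}

#' Specific activity from an exhaustive-consumption calibration assay
#'
#' Calibration reactions run to completion on a known amount of RuBP, so
#' total counts divided by the RuBP amount give the counting efficiency
#' in CPM per nanomole fixed.
#'
#' @param total_cpm Total counts of the exhausted calibration reaction.
#' @param rubp_nmol Nanomoles of RuBP in the calibration (default 5.2).
#' @return Specific activity in CPM per nmol.
#' @export
#' @examples
#' calibrate_specific_activity(780) # 150 CPM/nmol
calibrate_specific_activity <- function(total_cpm, rubp_nmol = 5.2) {
  if (any(total_cpm <= 0) || rubp_nmol <= 0) {
    abort("`total_cpm` and `rubp_nmol` must be > 0")
  }
  total_cpm / rubp_nmol
}

#' Convert scintillation counts to a per-site turnover rate
#'
#' Counts are converted to nanomoles of CO2 fixed through the specific
#' activity, then normalized by assay time and by the amount of active
#' sites (quantified by 14C-CABP binding), giving a rate in reactions
#' per site per second.
#'
#' @param points Data frame with columns `cpm`, `sa_cpm_per_nmol`,
#'   `time_s`, `sites_nmol` (vectorized over rows).
#' @return The input with a `rate_per_s` column appended.
#' @export
cpm_to_rate <- function(points) {
  needed <- c("cpm", "sa_cpm_per_nmol", "time_s", "sites_nmol")
  if (!all(needed %in% names(points))) {
    abort(paste0("`points` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (any(points$sa_cpm_per_nmol <= 0) || any(points$sites_nmol <= 0) ||
      any(points$time_s <= 0)) {
    abort("specific activity, active sites and assay time must all be > 0")
  }
  dplyr::mutate(
    as_tibble(points),
    rate_per_s = (.data$cpm / .data$sa_cpm_per_nmol) /
      (.data$time_s * .data$sites_nmol)
  )
}

#' Fit Michaelis-Menten kinetics to substrate-rate data
#'
#' Nonlinear least squares of `v = kcat * S / (KM + S)`, initialized
#' from a Hanes-Woolf linearization (`S/v` regressed on `S`), with
#' standard errors from the local covariance of the fit. Replicate
#' concentrations enter individually and unweighted.
#'
#' @param points Data frame with `co2_uM` (substrate) and `rate_per_s`
#'   columns.
#' @return An object of class `mm_fit` with `kcat_per_s`, `kcat_se`,
#'   `km_uM`, `km_se`, the parameter covariance, and residuals. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' s <- c(50, 100, 200, 350, 500, 700)
#' pts <- tibble::tibble(co2_uM = s, rate_per_s = 22.2 * s / (276 + s))
#' glance(fit_michaelis_menten(pts))
fit_michaelis_menten <- function(points) {
  if (!all(c("co2_uM", "rate_per_s") %in% names(points))) {
    abort("`points` needs `co2_uM` and `rate_per_s` columns")
  }
  pts <- as_tibble(points)[c("co2_uM", "rate_per_s")]
  if (length(unique(pts$co2_uM)) < 3) {
    abort("need >= 3 distinct substrate concentrations")
  }
  if (any(pts$rate_per_s < 0)) abort("rates must be >= 0")

  # Hanes-Woolf start values: S/v = S/kcat + KM/kcat
  hw <- pts[pts$rate_per_s > 0, , drop = FALSE]
  start <- list(kcat = max(pts$rate_per_s) * 1.5, km = stats::median(pts$co2_uM))
  if (nrow(hw) >= 2) {
    hw_fit <- lm(I(co2_uM / rate_per_s) ~ co2_uM, data = hw)
    k0 <- 1 / unname(coef(hw_fit)[2])
    km0 <- unname(coef(hw_fit)[1]) * k0
    if (is.finite(k0) && k0 > 0 && is.finite(km0) && km0 > 0) {
      start <- list(kcat = k0, km = km0)
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate_per_s ~ kcat * co2_uM / (km + co2_uM),
      data = pts, start = start,
      lower = c(kcat = 1e-12, km = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(paste0(
        "Michaelis-Menten fit did not converge (", conditionMessage(e),
        "); Hanes-Woolf fallback: kcat = ", signif(start$kcat, 4),
        ", KM = ", signif(start$km, 4)
      ))
    }
  )
  est <- coef(fit)
  sm <- summary(fit)
  structure(
    list(
      kcat_per_s = unname(est["kcat"]), km_uM = unname(est["km"]),
      kcat_se = sm$coefficients["kcat", "Std. Error"],
      km_se = sm$coefficients["km", "Std. Error"],
      covariance = stats::vcov(fit),
      residuals = unname(stats::residuals(fit)),
      points = pts
    ),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten fit: kcat = %.3g +/- %.2g /s, KM = %.3g +/- %.2g uM (n = %d)\n",
    x$kcat_per_s, x$kcat_se, x$km_uM, x$km_se, nrow(x$points)
  ))
  invisible(x)
}

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("kcat_per_s", "km_uM"),
    estimate = c(x$kcat_per_s, x$km_uM),
    std.error = c(x$kcat_se, x$km_se)
  )
}

#' @export
glance.mm_fit <- function(x, ...) {
  tibble(
    kcat_per_s = x$kcat_per_s, kcat_se = x$kcat_se,
    km_uM = x$km_uM, km_se = x$km_se,
    sigma = sqrt(mean(x$residuals^2)), n = nrow(x$points)
  )
}

#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble(
    co2_uM = seq(0, max(object$points$co2_uM) * 1.05, length.out = 200)
  )
  grid$rate_per_s <- mm_rate(object$kcat_per_s, object$km_uM, grid$co2_uM)
  ggplot2::ggplot(
    object$points,
    ggplot2::aes(x = .data$co2_uM, y = .data$rate_per_s)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(
      x = expression("[CO"[2] * "] (" * mu * "M)"),
      y = expression("rate (s"^-1 * ")"),
      title = "Michaelis-Menten fit"
    )
}

#' Dissolved gas concentration from a gas-phase mixing ratio
#'
#' Henry's law: `concentration = ppm * 1e-6 * pressure * K_H`, reported
#' in uM. Default Henry coefficients (25 C) are 0.0334 M/atm for CO2 and
#' 0.00126 M/atm for O2; pass the value for the gas at hand.
#'
#' @param ppm Mixing ratio in parts per million (0..1e6; vectorized).
#' @param henry_coeff_M_per_atm Henry solubility coefficient in M/atm.
#' @param total_pressure_atm Total pressure (default 1 atm).
#' @return Dissolved concentration in uM.
#' @export
#' @examples
#' dissolved_gas(4991, 0.0334) # CO2 in the specificity-assay gas mix
dissolved_gas <- function(ppm, henry_coeff_M_per_atm,
                          total_pressure_atm = 1) {
  if (any(ppm < 0) || any(ppm > 1e6)) abort("`ppm` must lie in [0, 1e6]")
  ppm * 1e-6 * total_pressure_atm * henry_coeff_M_per_atm * 1e6
}

#' CO2:O2 specificity factor from labeled product peaks
#'
#' With 1-labeled RuBP, each carboxylation yields one labeled glycerate
#' and each oxygenation one labeled glycolate, so the velocity ratio
#' `vc/vo` equals the glycerate:glycolate count ratio. The specificity
#' factor normalizes this ratio to equal gas concentrations:
#' `S_C/O = (vc/vo) * (O2 / CO2)`. The count-partition standard error is
#' propagated binomially.
#'
#' @param glycerate_cpm,glycolate_cpm Counts in the glycerate
#'   (carboxylation) and glycolate (oxygenation) product peaks.
#' @param co2_uM,o2_uM Dissolved gas concentrations during the assay.
#' @return One-row tibble: `glycerate_cpm`, `glycolate_cpm`, `co2_uM`,
#'   `o2_uM`, `vc_over_vo`, `s_co`, `s_co_se`.
#' @export
#' @examples
#' specificity_from_peaks(1330, 1000, co2_uM = 166.7, o2_uM = 1253.7)
specificity_from_peaks <- function(glycerate_cpm, glycolate_cpm,
                                   co2_uM, o2_uM) {
  if (glycolate_cpm <= 0) {
    abort("zero glycolate counts: specificity unbounded at assay sensitivity")
  }
  if (glycerate_cpm < 0 || co2_uM <= 0 || o2_uM <= 0) {
    abort("counts must be >= 0 and gas concentrations > 0")
  }
  ratio <- glycerate_cpm / glycolate_cpm
  s_co <- ratio * (o2_uM / co2_uM)
  # binomial partition of n total counts: se(ratio) ~ ratio * sqrt(1/g + 1/o)
  se <- if (glycerate_cpm > 0) {
    s_co * sqrt(1 / glycerate_cpm + 1 / glycolate_cpm)
  } else {
    NA_real_
  }
  tibble(
    glycerate_cpm = glycerate_cpm, glycolate_cpm = glycolate_cpm,
    co2_uM = co2_uM, o2_uM = o2_uM,
    vc_over_vo = ratio, s_co = s_co, s_co_se = se
  )
}
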