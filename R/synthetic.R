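# Evaluate `code` under a fixed Mersenne-Twister seed, restoring the
# caller's RNG state afterwards so generators never perturb a session.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# substitutions needed per sequence so two independently mutated copies
# of an ancestor show the requested pairwise identity in expectation
mutations_for_identity <- function(length, identity) {
  f <- 1 - identity
  if (f <= 0) return(0L)
  # mismatch fraction between two copies each mutated at fraction p of
  # sites: 2p(1-p) + p^2 * 18/19  (two random different targets match
  # with probability 1/19)
  a <- 20 / 19
  p <- (2 - sqrt(4 - 4 * a * f)) / (2 * a)
  as.integer(round(length * p))
}

mutate_sequence <- function(chars, n_mut) {
  if (n_mut == 0) return(chars)
  pos <- sample.int(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(CANONICAL_AA, chars[p]), 1)
  }
  chars
}

#' Generate synthetic protein families with controlled identity
#'
#' Emulates the clustered structure of a homolog set: a random root
#' ancestor spawns one ancestor per family, and members are mutated
#' copies (substitutions only, so identity arithmetic stays exact).
#' Mutation counts are calibrated so realized pairwise identities
#' bracket the requested within- and between-family values. One member
#' per family is marked as curated and given a form label, mimicking a
#' reference set for label propagation.
#'
#' @param n_families,members_per_family Family structure.
#' @param length Sequence length in residues.
#' @param within_identity,between_identity Target pairwise identities;
#'   must satisfy `0 < between < within <= 1`.
#' @param seed Integer seed (fixed Mersenne-Twister stream).
#' @return List with `records` (tibble `id`, `sequence`, `source`),
#'   `curated_labels` (tibble `id`, `form`), and a `manifest` carrying
#'   the seed, parameters and true family membership.
#' @export
#' @examples
#' fam <- gen_sequence_family(3, 4, length = 120, seed = 1)
#' fam$manifest$truth
gen_sequence_family <- function(n_families, members_per_family,
                                length = 300,
                                within_identity = 0.95,
                                between_identity = 0.55,
                                seed) {
  if (!(between_identity > 0 && between_identity < within_identity &&
        within_identity <= 1)) {
    abort("need 0 < between_identity < within_identity <= 1")
  }
  m_w <- mutations_for_identity(length, within_identity)
  m_total <- mutations_for_identity(length, between_identity)
  m_b <- m_total - m_w
  if (m_b < 0) {
    abort("identity targets infeasible: between-family divergence below within-family")
  }
  with_seed(seed, {
    root <- sample(CANONICAL_AA, length, replace = TRUE)
    rows <- list()
    curated <- list()
    forms <- setdiff(rubisco_forms(), "unknown")
    for (f in seq_len(n_families)) {
      anc <- mutate_sequence(root, m_b)
      form_f <- sample(forms, 1)
      for (m in seq_len(members_per_family)) {
        id <- sprintf("fam%02d_m%02d", f, m)
        rows[[id]] <- tibble(
          id = id,
          sequence = paste(mutate_sequence(anc, m_w), collapse = ""),
          source = "gen_sequence_family",
          family = f, curated = (m == 1L), form = form_f
        )
      }
      curated[[f]] <- tibble(id = sprintf("fam%02d_m01", f), form = form_f)
    }
    truth <- dplyr::bind_rows(rows)
    list(
      records = truth[c("id", "sequence", "source")],
      curated_labels = dplyr::bind_rows(curated),
      manifest = list(
        generator = "gen_sequence_family", seed = seed,
        params = list(
          n_families = n_families,
          members_per_family = members_per_family,
          length = length, within_identity = within_identity,
          between_identity = between_identity,
          mutations_within = m_w, mutations_between_extra = m_b
        ),
        truth = truth[c("id", "family", "curated", "form")]
      )
    )
  })
}

#' Generate synthetic plate-reader traces for a CABP titration
#'
#' Simulates NADH-coupled absorbance traces under a tight-binding
#' inhibitor model: with `c` nM CABP the carboxylation rate is
#' `true_kcat * max(true_sites - c, 0)` nM/s, each carboxylation
#' consumes two NADH, and the absorbance decays linearly from the
#' initial NADH pool with homoscedastic Gaussian noise (no drift term).
#'
#' @param true_kcat True per-site turnover (s^-1).
#' @param true_sites_nM True active-site concentration (default 50 nM).
#' @param cabp_series_nM Inhibitor series, duplicate zero included
#'   (default `c(0, 0, 10, 20, 30, 90)`).
#' @param epsilon_eff Effective extinction coefficient (absorbance per
#'   molar NADH; default 5000, a plate-geometry-scale value).
#' @param nadh0_uM Initial NADH (default 800 uM); must outlast the trace.
#' @param noise_sd Gaussian absorbance noise SD (default 0.002).
#' @param duration_s,interval_s Trace length and cadence (default 15 min
#'   sampled every 2 s).
#' @param seed Integer seed.
#' @param variant Variant id stamped on the traces.
#' @return List with `traces` (long tibble: `variant`, `well`,
#'   `cabp_nM`, `time_s`, `a340`) and a `manifest` with the truth.
#' @export
gen_plate_traces <- function(true_kcat, true_sites_nM = 50,
                             cabp_series_nM = c(0, 0, 10, 20, 30, 90),
                             epsilon_eff = 5000, nadh0_uM = 800,
                             noise_sd = 0.002,
                             duration_s = 900, interval_s = 2,
                             seed, variant = "synthetic") {
  if (true_kcat < 0 || true_sites_nM <= 0 || epsilon_eff <= 0 ||
      nadh0_uM <= 0 || noise_sd < 0) {
    abort("kinetic and instrument parameters must be positive (noise_sd >= 0)")
  }
  carbox_nM_s <- true_kcat * pmax(true_sites_nM - cabp_series_nM, 0)
  nadh_nM_s <- 2 * carbox_nM_s
  if (max(nadh_nM_s) * duration_s >= nadh0_uM * 1000) {
    abort(paste0(
      "NADH exhausted within the trace; increase `nadh0_uM` above ",
      ceiling(max(nadh_nM_s) * duration_s / 1000), " uM"
    ))
  }
  times <- seq(0, duration_s, by = interval_s)
  with_seed(seed, {
    traces <- purrr::map_dfr(seq_along(cabp_series_nM), function(i) {
      nadh_M <- nadh0_uM * 1e-6 - nadh_nM_s[i] * 1e-9 * times
      tibble(
        variant = variant,
        well = sprintf("W%02d", i),
        cabp_nM = cabp_series_nM[i],
        time_s = times,
        a340 = epsilon_eff * nadh_M + rnorm(length(times), 0, noise_sd)
      )
    })
    list(
      traces = traces,
      manifest = list(
        generator = "gen_plate_traces", seed = seed,
        truth = list(
          kcat_per_s = true_kcat, active_sites_nM = true_sites_nM,
          epsilon_eff = epsilon_eff, nadh0_uM = nadh0_uM,
          noise_sd = noise_sd, cabp_series_nM = cabp_series_nM,
          duration_s = duration_s, interval_s = interval_s
        )
      )
    )
  })
}

#' Generate synthetic radiometric fixation points
#'
#' Expected fixation follows Michaelis-Menten kinetics:
#' `nmol = kcat * S/(KM + S) * sites * time`; counts are the expected
#' CPM (`nmol * SA`) with optional Poisson counting noise. Bicarbonate
#' columns are filled by inverting the CO2/bicarbonate equilibrium at
#' the assay pH.
#'
#' @param true_kcat,true_km_uM True Michaelis-Menten parameters.
#' @param sites_nmol Active sites per assay (default 0.1 nmol).
#' @param co2_series_uM CO2 concentrations, replicates allowed (default
#'   50--700 uM in duplicate).
#' @param time_s Assay duration (default 120 s).
#' @param sa_cpm_per_nmol Specific activity (default 200 CPM/nmol).
#' @param pH Assay pH for the bicarbonate back-calculation (default 8).
#' @param counting_noise Poisson counts if `TRUE` (default), exact
#'   expectations otherwise.
#' @param seed Integer seed.
#' @param variant Variant id stamped on the points.
#' @return List with `points` (tibble ready for [cpm_to_rate()] /
#'   [fit_michaelis_menten()]) and a `manifest` with the truth.
#' @export
gen_radio_points <- function(true_kcat, true_km_uM, sites_nmol = 0.1,
                             co2_series_uM = rep(c(50, 100, 200, 350, 500, 700), 2),
                             time_s = 120, sa_cpm_per_nmol = 200,
                             pH = 8.0, counting_noise = TRUE, seed,
                             variant = "synthetic") {
  if (true_kcat <= 0 || true_km_uM <= 0 || sites_nmol <= 0 ||
      time_s < 0 || sa_cpm_per_nmol <= 0) {
    abort("all kinetic and assay parameters must be positive")
  }
  expected_nmol <- mm_rate(true_kcat, true_km_uM, co2_series_uM) *
    sites_nmol * time_s
  expected_cpm <- expected_nmol * sa_cpm_per_nmol
  with_seed(seed, {
    cpm <- if (counting_noise) {
      rpois(length(expected_cpm), expected_cpm)
    } else {
      expected_cpm
    }
    points <- tibble(
      variant = variant,
      co2_uM = co2_series_uM,
      hco3_mM = bicarbonate_from_co2(co2_series_uM, pH = pH),
      cpm = as.numeric(cpm),
      time_s = time_s,
      sites_nmol = sites_nmol,
      sa_cpm_per_nmol = sa_cpm_per_nmol
    )
    list(
      points = points,
      manifest = list(
        generator = "gen_radio_points", seed = seed,
        truth = list(
          kcat_per_s = true_kcat, km_uM = true_km_uM,
          sites_nmol = sites_nmol, time_s = time_s,
          sa_cpm_per_nmol = sa_cpm_per_nmol, pH = pH,
          counting_noise = counting_noise
        )
      )
    )
  })
}

#' Generate synthetic labeled-product counts for a specificity assay
#'
#' Each turnover is a carboxylation with probability
#' `p = S_C/O * CO2 / (S_C/O * CO2 + O2)` and an oxygenation otherwise;
#' carboxylations yield labeled glycerate counts and oxygenations
#' labeled glycolate counts (binomial partition).
#'
#' @param true_sco True specificity factor.
#' @param co2_uM,o2_uM Dissolved gas concentrations.
#' @param total_turnovers Number of turnovers to partition (> 0).
#' @param counting_noise Binomial partition if `TRUE` (default), exact
#'   expectation otherwise.
#' @param seed Integer seed.
#' @return List with `glycerate_cpm`, `glycolate_cpm`, and a `manifest`.
#' @export
gen_specificity_counts <- function(true_sco, co2_uM, o2_uM,
                                   total_turnovers, counting_noise = TRUE,
                                   seed) {
  if (true_sco <= 0 || co2_uM <= 0 || o2_uM <= 0) {
    abort("specificity and gas concentrations must be positive")
  }
  if (total_turnovers <= 0) {
    abort("`total_turnovers` must be > 0")
  }
  p <- true_sco * co2_uM / (true_sco * co2_uM + o2_uM)
  with_seed(seed, {
    glycerate <- if (counting_noise) {
      rbinom(1, total_turnovers, p)
    } else {
      total_turnovers * p
    }
    list(
      glycerate_cpm = as.numeric(glycerate),
      glycolate_cpm = total_turnovers - as.numeric(glycerate),
      manifest = list(
        generator = "gen_specificity_counts", seed = seed,
        truth = list(
          s_co = true_sco, co2_uM = co2_uM, o2_uM = o2_uM,
          p_carboxylation = p, total_turnovers = total_turnovers
        )
      )
    )
  })
}
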