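#' Describe one simulated taxon's wet-up response
#'
#' A taxon's abundance trajectory after wetting is a log-time Gaussian pulse
#' on top of a baseline: `baseline + amplitude * exp(-(log(t) - log(peak_time))^2 /
#' (2 * peak_width^2))`, scaled per successional stage. Working in log time
#' lets "early" responders peak at the first sampled minute while "late"
#' responders keep rising through two days.
#'
#' @param taxon_id Taxon label.
#' @param responder_class One of `"early"`, `"mid"`, `"late"`, `"flat"`.
#' @param peak_time Hours after wetting at which the pulse peaks (> 0).
#' @param peak_width Pulse width, as an SD in log-time (dimensionless, > 0).
#' @param baseline Baseline abundance (arbitrary units, >= 0).
#' @param amplitude Pulse height above baseline (>= 0; must be 0 for
#'   `responder_class = "flat"`).
#' @param succession_scale Named numeric vector of per-stage multipliers
#'   (names are stage labels); defaults to 1 for every stage at simulation
#'   time if a stage is not named.
#' @return A one-row tibble.
#' @export
taxon_spec <- function(taxon_id, responder_class, peak_time, peak_width,
                       baseline, amplitude,
                       succession_scale = c(A = 1, B = 1, C = 1, D = 1)) {
  responder_class <- match.arg(responder_class, c("early", "mid", "late", "flat"))
  stopifnot(peak_time > 0, peak_width > 0, baseline >= 0, amplitude >= 0,
            all(succession_scale >= 0))
  if (responder_class == "flat" && amplitude != 0) {
    abort("a 'flat' taxon must have amplitude 0")
  }
  tibble::tibble(
    taxon_id = as.character(taxon_id),
    responder_class = responder_class,
    peak_time = peak_time,
    peak_width = peak_width,
    baseline = baseline,
    amplitude = amplitude,
    succession_scale = list(succession_scale)
  )
}

#' Describe one simulated soil-water metabolite
#'
#' Soil-water pools follow a mass balance: an abiotic leaching source that
#' decays after wetting, release proportional to producer abundance, and
#' Michaelis-Menten-style uptake proportional to consumer abundance.
#'
#' @param metabolite_id Metabolite label.
#' @param initial_pool Pool at the moment of wetting (concentration units, >= 0).
#' @param leach_rate Initial abiotic leaching rate (concentration / hour, >= 0).
#' @param leach_decay Time constant of leaching decay (hours, > 0).
#' @param half_saturation Half-saturation constant of uptake (concentration, > 0).
#' @param release_rate Named numeric vector, per-taxon release rate
#'   (concentration / (abundance x hour), >= 0).
#' @param uptake_rate Named numeric vector, per-taxon uptake rate
#'   (1 / (abundance x hour), >= 0).
#' @return A one-row tibble.
#' @export
metabolite_spec <- function(metabolite_id, initial_pool, leach_rate = 0,
                            leach_decay = 3, half_saturation = 5,
                            release_rate = numeric(), uptake_rate = numeric()) {
  stopifnot(initial_pool >= 0, leach_rate >= 0, leach_decay > 0,
            half_saturation > 0,
            all(is.finite(release_rate)), all(release_rate >= 0),
            all(is.finite(uptake_rate)), all(uptake_rate >= 0))
  tibble::tibble(
    metabolite_id = as.character(metabolite_id),
    initial_pool = initial_pool,
    leach_rate = leach_rate,
    leach_decay = leach_decay,
    half_saturation = half_saturation,
    release_rate = list(release_rate),
    uptake_rate = list(uptake_rate)
  )
}

#' Assemble a wet-up simulation scenario
#'
#' Bundles the experimental design (stages, sampled time points, replicate
#' counts), the taxa and metabolites with their kinetic parameters, and the
#' observation model (multiplicative lognormal noise, detection limit,
#' sequencing depth). The defaults reproduce the study design the generator
#' emulates: four successional stages, five time points (3 min encoded as
#' 0.05 h, then 9, 18, 42 and 49.5 h), five active replicates (100 active
#' samples) and triplicate killed controls from the latest stage.
#'
#' @param taxa Tibble of [taxon_spec()] rows.
#' @param metabolites Tibble of [metabolite_spec()] rows.
#' @param stages Stage labels, ordered early to late.
#' @param time_points Sampled times in hours, strictly increasing, all > 0.
#' @param replicates_active,replicates_killed Replicate counts per
#'   (stage, time) cell for active samples and killed controls.
#' @param noise_sigma SD of the lognormal observation noise (log scale).
#' @param detection_limit Peak areas below this are recorded as missing.
#' @param gain Instrument gain mapping pool concentration to peak area.
#' @param read_depth Marker reads drawn per metagenome sample.
#' @param background_abundance Constant abundance of the unmodeled
#'   "background" community absorbing the remaining read mass.
#' @param euler_dt Forward-Euler step (hours) for pool integration.
#' @param seed Root seed; all randomness flows from it via named substreams.
#' @return A list with class `"wetup_scenario"`.
#' @export
wetup_scenario <- function(taxa, metabolites,
                           stages = c("A", "B", "C", "D"),
                           time_points = c(0.05, 9, 18, 42, 49.5),
                           replicates_active = 5L,
                           replicates_killed = 3L,
                           noise_sigma = 0.25,
                           detection_limit = 0.01,
                           gain = 1,
                           read_depth = 20000L,
                           background_abundance = 20,
                           euler_dt = 0.05,
                           seed = 1L) {
  scen <- structure(
    list(
      taxa = taxa, metabolites = metabolites, stages = stages,
      time_points = time_points,
      replicates_active = as.integer(replicates_active),
      replicates_killed = as.integer(replicates_killed),
      noise_sigma = noise_sigma, detection_limit = detection_limit,
      gain = gain, read_depth = as.integer(read_depth),
      background_abundance = background_abundance,
      euler_dt = euler_dt, seed = as.integer(seed)
    ),
    class = "wetup_scenario"
  )
  validate_scenario(scen)
  scen
}

#' @export
print.wetup_scenario <- function(x, ...) {
  cat("<wetup_scenario>\n")
  cat(sprintf("  %d taxa x %d metabolites; stages %s; times (h): %s\n",
              nrow(x$taxa), nrow(x$metabolites),
              paste(x$stages, collapse = ""),
              paste(x$time_points, collapse = ", ")))
  cat(sprintf("  replicates: %d active, %d killed; noise sigma %.3g; seed %d\n",
              x$replicates_active, x$replicates_killed, x$noise_sigma, x$seed))
  invisible(x)
}

validate_scenario <- function(scenario) {
  if (!inherits(scenario, "wetup_scenario")) abort("not a wetup_scenario")
  tp <- scenario$time_points
  if (any(tp <= 0)) abort("time points must be positive (hours)")
  if (any(diff(tp) <= 0)) abort("time points must be strictly increasing")
  if (scenario$replicates_active < 1L) abort("need at least one active replicate")
  if (scenario$noise_sigma < 0) abort("noise_sigma must be >= 0")
  if (scenario$euler_dt <= 0) abort("euler_dt must be positive")
  taxa <- scenario$taxa
  if (any(duplicated(taxa$taxon_id))) abort("duplicate taxon_id")
  if (any(taxa$peak_time > max(tp))) {
    abort("taxon peak_time outside the simulation horizon")
  }
  flat <- taxa$responder_class == "flat"
  if (any(taxa$amplitude[flat] != 0)) abort("flat taxa must have amplitude 0")
  met <- scenario$metabolites
  if (any(duplicated(met$metabolite_id))) abort("duplicate metabolite_id")
  invisible(scenario)
}

#' Default four-taxon, twelve-metabolite wet-up scenario
#'
#' Ships the generator's reference study conditions: an early phototroph
#' pulsing at the first sampled minute (the primary producer), a mid and a
#' late copiotrophic heterotroph rising through the wetting window, and a
#' flat generalist, plus twelve metabolites spanning the released-only,
#' consumed-only, released-then-consumed and neutral regimes. Ground-truth
#' interaction signs are recoverable with [ground_truth()].
#'
#' @param seed Root seed for the scenario.
#' @return A `"wetup_scenario"`.
#' @export
default_wetup_scenario <- function(seed = 1L) {
  taxa <- dplyr::bind_rows(
    taxon_spec("t_early_phototroph", "early", peak_time = 0.05, peak_width = 2.5,
               baseline = 0.4, amplitude = 6,
               succession_scale = c(A = 1.3, B = 1.1, C = 0.9, D = 0.7)),
    taxon_spec("t_mid_copiotroph", "mid", peak_time = 42, peak_width = 0.8,
               baseline = 0.3, amplitude = 4,
               succession_scale = c(A = 0.8, B = 1.0, C = 1.1, D = 1.2)),
    taxon_spec("t_late_sporeformer", "late", peak_time = 49.5, peak_width = 1.0,
               baseline = 0.2, amplitude = 5,
               succession_scale = c(A = 0.7, B = 0.9, C = 1.1, D = 1.3)),
    taxon_spec("t_flat_generalist", "flat", peak_time = 1, peak_width = 1,
               baseline = 1.5, amplitude = 0)
  )
  rel <- function(...) c(...)
  mets <- dplyr::bind_rows(
    # released by the early producer, consumed by the mid heterotroph
    metabolite_spec("m_sugar_1", 30, leach_rate = 2, leach_decay = 24,
                    release_rate = rel(t_early_phototroph = 0.4),
                    uptake_rate = rel(t_mid_copiotroph = 0.7)),
    metabolite_spec("m_sugar_2", 30, leach_rate = 2, leach_decay = 24,
                    release_rate = rel(t_early_phototroph = 0.4),
                    uptake_rate = rel(t_mid_copiotroph = 0.7)),
    metabolite_spec("m_aminoacid_1", 30, leach_rate = 2, leach_decay = 24,
                    release_rate = rel(t_early_phototroph = 0.4),
                    uptake_rate = rel(t_mid_copiotroph = 0.7)),
    # released by the early producer, consumed by the late heterotroph
    metabolite_spec("m_aminoacid_2", 30, leach_rate = 2, leach_decay = 24,
                    release_rate = rel(t_early_phototroph = 0.4),
                    uptake_rate = rel(t_late_sporeformer = 0.7)),
    metabolite_spec("m_nucleobase_1", 30, leach_rate = 2, leach_decay = 24,
                    release_rate = rel(t_early_phototroph = 0.4),
                    uptake_rate = rel(t_late_sporeformer = 0.7)),
    # consumed only (initial pool leached at wet-up)
    metabolite_spec("m_fattyacid_1", 40, leach_rate = 3, leach_decay = 24,
                    uptake_rate = rel(t_mid_copiotroph = 0.7)),
    metabolite_spec("m_fattyacid_2", 40, leach_rate = 3, leach_decay = 24,
                    uptake_rate = rel(t_mid_copiotroph = 0.7)),
    metabolite_spec("m_osmolyte_1", 40, leach_rate = 3, leach_decay = 24,
                    uptake_rate = rel(t_late_sporeformer = 0.7)),
    metabolite_spec("m_osmolyte_2", 40, leach_rate = 3, leach_decay = 24,
                    uptake_rate = rel(t_late_sporeformer = 0.7)),
    # released only, by the late responder
    metabolite_spec("m_secondary_1", 8, leach_rate = 0.5, leach_decay = 24,
                    release_rate = rel(t_late_sporeformer = 0.3)),
    # consumed by both heterotrophs
    metabolite_spec("m_nucleobase_2", 50, leach_rate = 3, leach_decay = 24,
                    uptake_rate = rel(t_mid_copiotroph = 0.4,
                                      t_late_sporeformer = 0.4)),
    # neutral: abiotic dynamics only
    metabolite_spec("m_inert_1", 20, leach_rate = 1, leach_decay = 5)
  )
  wetup_scenario(taxa = taxa, metabolites = mets, seed = seed)
}

#' Null wet-up scenario for calibration experiments
#'
#' Same community design as [default_wetup_scenario()] but with every
#' biological interaction switched off and no abiotic leaching: metabolite
#' pools are flat and observed areas are pure lognormal noise, so the sign
#' of any microbe-metabolite correlation is a fair coin. Used to check the
#' size of the binomial directionality test. The default of 11 metabolites
#' gives 44 taxon-metabolite pairs, where the discrete exact test attains
#' its size closest to the nominal 5%.
#'
#' @param seed Root seed.
#' @param n_metabolites Number of inert metabolites.
#' @return A `"wetup_scenario"`.
#' @export
null_wetup_scenario <- function(seed = 1L, n_metabolites = 11L) {
  base <- default_wetup_scenario(seed = seed)
  mets <- purrr::map_dfr(seq_len(n_metabolites), function(i) {
    metabolite_spec(sprintf("m_null_%02d", i), initial_pool = 20)
  })
  wetup_scenario(taxa = base$taxa, metabolites = mets, seed = seed)
}

#' Ground truth of a scenario
#'
#' Returns the expected correlation sign for every (taxon, metabolite) pair
#' (-1 for pure consumption, +1 for pure release, 0 otherwise) together with
#' the noiseless abundance and pool trajectories, for recovery testing.
#'
#' @param scenario A [wetup_scenario()].
#' @return A list with elements `expected_sign` (tibble), `true_abundance`
#'   and `true_pool` (tibbles from [simulate_abundance()] /
#'   [simulate_metabolites()]).
#' @export
ground_truth <- function(scenario) {
  validate_scenario(scenario)
  list(
    expected_sign = expected_signs(scenario),
    true_abundance = simulate_abundance(scenario),
    true_pool = simulate_metabolites(scenario, killed = FALSE)
  )
}

#' Expected correlation sign per (taxon, metabolite) pair
#'
#' @param scenario A [wetup_scenario()].
#' @return Tibble `taxon_id`, `metabolite_id`, `expected_sign`.
#' @export
expected_signs <- function(scenario) {
  inter <- scenario_interactions(scenario)
  grid <- tidyr::expand_grid(
    taxon_id = scenario$taxa$taxon_id,
    metabolite_id = scenario$metabolites$metabolite_id
  )
  grid %>%
    dplyr::left_join(inter, by = c("taxon_id", "metabolite_id")) %>%
    dplyr::mutate(
      release_rate = dplyr::coalesce(.data$release_rate, 0),
      uptake_rate = dplyr::coalesce(.data$uptake_rate, 0),
      expected_sign = dplyr::case_when(
        .data$uptake_rate > 0 & .data$release_rate == 0 ~ -1L,
        .data$release_rate > 0 & .data$uptake_rate == 0 ~ 1L,
        TRUE ~ 0L
      )
    ) %>%
    dplyr::select("taxon_id", "metabolite_id", "expected_sign")
}

# long (taxon_id, metabolite_id, release_rate, uptake_rate) view of the
# per-metabolite rate maps
scenario_interactions <- function(scenario) {
  met <- scenario$metabolites
  rows <- purrr::pmap_dfr(
    list(met$metabolite_id, met$release_rate, met$uptake_rate),
    function(mid, rel, upt) {
      taxa <- union(names(rel), names(upt))
      if (length(taxa) == 0L) {
        return(tibble::tibble(taxon_id = character(), metabolite_id = character(),
                              release_rate = numeric(), uptake_rate = numeric()))
      }
      tibble::tibble(
        taxon_id = taxa,
        metabolite_id = mid,
        release_rate = ifelse(taxa %in% names(rel), rel[taxa], 0),
        uptake_rate = ifelse(taxa %in% names(upt), upt[taxa], 0)
      )
    }
  )
  unknown <- setdiff(rows$taxon_id, scenario$taxa$taxon_id)
  if (length(unknown) > 0L) {
    abort(sprintf("interaction names unknown taxa: %s",
                  paste(unknown, collapse = ", ")))
  }
  rows
}
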