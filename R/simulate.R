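# Synthetic wet-up generator: abundance curves, metabolite mass balance,
# observation model, marker reads and isolate spent-media profiles.

# closed-form abundance of every taxon at continuous time t (hours) for one
# stage; returns a numeric vector aligned with scenario$taxa rows
taxon_curve <- function(taxa, t, stage) {
  if (any(t <= 0)) abort("abundance is defined for positive times only")
  mult <- vapply(taxa$succession_scale, function(s) {
    if (stage %in% names(s)) s[[stage]] else 1
  }, numeric(1))
  z <- outer(log(t), log(taxa$peak_time), "-") # time x taxon
  pulse <- exp(-(z^2) / matrix(2 * taxa$peak_width^2, nrow = length(t),
                               ncol = nrow(taxa), byrow = TRUE))
  b <- matrix(taxa$baseline, nrow = length(t), ncol = nrow(taxa), byrow = TRUE) +
    matrix(taxa$amplitude, nrow = length(t), ncol = nrow(taxa), byrow = TRUE) * pulse
  sweep(b, 2, mult, "*")
}

#' Simulate taxon abundance trajectories
#'
#' Evaluates each taxon's log-time Gaussian response at every sampled
#' (stage, time) combination. Deterministic given the scenario: observation
#' noise enters later, at the marker-read stage.
#'
#' @param scenario A [wetup_scenario()].
#' @return Tibble with columns `taxon_id`, `stage`, `time`, `abundance`.
#' @export
simulate_abundance <- function(scenario) {
  validate_scenario(scenario)
  taxa <- scenario$taxa
  purrr::map_dfr(scenario$stages, function(stg) {
    b <- taxon_curve(taxa, scenario$time_points, stg)
    tidyr::expand_grid(time = scenario$time_points, taxon_id = taxa$taxon_id) %>%
      dplyr::mutate(stage = stg, abundance = as.vector(t(b))) %>%
      dplyr::select("taxon_id", "stage", "time", "abundance")
  })
}

#' Simulate soil-water metabolite pools
#'
#' Integrates, per successional stage, the mass balance
#' `dM/dt = leach_rate * exp(-t / leach_decay) + sum_i release_i * B_i(t) -
#' sum_i uptake_i * B_i(t) * M / (half_saturation + M)` by forward Euler from
#' the moment of wetting, clamping pools at zero. In killed mode every
#' biological term (release and uptake) is switched off, leaving only the
#' abiotic leaching source - the killed-control contrast.
#'
#' @param scenario A [wetup_scenario()].
#' @param killed If `TRUE`, biology is off (autoclaved control).
#' @param dt Euler step in hours; defaults to the scenario's `euler_dt`.
#' @return Tibble with columns `metabolite_id`, `stage`, `time`, `pool`.
#' @export
simulate_metabolites <- function(scenario, killed = FALSE, dt = scenario$euler_dt) {
  validate_scenario(scenario)
  if (dt <= 0) abort("Euler step size must be positive")
  met <- scenario$metabolites
  taxa <- scenario$taxa
  n_m <- nrow(met)
  # rate matrices metabolite x taxon
  R <- matrix(0, n_m, nrow(taxa), dimnames = list(met$metabolite_id, taxa$taxon_id))
  U <- R
  for (i in seq_len(n_m)) {
    rel <- met$release_rate[[i]]
    upt <- met$uptake_rate[[i]]
    if (length(rel)) R[i, names(rel)] <- rel
    if (length(upt)) U[i, names(upt)] <- upt
  }
  if (killed) {
    R[] <- 0
    U[] <- 0
  }
  tp <- scenario$time_points
  need_biology <- any(R > 0) || any(U > 0)
  purrr::map_dfr(scenario$stages, function(stg) {
    M <- met$initial_pool
    out <- matrix(NA_real_, n_m, length(tp))
    t_prev <- 0
    for (j in seq_along(tp)) {
      span <- tp[j] - t_prev
      n_sub <- max(1L, ceiling(span / dt))
      h <- span / n_sub
      for (s in seq_len(n_sub)) {
        t_now <- t_prev + (s - 1) * h
        leach <- met$leach_rate * exp(-t_now / met$leach_decay)
        if (need_biology) {
          # abundance at the start of the substep (t = 0 maps to the first
          # instant after wetting; use a tiny positive time)
          B <- as.vector(taxon_curve(taxa, max(t_now, 1e-6), stg))
          release <- as.vector(R %*% B)
          uptake <- as.vector(U %*% B) * M / (met$half_saturation + M)
        } else {
          release <- 0
          uptake <- 0
        }
        M <- pmax(0, M + h * (leach + release - uptake))
      }
      t_prev <- tp[j]
      out[, j] <- M
    }
    tidyr::expand_grid(metabolite_id = met$metabolite_id, time = tp) %>%
      dplyr::mutate(stage = stg, pool = as.vector(t(out))) %>%
      dplyr::select("metabolite_id", "stage", "time", "pool")
  })
}

#' Observe peak areas from simulated pools
#'
#' Applies the LC/MS observation model: per replicate,
#' `area = gain * pool * exp(eps)` with `eps ~ Normal(0, noise_sigma^2)`
#' (multiplicative lognormal noise, constant CV), and areas below the
#' detection limit recorded as missing. Returns a long table carrying the
#' full sample metadata.
#'
#' @param pools Output of [simulate_metabolites()].
#' @param scenario The generating [wetup_scenario()].
#' @param condition Sample condition label (`"active"`, `"killed"`,
#'   `"extraction_control"`).
#' @param replicates Replicate count; defaults to the scenario's count for
#'   the condition.
#' @param stages Stages to observe; killed controls default to the latest
#'   stage only, matching the paired experimental design.
#' @param seed Root seed; defaults to the scenario seed. Each condition has
#'   its own noise substream.
#' @return Long tibble with columns `metabolite_id`, `sample_id`, `stage`,
#'   `time`, `replicate`, `condition`, `qc_pass`, `area`.
#' @export
observe_peak_areas <- function(pools, scenario,
                               condition = c("active", "killed", "extraction_control"),
                               replicates = NULL, stages = NULL, seed = NULL) {
  condition <- match.arg(condition)
  assert_columns(pools, c("metabolite_id", "stage", "time", "pool"))
  replicates <- replicates %||%
    if (condition == "active") scenario$replicates_active else scenario$replicates_killed
  stages <- stages %||%
    if (condition == "killed") scenario$stages[length(scenario$stages)] else scenario$stages
  seed <- seed %||% scenario$seed
  base <- pools %>% dplyr::filter(.data$stage %in% stages)
  obs <- tidyr::expand_grid(base, replicate = seq_len(replicates)) %>%
    dplyr::arrange(.data$metabolite_id, .data$stage, .data$time, .data$replicate)
  eps <- with_seed(
    substream_seed(seed, paste0("observe_", condition)),
    rnorm(nrow(obs), 0, scenario$noise_sigma)
  )
  obs %>%
    dplyr::mutate(
      area = scenario$gain * .data$pool * exp(eps),
      area = ifelse(.data$area < scenario$detection_limit, NA_real_, .data$area),
      condition = condition,
      qc_pass = TRUE,
      sample_id = sprintf("%s_%s_t%g_r%d", condition, .data$stage,
                          .data$time, .data$replicate)
    ) %>%
    dplyr::select("metabolite_id", "sample_id", "stage", "time", "replicate",
                  "condition", "qc_pass", "area")
}

#' Simulate marker-gene read counts
#'
#' Draws, for every (stage, time) metagenome sample, a multinomial read
#' vector over the focal taxa plus one constant "background" taxon that
#' absorbs unmodeled community mass, so focal relative abundances stay
#' below one. One metagenome per (stage, time) cell: marker counts carry no
#' biological replicates, matching the sequencing design.
#'
#' @param abundances Output of [simulate_abundance()].
#' @param scenario The generating [wetup_scenario()].
#' @param seed Root seed; defaults to the scenario seed.
#' @return Tibble with columns `taxon_id`, `sample_id`, `stage`, `time`,
#'   `count`.
#' @export
simulate_marker_reads <- function(abundances, scenario, seed = NULL) {
  assert_columns(abundances, c("taxon_id", "stage", "time", "abundance"))
  if (scenario$read_depth <= 0) abort("read_depth must be positive")
  seed <- seed %||% scenario$seed
  cells <- abundances %>%
    dplyr::distinct(.data$stage, .data$time) %>%
    dplyr::arrange(match(.data$stage, scenario$stages), .data$time)
  with_seed(substream_seed(seed, "reads"), {
    purrr::pmap_dfr(cells, function(stage, time) {
      ab <- abundances %>%
        dplyr::filter(.data$stage == !!stage, .data$time == !!time)
      taxa <- c(ab$taxon_id, "background")
      mass <- c(ab$abundance, scenario$background_abundance)
      if (sum(mass) <= 0) {
        abort(sprintf("all-zero abundance vector in sample %s t=%g", stage, time))
      }
      counts <- as.vector(rmultinom(1, scenario$read_depth, mass / sum(mass)))
      tibble::tibble(
        taxon_id = taxa,
        sample_id = sprintf("mg_%s_t%g", stage, time),
        stage = stage, time = time, count = counts
      )
    })
  })
}

#' Simulate isolate spent-media exometabolite profiles and marker sequences
#'
#' Emulates the culture side of the study: each focal taxon has an isolate
#' counterpart grown in a defined medium containing every metabolite at its
#' scenario pool. The noiseless spent-media fold-change follows the closed
#' form `exp(-uptake * biomass * time) * (1 + release * biomass * time /
#' initial_pool)`, multiplied by lognormal noise; the recorded ground-truth
#' class is the classification of the noiseless fold-change. Each isolate
#' also receives a marker gene derived from its environmental taxon's
#' marker by independent per-site substitution at the given divergence,
#' emulating the percent-identity gap between cultured isolates and their
#' closest environmental relatives.
#'
#' @param scenario A [wetup_scenario()].
#' @param culture_biomass Effective culture biomass (abundance units).
#' @param culture_time Incubation time (hours).
#' @param noise_sigma Lognormal SD of the spent-media means (log scale);
#'   set 0 (or `noise = FALSE`) for the deterministic closed form.
#' @param noise Master switch for profile noise.
#' @param divergence Expected per-site divergence between isolate and
#'   environmental marker sequences.
#' @param marker_length Length of the simulated marker genes (nt).
#' @param seed Root seed; defaults to the scenario seed.
#' @return List with class `"exo_simulation"`: `profiles` (tibble with
#'   spent-media means, true fold-change and ground-truth class),
#'   `isolate_markers` and `env_markers` (named [Biostrings::DNAStringSet]),
#'   and `isolate_map` (tibble `isolate_id`, `taxon_id`).
#' @export
simulate_exoprofiles <- function(scenario, culture_biomass = 3, culture_time = 48,
                                 noise_sigma = 0.12, noise = TRUE,
                                 divergence = 0.10, marker_length = 450,
                                 seed = NULL) {
  validate_scenario(scenario)
  seed <- seed %||% scenario$seed
  inter <- scenario_interactions(scenario)
  grid <- tidyr::expand_grid(
    taxon_id = scenario$taxa$taxon_id,
    metabolite_id = scenario$metabolites$metabolite_id
  ) %>%
    dplyr::left_join(inter, by = c("taxon_id", "metabolite_id")) %>%
    dplyr::mutate(
      release_rate = dplyr::coalesce(.data$release_rate, 0),
      uptake_rate = dplyr::coalesce(.data$uptake_rate, 0)
    ) %>%
    dplyr::left_join(
      scenario$metabolites %>% dplyr::select("metabolite_id", "initial_pool"),
      by = "metabolite_id"
    )
  bad <- grid$initial_pool == 0 & grid$release_rate > 0
  if (any(bad)) {
    abort(sprintf(
      "released metabolite(s) with zero initial pool: %s",
      paste(unique(grid$metabolite_id[bad]), collapse = ", ")
    ))
  }
  ct <- culture_biomass * culture_time
  fc_true <- exp(-grid$uptake_rate * ct) *
    ifelse(grid$release_rate > 0, 1 + grid$release_rate * ct / grid$initial_pool, 1)
  eps <- if (noise && noise_sigma > 0) {
    with_seed(substream_seed(seed, "exo"), rnorm(nrow(grid), 0, noise_sigma))
  } else {
    rep(0, nrow(grid))
  }
  profiles <- grid %>%
    dplyr::mutate(
      isolate_id = paste0("iso_", .data$taxon_id),
      fold_change_true = fc_true,
      class_true = classify_fold_change(fc_true),
      mean_area_control = .data$initial_pool * scenario$gain,
      mean_area_inoculated = .data$mean_area_control * fc_true * exp(eps)
    ) %>%
    dplyr::select("isolate_id", "taxon_id", "metabolite_id",
                  "mean_area_inoculated", "mean_area_control",
                  "fold_change_true", "class_true")
  seqs <- with_seed(substream_seed(seed, "markers"), {
    env <- vapply(seq_len(nrow(scenario$taxa) + 1L), function(i) {
      paste(sample(c("A", "C", "G", "T"), marker_length, replace = TRUE),
            collapse = "")
    }, character(1))
    names(env) <- c(scenario$taxa$taxon_id, "background")
    iso <- vapply(scenario$taxa$taxon_id, function(tx) {
      mutate_sequence(env[[tx]], divergence)
    }, character(1))
    names(iso) <- paste0("iso_", scenario$taxa$taxon_id)
    list(env = env, iso = iso)
  })
  structure(
    list(
      profiles = profiles,
      env_markers = Biostrings::DNAStringSet(seqs$env),
      isolate_markers = Biostrings::DNAStringSet(seqs$iso),
      isolate_map = tibble::tibble(
        isolate_id = paste0("iso_", scenario$taxa$taxon_id),
        taxon_id = scenario$taxa$taxon_id
      )
    ),
    class = "exo_simulation"
  )
}

# independent per-site substitution to a different base
mutate_sequence <- function(seq, divergence) {
  stopifnot(divergence >= 0, divergence <= 1)
  bases <- strsplit(seq, "")[[1]]
  hit <- runif(length(bases)) < divergence
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(bases, collapse = "")
}

#' Simulate a complete wet-up dataset
#'
#' Convenience wrapper running the whole generator: abundance curves, active
#' and killed pools, peak-area observation for both conditions, marker
#' reads, isolate profiles and ground truth.
#'
#' @param scenario A [wetup_scenario()].
#' @param ... Passed to [simulate_exoprofiles()].
#' @return List with class `"wetup_dataset"`: `peak_areas` (active + killed
#'   long table), `marker_reads`, `exo` (the `"exo_simulation"`), `truth`
#'   (from [ground_truth()]) and the `scenario`.
#' @export
simulate_wetup <- function(scenario = default_wetup_scenario(), ...) {
  validate_scenario(scenario)
  abund <- simulate_abundance(scenario)
  pools_active <- simulate_metabolites(scenario, killed = FALSE)
  pools_killed <- simulate_metabolites(scenario, killed = TRUE)
  peaks <- dplyr::bind_rows(
    observe_peak_areas(pools_active, scenario, condition = "active"),
    observe_peak_areas(pools_killed, scenario, condition = "killed")
  )
  reads <- simulate_marker_reads(abund, scenario)
  exo <- simulate_exoprofiles(scenario, ...)
  structure(
    list(
      peak_areas = peaks,
      marker_reads = reads,
      exo = exo,
      truth = list(
        expected_sign = expected_signs(scenario),
        true_abundance = abund,
        true_pool = pools_active
      ),
      scenario = scenario
    ),
    class = "wetup_dataset"
  )
}
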