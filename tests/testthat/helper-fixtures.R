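# Shared in-code fixtures.

# Minimal two-taxon, three-metabolite scenario for fast unit tests.
tiny_scenario <- function(seed = 1L, noise_sigma = 0, ...) {
  taxa <- dplyr::bind_rows(
    taxon_spec("tx_early", "early", peak_time = 0.05, peak_width = 2.5,
               baseline = 0.4, amplitude = 6),
    taxon_spec("tx_late", "late", peak_time = 49.5, peak_width = 1,
               baseline = 0.2, amplitude = 5)
  )
  mets <- dplyr::bind_rows(
    metabolite_spec("met_released", 10, leach_rate = 0.5, leach_decay = 24,
                    release_rate = c(tx_late = 0.3)),
    metabolite_spec("met_consumed", 40, leach_rate = 2, leach_decay = 24,
                    uptake_rate = c(tx_late = 0.7)),
    metabolite_spec("met_inert", 20, leach_rate = 0)
  )
  wetup_scenario(taxa = taxa, metabolites = mets, noise_sigma = noise_sigma,
                 seed = seed, ...)
}

# Long peak-area tibble built directly from a metabolite x cell matrix of
# per-replicate areas (one replicate per cell unless `replicates` given).
manual_peak_tbl <- function(values, metabolite_id, stages, times,
                            condition = "active", replicates = 1L,
                            qc_pass = TRUE) {
  grid <- tidyr::expand_grid(
    metabolite_id = metabolite_id,
    stage = stages, time = times, replicate = seq_len(replicates)
  )
  grid %>%
    dplyr::mutate(
      area = values,
      condition = condition,
      qc_pass = qc_pass,
      sample_id = sprintf("%s_%s_t%g_r%d", condition, stage, time, replicate)
    )
}

# Correlation + prediction tables encoding given per-class concordance
# counts: each row of `spec_tbl` has taxon_id, exo_class, n, n_concordant.
concordance_fixture <- function(spec_tbl) {
  rows <- purrr::pmap_dfr(spec_tbl, function(taxon_id, exo_class, n, n_concordant) {
    expected <- if (exo_class == "released") 1L else -1L
    rho_conc <- if (expected == 1L) 0.6 else -0.6
    tibble::tibble(
      taxon_id = taxon_id,
      metabolite_id = sprintf("%s_%s_%02d", taxon_id, exo_class, seq_len(n)),
      exo_class = exo_class,
      expected_sign = expected,
      rho = c(rep(rho_conc, n_concordant), rep(-rho_conc, n - n_concordant))
    )
  })
  list(
    correlations = rows %>%
      dplyr::mutate(p = 0.02, q = 0.04, n_pairs = 100L, status = "ok",
                    highly_correlated = TRUE) %>%
      dplyr::select("taxon_id", "metabolite_id", "rho", "p", "q", "n_pairs",
                    "status", "highly_correlated"),
    predictions = rows %>%
      dplyr::select("taxon_id", "metabolite_id", "exo_class", "expected_sign")
  )
}

# Random DNA sequence helper.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One null-calibration run: flat pools + noise, random sign predictions,
# returns the exact binomial p-value for the concordance of 44 pairs.
null_concordance_p <- function(seed) {
  scen <- null_wetup_scenario(seed = seed)
  scen$euler_dt <- 5 # pools are constant; coarse integration is exact
  pools <- simulate_metabolites(scen)
  peaks <- observe_peak_areas(pools, scen, condition = "active")
  abund <- relative_abundance(simulate_marker_reads(simulate_abundance(scen), scen)) %>%
    dplyr::filter(taxon_id != "background") %>%
    dplyr::select(taxon_id, stage, time, rel_abundance)
  cors <- correlate_pairs(abund, peaks)
  set.seed(metaboweb:::substream_seed(seed, "null_predictions"))
  preds <- tidyr::expand_grid(
    taxon_id = unique(abund$taxon_id),
    metabolite_id = unique(peaks$metabolite_id)
  ) %>%
    dplyr::mutate(
      expected_sign = sample(c(-1L, 1L), dplyr::n(), replace = TRUE),
      exo_class = ifelse(expected_sign > 0, "released", "consumed")
    )
  suppressMessages(evaluate_concordance(cors, preds)$p_binomial)
}
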