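# Synthetic wet-up generator: abundance curves, pool mass balance,
# observation model, marker reads and isolate profiles.

test_that("abundance curves honour flat, early and responder-ordering contracts", {
  scen <- default_wetup_scenario(seed = 1)
  ab <- simulate_abundance(scen)

  # flat taxon: constant at baseline everywhere
  flat <- ab %>% dplyr::filter(taxon_id == "t_flat_generalist")
  expect_true(all(flat$abundance == 1.5))

  # early responder peaking at the first sampled time dominates its own tail
  early <- ab %>% dplyr::filter(taxon_id == "t_early_phototroph", stage == "B")
  expect_gte(early$abundance[early$time == 0.05],
             early$abundance[early$time == 49.5])

  # argmax times ordered early < mid < late (evaluating the closed form on
  # the sampled grid)
  argmax_t <- ab %>%
    dplyr::filter(stage == "C") %>%
    dplyr::group_by(taxon_id) %>%
    dplyr::summarise(t_peak = time[which.max(abundance)], .groups = "drop")
  t_of <- function(id) argmax_t$t_peak[argmax_t$taxon_id == id]
  expect_lt(t_of("t_early_phototroph"), t_of("t_mid_copiotroph"))
  expect_lt(t_of("t_mid_copiotroph"), t_of("t_late_sporeformer"))

  # abundance undefined at non-positive times
  bad <- default_wetup_scenario()
  bad$time_points <- c(-1, 2)
  expect_error(simulate_abundance(bad), "positive")
})

test_that("pool integration obeys mass non-negativity, no-dynamics and killed dominance", {
  scen <- tiny_scenario()
  pools <- simulate_metabolites(scen)
  expect_true(all(pools$pool >= 0))

  # all rates zero: pool constant, active identical to killed
  inert <- wetup_scenario(
    taxa = scen$taxa,
    metabolites = metabolite_spec("m0", initial_pool = 10),
    seed = 1
  )
  pa <- simulate_metabolites(inert, killed = FALSE)
  pk <- simulate_metabolites(inert, killed = TRUE)
  expect_true(all(pa$pool == 10))
  expect_identical(pa, pk)

  # consumption-only metabolite: killed pool >= active pool at all samples
  act <- simulate_metabolites(scen, killed = FALSE) %>%
    dplyr::filter(metabolite_id == "met_consumed")
  kil <- simulate_metabolites(scen, killed = TRUE) %>%
    dplyr::filter(metabolite_id == "met_consumed")
  expect_true(all(kil$pool >= act$pool - 1e-12))

  expect_error(simulate_metabolites(scen, dt = -0.1), "positive")
})

test_that("Euler integration matches a 50x-finer-step oracle within 1%", {
  # one consumer at constant abundance: compare the terminal pool to an
  # independent fine-step integration
  taxa <- taxon_spec("tx_const", "flat", peak_time = 1, peak_width = 1,
                     baseline = 2, amplitude = 0)
  met <- metabolite_spec("m_c", initial_pool = 30,
                         uptake_rate = c(tx_const = 0.5), half_saturation = 5)
  scen <- wetup_scenario(taxa = taxa, metabolites = met, stages = "A", seed = 1)
  got <- simulate_metabolites(scen) %>% dplyr::filter(time == 49.5)
  want <- ode_uptake_oracle(M0 = 30, u = 0.5, B = 2, K = 5, t_end = 49.5,
                            dt = 0.001)
  expect_equal(got$pool, want, tolerance = 0.01)

  # default scenario: full pool table at default step vs 50x finer step
  scen2 <- tiny_scenario(stages = "A")
  coarse <- simulate_metabolites(scen2)
  fine <- simulate_metabolites(scen2, dt = scen2$euler_dt / 50)
  rel <- abs(coarse$pool - fine$pool) / pmax(fine$pool, 1e-6)
  expect_lt(max(rel[fine$pool > 0.1]), 0.01)
})

test_that("peak-area observation applies gain, noise, detection limit and is seeded", {
  scen <- tiny_scenario(noise_sigma = 0)
  pools <- simulate_metabolites(scen)

  # noise off, gain 1: areas equal pools exactly (above the detection limit)
  obs <- observe_peak_areas(pools, scen, condition = "active")
  joined <- obs %>% dplyr::left_join(pools, by = c("metabolite_id", "stage", "time"))
  above <- !is.na(joined$area)
  expect_equal(joined$area[above], joined$pool[above])
  expect_true(all(is.na(joined$area) | joined$area >= scen$detection_limit))

  # detection limit above everything: all entries missing
  scen_hi <- tiny_scenario(noise_sigma = 0, detection_limit = 1e9)
  obs_hi <- observe_peak_areas(pools, scen_hi)
  expect_true(all(is.na(obs_hi$area)))

  # same seed, same table; different substream for killed condition
  scen_n <- tiny_scenario(noise_sigma = 0.3)
  o1 <- observe_peak_areas(pools, scen_n)
  o2 <- observe_peak_areas(pools, scen_n)
  expect_identical(o1, o2)

  # metadata populated
  expect_setequal(unique(obs$stage), scen$stages)
  expect_setequal(unique(obs$replicate), seq_len(scen$replicates_active))
  expect_true(all(obs$condition == "active"))
})

test_that("marker reads are multinomial draws over abundances plus background", {
  scen <- default_wetup_scenario(seed = 3)
  ab <- simulate_abundance(scen)
  reads <- simulate_marker_reads(ab, scen)

  # closure: counts per sample sum to read_depth
  sums <- reads %>%
    dplyr::group_by(sample_id) %>%
    dplyr::summarise(n = sum(count), .groups = "drop")
  expect_true(all(sums$n == scen$read_depth))
  expect_true("background" %in% reads$taxon_id)

  # a taxon with all the mass gets all the reads
  solo <- wetup_scenario(
    taxa = taxon_spec("only", "flat", peak_time = 1, peak_width = 1,
                      baseline = 5, amplitude = 0),
    metabolites = metabolite_spec("m", 1),
    background_abundance = 0, seed = 1
  )
  r_solo <- simulate_marker_reads(simulate_abundance(solo), solo)
  expect_true(all(r_solo$count[r_solo$taxon_id == "only"] == solo$read_depth))

  # depth 1e5 and fixed probabilities: empirical proportions within 3 SD
  p <- c(0.1, 0.3, 0.6)
  taxa3 <- dplyr::bind_rows(
    taxon_spec("a", "flat", 1, 1, baseline = p[1], amplitude = 0),
    taxon_spec("b", "flat", 1, 1, baseline = p[2], amplitude = 0),
    taxon_spec("c", "flat", 1, 1, baseline = p[3], amplitude = 0)
  )
  scen3 <- wetup_scenario(taxa = taxa3, metabolites = metabolite_spec("m", 1),
                          stages = "A", time_points = 1,
                          background_abundance = 0, read_depth = 1e5, seed = 7)
  r3 <- simulate_marker_reads(simulate_abundance(scen3), scen3) %>%
    dplyr::filter(taxon_id != "background")
  prop <- r3$count / 1e5
  se <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(prop - p) <= 3 * se))

  # all-zero abundance vector is an error
  zero <- simulate_abundance(scen3) %>% dplyr::mutate(abundance = 0)
  expect_error(simulate_marker_reads(zero, scen3), "all-zero")
})

test_that("exoprofile fold-changes follow the closed form and markers mutate as configured", {
  scen <- tiny_scenario()
  exo <- simulate_exoprofiles(scen, culture_biomass = 3, culture_time = 48,
                              noise = FALSE)
  pr <- exo$profiles

  # no interaction: fold-change exactly 1
  inert <- pr %>% dplyr::filter(metabolite_id == "met_inert")
  expect_true(all(inert$fold_change_true == 1))

  # closed form by hand: consumer u = 0.7 -> exp(-0.7 * 3 * 48);
  # releaser r = 0.3 on pool 10 -> 1 + 0.3 * 144 / 10
  cons <- pr %>% dplyr::filter(taxon_id == "tx_late",
                               metabolite_id == "met_consumed")
  expect_equal(cons$fold_change_true, exp(-0.7 * 144))
  rel <- pr %>% dplyr::filter(taxon_id == "tx_late",
                              metabolite_id == "met_released")
  expect_equal(rel$fold_change_true, 1 + 0.3 * 144 / 10)

  # noiseless observed means reproduce the true fold-change
  expect_equal(pr$mean_area_inoculated / pr$mean_area_control,
               pr$fold_change_true)

  # ground-truth class equals the classifier applied to the fold-change
  expect_identical(pr$class_true, classify_fold_change(pr$fold_change_true))

  # divergence 0: isolate marker identical to its environmental source
  exo0 <- simulate_exoprofiles(scen, divergence = 0)
  expect_identical(as.character(exo0$isolate_markers[["iso_tx_late"]]),
                   as.character(exo0$env_markers[["tx_late"]]))

  # released metabolite with zero pool is an error
  bad <- wetup_scenario(
    taxa = scen$taxa,
    metabolites = metabolite_spec("m_bad", initial_pool = 0,
                                  release_rate = c(tx_late = 1)),
    seed = 1
  )
  expect_error(simulate_exoprofiles(bad), "zero initial pool")
})

test_that("the generator is deterministic given scenario and seed", {
  d1 <- simulate_wetup(default_wetup_scenario(seed = 9))
  d2 <- simulate_wetup(default_wetup_scenario(seed = 9))
  expect_identical(d1$peak_areas, d2$peak_areas)
  expect_identical(d1$marker_reads, d2$marker_reads)
  expect_identical(d1$exo$profiles, d2$exo$profiles)
  expect_identical(as.character(d1$exo$isolate_markers),
                   as.character(d2$exo$isolate_markers))
  # areas are non-negative wherever observed
  expect_true(all(is.na(d1$peak_areas$area) | d1$peak_areas$area >= 0))
})
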