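# End-to-end orchestration: simulate (or ingest) -> QC/filter -> classify ->
# match -> correlate -> concordance -> foodweb, with artifact writing and a
# provenance record.

#' Run the full microbe-metabolite concordance pipeline
#'
#' Executes the analysis end-to-end on a synthetic scenario or a
#' pre-simulated / ingested dataset: sample QC, the two-fold dynamic-range
#' filter, the killed-control significance test, spent-media fold-change
#' classification, isolate-to-environment marker matching, relative
#' abundance derivation, Spearman correlation of every predicted pair,
#' concordance scoring with the exact binomial directionality test, and
#' foodweb edge construction. All filtering decisions are logged as
#' messages; when `out_dir` is given every intermediate table is written as
#' tab-separated text, the foodweb additionally as GraphML, the summary as
#' key = value text, and a provenance record (config echo, package version,
#' seed) as YAML.
#'
#' @param data A `"wetup_dataset"` from [simulate_wetup()], or a
#'   `"wetup_scenario"` (simulated on the fly), or a list with elements
#'   `peak_areas`, `marker_reads`, `spent_media` (or `exo`), and marker
#'   sequence sets.
#' @param out_dir Optional output directory (created if needed).
#' @param alpha Killed-control significance level.
#' @param fdr FDR level for starred foodweb edges.
#' @param rho_threshold `|rho|` cutoff for the `highly_correlated` flag.
#' @param fc_consumed,fc_released Fold-change classification thresholds.
#' @param fold_threshold Dynamic-range retention threshold.
#' @param per_stage Compute per-stage correlations as well (reported, not
#'   used for concordance).
#' @param apply_fold_filter Restrict predictions to metabolites retained by
#'   the dynamic-range filter.
#' @return List with class `"wetup_run"`: all intermediate tables, the
#'   `"exo_concordance"` object, the foodweb edges and the config.
#' @export
run_pipeline <- function(data = default_wetup_scenario(), out_dir = NULL,
                         alpha = 0.05, fdr = 0.05, rho_threshold = 0.5,
                         fc_consumed = 0.5, fc_released = 2,
                         fold_threshold = 2, per_stage = FALSE,
                         apply_fold_filter = TRUE) {
  stopifnot(alpha > 0, fdr > 0, rho_threshold > 0, fold_threshold > 0,
            fc_consumed > 0, fc_released > fc_consumed)
  if (inherits(data, "wetup_scenario")) data <- simulate_wetup(data)
  if (!all(c("peak_areas", "marker_reads") %in% names(data))) {
    abort("data must provide `peak_areas` and `marker_reads`")
  }
  peaks <- qc_filter(data$peak_areas)

  fold_status <- fold_range_filter(peaks, threshold = fold_threshold)
  message(sprintf("fold_range_filter: %d of %d metabolites retained",
                  sum(fold_status$retained), nrow(fold_status)))
  verdicts <- killed_control_test(peaks, alpha = alpha)
  message(sprintf("killed_control_test: %d of %d metabolites biologically controlled",
                  sum(verdicts$biologically_controlled, na.rm = TRUE),
                  nrow(verdicts)))

  # spent-media side
  spent <- if (!is.null(data$spent_media)) data$spent_media
           else data$exo$profiles
  profiles <- classify_exoprofiles(spent, consumed_max = fc_consumed,
                                   released_min = fc_released)

  # marker matching
  iso_seqs <- if (!is.null(data$isolate_markers)) data$isolate_markers
              else data$exo$isolate_markers
  env_seqs <- if (!is.null(data$env_markers)) data$env_markers
              else data$exo$env_markers
  matches <- match_isolates(iso_seqs, env_seqs)
  best <- matches %>% dplyr::filter(.data$is_best)

  # community side
  abund <- relative_abundance(data$marker_reads) %>%
    dplyr::select("taxon_id", "stage", "time", "rel_abundance")

  shared <- intersect(unique(peaks$metabolite_id),
                      unique(profiles$metabolite_id))
  if (length(shared) == 0L) {
    abort(paste0(
      "no overlapping metabolites between the peak-area table and the ",
      "exometabolite profiles; peak table has: ",
      paste(head(unique(peaks$metabolite_id), 5), collapse = ", "), " ...; ",
      "profiles have: ",
      paste(head(unique(profiles$metabolite_id), 5), collapse = ", "), " ..."
    ))
  }

  predictions <- predict_signs(profiles, best) %>%
    restrict_predictions(verdicts,
                         fold_status = if (apply_fold_filter) fold_status else NULL)
  message(sprintf("predictions: %d signed pairs to evaluate", nrow(predictions)))

  correlations <- correlate_pairs(
    abund, peaks,
    pairs = predictions %>% dplyr::distinct(.data$taxon_id, .data$metabolite_id),
    rho_threshold = rho_threshold
  )
  correlations_stage <- if (per_stage) {
    correlate_pairs(abund, peaks,
                    pairs = predictions %>%
                      dplyr::distinct(.data$taxon_id, .data$metabolite_id),
                    rho_threshold = rho_threshold, per_stage = TRUE)
  } else NULL

  concordance <- evaluate_concordance(correlations, predictions)
  edges <- build_foodweb(concordance, fdr = fdr)

  run <- structure(
    list(
      peak_areas = peaks,
      fold_status = fold_status,
      verdicts = verdicts,
      profiles = profiles,
      matches = matches,
      abundances = abund,
      predictions = predictions,
      correlations = correlations,
      correlations_per_stage = correlations_stage,
      concordance = concordance,
      foodweb = edges,
      config = list(alpha = alpha, fdr = fdr, rho_threshold = rho_threshold,
                    fc_consumed = fc_consumed, fc_released = fc_released,
                    fold_threshold = fold_threshold, per_stage = per_stage,
                    apply_fold_filter = apply_fold_filter,
                    seed = if (!is.null(data$scenario)) data$scenario$seed else NA),
      scenario = data$scenario,
      truth = data$truth
    ),
    class = "wetup_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.wetup_run <- function(x, ...) {
  cat("<wetup_run>\n")
  print(x$concordance)
  invisible(x)
}

#' Write a pipeline run's artifacts to disk
#'
#' @param run A `"wetup_run"`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "wetup_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) readr::write_tsv(x, file.path(out_dir, name), na = "")
  tsv(run$fold_status, "fold_range_filter.tsv")
  tsv(run$verdicts, "killed_control_verdicts.tsv")
  tk <- attr(run$verdicts, "tukey")
  if (!is.null(tk) && nrow(tk) > 0L) tsv(tk, "killed_control_tukey.tsv")
  tsv(run$profiles, "exo_profiles.tsv")
  tsv(run$matches, "marker_matches.tsv")
  tsv(run$predictions, "predictions.tsv")
  tsv(run$correlations, "correlations.tsv")
  if (!is.null(run$correlations_per_stage)) {
    tsv(run$correlations_per_stage, "correlations_per_stage.tsv")
  }
  tsv(tidy(run$concordance), "concordance_pairs.tsv")
  tsv(run$foodweb, "foodweb_edges.tsv")
  write_foodweb_graphml(run$foodweb, file.path(out_dir, "foodweb.graphml"))
  g <- glance(run$concordance)
  summary_lines <- paste0(names(g), " = ",
                          vapply(g, function(v) format(v, digits = 10),
                                 character(1)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  prov <- run$config
  prov$package_version <- as.character(packageVersion("metaboweb"))
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}

#' Score ground-truth sign recovery of a synthetic run
#'
#' Among scenario pairs with a non-zero ground-truth sign, a pair is
#' recovered when the pipeline emitted a prediction for it, the
#' correlation was evaluable, and the observed sign matches the truth.
#'
#' @param run A `"wetup_run"` produced from a synthetic dataset (must carry
#'   `truth`).
#' @return One-row tibble `n_truth`, `n_recovered`, `recovery`.
#' @export
score_recovery <- function(run) {
  stopifnot(inherits(run, "wetup_run"))
  if (is.null(run$truth)) abort("run has no ground truth (not synthetic?)")
  truth <- run$truth$expected_sign %>% dplyr::filter(.data$expected_sign != 0L)
  pairs <- tidy(run$concordance) %>%
    dplyr::select("taxon_id", "metabolite_id", "observed_sign", "evaluable")
  scored <- truth %>%
    dplyr::left_join(pairs, by = c("taxon_id", "metabolite_id")) %>%
    dplyr::mutate(recovered = !is.na(.data$evaluable) & .data$evaluable &
                    .data$observed_sign == .data$expected_sign)
  tibble::tibble(
    n_truth = nrow(scored),
    n_recovered = sum(scored$recovered),
    recovery = sum(scored$recovered) / nrow(scored)
  )
}
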