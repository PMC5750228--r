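# Tab-separated table and FASTA readers/writers and scenario config files.
# Tables are UTF-8, tab-separated, '.' decimal, empty cell = missing.

#' Read a peak-area table with its sample metadata sidecar
#'
#' The area table has metabolites as rows (first column `metabolite_id`)
#' and samples as columns; the sidecar is keyed by `sample_id` and carries
#' `time`, `stage`, `replicate`, `condition` and `qc_pass`.
#'
#' @param areas_path Path to the tab-separated area table.
#' @param samples_path Path to the tab-separated sample metadata.
#' @return Long peak-area tibble (the package's standard shape).
#' @export
read_peak_areas <- function(areas_path, samples_path) {
  for (p in c(areas_path, samples_path)) {
    if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  areas <- readr::read_tsv(areas_path, show_col_types = FALSE)
  meta <- readr::read_tsv(samples_path, show_col_types = FALSE)
  assert_columns(areas, "metabolite_id", "areas table")
  assert_columns(meta, c("sample_id", "time", "stage", "replicate",
                         "condition", "qc_pass"), "sample metadata")
  long <- areas %>%
    tidyr::pivot_longer(-"metabolite_id", names_to = "sample_id",
                        values_to = "area")
  unknown <- setdiff(unique(long$sample_id), meta$sample_id)
  if (length(unknown) > 0L) {
    abort(sprintf("samples without metadata: %s", paste(unknown, collapse = ", ")))
  }
  long %>%
    dplyr::inner_join(meta, by = "sample_id") %>%
    dplyr::select("metabolite_id", "sample_id", "stage", "time", "replicate",
                  "condition", "qc_pass", "area")
}

#' Write a long peak-area tibble as a wide table plus metadata sidecar
#'
#' @param peak_tbl Long peak-area tibble.
#' @param areas_path,samples_path Output paths.
#' @return `areas_path`, invisibly.
#' @export
write_peak_areas <- function(peak_tbl, areas_path, samples_path) {
  wide <- peak_tbl %>%
    dplyr::select("metabolite_id", "sample_id", "area") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "area")
  readr::write_tsv(wide, areas_path, na = "")
  meta <- peak_tbl %>%
    dplyr::distinct(.data$sample_id, .data$time, .data$stage, .data$replicate,
                    .data$condition, .data$qc_pass)
  readr::write_tsv(meta, samples_path, na = "")
  invisible(areas_path)
}

#' Read a spent-media exometabolomics table
#'
#' @param path Tab-separated file with columns `isolate_id`,
#'   `metabolite_id`, `mean_area_inoculated`, `mean_area_control`.
#' @return Tibble.
#' @export
read_spent_media <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(out, c("isolate_id", "metabolite_id", "mean_area_inoculated",
                        "mean_area_control"), "spent-media table")
  out
}

#' Read marker sequences from FASTA
#'
#' @param path FASTA file (IUPAC nucleotides).
#' @return Named character vector of sequences.
#' @export
read_marker_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Write marker sequences to FASTA (80-column wrap)
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

# ---- scenario config files -------------------------------------------------

#' Write a scenario to a YAML config file
#'
#' @param scenario A [wetup_scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  validate_scenario(scenario)
  taxa <- purrr::pmap(scenario$taxa, function(taxon_id, responder_class,
                                              peak_time, peak_width, baseline,
                                              amplitude, succession_scale) {
    list(taxon_id = taxon_id, responder_class = responder_class,
         peak_time = peak_time, peak_width = peak_width, baseline = baseline,
         amplitude = amplitude, succession_scale = as.list(succession_scale))
  })
  mets <- purrr::pmap(scenario$metabolites, function(metabolite_id, initial_pool,
                                                     leach_rate, leach_decay,
                                                     half_saturation,
                                                     release_rate, uptake_rate) {
    list(metabolite_id = metabolite_id, initial_pool = initial_pool,
         leach_rate = leach_rate, leach_decay = leach_decay,
         half_saturation = half_saturation,
         release_rate = as.list(release_rate),
         uptake_rate = as.list(uptake_rate))
  })
  cfg <- list(
    stages = scenario$stages, time_points = scenario$time_points,
    replicates_active = scenario$replicates_active,
    replicates_killed = scenario$replicates_killed,
    noise_sigma = scenario$noise_sigma,
    detection_limit = scenario$detection_limit, gain = scenario$gain,
    read_depth = scenario$read_depth,
    background_abundance = scenario$background_abundance,
    euler_dt = scenario$euler_dt, seed = scenario$seed,
    taxa = taxa, metabolites = mets
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a scenario from a YAML config file
#'
#' @param path Path written by [write_scenario()] (or hand-authored with
#'   the same keys).
#' @return A [wetup_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  taxa <- purrr::map_dfr(cfg$taxa, function(tx) {
    taxon_spec(tx$taxon_id, tx$responder_class, tx$peak_time, tx$peak_width,
               tx$baseline, tx$amplitude,
               succession_scale = unlist(tx$succession_scale))
  })
  mets <- purrr::map_dfr(cfg$metabolites, function(m) {
    metabolite_spec(m$metabolite_id, m$initial_pool,
                    leach_rate = m$leach_rate %||% 0,
                    leach_decay = m$leach_decay %||% 3,
                    half_saturation = m$half_saturation %||% 5,
                    release_rate = unlist(m$release_rate) %||% numeric(),
                    uptake_rate = unlist(m$uptake_rate) %||% numeric())
  })
  wetup_scenario(
    taxa = taxa, metabolites = mets,
    stages = cfg$stages, time_points = cfg$time_points,
    replicates_active = cfg$replicates_active,
    replicates_killed = cfg$replicates_killed,
    noise_sigma = cfg$noise_sigma, detection_limit = cfg$detection_limit,
    gain = cfg$gain, read_depth = cfg$read_depth,
    background_abundance = cfg$background_abundance,
    euler_dt = cfg$euler_dt, seed = cfg$seed
  )
}
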