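# Isolate spent-media fold-change classification and sign predictions.

#' Classify fold-changes into consumed / released / unchanged
#'
#' Applies the spent-media thresholds inclusively: a metabolite is
#' `consumed` when the fold-change is 0.5 or less, `released` when it is 2
#' or greater, and `unchanged` otherwise. The thresholds are symmetric on
#' the log scale.
#'
#' @param fold_change Numeric vector of ratios (>= 0; `NA` passes through).
#' @param consumed_max,released_min Classification thresholds.
#' @return Character vector in `c("consumed", "released", "unchanged")`.
#' @export
classify_fold_change <- function(fold_change, consumed_max = 0.5, released_min = 2) {
  if (any(fold_change < 0, na.rm = TRUE)) abort("fold-change must be >= 0")
  stopifnot(consumed_max > 0, released_min > consumed_max)
  dplyr::case_when(
    is.na(fold_change) ~ NA_character_,
    fold_change <= consumed_max ~ "consumed",
    fold_change >= released_min ~ "released",
    TRUE ~ "unchanged"
  )
}

#' Build exometabolite profiles from spent-media means
#'
#' Computes, per (isolate, metabolite), the fold-change of the mean peak
#' area in inoculated spent medium over the uninoculated control medium
#' (raw means, not log), classifies it, and attaches the expected in-situ
#' correlation sign (-1 consumed, +1 released, 0 unchanged). Records with a
#' missing inoculated mean are skipped with a log message; metabolites
#' undetected in the control medium are unclassifiable, so a non-positive
#' control mean is an error.
#'
#' @param spent_media Tibble with columns `isolate_id`, `metabolite_id`,
#'   `mean_area_inoculated`, `mean_area_control`.
#' @param consumed_max,released_min Thresholds passed to
#'   [classify_fold_change()].
#' @return Tibble adding `fold_change`, `exo_class`, `expected_sign`.
#' @export
classify_exoprofiles <- function(spent_media, consumed_max = 0.5, released_min = 2) {
  assert_columns(spent_media, c("isolate_id", "metabolite_id",
                                "mean_area_inoculated", "mean_area_control"))
  if (any(is.na(spent_media$mean_area_control) | spent_media$mean_area_control <= 0)) {
    abort("control spent-media means must be strictly positive")
  }
  skipped <- is.na(spent_media$mean_area_inoculated)
  if (any(skipped)) {
    message(sprintf("classify_exoprofiles: skipping %d record(s) with missing inoculated mean",
                    sum(skipped)))
  }
  spent_media %>%
    dplyr::filter(!is.na(.data$mean_area_inoculated)) %>%
    dplyr::mutate(
      fold_change = .data$mean_area_inoculated / .data$mean_area_control,
      exo_class = classify_fold_change(.data$fold_change, consumed_max, released_min),
      expected_sign = dplyr::case_when(
        .data$exo_class == "consumed" ~ -1L,
        .data$exo_class == "released" ~ 1L,
        TRUE ~ 0L
      )
    )
}

#' Predict in-situ correlation signs from isolate profiles
#'
#' Translates classified exometabolite profiles into testable predictions:
#' a taxon should correlate negatively with metabolites its matched isolate
#' consumes and positively with metabolites it releases. Unchanged pairs
#' yield no prediction; isolates without a matched environmental taxon are
#' skipped with a log message.
#'
#' @param profiles Output of [classify_exoprofiles()].
#' @param matches Tibble mapping `isolate_id` to `taxon_id` (e.g. the
#'   `is_best` rows of [match_isolates()]).
#' @return Tibble `taxon_id`, `metabolite_id`, `isolate_id`, `exo_class`,
#'   `expected_sign` with non-zero signs only.
#' @export
predict_signs <- function(profiles, matches) {
  assert_columns(profiles, c("isolate_id", "metabolite_id", "exo_class",
                             "expected_sign"))
  assert_columns(matches, c("isolate_id", "taxon_id"))
  unmatched <- setdiff(unique(profiles$isolate_id), matches$isolate_id)
  if (length(unmatched) > 0L) {
    message(sprintf("predict_signs: no environmental match for isolate(s): %s",
                    paste(unmatched, collapse = ", ")))
  }
  profiles %>%
    dplyr::inner_join(
      matches %>% dplyr::select("isolate_id", env_taxon_id = "taxon_id"),
      by = "isolate_id"
    ) %>%
    dplyr::filter(.data$expected_sign != 0L) %>%
    dplyr::transmute(
      taxon_id = .data$env_taxon_id,
      metabolite_id = .data$metabolite_id,
      isolate_id = .data$isolate_id,
      exo_class = .data$exo_class,
      expected_sign = .data$expected_sign
    )
}
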