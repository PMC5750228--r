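# Pathway-level aggregation of gene-expression fold-changes (relative to
# dry biocrust) and the anabolic-vs-catabolic contrast.

#' Summarize gene fold-changes per pathway
#'
#' Computes, per pathway and time point, the arithmetic mean and standard
#' error (sample SD / sqrt(n)) of the member genes' expression fold-changes
#' relative to the dry state. Genes annotated to several pathways
#' contribute to each. Singleton pathways get SEM 0 with a flag.
#'
#' @param records Tibble with columns `gene_id`, `pathway_ids`
#'   (semicolon-delimited string or list-column), `time`, `fold_change`
#'   (> 0).
#' @param pathways Optional character vector restricting (and checking) the
#'   pathways; an entry with no member genes is an error.
#' @param log_scale If `TRUE`, mean and SEM are computed on log2
#'   fold-changes.
#' @return Tibble `pathway_id`, `time`, `mean_fc`, `sem_fc`, `n_genes`,
#'   `singleton`.
#' @export
summarize_pathways <- function(records, pathways = NULL, log_scale = FALSE) {
  assert_columns(records, c("gene_id", "pathway_ids", "time", "fold_change"))
  if (any(is.na(records$fold_change) | records$fold_change <= 0)) {
    abort("fold-changes must be positive")
  }
  long <- records %>%
    dplyr::mutate(pathway_id = if (is.list(.data$pathway_ids)) .data$pathway_ids
                  else strsplit(as.character(.data$pathway_ids), ";\\s*")) %>%
    tidyr::unnest_longer("pathway_id") %>%
    dplyr::filter(nzchar(.data$pathway_id))
  if (!is.null(pathways)) {
    missing <- setdiff(pathways, unique(long$pathway_id))
    if (length(missing) > 0L) {
      abort(sprintf("pathway(s) with no member genes: %s",
                    paste(missing, collapse = ", ")))
    }
    long <- long %>% dplyr::filter(.data$pathway_id %in% pathways)
  }
  val <- if (log_scale) log2(long$fold_change) else long$fold_change
  long$.val <- val
  long %>%
    dplyr::group_by(.data$pathway_id, .data$time) %>%
    dplyr::summarise(
      mean_fc = mean(.data$.val),
      sem_fc = if (dplyr::n() > 1L) sd(.data$.val) / sqrt(dplyr::n()) else 0,
      n_genes = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(singleton = .data$n_genes == 1L) %>%
    dplyr::arrange(.data$pathway_id, .data$time)
}

#' Contrast anabolic against catabolic pathway responses
#'
#' For each (anabolic, catabolic) pathway pair, computes at every shared
#' time point the ratio of mean fold-changes and flags time points where
#' the anabolic response exceeds the catabolic one - the biosynthesis-over-
#' degradation pattern expected when a producer is actively releasing the
#' pathway's end products.
#'
#' @param summaries Output of [summarize_pathways()].
#' @param pairing Tibble with columns `anabolic`, `catabolic` (pathway ids).
#' @return Tibble `anabolic`, `catabolic`, `time`, `ratio`,
#'   `anabolic_dominant`.
#' @export
anabolic_catabolic_contrast <- function(summaries, pairing) {
  assert_columns(summaries, c("pathway_id", "time", "mean_fc"))
  assert_columns(pairing, c("anabolic", "catabolic"))
  missing <- setdiff(c(pairing$anabolic, pairing$catabolic),
                     unique(summaries$pathway_id))
  if (length(missing) > 0L) {
    abort(sprintf("pathway(s) not summarized: %s", paste(missing, collapse = ", ")))
  }
  purrr::pmap_dfr(pairing, function(anabolic, catabolic) {
    a <- summaries %>% dplyr::filter(.data$pathway_id == anabolic)
    c_ <- summaries %>% dplyr::filter(.data$pathway_id == catabolic)
    dplyr::inner_join(
      a %>% dplyr::select("time", mean_a = "mean_fc"),
      c_ %>% dplyr::select("time", mean_c = "mean_fc"),
      by = "time"
    ) %>%
      dplyr::transmute(
        anabolic = anabolic, catabolic = catabolic, time = .data$time,
        ratio = .data$mean_a / .data$mean_c,
        anabolic_dominant = .data$mean_a > .data$mean_c
      )
  })
}
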