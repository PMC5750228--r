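# Peak-area table QC, filtering, normalization, ordination and the
# killed-control significance model.

peak_cols <- c("metabolite_id", "sample_id", "stage", "time", "replicate",
               "condition", "qc_pass", "area")

#' Drop samples that failed QC
#'
#' Removes every sample whose `qc_pass` flag is `FALSE` (for LC/MS data:
#' internal standards absent from their retention-time window) and logs the
#' removals.
#'
#' @param peak_tbl Long peak-area tibble (see [observe_peak_areas()] for the
#'   column contract).
#' @return The filtered tibble.
#' @export
qc_filter <- function(peak_tbl) {
  assert_columns(peak_tbl, c("sample_id", "qc_pass", "area"))
  if (nrow(peak_tbl) == 0L) abort("empty peak-area table")
  dropped <- peak_tbl %>%
    dplyr::filter(!.data$qc_pass) %>%
    dplyr::distinct(.data$sample_id)
  if (nrow(dropped) > 0L) {
    message(sprintf("qc_filter: removing %d sample(s): %s", nrow(dropped),
                    paste(dropped$sample_id, collapse = ", ")))
  }
  out <- peak_tbl %>% dplyr::filter(.data$qc_pass)
  if (nrow(out) == 0L) abort("qc_filter removed every sample")
  out
}

# per-metabolite per-(stage, time) replicate means over active samples;
# missing areas are ignored, all-missing cells yield NA
cell_means <- function(peak_tbl, conditions = "active") {
  assert_columns(peak_tbl, c("metabolite_id", "stage", "time", "area"))
  if (!is.null(conditions) && "condition" %in% names(peak_tbl)) {
    peak_tbl <- peak_tbl %>% dplyr::filter(.data$condition %in% !!conditions)
  }
  peak_tbl %>%
    dplyr::group_by(.data$metabolite_id, .data$stage, .data$time) %>%
    dplyr::summarise(
      mean_area = if (all(is.na(.data$area))) NA_real_ else
        mean(.data$area, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Two-fold dynamic-range filter
#'
#' A metabolite is retained when the ratio of its maximum to its minimum
#' positive per-(stage, time) mean peak area reaches `threshold` (default
#' two-fold). Metabolites with fewer than two non-missing cell means cannot
#' be evaluated and are flagged and excluded.
#'
#' @param peak_tbl Long peak-area tibble.
#' @param threshold Minimum max/min ratio for retention.
#' @param condition Condition(s) whose samples define the cells.
#' @return Tibble `metabolite_id`, `fold_range`, `evaluable`, `retained`.
#' @export
fold_range_filter <- function(peak_tbl, threshold = 2, condition = "active") {
  stopifnot(threshold > 0)
  cm <- cell_means(peak_tbl, condition)
  out <- cm %>%
    dplyr::group_by(.data$metabolite_id) %>%
    dplyr::summarise(
      n_cells = sum(!is.na(.data$mean_area)),
      fold_range = {
        pos <- .data$mean_area[!is.na(.data$mean_area) & .data$mean_area > 0]
        if (length(pos) == 0L) NA_real_ else
          max(.data$mean_area, na.rm = TRUE) / min(pos)
      },
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      evaluable = .data$n_cells >= 2L & !is.na(.data$fold_range),
      retained = .data$evaluable & .data$fold_range >= threshold
    ) %>%
    dplyr::select("metabolite_id", "fold_range", "evaluable", "retained")
  n_bad <- sum(!out$evaluable)
  if (n_bad > 0L) {
    message(sprintf("fold_range_filter: %d metabolite(s) unevaluable (< 2 cells)",
                    n_bad))
  }
  out
}

#' Row-normalize metabolite profiles
#'
#' Computes per-(stage, time) mean peak areas and divides each metabolite's
#' row by its maximum, the heatmap-ready scaling: every value lies in
#' \[0, 1\] and each row attains 1.
#'
#' @param peak_tbl Long peak-area tibble.
#' @param condition Condition(s) to average over.
#' @return Tibble `metabolite_id`, `stage`, `time`, `value`.
#' @export
row_normalize <- function(peak_tbl, condition = "active") {
  cm <- cell_means(peak_tbl, condition)
  bad <- cm %>%
    dplyr::group_by(.data$metabolite_id) %>%
    dplyr::summarise(ok = any(!is.na(.data$mean_area) & .data$mean_area > 0),
                     .groups = "drop") %>%
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0L) {
    abort(sprintf("row_normalize: no positive values for: %s",
                  paste(bad$metabolite_id, collapse = ", ")))
  }
  cm %>%
    dplyr::group_by(.data$metabolite_id) %>%
    dplyr::mutate(value = .data$mean_area / max(.data$mean_area, na.rm = TRUE)) %>%
    dplyr::ungroup() %>%
    dplyr::select("metabolite_id", "stage", "time", "value")
}

#' Hierarchically cluster metabolite profiles
#'
#' Agglomerative clustering of row-normalized profiles under correlation
#' distance (1 - Pearson between profiles) with average linkage, cut into
#' `k` groups. Missing values are mean-imputed within each profile first.
#' Cluster ids are relabeled in order of first appearance so the labeling is
#' deterministic in the input row order.
#'
#' @param normalized Output of [row_normalize()] (long tibble).
#' @param k Number of clusters.
#' @return Tibble `metabolite_id`, `cluster`; the `"hclust"` attribute holds
#'   the dendrogram and `"order"` the leaf order.
#' @export
cluster_metabolites <- function(normalized, k = 3) {
  assert_columns(normalized, c("metabolite_id", "stage", "time", "value"))
  wide <- normalized %>%
    dplyr::mutate(cell = paste(.data$stage, .data$time, sep = "_")) %>%
    dplyr::select("metabolite_id", "cell", "value") %>%
    tidyr::pivot_wider(names_from = "cell", values_from = "value")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$metabolite_id
  if (k > nrow(mat)) abort("k exceeds the number of metabolites")
  # mean-imputation within each profile
  for (i in seq_len(nrow(mat))) {
    row <- mat[i, ]
    if (anyNA(row)) mat[i, is.na(row)] <- mean(row, na.rm = TRUE)
  }
  cc <- suppressWarnings(cor(t(mat)))
  cc[!is.finite(cc)] <- 0 # zero-variance profiles: maximal distance
  diag(cc) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  raw <- stats::cutree(hc, k = k)
  relabel <- match(raw, unique(raw))
  out <- tibble::tibble(metabolite_id = rownames(mat), cluster = relabel)
  attr(out, "hclust") <- hc
  attr(out, "order") <- rownames(mat)[hc$order]
  out
}

#' PCA ordination of samples on their metabolite profiles
#'
#' Samples are ordinated on `log(1 + area)` profiles (areas span decades;
#' the log stabilizes variance), with per-metabolite mean imputation of
#' missing values, centering, and eigen-decomposition of the sample
#' covariance.
#'
#' @param peak_tbl Long peak-area tibble.
#' @param condition Condition(s) to ordinate.
#' @return Object of class `"wetup_pca"`: `scores` (tibble of sample
#'   metadata plus PC columns) and `explained_variance` (fractions, sorted
#'   non-increasing).
#' @export
pca_ordinate <- function(peak_tbl, condition = "active") {
  assert_columns(peak_tbl, peak_cols)
  sub <- peak_tbl %>% dplyr::filter(.data$condition %in% !!condition)
  wide <- sub %>%
    dplyr::select("sample_id", "metabolite_id", "area") %>%
    tidyr::pivot_wider(names_from = "metabolite_id", values_from = "area")
  mat <- log1p(as.matrix(wide[, -1, drop = FALSE]))
  rownames(mat) <- wide$sample_id
  if (nrow(mat) < 2L) abort("PCA needs at least two samples")
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (anyNA(col)) mat[is.na(col), j] <- mean(col, na.rm = TRUE)
  }
  keep <- colSums(is.finite(mat)) == nrow(mat)
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) < 2L) abort("PCA needs at least two complete metabolite dimensions")
  fit <- prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  scores <- tibble::as_tibble(fit$x, rownames = "sample_id") %>%
    dplyr::left_join(
      sub %>% dplyr::distinct(.data$sample_id, .data$stage, .data$time,
                              .data$replicate, .data$condition),
      by = "sample_id"
    ) %>%
    dplyr::relocate("sample_id", "stage", "time", "replicate", "condition")
  structure(
    list(scores = scores, explained_variance = ev / sum(ev)),
    class = "wetup_pca"
  )
}

#' @export
print.wetup_pca <- function(x, ...) {
  cat("<wetup_pca> ", nrow(x$scores), " samples\n", sep = "")
  ev <- utils::head(x$explained_variance, 3)
  cat("  explained variance:", paste(sprintf("%.1f%%", 100 * ev), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Killed-control significance test
#'
#' For each metabolite, fits `log(1 + area) ~ condition * time` over the
#' active samples (by default only those from the stage matched to the
#' killed controls) and the killed controls, with condition categorical and
#' time continuous, and extracts F-test p-values for the condition main
#' effect and the condition x time interaction. A metabolite is
#' "biologically controlled" when it is not detected in the killed controls
#' at all, or when either p-value falls below `alpha`. A Tukey HSD across
#' the condition x time cell means is attached as a supplementary table.
#'
#' "Detected" means at least half the replicates are non-missing in at
#' least one (stage, time) cell. Missing areas are treated as missing, not
#' zero.
#'
#' @param peak_tbl Long peak-area tibble holding both conditions.
#' @param alpha Significance level.
#' @param match_stage Active stage to compare against the killed controls
#'   (the experimental pairing); set `compare_all = TRUE` to use all stages.
#' @param compare_all Compare killed controls against all active samples.
#' @return Tibble of per-metabolite verdicts (`metabolite_id`,
#'   `detected_in_killed`, `p_condition`, `p_interaction`, `evaluable`,
#'   `biologically_controlled`), with a `"tukey"` attribute.
#' @export
killed_control_test <- function(peak_tbl, alpha = 0.05, match_stage = NULL,
                                compare_all = FALSE) {
  assert_columns(peak_tbl, peak_cols)
  stopifnot(alpha > 0, alpha < 1)
  killed <- peak_tbl %>% dplyr::filter(.data$condition == "killed")
  match_stage <- match_stage %||%
    if (nrow(killed) > 0L) sort(unique(killed$stage))[length(unique(killed$stage))] else NULL
  active <- peak_tbl %>% dplyr::filter(.data$condition == "active")
  if (!compare_all && !is.null(match_stage)) {
    active <- active %>% dplyr::filter(.data$stage %in% match_stage)
  }
  if (length(unique(active$time)) < 2L) {
    abort("killed_control_test needs >= 2 active time points")
  }
  mets <- sort(unique(active$metabolite_id))
  tukey_list <- list()
  out <- purrr::map_dfr(mets, function(m) {
    act <- active %>% dplyr::filter(.data$metabolite_id == m)
    kil <- killed %>% dplyr::filter(.data$metabolite_id == m)
    detected <- detected_in(kil)
    if (!detected) {
      return(tibble::tibble(
        metabolite_id = m, detected_in_killed = FALSE,
        p_condition = NA_real_, p_interaction = NA_real_,
        evaluable = TRUE, biologically_controlled = TRUE
      ))
    }
    dat <- dplyr::bind_rows(act, kil) %>%
      dplyr::filter(!is.na(.data$area)) %>%
      dplyr::mutate(y = log1p(.data$area),
                    condition = factor(.data$condition,
                                       levels = c("active", "killed")))
    n_by_cond <- table(dat$condition)
    enough <- length(n_by_cond) == 2L && all(n_by_cond >= 2L) &&
      all(tapply(dat$time, dat$condition, function(t) length(unique(t))) >= 2L)
    if (!enough) {
      return(tibble::tibble(
        metabolite_id = m, detected_in_killed = TRUE,
        p_condition = NA_real_, p_interaction = NA_real_,
        evaluable = FALSE, biologically_controlled = NA
      ))
    }
    fit <- lm(y ~ condition * time, data = dat)
    an <- anova(fit)
    p_cond <- an["condition", "Pr(>F)"]
    p_int <- an["condition:time", "Pr(>F)"]
    cell <- interaction(dat$condition, factor(dat$time), drop = TRUE)
    if (nlevels(cell) >= 2L && all(table(cell) >= 2L)) {
      tk <- TukeyHSD(aov(dat$y ~ cell))$cell
      tukey_list[[m]] <<- tibble::as_tibble(tk, rownames = "contrast") %>%
        dplyr::mutate(metabolite_id = m, .before = 1)
    }
    tibble::tibble(
      metabolite_id = m, detected_in_killed = TRUE,
      p_condition = p_cond, p_interaction = p_int,
      evaluable = TRUE,
      biologically_controlled = min(p_cond, p_int, na.rm = TRUE) < alpha
    )
  })
  attr(out, "tukey") <- dplyr::bind_rows(tukey_list)
  attr(out, "alpha") <- alpha
  out
}

# detection rule: >= 50% of replicates non-missing in >= 1 (stage, time) cell
detected_in <- function(tbl) {
  if (nrow(tbl) == 0L) return(FALSE)
  frac <- tbl %>%
    dplyr::group_by(.data$stage, .data$time) %>%
    dplyr::summarise(f = mean(!is.na(.data$area)), .groups = "drop")
  any(frac$f >= 0.5)
}
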