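# Microbe-metabolite Spearman correlations, FDR control, the exact
# two-tailed binomial directionality test, concordance scoring and the
# foodweb edge table.

#' Spearman rank correlation with t-approximation p-value
#'
#' Drops pairs missing in either vector, assigns average ranks to ties, and
#' computes rho as the Pearson correlation of the ranks. The two-sided
#' p-value uses `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom; `|rho| = 1` is reported as p = 0. Fewer than four complete
#' pairs, or a zero-variance vector, yield a flagged unevaluable record.
#'
#' @param x,y Numeric vectors of equal length; `NA` allowed.
#' @return One-row tibble `rho`, `p`, `n_pairs`, `status` (`"ok"`,
#'   `"too_few"`, `"zero_variance"`).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 4L) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n_pairs = n,
                          status = "too_few"))
  }
  xr <- rank(x[ok], ties.method = "average")
  yr <- rank(y[ok], ties.method = "average")
  if (sd(xr) == 0 || sd(yr) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n_pairs = n,
                          status = "zero_variance"))
  }
  rho <- cor(xr, yr)
  p <- if (abs(rho) >= 1 - 1e-12) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p = p, n_pairs = n, status = "ok")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values via [stats::p.adjust()]; the result is
#' invariant to input order and bounded by 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Vector of q-values aligned with `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Exact two-tailed binomial test
#'
#' Exact tail summation of the Binomial(n, p0) pmf, no normal
#' approximation. For the symmetric null `p0 = 0.5` the two-sided p-value
#' is `min(1, 2 * min(P(X <= k), P(X >= k)))`; for general `p0` the
#' minimum-likelihood rule is used (sum of all outcome probabilities not
#' exceeding that of the observed count).
#'
#' @param k Observed successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param p0 Null success probability.
#' @return The two-sided p-value.
#' @export
exact_binom_two_tailed <- function(k, n, p0 = 0.5) {
  stopifnot(length(k) == 1L, length(n) == 1L, p0 > 0, p0 < 1)
  if (n <= 0) abort("binomial test needs n > 0 trials")
  if (k < 0 || k > n || k != round(k)) abort("k must be an integer in [0, n]")
  if (abs(p0 - 0.5) < 1e-12) {
    lower <- pbinom(k, n, p0)
    upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
    return(min(1, 2 * min(lower, upper)))
  }
  d0 <- dbinom(k, n, p0)
  dall <- dbinom(0:n, n, p0)
  min(1, sum(dall[dall <= d0 * (1 + 1e-7)]))
}

#' Correlate taxon abundances with metabolite peak areas
#'
#' For every requested (taxon, metabolite) pair, attaches the taxon's
#' relative abundance at each sample's (stage, time) cell to the sample's
#' replicate peak area (marker abundances carry no replicates - one
#' metagenome per cell) and computes the Spearman correlation pooled across
#' all stages, times and replicates. q-values are BH-adjusted over the
#' evaluated pairs, and `|rho| >= rho_threshold` sets the
#' `highly_correlated` flag.
#'
#' @param abundances Tibble `taxon_id`, `stage`, `time`, `rel_abundance`
#'   (e.g. from [relative_abundance()] joined to sample cells).
#' @param peak_tbl Long peak-area tibble (active samples are used).
#' @param pairs Optional tibble `taxon_id`, `metabolite_id` restricting the
#'   pairs; defaults to the full cross product.
#' @param rho_threshold Threshold for the `highly_correlated` flag.
#' @param per_stage If `TRUE`, compute one correlation per successional
#'   stage instead of pooling (adds a `stage` column).
#' @return Tibble of correlation records: `taxon_id`, `metabolite_id`,
#'   (`stage`,) `rho`, `p`, `q`, `n_pairs`, `status`, `highly_correlated`.
#' @export
correlate_pairs <- function(abundances, peak_tbl, pairs = NULL,
                            rho_threshold = 0.5, per_stage = FALSE) {
  assert_columns(abundances, c("taxon_id", "stage", "time", "rel_abundance"))
  assert_columns(peak_tbl, c("metabolite_id", "stage", "time", "area"))
  active <- peak_tbl %>%
    dplyr::filter(!("condition" %in% names(peak_tbl)) | .data$condition == "active")
  pairs <- pairs %||% tidyr::expand_grid(
    taxon_id = unique(abundances$taxon_id),
    metabolite_id = unique(active$metabolite_id)
  )
  assert_columns(pairs, c("taxon_id", "metabolite_id"))
  joined <- active %>%
    dplyr::inner_join(abundances, by = c("stage", "time"),
                      relationship = "many-to-many")
  group_vars <- if (per_stage) c("taxon_id", "metabolite_id", "stage")
                else c("taxon_id", "metabolite_id")
  res <- joined %>%
    dplyr::semi_join(pairs, by = c("taxon_id", "metabolite_id")) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) %>%
    dplyr::group_modify(~ spearman_cor(.x$rel_abundance, .x$area)) %>%
    dplyr::ungroup()
  res %>%
    dplyr::mutate(
      q = {
        qq <- rep(NA_real_, dplyr::n())
        ok <- .data$status == "ok"
        qq[ok] <- bh_fdr(.data$p[ok])
        qq
      },
      highly_correlated = !is.na(.data$rho) & abs(.data$rho) >= rho_threshold
    )
}

#' Restrict predictions to biologically controlled, matched metabolites
#'
#' Applies the pre-correlation exclusions: predictions are kept only for
#' metabolites whose dynamics are distinguishable from the killed controls
#' (abiotic control cannot be ruled out otherwise) and, optionally, only
#' for metabolites retained by the dynamic-range filter.
#'
#' @param predictions Output of [predict_signs()].
#' @param verdicts Output of [killed_control_test()]; `NULL` skips the
#'   filter.
#' @param fold_status Output of [fold_range_filter()]; `NULL` skips it.
#' @return The filtered prediction tibble.
#' @export
restrict_predictions <- function(predictions, verdicts = NULL, fold_status = NULL) {
  assert_columns(predictions, c("taxon_id", "metabolite_id", "expected_sign"))
  out <- predictions
  if (!is.null(verdicts)) {
    keep <- verdicts$metabolite_id[!is.na(verdicts$biologically_controlled) &
                                     verdicts$biologically_controlled]
    n0 <- nrow(out)
    out <- out %>% dplyr::filter(.data$metabolite_id %in% keep)
    if (nrow(out) < n0) {
      message(sprintf("restrict_predictions: %d prediction(s) dropped (not biologically controlled)",
                      n0 - nrow(out)))
    }
  }
  if (!is.null(fold_status)) {
    keep <- fold_status$metabolite_id[fold_status$retained]
    n0 <- nrow(out)
    out <- out %>% dplyr::filter(.data$metabolite_id %in% keep)
    if (nrow(out) < n0) {
      message(sprintf("restrict_predictions: %d prediction(s) dropped (below dynamic-range filter)",
                      n0 - nrow(out)))
    }
  }
  out
}

#' Score sign concordance between correlations and predictions
#'
#' For every prediction, the observed sign is `sign(rho)` of the matching
#' correlation record. Pairs whose correlation is unevaluable (too few
#' complete pairs, zero variance, or rho exactly 0) are excluded from the
#' evaluated count and logged - counting them as failures would bias the
#' binomial test. The proportion of concordant signs is tested against
#' chance (p0 = 0.5) with the exact two-tailed binomial test, and a
#' per-class (consumed / released) breakdown is reported.
#'
#' @param correlations Output of [correlate_pairs()].
#' @param predictions Output of [predict_signs()] (optionally passed through
#'   [restrict_predictions()]).
#' @return Object of class `"exo_concordance"`; see [tidy()] / [glance()]
#'   methods.
#' @export
evaluate_concordance <- function(correlations, predictions) {
  assert_columns(correlations, c("taxon_id", "metabolite_id", "rho", "p", "q",
                                 "status"))
  assert_columns(predictions, c("taxon_id", "metabolite_id", "exo_class",
                                "expected_sign"))
  if (nrow(predictions) == 0L) abort("empty prediction set")
  pairs <- predictions %>%
    dplyr::left_join(correlations,
                     by = c("taxon_id", "metabolite_id")) %>%
    dplyr::mutate(
      observed_sign = sign_int(.data$rho),
      evaluable = !is.na(.data$rho) & .data$status == "ok" &
        .data$observed_sign != 0L,
      concordant = .data$evaluable & .data$observed_sign == .data$expected_sign
    )
  n_dropped <- sum(!pairs$evaluable)
  if (n_dropped > 0L) {
    message(sprintf("evaluate_concordance: %d pair(s) unevaluable (missing, zero-variance or rho = 0)",
                    n_dropped))
  }
  ev <- pairs %>% dplyr::filter(.data$evaluable)
  n_eval <- nrow(ev)
  n_conc <- sum(ev$concordant)
  per_class <- ev %>%
    dplyr::group_by(.data$exo_class) %>%
    dplyr::summarise(
      n_evaluated = dplyr::n(),
      n_concordant = sum(.data$concordant),
      proportion = .data$n_concordant / .data$n_evaluated,
      .groups = "drop"
    )
  structure(
    list(
      pairs = pairs,
      n_evaluated = n_eval,
      n_concordant = n_conc,
      proportion = if (n_eval > 0) n_conc / n_eval else NA_real_,
      p_binomial = if (n_eval > 0) exact_binom_two_tailed(n_conc, n_eval, 0.5)
                   else NA_real_,
      per_class = per_class
    ),
    class = "exo_concordance"
  )
}

#' @export
print.exo_concordance <- function(x, ...) {
  cat("<exo_concordance>\n")
  cat(sprintf("  %d of %d evaluated microbe-metabolite relationships concordant (%.0f%%)\n",
              x$n_concordant, x$n_evaluated, 100 * x$proportion))
  cat(sprintf("  exact two-tailed binomial p = %.4g\n", x$p_binomial))
  for (i in seq_len(nrow(x$per_class))) {
    cat(sprintf("  %s: %d/%d (%.0f%%)\n", x$per_class$exo_class[i],
                x$per_class$n_concordant[i], x$per_class$n_evaluated[i],
                100 * x$per_class$proportion[i]))
  }
  invisible(x)
}

#' Tidy per-pair concordance records
#'
#' @param x An `"exo_concordance"` object.
#' @param ... Unused.
#' @return The per-pair tibble (prediction, correlation, observed sign,
#'   concordance flag).
#' @export
tidy.exo_concordance <- function(x, ...) x$pairs

#' One-row concordance summary
#'
#' @param x An `"exo_concordance"` object.
#' @param ... Unused.
#' @return Tibble with `n_evaluated`, `n_concordant`, `proportion`,
#'   `p_binomial` and per-class proportions.
#' @export
glance.exo_concordance <- function(x, ...) {
  base <- tibble::tibble(
    n_evaluated = x$n_evaluated,
    n_concordant = x$n_concordant,
    proportion = x$proportion,
    p_binomial = x$p_binomial
  )
  for (cl in x$per_class$exo_class) {
    row <- x$per_class[x$per_class$exo_class == cl, ]
    base[[paste0("proportion_", cl)]] <- row$proportion
  }
  base
}

#' Build the foodweb edge table
#'
#' One edge per prediction: solid edges are concordant (observed sign
#' matches the isolate-based expectation), dotted edges are discordant,
#' width is `|rho|`, and edges with FDR-adjusted q below `fdr` are starred.
#'
#' @param concordance An `"exo_concordance"` object.
#' @param fdr FDR level for the star flag.
#' @return Tibble of edges: `taxon_id`, `metabolite_id`, `predicted`,
#'   `observed_sign`, `concordant`, `style`, `weight`, `starred`.
#' @export
build_foodweb <- function(concordance, fdr = 0.05) {
  stopifnot(inherits(concordance, "exo_concordance"))
  concordance$pairs %>%
    dplyr::transmute(
      taxon_id = .data$taxon_id,
      metabolite_id = .data$metabolite_id,
      predicted = .data$exo_class,
      observed_sign = .data$observed_sign,
      concordant = .data$concordant,
      style = ifelse(.data$concordant, "solid", "dotted"),
      weight = ifelse(is.na(.data$rho), 0, abs(.data$rho)),
      starred = !is.na(.data$q) & .data$q < fdr
    )
}

#' Foodweb as an igraph object
#'
#' Bipartite graph with vertices typed `taxon` / `metabolite` and the edge
#' attributes of [build_foodweb()].
#'
#' @param edges Output of [build_foodweb()].
#' @return An [igraph::graph] object.
#' @export
foodweb_igraph <- function(edges) {
  assert_columns(edges, c("taxon_id", "metabolite_id", "predicted",
                          "concordant", "weight", "starred"))
  vertices <- dplyr::bind_rows(
    tibble::tibble(name = unique(edges$taxon_id), type = "taxon"),
    tibble::tibble(name = unique(edges$metabolite_id), type = "metabolite")
  )
  igraph::graph_from_data_frame(
    edges %>% dplyr::select(from = "taxon_id", to = "metabolite_id",
                            dplyr::everything()),
    directed = TRUE, vertices = vertices
  )
}

#' Write the foodweb to GraphML
#'
#' @param edges Output of [build_foodweb()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_foodweb_graphml <- function(edges, path) {
  g <- foodweb_igraph(edges)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
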