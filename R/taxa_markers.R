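# Marker-family selection, isolate-to-environment matching by sequence
# identity, fragment-based genome identity, and relative abundances.

#' Select the marker gene family with maximal community coverage
#'
#' Among candidate single-copy marker families (rplO, rpsC, ...), returns
#' the one with the largest total number of assembled marker genes across
#' the dataset. Ties are broken alphabetically and logged.
#'
#' @param marker_counts Tibble with columns `family` and `count` (one row
#'   per assembled gene, or per gene x sample; counts are summed).
#' @return The selected family label (character scalar).
#' @export
select_marker_family <- function(marker_counts) {
  assert_columns(marker_counts, c("family", "count"))
  if (nrow(marker_counts) == 0L) abort("empty marker catalog")
  totals <- marker_counts %>%
    dplyr::group_by(.data$family) %>%
    dplyr::summarise(total = sum(.data$count), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$total), .data$family)
  if (nrow(totals) > 1L && totals$total[1] == totals$total[2]) {
    message(sprintf("select_marker_family: tie at %s genes, choosing '%s' alphabetically",
                    totals$total[1], totals$family[1]))
  }
  totals$family[1]
}

# shared Needleman-Wunsch / Smith-Waterman front-end on Biostrings
pairwise_align <- function(a, b, type, match = 1, mismatch = -1, gap_penalty = -2) {
  if (nchar(as.character(a)) == 0L || nchar(as.character(b)) == 0L) {
    abort("cannot align an empty sequence")
  }
  stopifnot(gap_penalty < 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(as.character(a)),
    subject = Biostrings::DNAString(as.character(b)),
    type = type, substitutionMatrix = mat,
    gapOpening = 0, gapExtension = abs(gap_penalty)
  )
}

alignment_identity <- function(aln) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident <- sum(p == s & p != "-")
  list(identity = 100 * ident / length(p), columns = length(p))
}

#' Global percent identity between two marker sequences
#'
#' Needleman-Wunsch global alignment (default scoring: match +1, mismatch
#' -1, gap -2) with identity defined as identical columns divided by the
#' full alignment length (gap columns included) times 100.
#'
#' @param seq_a,seq_b Nucleotide sequences (character or
#'   [Biostrings::DNAString]).
#' @param match,mismatch,gap_penalty Alignment scoring parameters.
#' @return Percent identity in \[0, 100\].
#' @export
global_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                            gap_penalty = -2) {
  aln <- pairwise_align(seq_a, seq_b, type = "global", match = match,
                        mismatch = mismatch, gap_penalty = gap_penalty)
  alignment_identity(aln)$identity
}

#' Match one isolate marker against environmental markers
#'
#' Computes the global percent identity of the isolate's marker gene
#' against every environmental marker and flags the best hit (highest
#' identity; ties broken by taxon label, both reported). The full ranked
#' list is returned.
#'
#' @param isolate_seq The isolate's marker sequence.
#' @param env_seqs Named character vector or [Biostrings::DNAStringSet] of
#'   environmental marker sequences (names are taxon ids).
#' @param isolate_id Label for the isolate.
#' @param ... Scoring parameters for [global_identity()].
#' @return Tibble `isolate_id`, `taxon_id`, `percent_identity`, `rank`,
#'   `is_best`, sorted by decreasing identity.
#' @export
best_match <- function(isolate_seq, env_seqs, isolate_id = "isolate", ...) {
  if (length(env_seqs) == 0L) abort("need at least one environmental marker")
  env <- setNames(as.character(env_seqs), names(env_seqs))
  if (is.null(names(env)) || any(names(env) == "")) {
    abort("environmental markers must be named by taxon_id")
  }
  ids <- vapply(env, function(s) global_identity(isolate_seq, s, ...), numeric(1))
  out <- tibble::tibble(
    isolate_id = isolate_id,
    taxon_id = names(env),
    percent_identity = unname(ids)
  ) %>%
    dplyr::arrange(dplyr::desc(.data$percent_identity), .data$taxon_id) %>%
    dplyr::mutate(rank = dplyr::row_number(),
                  is_best = dplyr::row_number() == 1L)
  out
}

#' Match every isolate to its closest environmental relative
#'
#' @param isolate_seqs Named character vector or
#'   [Biostrings::DNAStringSet] of isolate marker sequences.
#' @param env_seqs Environmental markers, named by taxon id.
#' @param ... Scoring parameters for [global_identity()].
#' @return Tibble of ranked matches for all isolates (see [best_match()]).
#' @export
match_isolates <- function(isolate_seqs, env_seqs, ...) {
  iso <- setNames(as.character(isolate_seqs), names(isolate_seqs))
  if (is.null(names(iso))) abort("isolate markers must be named")
  purrr::imap_dfr(iso, function(s, id) best_match(s, env_seqs, isolate_id = id, ...))
}

#' Fragment-based mean nucleotide identity between two genomes
#'
#' A light-weight fragment identity in the spirit of fragment-based ANI:
#' the query genome is cut into non-overlapping fragments (default 1020
#' nt), each fragment is aligned to its best-scoring location in the target
#' genome by local (Smith-Waterman) alignment, fragments aligning over less
#' than `min_coverage` of their length or below `min_identity` percent
#' identity are dropped, and the mean identity over surviving fragments is
#' returned.
#'
#' @param genome_a Query genome sequence (length >= `fragment_length`).
#' @param genome_b Target genome sequence.
#' @param fragment_length Fragment size in nt.
#' @param min_coverage Minimum aligned fraction of a fragment.
#' @param min_identity Minimum percent identity of a fragment alignment.
#' @param ... Scoring parameters (see [global_identity()]).
#' @return One-row tibble `mean_identity`, `n_fragments`, `n_total`,
#'   `defined` (`FALSE` when no fragment survives; then `mean_identity` is
#'   `NA`).
#' @export
fragment_identity <- function(genome_a, genome_b, fragment_length = 1020,
                              min_coverage = 0.7, min_identity = 30, ...) {
  a <- as.character(genome_a)
  if (nchar(a) < fragment_length) {
    abort("query genome shorter than one fragment")
  }
  n_frag <- floor(nchar(a) / fragment_length)
  starts <- (seq_len(n_frag) - 1L) * fragment_length + 1L
  ids <- purrr::map_dbl(starts, function(st) {
    frag <- substr(a, st, st + fragment_length - 1L)
    aln <- pairwise_align(frag, genome_b, type = "local", ...)
    stats <- alignment_identity(aln)
    aligned <- nchar(gsub("-", "", as.character(Biostrings::alignedPattern(aln))))
    coverage <- aligned / fragment_length
    if (coverage < min_coverage || stats$identity < min_identity) NA_real_
    else stats$identity
  })
  ok <- !is.na(ids)
  tibble::tibble(
    mean_identity = if (any(ok)) mean(ids[ok]) else NA_real_,
    n_fragments = sum(ok),
    n_total = n_frag,
    defined = any(ok)
  )
}

#' Relative abundances from marker counts
#'
#' Divides each sample's marker counts by the sample total so columns sum
#' to one.
#'
#' @param counts Tibble with columns `taxon_id`, `sample_id`, `count`.
#' @return The input with a `rel_abundance` column added.
#' @export
relative_abundance <- function(counts) {
  assert_columns(counts, c("taxon_id", "sample_id", "count"))
  if (any(counts$count < 0)) abort("negative marker counts")
  sums <- counts %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  zero <- sums$sample_id[sums$total == 0]
  if (length(zero) > 0L) {
    abort(sprintf("zero total marker count in sample(s): %s",
                  paste(zero, collapse = ", ")))
  }
  counts %>%
    dplyr::left_join(sums, by = "sample_id") %>%
    dplyr::mutate(rel_abundance = .data$count / .data$total) %>%
    dplyr::select(-"total")
}

#' Parse a rank-annotated lineage string
#'
#' Lineages follow the `"Name (p)/ Name (c)/ Name (o)/ Name (f)/ Name (g)"`
#' convention (phylum, class, order, family, genus).
#'
#' @param lineage Character vector of lineage strings.
#' @return Tibble `lineage`, `rank`, `name` (one row per parsed segment).
#' @export
parse_lineage <- function(lineage) {
  purrr::map_dfr(lineage, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) {
      return(tibble::tibble(lineage = x, rank = character(), name = character()))
    }
    segs <- trimws(strsplit(x, "/")[[1]])
    m <- regmatches(segs, regexec("^(.*\\S)\\s*\\(([a-z])\\)$", segs))
    bad <- lengths(m) != 3L
    if (any(bad)) {
      abort(sprintf("malformed lineage string: '%s'", x))
    }
    tibble::tibble(
      lineage = x,
      rank = vapply(m, `[`, character(1), 3L),
      name = vapply(m, `[`, character(1), 2L)
    )
  })
}

#' Aggregate relative abundances to a taxonomic rank
#'
#' Sums taxon relative abundances within the named rank of each taxon's
#' lineage; taxa without a lineage, or whose lineage lacks the rank, fall
#' into an `"unclassified"` bucket, so columns still sum to one.
#'
#' @param abundances Output of [relative_abundance()].
#' @param taxonomy Tibble with columns `taxon_id`, `lineage`.
#' @param rank Single-letter rank code (`"p"`, `"c"`, `"o"`, `"f"`, `"g"`).
#' @return Tibble `group`, `sample_id`, `rel_abundance`.
#' @export
aggregate_taxonomy <- function(abundances, taxonomy, rank = "p") {
  assert_columns(abundances, c("taxon_id", "sample_id", "rel_abundance"))
  assert_columns(taxonomy, c("taxon_id", "lineage"))
  stopifnot(is.character(rank), length(rank) == 1L)
  parsed <- parse_lineage(taxonomy$lineage) %>%
    dplyr::filter(.data$rank == !!rank) %>%
    dplyr::distinct(.data$lineage, .keep_all = TRUE)
  lut <- taxonomy %>%
    dplyr::left_join(parsed %>% dplyr::select("lineage", "name"), by = "lineage") %>%
    dplyr::mutate(group = dplyr::coalesce(.data$name, "unclassified")) %>%
    dplyr::select("taxon_id", "group")
  abundances %>%
    dplyr::left_join(lut, by = "taxon_id") %>%
    dplyr::mutate(group = dplyr::coalesce(.data$group, "unclassified")) %>%
    dplyr::group_by(.data$group, .data$sample_id) %>%
    dplyr::summarise(rel_abundance = sum(.data$rel_abundance), .groups = "drop")
}
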