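#' Consensus cistrome across ChIP-seq studies
#'
#' Pools the peaks of all studies, clusters them transitively by >= 1 bp
#' overlap, counts the distinct studies contributing to each cluster, and
#' emits the merged span of every cluster supported by at least `min_studies`
#' studies. Support is counted at the site level: a study supports a cluster
#' if any of its peaks overlaps it.
#'
#' @param studies a named list of interval tibbles (one per study), or a
#'   single tibble with a `study` column.
#' @param min_studies minimum number of distinct supporting studies
#'   (default 2, the usual "overlapping sites in at least two studies" rule).
#' @return Tibble of consensus sites: `chrom`, `start`, `end`, `support`,
#'   `study_ids` (comma-separated), sorted and non-overlapping.
#' @examples
#' s <- list(a = interval_tbl("chr1", c(100, 400), c(200, 500)),
#'           b = interval_tbl("chr1", 150, 250))
#' consensus_cistrome(s, min_studies = 2)
#' @export
consensus_cistrome <- function(studies, min_studies = 2) {
  if (is.data.frame(studies)) {
    .required_cols(studies, c("chrom", "start", "end", "study"), "pooled peaks")
    pool <- as_tibble(studies)
  } else {
    nms <- names(studies) %||% as.character(seq_along(studies))
    pool <- bind_rows(purrr::imap(studies, function(x, nm) {
      validate_intervals(x, paste0("study ", nm))
      tibble(chrom = x$chrom, start = x$start, end = x$end, study = nm)
    }))
  }
  n_studies <- length(unique(pool$study))
  if (min_studies > max(n_studies, 0)) {
    abort(sprintf("min_studies = %d exceeds the %d studies supplied",
                  min_studies, n_studies))
  }
  if (nrow(pool) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  support = integer(), study_ids = character()))
  }
  # clusters = strict-overlap merge of the pooled peaks (adjacency is not overlap)
  clusters <- merge_intervals(pool[c("chrom", "start", "end")], min_gap = -1)
  hits <- overlap_any(pool, clusters)
  per_cluster <- hits %>%
    mutate(cluster = vapply(.data$matches, `[`, 1L, FUN.VALUE = integer(1))) %>%
    group_by(.data$cluster) %>%
    summarise(support = length(unique(.data$study)),
              study_ids = paste(sort(unique(.data$study)), collapse = ","),
              .groups = "drop")
  clusters %>%
    mutate(cluster = row_number()) %>%
    inner_join(per_cluster, by = "cluster") %>%
    filter(.data$support >= min_studies) %>%
    select("chrom", "start", "end", "support", "study_ids") %>%
    arrange(.data$chrom, .data$start)
}

#' Fraction of sites co-occurring with partner factors
#'
#' Restricts `sites` to those overlapping `within` (when given, e.g. complex
#' anchors), then counts how many overlap at least one peak of any partner
#' set.
#'
#' @param sites interval tibble (e.g. a consensus cistrome).
#' @param partner_sets list of interval tibbles (e.g. pioneer-factor peak
#'   sets); must be non-empty.
#' @param within optional interval tibble restricting the site universe.
#' @return Tibble with one row: `n_cooccurring`, `n_total`, `fraction`
#'   (`NA` when the restricted universe is empty).
#' @export
cooccurrence_fraction <- function(sites, partner_sets, within = NULL) {
  validate_intervals(sites, "sites")
  if (!is.list(partner_sets) || is.data.frame(partner_sets) || length(partner_sets) == 0) {
    abort("partner_sets must be a non-empty list of interval tibbles")
  }
  if (!is.null(within)) {
    sites <- sites[.overlaps_flag(sites, within), , drop = FALSE]
  }
  if (nrow(sites) == 0) {
    return(tibble(n_cooccurring = 0L, n_total = 0L, fraction = NA_real_))
  }
  hit <- rep(FALSE, nrow(sites))
  for (p in partner_sets) hit <- hit | .overlaps_flag(sites, p)
  tibble(n_cooccurring = sum(hit), n_total = nrow(sites),
         fraction = sum(hit) / nrow(sites))
}
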