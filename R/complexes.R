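#' Assemble chromatin complexes from interaction pairs
#'
#' A complex is a connected component of the anchor graph: every interaction
#' pair joins its two anchors, and anchors overlapping by >= 1 bp are fused
#' into one node. Anchors of a component are merged intervals; the complex
#' span runs from the first anchor start to the last anchor end. This is the
#' standard ChIA-PET cluster-to-complex construction, which is what makes
#' "multiple loops and anchor regions per complex" well defined.
#'
#' @param pairs interactions tibble (see [read_interactions()]).
#'   Inter-chromosomal pairs are dropped with a message.
#' @return Tibble with one row per complex: `complex_id` (deterministic, by
#'   chromosome then span start), `chrom`, `span_start`, `span_end`,
#'   `n_anchors`, `n_interactions`, and `anchors` (list column of interval
#'   tibbles).
#' @export
assemble_complexes <- function(pairs) {
  .required_cols(pairs, c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b"),
                 "interaction pairs")
  inter <- pairs$chrom_a != pairs$chrom_b
  if (any(inter)) {
    inform(sprintf("excluding %d inter-chromosomal pair(s) from complex assembly", sum(inter)))
    pairs <- pairs[!inter, , drop = FALSE]
  }
  if (nrow(pairs) == 0) {
    return(tibble(complex_id = character(), chrom = character(),
                  span_start = numeric(), span_end = numeric(),
                  n_anchors = integer(), n_interactions = integer(),
                  anchors = list()))
  }
  anchors <- tibble(
    chrom = c(pairs$chrom_a, pairs$chrom_b),
    start = c(pairs$start_a, pairs$start_b),
    end = c(pairs$end_a, pairs$end_b),
    pair = rep(seq_len(nrow(pairs)), 2)
  )
  # fuse overlapping anchors into nodes (strict overlap; adjacency stays split)
  nodes <- merge_intervals(anchors[c("chrom", "start", "end")], min_gap = -1)
  node_of <- overlap_any(anchors, nodes)$matches
  node_of <- vapply(node_of, `[`, 1L, FUN.VALUE = integer(1))
  # union-find over nodes, joined by pair membership
  parent <- seq_len(nrow(nodes))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  na <- node_of[seq_len(nrow(pairs))]
  nb <- node_of[nrow(pairs) + seq_len(nrow(pairs))]
  for (k in seq_len(nrow(pairs))) {
    ra <- find(na[k]); rb <- find(nb[k])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_len(nrow(nodes)), find, integer(1))
  groups <- split(seq_len(nrow(nodes)), comp)
  by_comp <- purrr::map(groups, function(ix) {
    tibble(chrom = nodes$chrom[ix[1]], span_start = min(nodes$start[ix]),
           span_end = max(nodes$end[ix]), n_anchors = length(ix),
           anchors = list(tibble(chrom = nodes$chrom[ix], start = nodes$start[ix],
                                 end = nodes$end[ix])))
  }) %>% bind_rows()
  pair_comp <- comp[na]
  by_comp$n_interactions <- as.integer(table(factor(pair_comp, levels = names(groups))))
  by_comp <- by_comp %>%
    arrange(.data$chrom, .data$span_start) %>%
    mutate(complex_id = sprintf("cx%05d", row_number())) %>%
    select("complex_id", "chrom", "span_start", "span_end",
           "n_anchors", "n_interactions", "anchors")
  by_comp
}

#' Flatten complex anchors to one interval tibble
#' @param complexes complex tibble from [assemble_complexes()].
#' @return Interval tibble with a `complex_id` column.
#' @export
complex_anchors <- function(complexes) {
  if (nrow(complexes) == 0) {
    return(tibble(complex_id = character(), chrom = character(),
                  start = numeric(), end = numeric()))
  }
  tidyr::unnest(select(complexes, "complex_id", "anchors"), "anchors") %>%
    select("complex_id", "chrom", "start", "end")
}

#' Categorise genes relative to chromatin complexes
#'
#' A gene is an *anchor* gene when its TSS lies within `anchor_window` bp of
#' a complex anchor (boundary inclusive: exactly `anchor_window` bp still
#' counts); otherwise a *loop* gene when its TSS falls inside a complex span;
#' otherwise *outside*. A TSS near anchors of several complexes goes to the
#' nearest anchor, ties broken by smallest `complex_id`.
#'
#' @param genes gene tibble (see [gene_tbl()]).
#' @param complexes complex tibble from [assemble_complexes()].
#' @param anchor_window half-width in bp of the TSS-to-anchor rule
#'   (default 5000).
#' @param condition optional label stored in the output.
#' @return Tibble: `gene_id`, `condition`, `category` (`anchor`/`loop`/
#'   `outside`), `complex_id` (`NA` when outside),
#'   `distance_to_nearest_anchor`.
#' @export
categorize_genes <- function(genes, complexes, anchor_window = 5000,
                             condition = NA_character_) {
  .required_cols(genes, c("gene_id", "chrom", "tss"), "genes")
  anc <- complex_anchors(complexes)
  rank_of <- match(anc$complex_id, sort(unique(anc$complex_id)))
  near <- .nearest_interval(genes$chrom, genes$tss, anc, tie_key = rank_of)
  spans <- if (nrow(complexes) == 0) {
    tibble(complex_id = character(), chrom = character(), start = numeric(), end = numeric())
  } else {
    tibble(complex_id = complexes$complex_id, chrom = complexes$chrom,
           start = complexes$span_start, end = complexes$span_end)
  }
  span_rank <- match(spans$complex_id, sort(unique(spans$complex_id)))
  in_span <- .nearest_interval(genes$chrom, genes$tss, spans, tie_key = span_rank)
  category <- ifelse(near$distance <= anchor_window, "anchor",
                     ifelse(in_span$distance == 0, "loop", "outside"))
  complex_id <- ifelse(category == "anchor", anc$complex_id[near$index],
                       ifelse(category == "loop", spans$complex_id[in_span$index],
                              NA_character_))
  tibble(gene_id = genes$gene_id, condition = condition, category = category,
         complex_id = complex_id, distance_to_nearest_anchor = near$distance)
}

#' Stand-alone binding sites: events outside any complex anchor
#'
#' @param sites interval tibble of binding events.
#' @param complexes complex tibble; sites overlapping any of its anchors are
#'   removed.
#' @return Subset of `sites` not overlapping any complex anchor.
#' @export
standalone_sites <- function(sites, complexes) {
  validate_intervals(sites, "sites")
  anc <- complex_anchors(complexes)
  sites[!.overlaps_flag(sites, anc), , drop = FALSE]
}

#' Is each gene near a stand-alone binding site?
#'
#' True when the gene's TSS lies within `standalone_window` bp (boundary
#' inclusive) of a stand-alone site, i.e. a binding event external to any
#' higher-order structure.
#'
#' @param genes gene tibble.
#' @param sites stand-alone site tibble (see [standalone_sites()]).
#' @param standalone_window bp, default 20000.
#' @param promoter_flank treat the promoter as the interval
#'   `TSS +/- promoter_flank` instead of the TSS point (default 0 = point);
#'   distances shrink accordingly.
#' @return Tibble: `gene_id`, `standalone` (logical), `distance`.
#' @export
assign_standalone <- function(genes, sites, standalone_window = 20000,
                              promoter_flank = 0) {
  near <- .nearest_interval(genes$chrom, genes$tss, sites)
  d <- pmax(near$distance - promoter_flank, 0)
  tibble(gene_id = genes$gene_id, standalone = d <= standalone_window,
         distance = d)
}

#' Binding-site content of complexes
#'
#' Counts, per complex and per factor, the binding sites overlapping the
#' complex (its merged anchors by default, or its whole span).
#'
#' @param complexes complex tibble.
#' @param site_sets named list of interval tibbles, one per factor.
#' @param in_anchors_only count only sites overlapping anchor regions
#'   (default `TRUE`); otherwise any site within the span.
#' @return List of two tibbles: `per_complex` (`complex_id`, `factor`,
#'   `n_sites`) and `summary` (`factor`, `n_complexes`,
#'   `n_with_site`, `fraction_with_site`, `mean_sites_when_present`).
#' @export
complex_content <- function(complexes, site_sets, in_anchors_only = TRUE) {
  if (!is.list(site_sets) || is.data.frame(site_sets)) {
    abort("site_sets must be a named list of interval tibbles")
  }
  target <- if (in_anchors_only) complex_anchors(complexes) else
    tibble(complex_id = complexes$complex_id, chrom = complexes$chrom,
           start = complexes$span_start, end = complexes$span_end)
  per <- purrr::imap(site_sets, function(sites, nm) {
    validate_intervals(sites, nm)
    counts <- setNames(rep(0L, nrow(complexes)), complexes$complex_id)
    if (nrow(sites) > 0 && nrow(target) > 0) {
      hits <- overlap_any(sites, target)
      hit_cx <- unlist(lapply(hits$matches, function(ix) unique(target$complex_id[ix])))
      tt <- table(hit_cx)
      counts[names(tt)] <- as.integer(tt)
    }
    tibble(complex_id = complexes$complex_id, factor = nm, n_sites = unname(counts))
  })
  per_complex <- bind_rows(per)
  summary <- per_complex %>%
    group_by(factor = .data$factor) %>%
    summarise(n_complexes = n(), n_with_site = sum(.data$n_sites > 0),
              fraction_with_site = if (n() > 0) sum(.data$n_sites > 0) / n() else NA_real_,
              mean_sites_when_present = if (any(.data$n_sites > 0))
                mean(.data$n_sites[.data$n_sites > 0]) else NA_real_,
              .groups = "drop")
  list(per_complex = per_complex, summary = summary)
}
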