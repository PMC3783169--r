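# sorted position index per (chrom, strand) with cumulative counts; makes
# region sums O(log n) and per-bp extraction a slice
.cov_index <- function(track) {
  idx <- list()
  key <- paste(track$chrom, track$strand, sep = "\r")
  for (k in unique(key)) {
    rows <- which(key == k)
    o <- rows[order(track$pos[rows])]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    idx[[parts[1]]][[parts[2]]] <- list(pos = track$pos[o],
                                        cum = c(0, cumsum(track$count[o])))
  }
  idx
}

.region_count1 <- function(ix, start, end) {
  if (is.null(ix)) return(0)
  lo <- findInterval(start - 0.5, ix$pos)
  hi <- findInterval(end - 0.5, ix$pos)
  ix$cum[hi + 1] - ix$cum[lo + 1]
}

.region_count <- function(idx, chrom, start, end, strand = NULL) {
  strands <- strand %||% c("+", "-")
  sum(vapply(strands, function(s) .region_count1(idx[[chrom]][[s]], start, end),
             numeric(1)))
}

# per-bp counts over [start, end)
.region_vector <- function(idx, chrom, start, end, strand = NULL) {
  v <- numeric(end - start)
  for (s in strand %||% c("+", "-")) {
    ix <- idx[[chrom]][[s]]
    if (is.null(ix)) next
    lo <- findInterval(start - 0.5, ix$pos) + 1
    hi <- findInterval(end - 0.5, ix$pos)
    if (hi >= lo) {
      p <- ix$pos[lo:hi]
      v[p - start + 1] <- v[p - start + 1] + diff(ix$cum)[lo:hi]
    }
  }
  v
}

# TSS-centred window, strand-mirrored so +/- genes are exact mirror images
.tss_window <- function(tss, w, strand) {
  if (strand == "+") c(tss - w, tss + w) else c(tss - w + 1, tss + w + 1)
}

#' Reads-per-million over genomic regions
#'
#' `(read-start count in region) * 1e6 / library_size`. Regions on
#' chromosomes absent from the track get 0 with a warning.
#'
#' @param track `coverage_track`.
#' @param regions interval tibble; a `strand` column restricts counting to
#'   that strand (`.` or absent = both strands).
#' @param lib library size override; defaults to the track attribute.
#' @return Numeric vector of RPM values, one per region.
#' @export
region_rpm <- function(track, regions, lib = NULL) {
  validate_intervals(regions, "regions")
  lib <- lib %||% library_size(track)
  if (lib == 0) abort("library_size is 0; RPM undefined")
  idx <- .cov_index(track)
  missing_chrom <- setdiff(unique(regions$chrom), names(idx))
  if (length(missing_chrom) > 0) {
    warn(sprintf("chromosome(s) absent from track: %s (RPM 0)",
                 paste(missing_chrom, collapse = ", ")))
  }
  strand <- regions[["strand"]] %||% rep(".", nrow(regions))
  vapply(seq_len(nrow(regions)), function(i) {
    s <- if (strand[i] %in% c("+", "-")) strand[i] else NULL
    .region_count(idx, regions$chrom[i], regions$start[i], regions$end[i], s) * 1e6 / lib
  }, numeric(1))
}

#' Metagene profile with spline-scaled gene bodies
#'
#' Averages signal across genes in gene-oriented coordinates (minus-strand
#' genes are flipped). The promoter segment is per-bp RPM over
#' `[TSS - flank, TSS + flank)`, the 3'-end segment likewise around the TES.
#' The gene body (`[TSS + flank, TES - flank)`) is represented by a natural
#' cubic spline over base index evaluated at `body_points` equally spaced
#' points, averaged into `body_bins` consecutive bins, so all genes appear to
#' have the same length; negative spline values are clipped to 0. Genes
#' shorter than `min_gene_length` (or with a body too short to interpolate)
#' are excluded and counted.
#'
#' @param genes gene tibble.
#' @param track `coverage_track` (unstranded use sums both strands).
#' @param flank bp of the fixed-width segments (500 for Pol II ChIP
#'   profiles, 1000 for GRO-seq).
#' @param body_points spline evaluation points (default 1000).
#' @param body_bins body bins (default 100; must divide `body_points`).
#' @param strand_mode `"unstranded"`, `"sense"` or `"antisense"`.
#' @param min_gene_length minimum transcript length in bp (default 2000).
#' @param lib library size override.
#' @return A `metagene_profile`: tibble with `segment` (`promoter`, `body`,
#'   `tes`), `position` (bp offset for the flanks, bin index for the body)
#'   and `rpm`; attributes `n_genes`, `n_excluded`, `flank`.
#' @export
metagene_profile <- function(genes, track, flank = 500, body_points = 1000,
                             body_bins = 100,
                             strand_mode = c("unstranded", "sense", "antisense"),
                             min_gene_length = 2000, lib = NULL) {
  strand_mode <- match.arg(strand_mode)
  if (body_points %% body_bins != 0) abort("body_points must be divisible by body_bins")
  lib <- lib %||% library_size(track)
  if (lib == 0) abort("library_size is 0; RPM undefined")
  idx <- .cov_index(track)
  len <- genes$tx_end - genes$tx_start
  eligible <- len >= min_gene_length & (len - 2 * flank) >= 4
  if (!any(eligible)) abort("no gene is long enough for a metagene profile")
  g <- genes[eligible, , drop = FALSE]
  prom_sum <- numeric(2 * flank); tes_sum <- numeric(2 * flank); body_sum <- numeric(body_bins)
  per_bin <- body_points / body_bins
  for (i in seq_len(nrow(g))) {
    st <- g$strand[i]
    strand_sel <- switch(strand_mode,
                         unstranded = NULL,
                         sense = st,
                         antisense = if (st == "+") "-" else "+")
    tssw <- .tss_window(g$tss[i], flank, st)
    tesw <- .tss_window(g$tes[i], flank, st)
    prom <- .region_vector(idx, g$chrom[i], tssw[1], tssw[2], strand_sel)
    tes <- .region_vector(idx, g$chrom[i], tesw[1], tesw[2], strand_sel)
    body <- .region_vector(idx, g$chrom[i], g$tx_start[i] + flank,
                           g$tx_end[i] - flank, strand_sel)
    if (st == "-") { prom <- rev(prom); tes <- rev(tes); body <- rev(body) }
    sp <- spline(seq_along(body), body, n = body_points, method = "natural")
    spy <- pmax(sp$y, 0)
    prom_sum <- prom_sum + prom
    tes_sum <- tes_sum + tes
    body_sum <- body_sum + colMeans(matrix(spy, nrow = per_bin))
  }
  scale <- 1e6 / (lib * nrow(g))
  out <- bind_rows(
    tibble(segment = "promoter", position = seq(-flank, flank - 1), rpm = prom_sum * scale),
    tibble(segment = "body", position = seq_len(body_bins), rpm = body_sum * scale),
    tibble(segment = "tes", position = seq(-flank, flank - 1), rpm = tes_sum * scale)
  )
  attr(out, "n_genes") <- nrow(g)
  attr(out, "n_excluded") <- sum(!eligible)
  attr(out, "flank") <- flank
  class(out) <- c("metagene_profile", class(out))
  out
}

#' Transcription-starting (initiation) rates near the TSS
#'
#' Total RPM of read starts in the TSS window (default +/- 300 bp) on the
#' gene's own strand (sense) and the opposite strand (antisense).
#'
#' @param genes gene tibble.
#' @param track strand-specific `coverage_track`.
#' @param tss_window half-width in bp (default 300).
#' @param lib library size override.
#' @return Tibble: `gene_id`, `sense_rpm`, `antisense_rpm`.
#' @export
initiation_rate <- function(genes, track, tss_window = 300, lib = NULL) {
  lib <- lib %||% library_size(track)
  if (lib == 0) abort("library_size is 0; RPM undefined")
  idx <- .cov_index(track)
  res <- purrr::map(seq_len(nrow(genes)), function(i) {
    w <- .tss_window(genes$tss[i], tss_window, genes$strand[i])
    anti <- if (genes$strand[i] == "+") "-" else "+"
    c(.region_count(idx, genes$chrom[i], w[1], w[2], genes$strand[i]),
      .region_count(idx, genes$chrom[i], w[1], w[2], anti))
  })
  m <- do.call(rbind, res)
  tibble(gene_id = genes$gene_id,
         sense_rpm = m[, 1] * 1e6 / lib,
         antisense_rpm = m[, 2] * 1e6 / lib)
}

#' Pol II pause ratio (pausing index) per gene
#'
#' Ratio of sense-strand read-start density near the TSS (+/- `tss_window`
#' bp) to density over the gene body (from `tss_window` bp downstream of the
#' TSS to the TES), both as RPM per kb. A pseudocount (default 1 read) is
#' added to both region counts before forming densities; with
#' `pseudocount = 0` genes with an empty body get `NA` and a flag. Genes too
#' short to hold a TSS window plus `min_body` bp of body are skipped with a
#' flag. High values indicate promoter-proximal pausing.
#'
#' @param genes gene tibble.
#' @param track strand-specific `coverage_track`.
#' @param tss_window half-width of the TSS window in bp (default 300).
#' @param min_body minimum gene-body length in bp (default 300).
#' @param pseudocount reads added to each region count (default 1).
#' @param per_kb normalise each region by its length in kb (default `TRUE`);
#'   `FALSE` gives the raw RPM-total ratio instead of the density ratio.
#' @param condition label copied to the output.
#' @param lib library size override.
#' @return Tibble: `gene_id`, `condition`, `tss_density`, `body_density`
#'   (RPM/kb, or RPM totals when `per_kb = FALSE`), `pause_ratio`,
#'   `antisense_tss_rpm`, `flagged`.
#' @export
pause_ratio <- function(genes, track, tss_window = 300, min_body = 300,
                        pseudocount = 1, per_kb = TRUE,
                        condition = NA_character_, lib = NULL) {
  lib <- lib %||% library_size(track)
  if (lib == 0) abort("library_size is 0; RPM undefined")
  idx <- .cov_index(track)
  n <- nrow(genes)
  tss_d <- body_d <- ratio <- anti <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    L <- genes$tx_end[i] - genes$tx_start[i]
    if ((L - 1) <= tss_window + min_body) { flagged[i] <- TRUE; next }
    st <- genes$strand[i]
    w <- .tss_window(genes$tss[i], tss_window, st)
    body_len <- L - 1 - tss_window  # gene-oriented [tss_window, L-1)
    if (st == "+") {
      b <- c(genes$tss[i] + tss_window, genes$tx_end[i] - 1)
    } else {
      b <- c(genes$tx_start[i] + 1, genes$tss[i] - tss_window + 1)
    }
    tss_c <- .region_count(idx, genes$chrom[i], w[1], w[2], st)
    body_c <- .region_count(idx, genes$chrom[i], b[1], b[2], st)
    anti_st <- if (st == "+") "-" else "+"
    anti[i] <- .region_count(idx, genes$chrom[i], w[1], w[2], anti_st) * 1e6 / lib
    if (pseudocount == 0 && body_c == 0) { flagged[i] <- TRUE; next }
    kb_tss <- if (per_kb) 2 * tss_window / 1000 else 1
    kb_body <- if (per_kb) body_len / 1000 else 1
    tss_d[i] <- (tss_c + pseudocount) * 1e6 / lib / kb_tss
    body_d[i] <- (body_c + pseudocount) * 1e6 / lib / kb_body
    ratio[i] <- tss_d[i] / body_d[i]
  }
  tibble(gene_id = genes$gene_id, condition = condition, tss_density = tss_d,
         body_density = body_d, pause_ratio = ratio, antisense_tss_rpm = anti,
         flagged = flagged)
}

#' Compare a per-gene metric between two conditions
#'
#' Joins the two stat tables on `gene_id`, drops flagged or missing genes,
#' and runs a paired (default) or Welch t-test on the chosen metric.
#'
#' @param stats_before,stats_after tibbles from [pause_ratio()] or
#'   [initiation_rate()] (any tibble with `gene_id` and the metric).
#' @param metric column name to compare, e.g. `"pause_ratio"`,
#'   `"body_density"`, `"sense_rpm"`.
#' @param paired paired test (default `TRUE`).
#' @return One-row tibble: `metric`, `n`, `median_before`, `median_after`,
#'   `direction`, plus the [group_mean_test()] columns.
#' @export
compare_conditions <- function(stats_before, stats_after, metric, paired = TRUE) {
  j <- inner_join(select(stats_before, "gene_id", before = dplyr::all_of(metric)),
                  select(stats_after, "gene_id", after = dplyr::all_of(metric)),
                  by = "gene_id")
  j <- filter(j, is.finite(.data$before), is.finite(.data$after))
  if (nrow(j) < 2) abort("fewer than 2 shared genes with finite values")
  test <- group_mean_test(j$after, j$before, paired = paired)
  mb <- median(j$before); ma <- median(j$after)
  tibble(metric = metric, n = nrow(j), median_before = mb, median_after = ma,
         direction = dplyr::case_when(ma > mb ~ "increase", ma < mb ~ "decrease",
                                      TRUE ~ "none")) %>%
    dplyr::bind_cols(test)
}
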