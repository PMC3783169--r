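.chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    .required_cols(chrom_sizes, c("chrom", "size"), "chrom_sizes")
    setNames(chrom_sizes$size, chrom_sizes$chrom)
  } else {
    if (is.null(names(chrom_sizes))) abort("chrom_sizes must be named by chromosome")
    chrom_sizes
  }
}

# merged per-chromosome endpoint lists
.by_chrom <- function(x) {
  out <- list()
  for (ch in unique(x$chrom)) {
    rows <- x$chrom == ch
    out[[ch]] <- .merge1(x$start[rows], x$end[rows], min_gap = -1)
  }
  out
}

.merged_len <- function(m) sum(m$end - m$start)

# Jaccard on per-chrom merged lists: |A n B| / |A u B| via union lengths
.jaccard_lists <- function(a, b) {
  lenA <- sum(vapply(a, .merged_len, numeric(1)))
  lenB <- sum(vapply(b, .merged_len, numeric(1)))
  lenU <- 0
  for (ch in union(names(a), names(b))) {
    s <- c(a[[ch]]$start, b[[ch]]$start); e <- c(a[[ch]]$end, b[[ch]]$end)
    m <- .merge1(s, e, min_gap = -1)
    lenU <- lenU + sum(m$end - m$start)
  }
  if (lenU == 0) return(NA_real_)
  (lenA + lenB - lenU) / lenU
}

#' Jaccard statistic between two interval sets
#'
#' Base-level Jaccard index: shared bases over covered bases, after merging
#' each set internally (so the statistic is invariant to how either set is
#' fragmented).
#'
#' @param a,b interval tibbles on a common chromosome namespace.
#' @return Value in `[0, 1]`.
#' @examples
#' jaccard_statistic(interval_tbl("chr1", 0, 100), interval_tbl("chr1", 50, 150))
#' @export
jaccard_statistic <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (nrow(a) == 0 && nrow(b) == 0) abort("both interval sets are empty; Jaccard undefined")
  .jaccard_lists(.by_chrom(a), .by_chrom(b))
}

# mean over `targets` of distance to nearest interval in `m` (per-chrom merged
# list); distance 0 on overlap; targets on chromosomes without any interval
# contribute the cap (chromosome size when known)
.mean_nearest_dist <- function(targets, m, cap) {
  d <- numeric(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    mm <- m[[targets$chrom[i]]]
    if (is.null(mm) || length(mm$start) == 0) {
      d[i] <- cap[[targets$chrom[i]]] %||% max(unlist(cap))
      next
    }
    s <- targets$start[i]; e <- targets$end[i]
    k <- findInterval(s, mm$start)
    cand <- unique(pmin(pmax(c(k, k + 1), 1), length(mm$start)))
    gaps <- pmax(pmax(mm$start[cand] - e, s - mm$end[cand]), 0)
    d[i] <- min(gaps)
  }
  mean(d)
}

.relocate <- function(x, sizes) {
  w <- x$end - x$start
  L <- sizes[x$chrom]
  ns <- floor(runif(nrow(x)) * (L - w + 1))
  tibble(chrom = x$chrom, start = ns, end = ns + w)
}

# gap-preserving null: one circular shift per chromosome; intervals wrapping
# past the end are split at the origin
.circular_shift <- function(x, sizes) {
  out <- vector("list", 0)
  for (ch in unique(x$chrom)) {
    rows <- x[x$chrom == ch, , drop = FALSE]
    L <- sizes[[ch]]
    off <- floor(runif(1) * L)
    s <- (rows$start + off) %% L
    e <- s + (rows$end - rows$start)
    keep <- e <= L
    parts <- list(tibble(chrom = ch, start = s[keep], end = e[keep]))
    if (any(!keep)) {
      parts <- c(parts,
                 list(tibble(chrom = ch, start = s[!keep], end = L),
                      tibble(chrom = ch, start = 0, end = e[!keep] - L)))
    }
    out <- c(out, parts)
  }
  bind_rows(out)
}

#' Permutation test of spatial enrichment between interval sets
#'
#' Each permutation relocates every query interval independently and
#' uniformly within its own chromosome, preserving interval lengths
#' (relocated intervals may overlap each other), and recomputes the
#' statistic. The p-value is `(1 + #{null as-or-more-extreme}) / (n_perm + 1)`,
#' one-sided in the direction of `alternative`, so it is never 0 and never
#' below `1/(n_perm + 1)`.
#'
#' @param query interval tibble that gets relocated under the null.
#' @param reference fixed interval tibble.
#' @param statistic `"jaccard"` (shared-base fraction) or
#'   `"mean_nearest_distance"` (mean over `reference` intervals of the
#'   distance to the nearest query interval).
#' @param n_perm number of permutations (default 500).
#' @param alternative `"greater"` (enrichment for Jaccard) or `"less"`
#'   (closer than chance for distances).
#' @param seed integer; when given, the null is reproducible bit-exactly and
#'   the caller's RNG state is restored.
#' @param chrom_sizes named vector or `chrom`/`size` tibble covering every
#'   interval.
#' @param null_model `"relocate"` (default, independent uniform placement) or
#'   `"shift"` (gap-preserving circular shift of each chromosome's query
#'   intervals by one random offset, wrapped intervals split at the origin).
#' @return Object of class `perm_enrichment`: list with `statistic_name`,
#'   `observed`, `null_values`, `p_value`, `n_perm`, `alternative`, `seed`.
#' @export
permutation_enrichment <- function(query, reference,
                                   statistic = c("jaccard", "mean_nearest_distance"),
                                   n_perm = 500,
                                   alternative = c("greater", "less"),
                                   seed = NULL, chrom_sizes = NULL,
                                   null_model = c("relocate", "shift")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  null_model <- match.arg(null_model)
  validate_intervals(query, "query"); validate_intervals(reference, "reference")
  if (is.null(chrom_sizes)) abort("chrom_sizes is required for relocation")
  sizes <- .chrom_sizes(chrom_sizes)
  for (x in list(query, reference)) {
    miss <- setdiff(unique(x$chrom), names(sizes))
    if (length(miss) > 0) abort(sprintf("chrom_sizes missing: %s", paste(miss, collapse = ", ")))
  }
  if (any(query$end - query$start > sizes[query$chrom])) {
    abort("an interval is longer than its chromosome; cannot relocate")
  }
  ref_m <- .by_chrom(reference)
  cap <- as.list(sizes)
  stat_fun <- if (statistic == "jaccard") {
    function(q) .jaccard_lists(.by_chrom(q), ref_m)
  } else {
    function(q) .mean_nearest_dist(reference, .by_chrom(q), cap)
  }
  observed <- stat_fun(query)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  permute <- if (null_model == "relocate") .relocate else .circular_shift
  null_values <- vapply(seq_len(n_perm), function(k) stat_fun(permute(query, sizes)),
                        numeric(1))
  extreme <- if (alternative == "greater") sum(null_values >= observed)
             else sum(null_values <= observed)
  structure(list(statistic_name = statistic, observed = observed,
                 null_values = null_values,
                 p_value = (1 + extreme) / (n_perm + 1),
                 n_perm = n_perm, alternative = alternative, seed = seed),
            class = "perm_enrichment")
}

#' Spatial association of marker peaks with gene promoters
#'
#' Statistic: mean, over promoters (`TSS +/- promoter_flank`), of the
#' distance to the nearest marker peak (0 when overlapping; promoters on
#' chromosomes without any marker contribute the chromosome size as a
#' maximal distance). Marker peaks are relocated under the null; small
#' observed distances mean association (`alternative = "less"`).
#'
#' @param genes gene tibble.
#' @param marker_peaks interval tibble (e.g. a histone-mark peak set); must
#'   be non-empty.
#' @param promoter_flank half-width of the promoter window (default 1000).
#' @param n_perm,seed,chrom_sizes see [permutation_enrichment()].
#' @return A `perm_enrichment` object.
#' @export
promoter_marker_association <- function(genes, marker_peaks, promoter_flank = 1000,
                                        n_perm = 500, seed = NULL, chrom_sizes = NULL) {
  if (nrow(marker_peaks) == 0) abort("no marker peaks supplied")
  promoters <- tibble(chrom = genes$chrom,
                      start = pmax(genes$tss - promoter_flank, 0),
                      end = genes$tss + promoter_flank)
  permutation_enrichment(marker_peaks, promoters,
                         statistic = "mean_nearest_distance", n_perm = n_perm,
                         alternative = "less", seed = seed, chrom_sizes = chrom_sizes)
}

#' @export
print.perm_enrichment <- function(x, ...) {
  cat(sprintf("Permutation enrichment (%s, alternative = %s)\n",
              x$statistic_name, x$alternative))
  cat(sprintf("observed = %.6g, null mean = %.6g, p = %.4g (n_perm = %d)\n",
              x$observed, mean(x$null_values), x$p_value, x$n_perm))
  invisible(x)
}
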