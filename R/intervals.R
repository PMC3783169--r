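#' Interval tibbles
#'
#' All genomic intervals in loopshift are plain tibbles with columns `chrom`
#' (character), `start` and `end` (0-based, half-open: `[start, end)`), plus
#' any extra columns (`strand`, `name`, ...). Every function below keeps that
#' convention; 1-based inputs are converted at read time, never here.
#'
#' @param chrom,start,end,strand vectors defining the intervals.
#' @param ... further columns carried along.
#' @return A tibble with at least `chrom`, `start`, `end`.
#' @examples
#' interval_tbl("chr1", c(0, 100), c(50, 200))
#' @export
interval_tbl <- function(chrom, start, end, strand = NULL, ...) {
  x <- tibble(chrom = as.character(chrom), start = as.numeric(start),
              end = as.numeric(end), ...)
  if (!is.null(strand)) x$strand <- strand
  validate_intervals(x)
}

#' Validate an interval tibble
#'
#' Checks the half-open invariant `0 <= start < end` and finite coordinates.
#' Intervals of length zero are rejected: `[a, a)` covers no base.
#'
#' @param x interval tibble.
#' @param what label used in error messages.
#' @return `x`, invisibly validated (returned for piping).
#' @export
validate_intervals <- function(x, what = "interval set") {
  .required_cols(x, c("chrom", "start", "end"), what)
  bad <- !is.finite(x$start) | !is.finite(x$end) | x$start < 0 | x$start >= x$end
  if (any(bad)) {
    abort(sprintf("%s: %d interval(s) violate 0 <= start < end (first at row %d)",
                  what, sum(bad), which(bad)[1]))
  }
  x
}

#' Normalise chromosome naming styles
#'
#' Chromosome names are otherwise matched as exact strings (no silent "chr"
#' repair, which invites cross-assembly accidents); this helper converts a
#' tibble's `chrom` column explicitly.
#'
#' @param x tibble with a `chrom` column.
#' @param style `"ucsc"` (`chr1`) or `"plain"` (`1`).
#' @return `x` with `chrom` rewritten.
#' @export
normalize_chrom_names <- function(x, style = c("ucsc", "plain")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", x$chrom)
  x$chrom <- if (style == "ucsc") paste0("chr", bare) else bare
  x
}

# IRanges bridge: 0-based half-open -> 1-based closed
.as_ir <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

#' Distance between two intervals
#'
#' Vectorised over paired rows of `a` and `b` (recycled if one has a single
#' row). Returns 0 for any overlap of at least 1 bp, the gap in bp otherwise,
#' and `Inf` when the chromosomes differ. Intervals `[a,b)` and `[b,c)` are
#' adjacent, not overlapping: their distance is 0 only because the gap is 0.
#'
#' @param a,b interval tibbles.
#' @return Numeric vector of distances (`Inf` = different chromosomes).
#' @examples
#' interval_distance(interval_tbl("chr1", 10, 20), interval_tbl("chr1", 25, 30))
#' @export
interval_distance <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  gap <- pmax(a$start[ai], b$start[bi]) - pmin(a$end[ai], b$end[bi])
  d <- pmax(gap, 0)
  d[a$chrom[ai] != b$chrom[bi]] <- Inf
  d
}

#' Distance from a genomic point to an interval
#'
#' The distance is 0 when the point lies inside the interval, otherwise the
#' number of bases to the nearest *contained* base, i.e.
#' `min(|p - start|, |p - (end - 1)|)`; `Inf` across chromosomes. This is the
#' metric behind all "TSS within +/- w of a region" rules, which are
#' boundary-inclusive: a point exactly `w` bp away passes a `<= w` window.
#'
#' @param p_chrom,p_pos point chromosome(s) and position(s).
#' @param b interval tibble (recycled against the points).
#' @return Numeric vector of distances.
#' @examples
#' point_interval_distance("chr1", 50000, interval_tbl("chr1", 38000, 42000))
#' @export
point_interval_distance <- function(p_chrom, p_pos, b) {
  validate_intervals(b, "b")
  n <- max(length(p_pos), nrow(b))
  pi <- rep_len(seq_along(p_pos), n); bi <- rep_len(seq_len(nrow(b)), n)
  p <- p_pos[pi]; s <- b$start[bi]; e <- b$end[bi]
  d <- ifelse(p >= s & p < e, 0, pmin(abs(p - s), abs(p - (e - 1))))
  pc <- rep_len(as.character(p_chrom), length(p_pos))[pi]
  d[pc != b$chrom[bi]] <- Inf
  d
}

# merge on one chromosome; plain vectors, used by hot paths
.merge1 <- function(start, end, min_gap = 0) {
  if (length(start) == 0) return(list(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  cm <- cummax(e)
  grp <- cumsum(c(TRUE, s[-1] > cm[-length(cm)] + min_gap))
  list(start = s[!duplicated(grp)],
       end = as.numeric(tapply(e, grp, max)))
}

#' Merge overlapping or near-adjacent intervals
#'
#' Two intervals merge iff they overlap by at least 1 bp or are separated by a
#' gap of at most `min_gap` bases. With the default `min_gap = 0`, touching
#' intervals `[a,b)`, `[b,c)` merge (their gap is 0); use `min_gap = -1` for
#' strict-overlap-only merging. Output is sorted by (chrom, start) and covers
#' exactly the same bases as the input (plus closed gaps).
#'
#' @param x interval tibble.
#' @param min_gap largest gap (bp) still merged; default 0.
#' @return Tibble of disjoint intervals, extra columns dropped.
#' @examples
#' merge_intervals(interval_tbl("chr1", c(0, 5, 30), c(10, 20, 40)))
#' @export
merge_intervals <- function(x, min_gap = 0) {
  validate_intervals(x)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  x %>%
    group_by(.data$chrom) %>%
    dplyr::reframe({
      m <- .merge1(.data$start, .data$end, min_gap)
      tibble(start = m$start, end = m$end)
    }) %>%
    arrange(.data$chrom, .data$start)
}

#' Which query intervals overlap a reference set?
#'
#' Overlap means at least 1 bp shared; half-open coordinates, so `[a,b)` and
#' `[b,c)` do not overlap.
#'
#' @param query,reference interval tibbles.
#' @return `query` with two added columns: `overlaps` (logical) and `matches`
#'   (list of reference row indices, empty integer vector when none).
#' @export
overlap_any <- function(query, reference) {
  validate_intervals(query, "query"); validate_intervals(reference, "reference")
  matches <- rep(list(integer(0)), nrow(query))
  if (nrow(query) > 0 && nrow(reference) > 0) {
    for (ch in intersect(unique(query$chrom), unique(reference$chrom))) {
      qi <- which(query$chrom == ch); ri <- which(reference$chrom == ch)
      hits <- IRanges::findOverlaps(.as_ir(query$start[qi], query$end[qi]),
                                    .as_ir(reference$start[ri], reference$end[ri]))
      qh <- S4Vectors::queryHits(hits); rh <- S4Vectors::subjectHits(hits)
      for (k in unique(qh)) matches[[qi[k]]] <- ri[rh[qh == k]]
    }
  }
  query$overlaps <- lengths(matches) > 0
  query$matches <- matches
  query
}

# fast logical: does each query interval overlap >=1 reference interval?
.overlaps_flag <- function(query, reference) {
  out <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(reference) == 0) return(out)
  for (ch in intersect(unique(query$chrom), unique(reference$chrom))) {
    qi <- which(query$chrom == ch); ri <- which(reference$chrom == ch)
    out[qi] <- IRanges::overlapsAny(.as_ir(query$start[qi], query$end[qi]),
                                    .as_ir(reference$start[ri], reference$end[ri]))
  }
  out
}

# total merged base coverage of an interval tibble
.coverage_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  m <- merge_intervals(x, min_gap = -1)
  sum(m$end - m$start)
}

# nearest interval (by point_interval_distance) per point, same-chromosome only.
# Returns tibble(distance, index) with index = row of `b`, NA when no interval
# on the chromosome. Ties broken by smallest distance, then smallest tie_key.
.nearest_interval <- function(p_chrom, p_pos, b, tie_key = seq_len(nrow(b))) {
  n <- length(p_pos)
  res <- tibble(distance = rep(Inf, n), index = rep(NA_integer_, n))
  if (nrow(b) == 0 || n == 0) return(res)
  by_chrom <- split(seq_len(nrow(b)), b$chrom)
  for (i in seq_len(n)) {
    ri <- by_chrom[[p_chrom[i]]]
    if (is.null(ri)) next
    s <- b$start[ri]; e <- b$end[ri]; p <- p_pos[i]
    d <- ifelse(p >= s & p < e, 0, pmin(abs(p - s), abs(p - (e - 1))))
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[which.min(tie_key[ri][best])]
    res$distance[i] <- min(d)
    res$index[i] <- ri[best]
  }
  res
}
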