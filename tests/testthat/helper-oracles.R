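# Brute-force oracles, independent of the package's interval algebra.
# All work on single-chromosome tibbles with small coordinates so that
# per-base masks are cheap.

mask_from_intervals <- function(x, L) {
  m <- logical(L)
  for (i in seq_len(nrow(x))) m[(x$start[i] + 1):x$end[i]] <- TRUE
  m
}

runs_from_mask <- function(m, chrom = "chr1") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(chrom = chrom, start = as.numeric(starts[r$values]),
                 end = as.numeric(ends[r$values]))
}

# per-base oracle for merge with min_gap = 0 (covered runs absorb adjacency)
oracle_merge0 <- function(x, L) runs_from_mask(mask_from_intervals(x, L), x$chrom[1])

# quadratic union-find: clusters of transitively >=1 bp-overlapping intervals
oracle_overlap_clusters <- function(x) {
  n <- nrow(x)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && x$chrom[i] == x$chrom[j] &&
          x$start[i] < x$end[j] && x$start[j] < x$end[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# consensus oracle: cluster pooled peaks, count studies, emit spans
oracle_consensus <- function(pool, min_studies) {
  if (nrow(pool) == 0) return(pool[c("chrom", "start", "end")])
  comp <- oracle_overlap_clusters(pool)
  out <- lapply(unique(comp), function(k) {
    rows <- pool[comp == k, , drop = FALSE]
    if (length(unique(rows$study)) >= min_studies) {
      tibble::tibble(chrom = rows$chrom[1], start = min(rows$start), end = max(rows$end))
    }
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  dplyr::arrange(res, chrom, start)
}

# BFS oracle for complex assembly: nodes are the raw per-pair anchors,
# adjacency = same pair or >=1 bp overlap; returns per-component summaries
oracle_components <- function(pairs) {
  n <- nrow(pairs)
  anc <- tibble::tibble(
    chrom = c(pairs$chrom_a, pairs$chrom_b),
    start = c(pairs$start_a, pairs$start_b),
    end = c(pairs$end_a, pairs$end_b),
    pair = rep(seq_len(n), 2)
  )
  m <- nrow(anc)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (anc$pair[i] == anc$pair[j] ||
        (anc$chrom[i] == anc$chrom[j] && anc$start[i] < anc$end[j] &&
         anc$start[j] < anc$end[i])) adj[i, j] <- TRUE
  }
  comp <- rep(NA_integer_, m); k <- 0
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    k <- k + 1; queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  out <- lapply(seq_len(k), function(cc) {
    rows <- anc[comp == cc, , drop = FALSE]
    merged <- oracle_strict_merge(rows)
    tibble::tibble(chrom = rows$chrom[1], span_start = min(rows$start),
                   span_end = max(rows$end), n_anchors = nrow(merged),
                   n_interactions = length(unique(rows$pair)))
  })
  dplyr::arrange(dplyr::bind_rows(out), chrom, span_start)
}

# strict-overlap merge oracle (adjacent intervals stay apart)
oracle_strict_merge <- function(x) {
  comp <- oracle_overlap_clusters(x)
  out <- lapply(unique(comp), function(k) {
    rows <- x[comp == k, , drop = FALSE]
    tibble::tibble(chrom = rows$chrom[1], start = min(rows$start), end = max(rows$end))
  })
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

oracle_jaccard <- function(a, b, L) {
  ma <- mask_from_intervals(a, L); mb <- mask_from_intervals(b, L)
  sum(ma & mb) / sum(ma | mb)
}

rand_intervals <- function(n, L, wmax = 500, chrom = "chr1") {
  w <- sample.int(wmax, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(L - wi, 1) - 1, numeric(1))
  tibble::tibble(chrom = chrom, start = s, end = s + w)
}

# coverage track from explicit per-region Poisson-free counts: `spec` is a
# tibble with chrom, start, end, strand, reads; reads are spread uniformly
make_track <- function(spec, library_size = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tags <- dplyr::bind_rows(lapply(seq_len(nrow(spec)), function(i) {
    k <- spec$reads[i]
    if (k == 0) return(NULL)
    pos <- spec$start[i] + sample.int(spec$end[i] - spec$start[i], k, replace = TRUE) - 1
    tibble::tibble(chrom = spec$chrom[i], pos = pos, strand = spec$strand[i], count = 1)
  }))
  tags <- dplyr::summarise(dplyr::group_by(tags, chrom, pos, strand),
                           count = sum(count), .groups = "drop")
  coverage_track(tags, library_size = library_size)
}

# uniform coverage c at every base of [start, end) on both strands
flat_track <- function(chrom, start, end, value, library_size) {
  pos1 <- seq(start, end - 1)
  tags <- tibble::tibble(chrom = chrom, pos = rep(pos1, 2),
                         strand = rep(c("+", "-"), each = length(pos1)),
                         count = value)
  coverage_track(tags, library_size = library_size)
}
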