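#' Read a BED file of peaks or binding sites
#'
#' Accepts BED3 and wider; columns beyond the sixth are ignored. Coordinates
#' are kept 0-based half-open as in the file. Malformed rows are rejected, not
#' repaired.
#'
#' @param path file path. Lines starting with `#`, `track` or `browser` are
#'   skipped.
#' @param name label for the peak set (factor/condition/study); defaults to
#'   the file name.
#' @return Interval tibble with `chrom`, `start`, `end` and, when present in
#'   the file, `name` and `strand`; sorted by (chrom, start). Attributes:
#'   `peakset_name`, `source`.
#' @export
read_bed <- function(path, name = basename(path)) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric())
  } else {
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 3)) {
      abort(sprintf("%s: line %d has %d column(s); BED needs >= 3",
                    path, which(nf < 3)[1], min(nf)))
    }
    start <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2)))
    end <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3)))
    bad <- is.na(start) | is.na(end) | start < 0 | start >= end
    if (any(bad)) {
      abort(sprintf("%s: line %d: invalid coordinates (need 0 <= start < end)",
                    path, which(bad)[1]))
    }
    out <- tibble(chrom = vapply(f, `[`, "", 1), start = start, end = end)
    if (all(nf >= 4)) out$name <- vapply(f, `[`, "", 4)
    if (all(nf >= 6)) {
      strand <- vapply(f, `[`, "", 6)
      if (!all(strand %in% c("+", "-", "."))) {
        abort(sprintf("%s: line %d: unknown strand symbol '%s'",
                      path, which(!strand %in% c("+", "-", "."))[1],
                      strand[!strand %in% c("+", "-", ".")][1]))
      }
      out$strand <- strand
    }
    out <- arrange(out, .data$chrom, .data$start)
  }
  attr(out, "peakset_name") <- name
  attr(out, "source") <- path
  out
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` and, when present, `name`, `score`,
#' `strand`. Coordinates are written as integers.
#'
#' @param x interval tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- list(x$chrom, sprintf("%d", as.integer(x$start)), sprintf("%d", as.integer(x$end)))
  if (!is.null(x[["name"]])) {
    cols <- c(cols, list(x[["name"]]))
    if (!is.null(x[["score"]])) {
      cols <- c(cols, list(as.character(x[["score"]])))
      if (!is.null(x[["strand"]])) cols <- c(cols, list(x[["strand"]]))
    }
  }
  readr::write_lines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read ChIA-PET interaction clusters (BEDPE)
#'
#' Expected columns: `chromA startA endA chromB startB endB [name] [pet_count]`.
#' Inter-chromosomal pairs are read and flagged (`inter_chromosomal`); complex
#' assembly excludes them by default.
#'
#' @param path BEDPE file.
#' @return Tibble with `chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`,
#'   `end_b`, `name`, `pet_count`, `inter_chromosomal`.
#' @export
read_interactions <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom_a = character(), start_a = numeric(), end_a = numeric(),
                  chrom_b = character(), start_b = numeric(), end_b = numeric(),
                  name = character(), pet_count = numeric(),
                  inter_chromosomal = logical()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 6)) {
    abort(sprintf("%s: line %d has %d column(s); BEDPE needs >= 6",
                  path, which(nf < 6)[1], min(nf)))
  }
  num <- function(k) suppressWarnings(as.numeric(vapply(f, `[`, "", k)))
  out <- tibble(
    chrom_a = vapply(f, `[`, "", 1), start_a = num(2), end_a = num(3),
    chrom_b = vapply(f, `[`, "", 4), start_b = num(5), end_b = num(6),
    name = if (all(nf >= 7)) vapply(f, `[`, "", 7) else NA_character_,
    pet_count = if (all(nf >= 8)) num(8) else NA_real_
  )
  bad <- with(out, is.na(start_a) | is.na(end_a) | is.na(start_b) | is.na(end_b) |
                start_a < 0 | start_a >= end_a | start_b < 0 | start_b >= end_b)
  if (any(bad)) {
    abort(sprintf("%s: line %d: invalid anchor coordinates", path, which(bad)[1]))
  }
  out$inter_chromosomal <- out$chrom_a != out$chrom_b
  out
}

#' Write interaction pairs as BEDPE
#' @param x interactions tibble (as from [read_interactions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  nm <- if (is.null(x[["name"]])) sprintf("pair_%d", seq_len(nrow(x))) else x[["name"]]
  pc <- if (is.null(x[["pet_count"]])) rep(1, nrow(x)) else x[["pet_count"]]
  readr::write_lines(paste(
    x$chrom_a, sprintf("%d", as.integer(x$start_a)), sprintf("%d", as.integer(x$end_a)),
    x$chrom_b, sprintf("%d", as.integer(x$start_b)), sprintf("%d", as.integer(x$end_b)),
    nm, as.character(pc), sep = "\t"), path)
  invisible(path)
}

#' Construct a gene table
#'
#' Genes carry exactly one TSS. The TSS of a `+` strand gene is `tx_start`;
#' for a `-` strand gene it is `tx_end - 1`, the position of the first
#' transcribed base, which keeps +/- window rules symmetric across strands.
#' The TES is the opposite bound.
#'
#' @param gene_id,chrom,strand,tx_start,tx_end vectors; `strand` in `+`/`-`.
#' @param ... extra columns.
#' @return Gene tibble with derived `tss` and `tes` columns.
#' @export
gene_tbl <- function(gene_id, chrom, strand, tx_start, tx_end, ...) {
  if (!all(strand %in% c("+", "-"))) {
    abort(sprintf("unknown strand symbol '%s' (genes must be + or -)",
                  setdiff(strand, c("+", "-"))[1]))
  }
  x <- tibble(gene_id = as.character(gene_id), chrom = as.character(chrom),
              strand = strand, tx_start = as.numeric(tx_start),
              tx_end = as.numeric(tx_end), ...)
  if (any(x$tx_start < 0 | x$tx_start >= x$tx_end)) {
    abort("genes must satisfy 0 <= tx_start < tx_end")
  }
  x$tss <- ifelse(x$strand == "+", x$tx_start, x$tx_end - 1)
  x$tes <- ifelse(x$strand == "+", x$tx_end - 1, x$tx_start)
  x
}

#' Read gene annotations (refFlat-like TSV or BED6/BED12)
#'
#' refFlat-like input has columns `geneName chrom strand txStart txEnd`
#' (0-based half-open, tab-separated, optional further columns ignored).
#' BED6/BED12 input is detected by its column order (`chrom start end name
#' score strand`). Gene names appearing with more than one distinct TSS are
#' dropped when `require_single_tss` is `TRUE` (the single-TSS filter);
#' duplicate records with identical coordinates collapse to one.
#'
#' @param path input file.
#' @param require_single_tss drop multi-TSS gene names (default `TRUE`).
#' @param format `"auto"`, `"refflat"` or `"bed"`.
#' @return Gene tibble (see [gene_tbl()]); attribute `n_dropped` counts gene
#'   names removed by the single-TSS filter.
#' @export
read_genes <- function(path, require_single_tss = TRUE,
                       format = c("auto", "refflat", "bed")) {
  format <- match.arg(format)
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    out <- gene_tbl(character(), character(), character(), numeric(), numeric())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 5)) {
    abort(sprintf("%s: line %d has %d column(s); need >= 5", path, which(nf < 5)[1], min(nf)))
  }
  if (format == "auto") {
    # BED has numeric columns 2 and 3; refFlat has strand in column 3
    format <- if (all(vapply(f, `[`, "", 3) %in% c("+", "-"))) "refflat" else "bed"
  }
  if (format == "refflat") {
    raw <- tibble(gene_id = vapply(f, `[`, "", 1),
                  chrom = vapply(f, `[`, "", 2),
                  strand = vapply(f, `[`, "", 3),
                  tx_start = suppressWarnings(as.numeric(vapply(f, `[`, "", 4))),
                  tx_end = suppressWarnings(as.numeric(vapply(f, `[`, "", 5))))
  } else {
    if (any(nf < 6)) abort(sprintf("%s: BED gene input needs >= 6 columns", path))
    raw <- tibble(gene_id = vapply(f, `[`, "", 4),
                  chrom = vapply(f, `[`, "", 1),
                  strand = vapply(f, `[`, "", 6),
                  tx_start = suppressWarnings(as.numeric(vapply(f, `[`, "", 2))),
                  tx_end = suppressWarnings(as.numeric(vapply(f, `[`, "", 3))))
  }
  if (anyNA(raw$tx_start) || anyNA(raw$tx_end)) {
    abort(sprintf("%s: line %d: non-numeric coordinates", path,
                  which(is.na(raw$tx_start) | is.na(raw$tx_end))[1]))
  }
  raw <- distinct(raw)
  n_dropped <- 0L
  if (require_single_tss) {
    tss <- ifelse(raw$strand == "+", raw$tx_start, raw$tx_end - 1)
    multi <- names(which(tapply(tss, raw$gene_id, function(v) length(unique(v))) > 1))
    n_dropped <- length(multi)
    if (n_dropped > 0) {
      inform(sprintf("single-TSS filter: dropped %d gene name(s) with multiple TSSs", n_dropped))
      raw <- filter(raw, !.data$gene_id %in% multi)
    }
    raw <- distinct(raw, .data$gene_id, .keep_all = TRUE)
  }
  out <- gene_tbl(raw$gene_id, raw$chrom, raw$strand, raw$tx_start, raw$tx_end)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write genes as refFlat-like TSV
#' @param x gene tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(x, path) {
  readr::write_lines(paste(x$gene_id, x$chrom, x$strand,
                           sprintf("%d", as.integer(x$tx_start)),
                           sprintf("%d", as.integer(x$tx_end)), sep = "\t"), path)
  invisible(path)
}

#' Read strand-specific read-start coverage
#'
#' Each file holds one strand's nascent-transcription signal, either as a
#' bedGraph of per-base read-start counts (`chrom start end count`, the count
#' applying to every base of the interval) or as BED6 of reads whose 5' end is
#' taken as the tag position (`start` for `+` reads, `end - 1` for `-` reads,
#' using the file's strand column when present).
#'
#' @param path_plus,path_minus files for the two strands; either may be `NULL`.
#' @param library_size total mapped reads for RPM normalisation; defaults to
#'   the total count across both files.
#' @param condition free-text label stored on the track.
#' @return A `coverage_track`: tibble with `chrom`, `pos`, `strand`, `count`
#'   (one row per base with signal), attributes `library_size` and
#'   `condition`.
#' @export
read_coverage <- function(path_plus = NULL, path_minus = NULL,
                          library_size = NULL, condition = "") {
  one <- function(path, strand) {
    if (is.null(path)) return(NULL)
    lines <- readr::read_lines(path)
    lines <- lines[!grepl("^(#|track\\b)", lines) & nzchar(lines)]
    if (length(lines) == 0) {
      return(tibble(chrom = character(), pos = numeric(), strand = character(),
                    count = numeric()))
    }
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 4)) abort(sprintf("%s: line %d: need >= 4 columns", path, which(nf < 4)[1]))
    chrom <- vapply(f, `[`, "", 1)
    start <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2)))
    end <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3)))
    c4 <- vapply(f, `[`, "", 4)
    is_bedgraph <- all(nf == 4) && !anyNA(suppressWarnings(as.numeric(c4)))
    if (is_bedgraph) {
      val <- as.numeric(c4)
      if (any(val < 0)) abort(sprintf("%s: line %d: negative coverage value",
                                      path, which(val < 0)[1]))
      if (any(start >= end | start < 0, na.rm = TRUE) || anyNA(start) || anyNA(end)) {
        abort(sprintf("%s: invalid bedGraph coordinates", path))
      }
      keep <- val > 0
      len <- end[keep] - start[keep]
      tibble(chrom = rep(chrom[keep], len),
             pos = sequence(len, from = start[keep]),
             strand = strand,
             count = rep(val[keep], len))
    } else {
      read_strand <- if (all(nf >= 6)) vapply(f, `[`, "", 6) else rep("+", length(f))
      pos <- ifelse(read_strand == "-", end - 1, start)
      tibble(chrom = chrom, pos = pos, strand = strand, count = 1)
    }
  }
  tags <- bind_rows(one(path_plus, "+"), one(path_minus, "-"))
  coverage_track(.aggregate_tags(tags), library_size = library_size,
                 condition = condition)
}

# collapse duplicate (chrom, strand, pos) rows, summing counts; sorted output
.aggregate_tags <- function(tags) {
  if (nrow(tags) == 0) return(as_tibble(tags))
  # radix sort on integer codes; character sort is the hot spot otherwise
  o <- order(match(tags$chrom, sort(unique(tags$chrom))),
             match(tags$strand, c("+", "-", ".")), tags$pos, method = "radix")
  t <- tags[o, , drop = FALSE]
  n <- nrow(t)
  new <- c(TRUE, t$chrom[-1] != t$chrom[-n] | t$strand[-1] != t$strand[-n] |
             t$pos[-1] != t$pos[-n])
  g <- cumsum(new)
  out <- t[new, , drop = FALSE]
  out$count <- as.vector(rowsum(t$count, g))
  out
}

#' Build a coverage track from a tag tibble
#'
#' @param tags tibble with `chrom`, `pos`, `strand`, `count` (read-start
#'   counts per base).
#' @param library_size total mapped reads; defaults to `sum(tags$count)`.
#' @param condition label.
#' @return `coverage_track` tibble.
#' @export
coverage_track <- function(tags, library_size = NULL, condition = "") {
  .required_cols(tags, c("chrom", "pos", "strand", "count"), "coverage track")
  if (any(tags$count < 0)) abort("coverage counts must be >= 0")
  out <- as_tibble(tags)
  attr(out, "library_size") <- library_size %||% sum(out$count)
  attr(out, "condition") <- condition
  class(out) <- c("coverage_track", class(out))
  out
}

#' Library size of a coverage track
#' @param track a `coverage_track`.
#' @return Numeric scalar.
#' @export
library_size <- function(track) {
  attr(track, "library_size") %||% sum(track$count)
}

#' Write one strand of a coverage track as bedGraph
#' @param track `coverage_track`.
#' @param strand `"+"` or `"-"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, strand, path) {
  x <- track[track$strand == strand, , drop = FALSE]
  x <- x[order(x$chrom, x$pos), ]
  if (nrow(x) == 0) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  # collapse runs of consecutive positions with equal counts
  new_run <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                 x$pos[-1] != x$pos[-nrow(x)] + 1 |
                 x$count[-1] != x$count[-nrow(x)])
  run <- cumsum(new_run)
  s <- x$pos[!duplicated(run)]
  e <- as.numeric(tapply(x$pos, run, max)) + 1
  readr::write_lines(paste(x$chrom[!duplicated(run)],
                           sprintf("%d", as.integer(s)), sprintf("%d", as.integer(e)),
                           format(x$count[!duplicated(run)], trim = TRUE, scientific = FALSE),
                           sep = "\t"), path)
  invisible(path)
}

#' Read a gene response table
#'
#' TSV of `gene_id <tab> label` with labels `induced`, `repressed` or
#' `nonresponsive`. Duplicated consistent rows collapse with a warning;
#' conflicting labels for one gene are an error.
#'
#' @param path TSV file (optional header line `gene_id label` is skipped).
#' @return Tibble with `gene_id`, `label`.
#' @export
read_response_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  lines <- lines[!grepl("^gene_id\\b", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (length(f) > 0 && any(lengths(f) < 2)) {
    abort(sprintf("%s: line %d: need gene_id<tab>label", path, which(lengths(f) < 2)[1]))
  }
  out <- tibble(gene_id = vapply(f, `[`, "", 1), label = vapply(f, `[`, "", 2))
  allowed <- c("induced", "repressed", "nonresponsive")
  if (!all(out$label %in% allowed)) {
    abort(sprintf("%s: unknown response label '%s'; allowed: %s", path,
                  setdiff(out$label, allowed)[1], paste(allowed, collapse = ", ")))
  }
  if (anyDuplicated(out$gene_id)) {
    per <- tapply(out$label, out$gene_id, function(v) length(unique(v)))
    if (any(per > 1)) {
      abort(sprintf("%s: gene '%s' has conflicting response labels",
                    path, names(which(per > 1))[1]))
    }
    warn(sprintf("%s: %d duplicated consistent row(s) collapsed",
                 path, sum(duplicated(out))))
    out <- distinct(out)
  }
  out
}

#' Write a response table
#' @param x tibble with `gene_id`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(x, path) {
  readr::write_lines(c("gene_id\tlabel", paste(x$gene_id, x$label, sep = "\t")), path)
  invisible(path)
}

# TSV writer with a '#' comment header recording provenance (seed, config)
.write_result_tsv <- function(x, path, comments = character(0)) {
  hdr <- if (length(comments)) paste0("# ", comments) else character(0)
  body <- c(paste(names(x), collapse = "\t"),
            do.call(paste, c(lapply(x, function(col) {
              if (is.numeric(col)) format(col, trim = TRUE, scientific = FALSE, digits = 12)
              else as.character(col)
            }), sep = "\t")))
  readr::write_lines(c(hdr, if (nrow(x) == 0) body[1] else body), path)
  invisible(path)
}
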