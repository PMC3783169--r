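#' Configuration of the synthetic study generator
#'
#' Defaults define the simulated study conditions: gene counts and response
#' fractions, complex geometry, class-specific disruption probabilities
#' (`d_repressed = 0.86`, `d_induced = 0.49`), pre-treatment pause-ratio
#' distributions (induced ~ LogNormal(ln 8, 0.4), repressed ~
#' LogNormal(ln 2, 0.4)), sequencing depth, and post-treatment effect sizes
#' (induced body density x3; repressed TSS density x0.4, antisense x0.5).
#'
#' @param seed RNG seed.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes total genes; `n_induced`/`n_repressed` override the
#'   fraction-based class counts when given (e.g. to mirror a study's class
#'   sizes exactly).
#' @param gene_length_meanlog,gene_length_sdlog,gene_length_min,gene_length_max
#'   log-normal transcript-length model, truncated.
#' @param frac_induced,frac_repressed response-class fractions (rest
#'   nonresponsive).
#' @param n_background_complexes gene-free complexes added for realism.
#' @param anchors_per_complex_lambda anchors per complex = 2 + Poisson(lambda).
#' @param anchor_width_range bp range of anchor widths.
#' @param p_tss_in_anchor probability a responsive gene's TSS is covered by
#'   an anchor of its complex (else it is a loop gene).
#' @param er_sites_per_complex,er_background_per_bp binding-site placement
#'   rates inside anchors vs background.
#' @param n_pseudo_studies,study_dropout,study_jitter pseudo-study emulation
#'   of independent ChIP-seq experiments (per-study peak dropout
#'   probability; edge jitter in bp).
#' @param pause_meanlog_induced,pause_meanlog_repressed,pause_meanlog_nonresponsive,pause_sdlog
#'   pre-treatment pause-ratio distributions per class.
#' @param library_size expected reads per library.
#' @param k_elong,k_rep,k_antisense_rep post-treatment multipliers (induced
#'   body; repressed TSS; repressed antisense).
#' @param d_repressed,d_induced per-complex disruption probabilities by the
#'   response class of the enclosed gene.
#' @param p_standalone,p_loop,p_none outcome split among disrupted complexes.
#' @param antisense_frac antisense-at-TSS component as a fraction of sense
#'   TSS reads.
#' @param anchor_window,standalone_window windows the construction must
#'   respect so that truth labels are exact.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 4, chrom_length = 2e7,
                       n_genes = 800,
                       gene_length_meanlog = 9.5, gene_length_sdlog = 0.6,
                       gene_length_min = 2000, gene_length_max = 200000,
                       frac_induced = 0.30, frac_repressed = 0.25,
                       n_induced = NULL, n_repressed = NULL,
                       n_background_complexes = 250,
                       anchors_per_complex_lambda = 1,
                       anchor_width_range = c(1000, 4000),
                       p_tss_in_anchor = 0.9,
                       er_sites_per_complex = 3,
                       er_background_per_bp = 1 / 5e5,
                       n_pseudo_studies = 3, study_dropout = 0.2,
                       study_jitter = 150,
                       pause_meanlog_induced = log(8),
                       pause_meanlog_repressed = log(2),
                       pause_meanlog_nonresponsive = log(4),
                       pause_sdlog = 0.4,
                       library_size = 2e6,
                       k_elong = 3, k_rep = 0.4, k_antisense_rep = 0.5,
                       d_repressed = 0.86, d_induced = 0.49,
                       p_standalone = 0.4, p_loop = 0.4, p_none = 0.2,
                       antisense_frac = 0.2,
                       anchor_window = 5000, standalone_window = 20000) {
  cfg <- as.list(environment())
  probs <- c(cfg$frac_induced, cfg$frac_repressed, cfg$p_tss_in_anchor,
             cfg$study_dropout, cfg$d_repressed, cfg$d_induced,
             cfg$p_standalone, cfg$p_loop, cfg$p_none, cfg$antisense_frac)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (cfg$frac_induced + cfg$frac_repressed > 1) abort("response fractions sum above 1")
  if (abs(cfg$p_standalone + cfg$p_loop + cfg$p_none - 1) > 1e-9) {
    abort("p_standalone + p_loop + p_none must be 1")
  }
  structure(cfg, class = "sim_config")
}

# truncated log-normal transcript lengths
.sim_gene_lengths <- function(n, cfg) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(n, cfg$gene_length_meanlog, cfg$gene_length_sdlog)
    out <- c(out, x[x >= cfg$gene_length_min & x <= cfg$gene_length_max])
  }
  round(out[seq_len(n)])
}

# place blocks (territories) of given lengths without overlap, uniformly on
# the genome; returns chrom and start per block
.place_blocks <- function(lengths, cfg) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  occ <- setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) occ[[ch]] <- list(start = numeric(0), end = numeric(0))
  chrom <- character(length(lengths)); start <- numeric(length(lengths))
  for (i in seq_along(lengths)) {
    placed <- FALSE
    for (attempt in seq_len(1000)) {
      ch <- chroms[sample.int(length(chroms), 1)]
      s <- floor(runif(1) * (cfg$chrom_length - lengths[i] + 1))
      e <- s + lengths[i]
      o <- occ[[ch]]
      if (!any(s < o$end & e > o$start)) {
        occ[[ch]]$start <- c(o$start, s); occ[[ch]]$end <- c(o$end, e)
        chrom[i] <- ch; start[i] <- s; placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("could not place all genes/complexes without overlap in 1000 attempts; use a larger genome (chrom_length / n_chromosomes)")
    }
  }
  list(chrom = chrom, start = start)
}

# anchors around a TSS; cover_tss decides anchor-gene vs loop-gene geometry.
# All coordinates stay within tss +/- 14 kb so territories contain them.
.sim_complex_anchors <- function(tss, cover_tss, n_anchors, cfg) {
  wmin <- cfg$anchor_width_range[1]; wmax <- cfg$anchor_width_range[2]
  w <- round(runif(n_anchors, wmin, wmax))
  starts <- numeric(n_anchors)
  if (cover_tss) {
    starts[1] <- tss - round(w[1] * runif(1, 0.2, 0.8))
    if (n_anchors > 1) {
      d <- round(runif(n_anchors - 1, 6000, 10000))
      side <- sample(c(-1, 1), n_anchors - 1, replace = TRUE)
      starts[-1] <- ifelse(side > 0, tss + d, tss - d - w[-1])
    }
  } else {
    # one anchor each side, strictly outside the +/- anchor_window rule
    d1 <- round(runif(1, 6000, 10000))
    starts[1] <- tss - d1 - w[1]
    d2 <- round(runif(n_anchors - 1, 6000, 10000))
    starts[-1] <- tss + d2
  }
  tibble(start = starts, end = starts + w)
}

# chain consecutive anchors into interaction pairs
.anchors_to_pairs <- function(anchors, chrom, name_prefix) {
  a <- anchors[order(anchors$start), , drop = FALSE]
  n <- nrow(a)
  if (n < 2) {
    # a single-anchor complex is represented as a self-pair
    return(tibble(chrom_a = chrom, start_a = a$start, end_a = a$end,
                  chrom_b = chrom, start_b = a$start, end_b = a$end,
                  name = paste0(name_prefix, "_p1"), pet_count = 2 + rpois(1, 3)))
  }
  tibble(chrom_a = chrom, start_a = a$start[-n], end_a = a$end[-n],
         chrom_b = chrom, start_b = a$start[-1], end_b = a$end[-1],
         name = sprintf("%s_p%d", name_prefix, seq_len(n - 1)),
         pet_count = 2 + rpois(n - 1, 3))
}

# binding sites dropped inside randomly chosen anchors
.sites_in_anchors <- function(anchors, chrom, n_sites, width_range = c(200, 800)) {
  if (n_sites == 0 || nrow(anchors) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  pick <- sample.int(nrow(anchors), n_sites, replace = TRUE)
  w <- pmin(round(runif(n_sites, width_range[1], width_range[2])),
            anchors$end[pick] - anchors$start[pick])
  s <- anchors$start[pick] +
    floor(runif(n_sites) * (anchors$end[pick] - anchors$start[pick] - w + 1))
  tibble(chrom = chrom, start = s, end = s + w)
}

#' Simulate a self-consistent synthetic study
#'
#' Generates genes, pre-treatment (Pol II-like) chromatin complexes,
#' post-treatment (ER-like) complexes realised from per-complex disruption
#' draws, binding-site cistromes with pseudo-study replicates, stand-alone
#' binding events, strand-specific GRO-seq-like read-start coverage for both
#' conditions, and a truth table. Construction is truth-first: signal and
#' geometry are placed to match the drawn labels, and gene/complex
#' territories are kept far enough apart that the window rules cannot mix
#' neighbours, so on noiseless settings the analysis must reproduce the
#' truth exactly.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, the full file bundle
#'   (genes.tsv, response.tsv, BEDPE interactions, study BEDs, bedGraphs,
#'   truth.tsv, chrom.sizes, config.yaml) is written there.
#' @return A list: `genes`, `response`, `pairs_pre`, `pairs_post`,
#'   `er_studies` (list of pre-treatment study peak sets), `er_sites_true`,
#'   `er_sites_post`, `pioneer_sets`, `coverage_pre`, `coverage_post`,
#'   `truth`, `chrom_sizes`, `config`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes

  # response labels
  n_ind <- cfg$n_induced %||% round(cfg$frac_induced * n)
  n_rep <- cfg$n_repressed %||% round(cfg$frac_repressed * n)
  if (n_ind + n_rep > n) abort("class counts exceed n_genes")
  label <- sample(c(rep("induced", n_ind), rep("repressed", n_rep),
                    rep("nonresponsive", n - n_ind - n_rep)))

  # genes and territories (responsive genes need room for a private complex)
  len <- .sim_gene_lengths(n, cfg)
  pad <- ifelse(label == "nonresponsive", 2000, 18000)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  bg_span <- round(runif(cfg$n_background_complexes, 20000, 50000))
  blocks <- .place_blocks(c(len + 2 * pad, bg_span + 12000), cfg)
  tx_start <- blocks$start[seq_len(n)] + pad
  genes <- gene_tbl(sprintf("g%04d", seq_len(n)), blocks$chrom[seq_len(n)],
                    strand, tx_start, tx_start + len)
  response <- tibble(gene_id = genes$gene_id, label = label)

  # pre-treatment complexes: one per responsive gene (class-pure), plus
  # gene-free background complexes
  responsive <- which(label != "nonresponsive")
  in_anchor <- rep(FALSE, n)
  in_anchor[responsive] <- runif(length(responsive)) < cfg$p_tss_in_anchor
  gene_anchors <- vector("list", n)
  pairs_pre <- list()
  for (i in responsive) {
    k <- 2 + rpois(1, cfg$anchors_per_complex_lambda)
    anc <- .sim_complex_anchors(genes$tss[i], in_anchor[i], k, cfg)
    gene_anchors[[i]] <- anc
    pairs_pre[[length(pairs_pre) + 1]] <-
      .anchors_to_pairs(anc, genes$chrom[i], genes$gene_id[i])
  }
  bg_chrom <- blocks$chrom[n + seq_len(cfg$n_background_complexes)]
  bg_start <- blocks$start[n + seq_len(cfg$n_background_complexes)] + 6000
  bg_anchors <- vector("list", cfg$n_background_complexes)
  for (j in seq_len(cfg$n_background_complexes)) {
    k <- 2 + rpois(1, cfg$anchors_per_complex_lambda)
    pos <- sort(round(runif(k, 0, bg_span[j] - cfg$anchor_width_range[2])))
    w <- round(runif(k, cfg$anchor_width_range[1], cfg$anchor_width_range[2]))
    anc <- merge_intervals(tibble(chrom = "x", start = bg_start[j] + pos,
                                  end = bg_start[j] + pos + w), min_gap = -1)
    bg_anchors[[j]] <- select(anc, "start", "end")
    pairs_pre[[length(pairs_pre) + 1]] <-
      .anchors_to_pairs(bg_anchors[[j]], bg_chrom[j], sprintf("bg%04d", j))
  }
  pairs_pre <- bind_rows(pairs_pre)
  pairs_pre$inter_chromosomal <- FALSE

  # per-complex disruption by response class; outcomes among disrupted
  d_of <- c(induced = cfg$d_induced, repressed = cfg$d_repressed)
  disrupted <- rep(NA, n)
  outcome <- rep(NA_character_, n)
  for (i in responsive) {
    disrupted[i] <- runif(1) < d_of[[label[i]]]
    outcome[i] <- if (!disrupted[i]) "anchor" else
      sample(c("stand-alone", "loop", "none"), 1,
             prob = c(cfg$p_standalone, cfg$p_loop, cfg$p_none))
  }

  # post-treatment complexes and stand-alone sites realised per outcome
  pairs_post <- list()
  standalone_emitted <- list()
  er_post_anchor_sites <- list()
  for (i in responsive) {
    if (outcome[i] == "anchor") {
      anc <- gene_anchors[[i]]
      pairs_post[[length(pairs_post) + 1]] <-
        .anchors_to_pairs(anc, genes$chrom[i], paste0(genes$gene_id[i], "_er"))
      er_post_anchor_sites[[length(er_post_anchor_sites) + 1]] <-
        .sites_in_anchors(anc, genes$chrom[i], cfg$er_sites_per_complex)
    } else if (outcome[i] == "loop") {
      k <- 2 + rpois(1, cfg$anchors_per_complex_lambda)
      anc <- .sim_complex_anchors(genes$tss[i], FALSE, k, cfg)
      pairs_post[[length(pairs_post) + 1]] <-
        .anchors_to_pairs(anc, genes$chrom[i], paste0(genes$gene_id[i], "_er"))
      er_post_anchor_sites[[length(er_post_anchor_sites) + 1]] <-
        .sites_in_anchors(anc, genes$chrom[i], cfg$er_sites_per_complex)
    } else if (outcome[i] == "stand-alone") {
      d <- round(runif(1, 6000, 12000)) * sample(c(-1, 1), 1)
      w <- round(runif(1, 200, 800))
      s <- genes$tss[i] + d - if (d < 0) w else 0
      standalone_emitted[[length(standalone_emitted) + 1]] <-
        tibble(chrom = genes$chrom[i], start = s, end = s + w)
    }
  }
  # background complexes persist with probability 1/2
  for (j in seq_len(cfg$n_background_complexes)) {
    if (runif(1) < 0.5) {
      pairs_post[[length(pairs_post) + 1]] <-
        .anchors_to_pairs(bg_anchors[[j]], bg_chrom[j], sprintf("bg%04d_er", j))
      er_post_anchor_sites[[length(er_post_anchor_sites) + 1]] <-
        .sites_in_anchors(bg_anchors[[j]], bg_chrom[j], cfg$er_sites_per_complex)
    }
  }
  pairs_post <- bind_rows(pairs_post)
  if (nrow(pairs_post) > 0) pairs_post$inter_chromosomal <- FALSE

  # pre-treatment binding sites: enriched in anchors, sparse background kept
  # clear of every TSS so it can never fake stand-alone evidence
  er_true <- list()
  for (i in responsive) {
    er_true[[length(er_true) + 1]] <-
      .sites_in_anchors(gene_anchors[[i]], genes$chrom[i], cfg$er_sites_per_complex)
  }
  for (j in seq_len(cfg$n_background_complexes)) {
    er_true[[length(er_true) + 1]] <-
      .sites_in_anchors(bg_anchors[[j]], bg_chrom[j], cfg$er_sites_per_complex)
  }
  n_bg_sites <- rpois(1, cfg$er_background_per_bp * cfg$chrom_length * cfg$n_chromosomes)
  bg_sites <- list()
  guard <- cfg$standalone_window + 1000
  while (length(bg_sites) < n_bg_sites) {
    ch <- sprintf("chr%d", sample.int(cfg$n_chromosomes, 1))
    w <- round(runif(1, 200, 800))
    s <- floor(runif(1) * (cfg$chrom_length - w))
    near <- genes$chrom == ch & abs(genes$tss - (s + w / 2)) < guard
    if (!any(near)) bg_sites[[length(bg_sites) + 1]] <- tibble(chrom = ch, start = s, end = s + w)
  }
  er_sites_true <- arrange(bind_rows(c(er_true, bg_sites)), .data$chrom, .data$start)

  # pseudo-studies: dropout + edge jitter
  er_studies <- purrr::map(seq_len(cfg$n_pseudo_studies), function(s) {
    keep <- runif(nrow(er_sites_true)) >= cfg$study_dropout
    x <- er_sites_true[keep, , drop = FALSE]
    if (cfg$study_jitter > 0 && nrow(x) > 0) {
      j1 <- round(runif(nrow(x), -cfg$study_jitter, cfg$study_jitter))
      j2 <- round(runif(nrow(x), -cfg$study_jitter, cfg$study_jitter))
      x$start <- pmax(0, x$start + j1)
      x$end <- pmax(x$start + 1, x$end + j2)
    }
    x
  })
  names(er_studies) <- sprintf("study%d", seq_len(cfg$n_pseudo_studies))

  er_sites_post <- arrange(bind_rows(c(er_post_anchor_sites, standalone_emitted, bg_sites)),
                           .data$chrom, .data$start)

  # pioneer-factor peak sets: present in most complex anchors plus background
  all_anchor_tbl <- bind_rows(
    purrr::map(responsive, ~ mutate(gene_anchors[[.x]], chrom = genes$chrom[.x])),
    purrr::map(seq_len(cfg$n_background_complexes),
               ~ mutate(bg_anchors[[.x]], chrom = bg_chrom[.x]))
  )
  pioneer_sets <- purrr::map(c(foxa1 = 0.7, gata3 = 0.5), function(p) {
    pick <- which(runif(nrow(all_anchor_tbl)) < p)
    if (length(pick) == 0) {
      return(tibble(chrom = character(), start = numeric(), end = numeric()))
    }
    w <- round(runif(length(pick), 200, 600))
    a <- all_anchor_tbl[pick, , drop = FALSE]
    w <- pmin(w, a$end - a$start)
    s <- a$start + floor(runif(length(pick)) * (a$end - a$start - w + 1))
    arrange(tibble(chrom = a$chrom, start = s, end = s + w), .data$chrom, .data$start)
  })

  # true pause ratios and their post-treatment counterparts
  meanlog <- c(induced = cfg$pause_meanlog_induced,
               repressed = cfg$pause_meanlog_repressed,
               nonresponsive = cfg$pause_meanlog_nonresponsive)
  r_pre <- rlnorm(n, meanlog[label], cfg$pause_sdlog)
  tss_mult <- ifelse(label == "repressed", cfg$k_rep, 1)
  body_mult <- ifelse(label == "induced", cfg$k_elong, 1)
  anti_mult <- ifelse(label == "repressed", cfg$k_antisense_rep, 1)
  r_post <- r_pre * tss_mult / body_mult

  cov_pre <- .sim_coverage(genes, r_pre, rep(1, n), rep(1, n), rep(1, n), cfg,
                           condition = "pre")
  cov_post <- .sim_coverage(genes, r_pre, tss_mult, body_mult, anti_mult, cfg,
                            condition = "post")

  truth <- tibble(
    gene_id = genes$gene_id, response = label,
    true_pre_category = ifelse(label == "nonresponsive", "outside",
                               ifelse(in_anchor, "anchor", "loop")),
    complex_disrupted = disrupted,
    true_transition = ifelse(label == "nonresponsive" | !in_anchor, NA_character_,
                             paste0("anchor-to-", outcome)),
    true_pause_pre = r_pre, true_pause_post = r_post
  )

  chrom_sizes <- tibble(chrom = sprintf("chr%d", seq_len(cfg$n_chromosomes)),
                        size = cfg$chrom_length)
  out <- list(genes = genes, response = response, pairs_pre = pairs_pre,
              pairs_post = pairs_post, er_studies = er_studies,
              er_sites_true = er_sites_true, er_sites_post = er_sites_post,
              pioneer_sets = pioneer_sets, coverage_pre = cov_pre,
              coverage_post = cov_post, truth = truth,
              chrom_sizes = chrom_sizes, config = cfg)
  if (!is.null(out_dir)) .write_sim_bundle(out, out_dir)
  out
}

# Poisson read-start coverage per gene: sense TSS window at r x body density,
# sense body at the base density, antisense at the TSS as a fixed fraction of
# the sense TSS intensity
.sim_coverage <- function(genes, r, tss_mult, body_mult, anti_mult, cfg, condition) {
  n <- nrow(genes)
  L <- genes$tx_end - genes$tx_start
  body_len <- pmax(L - 1 - 300, 1)
  tss_len <- 600
  unit_tss <- r * tss_len * tss_mult
  unit_body <- body_len * body_mult
  unit_anti <- cfg$antisense_frac * r * tss_len * anti_mult
  lambda0 <- cfg$library_size / sum(unit_tss + unit_body + unit_anti)
  pos_l <- vector("list", 3 * n); chrom_l <- character(3 * n); strand_l <- character(3 * n)
  for (i in seq_len(n)) {
    st <- genes$strand[i]; anti_st <- if (st == "+") "-" else "+"
    w <- .tss_window(genes$tss[i], 300, st)
    if (st == "+") b <- c(genes$tss[i] + 300, genes$tx_end[i] - 1)
    else b <- c(genes$tx_start[i] + 1, genes$tss[i] - 300 + 1)
    draw <- function(lambda, lo, hi) {
      k <- rpois(1, lambda)
      if (k == 0) numeric(0) else lo + sample.int(hi - lo, k, replace = TRUE) - 1
    }
    pos_l[[3 * i - 2]] <- draw(lambda0 * unit_tss[i], w[1], w[2])
    pos_l[[3 * i - 1]] <- draw(lambda0 * unit_body[i], b[1], b[2])
    pos_l[[3 * i]] <- draw(lambda0 * unit_anti[i], w[1], w[2])
    chrom_l[(3 * i - 2):(3 * i)] <- genes$chrom[i]
    strand_l[(3 * i - 2):(3 * i)] <- c(st, st, anti_st)
  }
  reps <- lengths(pos_l)
  tags <- .aggregate_tags(tibble(chrom = rep(chrom_l, reps),
                                 pos = unlist(pos_l),
                                 strand = rep(strand_l, reps),
                                 count = 1))
  coverage_track(tags, library_size = sum(tags$count), condition = condition)
}

# write the full file bundle; deterministic content for a fixed config seed
.write_sim_bundle <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_genes(sim$genes, p("genes.tsv"))
  write_response_table(sim$response, p("response.tsv"))
  write_interactions(sim$pairs_pre, p("polII_pre.bedpe"))
  write_interactions(sim$pairs_post, p("er_post.bedpe"))
  purrr::iwalk(sim$er_studies, function(x, nm) write_bed(x, p(sprintf("er_pre_%s.bed", nm))))
  write_bed(sim$er_sites_true, p("er_sites_pre_truth.bed"))
  write_bed(sim$er_sites_post, p("er_sites_post.bed"))
  purrr::iwalk(sim$pioneer_sets, function(x, nm) write_bed(x, p(sprintf("pioneer_%s.bed", nm))))
  write_coverage(sim$coverage_pre, "+", p("gro_pre_plus.bedGraph"))
  write_coverage(sim$coverage_pre, "-", p("gro_pre_minus.bedGraph"))
  write_coverage(sim$coverage_post, "+", p("gro_post_plus.bedGraph"))
  write_coverage(sim$coverage_post, "-", p("gro_post_minus.bedGraph"))
  .write_result_tsv(sim$truth, p("truth.tsv"),
                    comments = sprintf("seed=%d", sim$config$seed))
  readr::write_lines(paste(sim$chrom_sizes$chrom, sim$chrom_sizes$size, sep = "\t"),
                     p("chrom.sizes"))
  yaml::write_yaml(unclass(sim$config), p("config.yaml"))
  invisible(out_dir)
}

#' Score pipeline output against the generator truth
#'
#' @param annotations pre-treatment annotation tibble from
#'   [categorize_genes()].
#' @param transitions transition tibble from [classify_transitions()].
#' @param pause per-gene pause tibble from [pause_ratio()] (pre-treatment).
#' @param truth truth tibble from [simulate_study()].
#' @param consensus optional consensus-site tibble, scored against
#'   `er_sites_true`.
#' @param er_sites_true optional true site tibble.
#' @return List: `category_accuracy`, `transition_confusion` (tibble),
#'   `disruption_error` (per class), `pause_spearman`, and when sites are
#'   given, `consensus_precision` / `consensus_recall` (site level).
#' @export
truth_compare <- function(annotations, transitions, pause, truth,
                          consensus = NULL, er_sites_true = NULL) {
  if (!setequal(annotations$gene_id, truth$gene_id)) {
    abort("gene ids of annotations and truth do not match")
  }
  j <- inner_join(annotations, truth, by = "gene_id")
  category_accuracy <- mean(j$category == j$true_pre_category)
  tc <- transitions %>%
    inner_join(select(truth, "gene_id", "true_transition"), by = "gene_id") %>%
    count(.data$true_transition, .data$transition)
  disr <- transitions %>%
    inner_join(select(truth, "gene_id", "complex_disrupted"), by = "gene_id") %>%
    filter(.data$response %in% c("induced", "repressed")) %>%
    group_by(.data$response) %>%
    summarise(estimated = mean(.data$disrupted), realized = mean(.data$complex_disrupted),
              n = n(), .groups = "drop")
  ps <- pause %>%
    inner_join(select(truth, "gene_id", "true_pause_pre"), by = "gene_id") %>%
    filter(!.data$flagged, is.finite(.data$pause_ratio))
  pause_spearman <- if (nrow(ps) >= 3)
    cor(ps$pause_ratio, ps$true_pause_pre, method = "spearman") else NA_real_
  out <- list(category_accuracy = category_accuracy, transition_confusion = tc,
              disruption_error = disr, pause_spearman = pause_spearman)
  if (!is.null(consensus) && !is.null(er_sites_true)) {
    out$consensus_precision <- if (nrow(consensus) > 0)
      mean(.overlaps_flag(consensus, er_sites_true)) else NA_real_
    out$consensus_recall <- if (nrow(er_sites_true) > 0)
      mean(.overlaps_flag(er_sites_true, consensus)) else NA_real_
  }
  out
}
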