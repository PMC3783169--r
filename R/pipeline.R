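.pipeline_defaults <- function() {
  list(
    simulate = NULL,        # sim_config() argument list, or TRUE for defaults
    data_dir = NULL,        # optional: write the simulated bundle here
    inputs = NULL,          # or: list of file paths (genes, response, ...)
    anchor_window = 5000,
    standalone_window = 20000,
    min_studies = 2,
    tss_window = 300,
    pseudocount = 1,
    metagene_flank = 1000,
    n_perm = 500,
    seed = 7,
    out_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list; unknown keys and type mismatches are
#' errors, missing keys are filled with defaults.
#'
#' @param config list or YAML path.
#' @return The completed config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  defaults <- .pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defaults, config)
  for (k in c("anchor_window", "standalone_window", "min_studies", "tss_window",
              "pseudocount", "metagene_flank", "n_perm", "seed")) {
    if (!is.numeric(out[[k]]) || length(out[[k]]) != 1) {
      abort(sprintf("config key '%s' must be a single number", k))
    }
  }
  if (is.null(out$simulate) && is.null(out$inputs)) {
    abort("config needs either 'simulate' or 'inputs'")
  }
  out
}

.load_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    args <- if (isTRUE(cfg$simulate)) list() else cfg$simulate
    if (is.null(args$seed)) args$seed <- cfg$seed
    sim <- simulate_study(do.call(sim_config, args), out_dir = cfg$data_dir)
    return(sim)
  }
  ins <- cfg$inputs
  for (k in c("genes", "response", "interactions_pre", "interactions_post",
              "er_studies", "er_sites_post", "chrom_sizes")) {
    if (is.null(ins[[k]])) abort(sprintf("inputs$%s is required", k))
    for (f in unlist(ins[[k]])) {
      if (is.character(f) && !file.exists(f)) abort(sprintf("input file missing: %s", f))
    }
  }
  cs <- readr::read_tsv(ins$chrom_sizes, col_names = c("chrom", "size"),
                        col_types = "cd", progress = FALSE)
  list(
    genes = read_genes(ins$genes),
    response = read_response_table(ins$response),
    pairs_pre = read_interactions(ins$interactions_pre),
    pairs_post = read_interactions(ins$interactions_post),
    er_studies = purrr::map(ins$er_studies, read_bed),
    er_sites_post = read_bed(ins$er_sites_post),
    pioneer_sets = purrr::map(ins$pioneer_sets %||% list(), read_bed),
    coverage_pre = if (!is.null(ins$coverage_pre_plus))
      read_coverage(ins$coverage_pre_plus, ins$coverage_pre_minus, condition = "pre"),
    coverage_post = if (!is.null(ins$coverage_post_plus))
      read_coverage(ins$coverage_post_plus, ins$coverage_post_minus, condition = "post"),
    truth = NULL,
    chrom_sizes = cs,
    config = NULL
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: input loading (or simulation), consensus
#' cistrome construction, complex assembly for both conditions, gene
#' categorisation, stand-alone site extraction, transition classification
#' with the chi-squared homogeneity test, pause-ratio computation and paired
#' before/after comparisons per response class, and permutation enrichment of
#' binding sites in complex anchors. Deterministic for a fixed config.
#'
#' @param config list or YAML path (see [validate_config()]).
#' @return A report list; when `config$out_dir` is set, `report.json` and TSV
#'   intermediates are written there.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dat <- .load_inputs(cfg)

  consensus <- consensus_cistrome(dat$er_studies, min_studies = cfg$min_studies)
  complexes_pre <- assemble_complexes(dat$pairs_pre)
  complexes_post <- assemble_complexes(dat$pairs_post)
  annot_pre <- categorize_genes(dat$genes, complexes_pre,
                                anchor_window = cfg$anchor_window, condition = "pre")
  annot_post <- categorize_genes(dat$genes, complexes_post,
                                 anchor_window = cfg$anchor_window, condition = "post")
  standalone <- standalone_sites(dat$er_sites_post, complexes_post)
  er_flag <- er_in_anchor_flag(annot_pre, complexes_pre,
                               consensus[c("chrom", "start", "end")])
  transitions <- classify_transitions(dat$genes, annot_pre, annot_post, standalone,
                                      response = dat$response,
                                      standalone_window = cfg$standalone_window,
                                      er_in_anchor = er_flag)
  chisq_full <- transition_contingency(transitions, collapse_to_disruption = FALSE)
  chisq_2x2 <- transition_contingency(transitions, collapse_to_disruption = TRUE)

  disrupted <- transitions %>%
    filter(.data$response %in% c("induced", "repressed")) %>%
    group_by(.data$response) %>%
    summarise(n = n(), n_disrupted = sum(.data$disrupted),
              fraction = mean(.data$disrupted), .groups = "drop") %>%
    mutate(ci_lo = purrr::map2_dbl(.data$n_disrupted, .data$n,
                                   ~ stats::binom.test(.x, .y)$conf.int[1]),
           ci_hi = purrr::map2_dbl(.data$n_disrupted, .data$n,
                                   ~ stats::binom.test(.x, .y)$conf.int[2]))

  category_counts <- annot_pre %>%
    left_join(dat$response, by = "gene_id") %>%
    count(.data$label, .data$category)
  transition_counts <- transitions %>% count(.data$response, .data$transition)

  pausing <- NULL
  if (!is.null(dat$coverage_pre) && !is.null(dat$coverage_post)) {
    pp <- pause_ratio(dat$genes, dat$coverage_pre, tss_window = cfg$tss_window,
                      pseudocount = cfg$pseudocount, condition = "pre")
    pa <- pause_ratio(dat$genes, dat$coverage_post, tss_window = cfg$tss_window,
                      pseudocount = cfg$pseudocount, condition = "post")
    by_class <- purrr::map(c(induced = "induced", repressed = "repressed"), function(cl) {
      ids <- dat$response$gene_id[dat$response$label == cl]
      list(
        pause = compare_conditions(pp[pp$gene_id %in% ids, ], pa[pa$gene_id %in% ids, ],
                                   "pause_ratio"),
        body = compare_conditions(pp[pp$gene_id %in% ids, ], pa[pa$gene_id %in% ids, ],
                                  "body_density"),
        tss = compare_conditions(pp[pp$gene_id %in% ids, ], pa[pa$gene_id %in% ids, ],
                                 "tss_density")
      )
    })
    pausing <- list(pre = pp, post = pa, tests = by_class)
  }

  enrich <- permutation_enrichment(
    consensus[c("chrom", "start", "end")],
    complex_anchors(complexes_pre)[c("chrom", "start", "end")],
    statistic = "jaccard", n_perm = cfg$n_perm, alternative = "greater",
    seed = cfg$seed, chrom_sizes = dat$chrom_sizes)

  report <- list(
    seed = cfg$seed,
    n_genes = nrow(dat$genes),
    n_consensus_sites = nrow(consensus),
    n_complexes_pre = nrow(complexes_pre),
    n_complexes_post = nrow(complexes_post),
    n_standalone_sites = nrow(standalone),
    category_counts = category_counts,
    transition_counts = transition_counts,
    disrupted_fractions = disrupted,
    chisq_transitions = list(statistic = chisq_full$statistic, df = chisq_full$df,
                             p_value = chisq_full$p_value),
    chisq_disruption = list(statistic = chisq_2x2$statistic, df = chisq_2x2$df,
                            p_value = chisq_2x2$p_value),
    pause_tests = if (!is.null(pausing))
      purrr::map(pausing$tests, ~ purrr::map(.x, as.list)),
    enrichment = list(statistic = "jaccard", observed = enrich$observed,
                      p_value = enrich$p_value, n_perm = enrich$n_perm)
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    cmt <- sprintf("seed=%d", cfg$seed)
    .write_result_tsv(annot_pre, file.path(cfg$out_dir, "annotations_pre.tsv"), cmt)
    .write_result_tsv(annot_post, file.path(cfg$out_dir, "annotations_post.tsv"), cmt)
    .write_result_tsv(transitions, file.path(cfg$out_dir, "transitions.tsv"), cmt)
    .write_result_tsv(consensus, file.path(cfg$out_dir, "consensus.tsv"), cmt)
    if (!is.null(pausing)) {
      .write_result_tsv(pausing$pre, file.path(cfg$out_dir, "pause_pre.tsv"), cmt)
      .write_result_tsv(pausing$post, file.path(cfg$out_dir, "pause_post.tsv"), cmt)
    }
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(report, "tables") <- list(annot_pre = annot_pre, annot_post = annot_post,
                                 transitions = transitions, consensus = consensus,
                                 complexes_pre = complexes_pre,
                                 complexes_post = complexes_post,
                                 pausing = pausing, truth = dat$truth)
  report
}
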