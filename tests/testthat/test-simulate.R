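# small-but-complete simulation used across these tests
small_cfg <- function(...) {
  base <- list(seed = 101, n_genes = 90, n_chromosomes = 2, chrom_length = 6e6,
               n_background_complexes = 20, library_size = 2e5)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

test_that("noiseless construction is reproduced exactly by the analysis", {
  sim <- simulate_study(small_cfg(p_tss_in_anchor = 1, study_jitter = 0,
                                  study_dropout = 0))
  cx_pre <- assemble_complexes(sim$pairs_pre)
  ann <- categorize_genes(sim$genes, cx_pre, condition = "pre")
  expect_equal(ann$category, sim$truth$true_pre_category)
  cx_post <- assemble_complexes(sim$pairs_post)
  ann_post <- categorize_genes(sim$genes, cx_post, condition = "post")
  sa <- standalone_sites(sim$er_sites_post, cx_post)
  tr <- classify_transitions(sim$genes, ann, ann_post, sa, response = sim$response)
  j <- dplyr::inner_join(tr, sim$truth, by = "gene_id")
  expect_equal(j$transition, j$true_transition)
  # constructive consistency: every anchor-truth gene has an anchor within 5 kb
  anchor_ids <- sim$truth$gene_id[sim$truth$true_pre_category == "anchor"]
  expect_true(all(ann$distance_to_nearest_anchor[ann$gene_id %in% anchor_ids] <= 5000))
})

test_that("simulation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(small_cfg(), out_dir = d1)
  simulate_study(small_cfg(), out_dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 12)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("recorded library size equals total emitted reads", {
  sim <- simulate_study(small_cfg())
  expect_equal(library_size(sim$coverage_pre), sum(sim$coverage_pre$count))
  expect_equal(library_size(sim$coverage_post), sum(sim$coverage_post$count))
})

test_that("realized disruption fractions stay within binomial error of the targets", {
  sim <- simulate_study(small_cfg(n_genes = 240, chrom_length = 1.2e7,
                                  frac_induced = 0.4, frac_repressed = 0.4))
  tt <- sim$truth[!is.na(sim$truth$complex_disrupted), ]
  for (cl in c("induced", "repressed")) {
    d <- if (cl == "induced") sim$config$d_induced else sim$config$d_repressed
    x <- tt$complex_disrupted[tt$response == cl]
    se <- sqrt(d * (1 - d) / length(x))
    expect_lt(abs(mean(x) - d), 3 * se + 1e-9)
  }
})

test_that("the generator refuses genomes too small to hold the territories", {
  expect_error(simulate_study(sim_config(seed = 1, n_genes = 400,
                                         n_chromosomes = 1, chrom_length = 1e6)),
               "larger genome")
})

test_that("truth_compare scores a faithful run and a shuffled negative control", {
  sim <- simulate_study(small_cfg(p_tss_in_anchor = 1, study_jitter = 0,
                                  study_dropout = 0))
  cx_pre <- assemble_complexes(sim$pairs_pre)
  ann <- categorize_genes(sim$genes, cx_pre)
  cx_post <- assemble_complexes(sim$pairs_post)
  ann_post <- categorize_genes(sim$genes, cx_post)
  sa <- standalone_sites(sim$er_sites_post, cx_post)
  tr <- classify_transitions(sim$genes, ann, ann_post, sa, response = sim$response)
  pp <- pause_ratio(sim$genes, sim$coverage_pre)
  cons <- consensus_cistrome(sim$er_studies)
  sc <- truth_compare(ann, tr, pp, sim$truth, consensus = cons,
                      er_sites_true = sim$er_sites_true)
  expect_equal(sc$category_accuracy, 1)
  expect_gte(sc$pause_spearman, 0.8)
  expect_gte(sc$consensus_precision, 0.99)
  expect_gte(sc$consensus_recall, 0.99)
  # shuffled truth labels drop category accuracy to chance
  shuffled <- sim$truth
  set.seed(1)
  shuffled$true_pre_category <- sample(shuffled$true_pre_category)
  sc2 <- truth_compare(ann, tr, pp, shuffled)
  expect_lt(sc2$category_accuracy, 0.8)
  expect_error(truth_compare(ann[-1, ], tr, pp, sim$truth), "do not match")
})

test_that("deeper sequencing never worsens pause-ratio recovery", {
  sp <- numeric(3)
  for (k in 1:3) {
    sim <- simulate_study(small_cfg(library_size = c(5e4, 2e5, 8e5)[k]))
    pp <- pause_ratio(sim$genes, sim$coverage_pre)
    ok <- !pp$flagged
    sp[k] <- cor(pp$pause_ratio[ok], sim$truth$true_pause_pre[ok],
                 method = "spearman")
  }
  expect_true(all(diff(sp) > -0.02))
})
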