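make_scene <- function() {
  # pre: one Pol II complex per gene; post: three fates
  pairs_pre <- tibble::tibble(
    chrom_a = "chr1", start_a = c(10000, 110000, 210000),
    end_a = c(12000, 112000, 212000),
    chrom_b = "chr1", start_b = c(30000, 130000, 230000),
    end_b = c(32000, 132000, 232000))
  # gene TSSs sit inside the first anchor of their complex
  genes <- gene_tbl(c("gA", "gB", "gC"), "chr1", "+",
                    c(11000, 111000, 211000), c(29000, 129000, 229000))
  # post: gA keeps its complex; gB gets a complex whose anchors avoid its TSS
  # but whose span covers it; gC gets nothing but a nearby stand-alone site
  pairs_post <- tibble::tibble(
    chrom_a = "chr1", start_a = c(10000, 102000), end_a = c(12000, 104000),
    chrom_b = "chr1", start_b = c(30000, 125000), end_b = c(32000, 127000))
  standalone <- interval_tbl("chr1", 221000, 221500)  # 10 kb from gC TSS
  list(genes = genes, pairs_pre = pairs_pre, pairs_post = pairs_post,
       standalone = standalone)
}

test_that("the three canonical transitions are classified and disruption inferred", {
  sc <- make_scene()
  cx_pre <- assemble_complexes(sc$pairs_pre)
  cx_post <- assemble_complexes(sc$pairs_post)
  ann_pre <- categorize_genes(sc$genes, cx_pre, condition = "pre")
  ann_post <- categorize_genes(sc$genes, cx_post, condition = "post")
  expect_equal(ann_pre$category, rep("anchor", 3))
  tr <- classify_transitions(sc$genes, ann_pre, ann_post, sc$standalone)
  expect_equal(tr$transition,
               c("anchor-to-anchor", "anchor-to-loop", "anchor-to-stand-alone"))
  expect_equal(tr$disrupted, c(FALSE, TRUE, TRUE))
  # removing the stand-alone site sends gC to anchor-to-none; the partition
  # over the four transitions is exhaustive either way
  tr2 <- classify_transitions(sc$genes, ann_pre, ann_post, sc$standalone[0, ])
  expect_equal(tr2$transition[3], "anchor-to-none")
  expect_equal(nrow(tr2), sum(ann_pre$category == "anchor"))
  expect_true(all(tr2$transition %in% paste0("anchor-to-",
                                             c("anchor", "loop", "stand-alone", "none"))))
})

test_that("annotations for unknown genes are an error", {
  sc <- make_scene()
  cx_pre <- assemble_complexes(sc$pairs_pre)
  ann <- categorize_genes(sc$genes, cx_pre)
  expect_error(classify_transitions(sc$genes[-1, ], ann, ann, sc$standalone),
               "missing from the gene list")
})

test_that("er_in_anchor_flag looks only inside the gene's complex anchors", {
  sc <- make_scene()
  cx <- assemble_complexes(sc$pairs_pre)
  ann <- categorize_genes(sc$genes, cx)
  sites <- interval_tbl("chr1", c(11500, 120000), c(11600, 120100))
  # site 1 is inside gA's anchor; site 2 is loop DNA of gB's complex
  flag <- er_in_anchor_flag(ann, cx, sites)
  expect_equal(flag$had_er_in_anchor_before[match(c("gA", "gB", "gC"), flag$gene_id)],
               c(TRUE, FALSE, FALSE))
})

test_that("chi-squared contingency reproduces the worked disruption table", {
  # repressed 124/144 disrupted vs induced 104/213 disrupted
  tab <- matrix(c(124, 20, 104, 109), nrow = 2, byrow = TRUE)
  res <- contingency_test(tab)
  expect_equal(res$statistic, 51.7547, tolerance = 1e-4)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 1e-11)
  # identity margins give a null result
  flat <- contingency_test(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # invariant under row and column swaps
  expect_equal(contingency_test(tab[2:1, ])$statistic, res$statistic)
  expect_equal(contingency_test(tab[, 2:1])$statistic, res$statistic)
  expect_error(contingency_test(matrix(c(5, 0, 7, 0), 2)), "collapse")
})

test_that("chi-squared p agrees with a Monte-Carlo multinomial null", {
  tab <- matrix(c(30, 20, 25, 25), nrow = 2, byrow = TRUE)
  res <- contingency_test(tab)
  set.seed(99)
  n <- sum(tab)
  p_cell <- outer(rowSums(tab), colSums(tab)) / n^2
  draws <- 20000
  stats <- replicate(draws, {
    sim <- matrix(stats::rmultinom(1, n, as.vector(p_cell)), 2)
    e <- outer(rowSums(sim), colSums(sim)) / n
    if (any(e == 0)) NA_real_ else sum((sim - e)^2 / e)
  })
  mc_p <- mean(stats >= res$statistic, na.rm = TRUE)
  se <- sqrt(mc_p * (1 - mc_p) / sum(!is.na(stats)))
  expect_lt(abs(mc_p - res$p_value), 3 * se + 0.005)
})

test_that("transition_contingency builds both table shapes from records", {
  rec <- tibble::tibble(
    gene_id = sprintf("g%d", 1:40),
    response = rep(c("induced", "repressed"), each = 20),
    transition = c(rep("anchor-to-anchor", 12), rep("anchor-to-loop", 8),
                   rep("anchor-to-anchor", 3), rep("anchor-to-loop", 9),
                   rep("anchor-to-stand-alone", 8)),
    disrupted = NA)
  rec$disrupted <- rec$transition != "anchor-to-anchor"
  full <- transition_contingency(rec)
  expect_equal(full$df, 2)
  coll <- transition_contingency(rec, collapse_to_disruption = TRUE)
  expect_equal(coll$df, 1)
  expect_equal(sum(coll$table), 40)
  expect_error(transition_contingency(rec[rec$response == "induced", ]),
               "both induced and repressed")
})

test_that("group_mean_test handles identical, degenerate and shifted inputs", {
  x <- c(1, 2, 3, 4)
  same <- group_mean_test(x, x, paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shifted <- group_mean_test(x + 2, x, paired = TRUE)
  expect_true(shifted$degenerate)
  expect_equal(shifted$p_value, 0)
  flat <- group_mean_test(rep(1, 5), rep(1, 5))
  expect_equal(flat$p_value, 1)
})

test_that("Welch test detects a unit shift at n = 100 almost always", {
  set.seed(7)
  rejections <- sum(replicate(200, {
    group_mean_test(rnorm(100), rnorm(100, 1))$p_value < 0.05
  }))
  expect_gte(rejections / 200, 0.99)
})
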