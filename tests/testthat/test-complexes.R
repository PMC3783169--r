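pairs_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    chrom_a = sapply(rows, `[[`, 1), start_a = as.numeric(sapply(rows, `[[`, 2)),
    end_a = as.numeric(sapply(rows, `[[`, 3)), chrom_b = sapply(rows, `[[`, 4),
    start_b = as.numeric(sapply(rows, `[[`, 5)), end_b = as.numeric(sapply(rows, `[[`, 6))
  )
}

test_that("overlapping anchors fuse and connect pairs into one complex", {
  p <- pairs_tbl(list("chr1", 1000, 2000, "chr1", 5000, 6000),
                 list("chr1", 5500, 6500, "chr1", 9000, 10000))
  cx <- assemble_complexes(p)
  expect_equal(nrow(cx), 1)
  expect_equal(cx$n_anchors, 3L)   # A, merge(B, B'), C
  expect_equal(cx$span_start, 1000)
  expect_equal(cx$span_end, 10000)
  expect_equal(cx$n_interactions, 2L)
  anc <- cx$anchors[[1]]
  expect_true(any(anc$start == 5000 & anc$end == 6500))

  p2 <- pairs_tbl(list("chr1", 0, 100, "chr1", 500, 600),
                  list("chr2", 0, 100, "chr2", 500, 600))
  expect_equal(nrow(assemble_complexes(p2)), 2)
})

test_that("assembly matches the brute-force BFS oracle on random pair sets", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(20:100, 1)
    a <- rand_intervals(n, 50000, wmax = 1500)
    b <- rand_intervals(n, 50000, wmax = 1500)
    p <- tibble::tibble(chrom_a = a$chrom, start_a = a$start, end_a = a$end,
                        chrom_b = b$chrom, start_b = b$start, end_b = b$end)
    got <- assemble_complexes(p)[c("chrom", "span_start", "span_end",
                                   "n_anchors", "n_interactions")]
    want <- oracle_components(p)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("gene categories follow the anchor-window and span rules", {
  p <- pairs_tbl(list("chr1", 38000, 42000, "chr1", 70000, 72000))
  cx <- assemble_complexes(p)
  g <- gene_tbl(c("anchor_g", "loop_g", "edge_g", "out_g"),
                "chr1", "+", c(40000, 50000, 46999, 200000),
                c(60000, 65000, 66999, 220000))
  ann <- categorize_genes(g, cx)
  expect_equal(ann$category, c("anchor", "loop", "anchor", "outside"))
  expect_equal(ann$distance_to_nearest_anchor[1], 0)
  # loop gene: nearest anchor edge 41999, distance 8001 > 5000, TSS in span
  expect_equal(ann$distance_to_nearest_anchor[2], 8001)
  # boundary gene exactly 5000 bp away is still an anchor gene (inclusive rule)
  expect_equal(ann$distance_to_nearest_anchor[3], 5000)
  expect_true(is.na(ann$complex_id[4]))
  # shrinking the window demotes but never promotes
  ann2 <- categorize_genes(g, cx, anchor_window = 2000)
  demote <- ann$category == "anchor" & ann2$category != "anchor"
  promote <- ann$category != "anchor" & ann2$category == "anchor"
  expect_false(any(promote))
  expect_true(any(demote))
})

test_that("tied anchor distances resolve to the nearest then smallest complex id", {
  p <- pairs_tbl(list("chr1", 0, 1000, "chr1", 8000, 9000),
                 list("chr1", 30000, 31000, "chr1", 40000, 41000))
  cx <- assemble_complexes(p)
  g <- gene_tbl("g_mid", "chr1", "+", 12000, 20000)  # 3001 bp from cx1, 17999 from cx2
  ann <- categorize_genes(g, cx)
  expect_equal(ann$complex_id, cx$complex_id[1])
  expect_equal(ann$distance_to_nearest_anchor, 3001)
})

test_that("stand-alone assignment uses the inclusive 20 kb TSS rule", {
  g <- gene_tbl("g1", "chr1", "+", 90000, 120000)
  expect_true(assign_standalone(g, interval_tbl("chr1", 75000, 75500))$standalone)   # 14501
  expect_false(assign_standalone(g, interval_tbl("chr1", 60000, 60100))$standalone)  # 29901
  expect_true(assign_standalone(g, interval_tbl("chr1", 89000, 91000))$standalone)   # overlap
  expect_equal(assign_standalone(g, interval_tbl("chr1", 75000, 75500))$distance, 14501)
})

test_that("complex content counts sites per complex and summarises", {
  p <- pairs_tbl(list("chr1", 0, 1000, "chr1", 8000, 9000),
                 list("chr2", 0, 1000, "chr2", 8000, 9000))
  cx <- assemble_complexes(p)
  sites <- list(er = interval_tbl("chr1", c(10, 100, 8100), c(60, 150, 8200)))
  res <- complex_content(cx, sites)
  expect_equal(sort(res$per_complex$n_sites), c(0L, 3L))
  expect_equal(res$summary$fraction_with_site, 0.5)
  expect_equal(res$summary$mean_sites_when_present, 3)
  res0 <- complex_content(cx, list(er = interval_tbl(character(), numeric(), numeric())))
  expect_true(all(res0$per_complex$n_sites == 0))
})

test_that("standalone_sites removes anything touching a complex anchor", {
  p <- pairs_tbl(list("chr1", 1000, 2000, "chr1", 5000, 6000))
  cx <- assemble_complexes(p)
  sites <- interval_tbl("chr1", c(1500, 3000, 9000), c(1600, 3100, 9100))
  sa <- standalone_sites(sites, cx)
  expect_equal(sa$start, c(3000, 9000))
})

test_that("a promoter interval widens the stand-alone catchment", {
  g <- gene_tbl("g1", "chr1", "+", 90000, 120000)
  site <- interval_tbl("chr1", 69000, 69100)  # 20901 bp from the TSS point
  expect_false(assign_standalone(g, site)$standalone)
  expect_true(assign_standalone(g, site, promoter_flank = 1000)$standalone)
})

test_that("chromosome name styles convert explicitly, never silently", {
  x <- interval_tbl(c("1", "chr2"), c(0, 0), c(10, 10))
  expect_equal(normalize_chrom_names(x, "ucsc")$chrom, c("chr1", "chr2"))
  expect_equal(normalize_chrom_names(x, "plain")$chrom, c("1", "2"))
  expect_false(overlap_any(interval_tbl("1", 0, 10),
                           interval_tbl("chr1", 0, 10))$overlaps)
})
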