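test_that("region_rpm normalises counts by library size", {
  spec <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000,
                         strand = "+", reads = 50)
  tr <- make_track(spec, library_size = 1e6, seed = 1)
  expect_equal(region_rpm(tr, interval_tbl("chr1", 1000, 2000)), 50)
  expect_equal(region_rpm(tr, interval_tbl("chr1", 5000, 6000)), 0)
  expect_warning(out <- region_rpm(tr, interval_tbl("chr9", 0, 100)), "absent")
  expect_equal(out, 0)
  expect_error(region_rpm(tr, interval_tbl("chr1", 0, 10), lib = 0), "library_size")
})

test_that("region_rpm agrees with a dense-array oracle and is linear", {
  set.seed(31)
  pos <- sample.int(5000, 400, replace = TRUE) - 1
  tr <- coverage_track(tibble::tibble(chrom = "chr1", pos = pos, strand = "+",
                                      count = 1) |>
                         dplyr::count(chrom, pos, strand, name = "count"),
                       library_size = 400)
  dense <- numeric(5000)
  for (p in pos) dense[p + 1] <- dense[p + 1] + 1
  for (rep in 1:20) {
    s <- sample.int(4000, 1); e <- s + sample.int(900, 1)
    expect_equal(region_rpm(tr, interval_tbl("chr1", s, e)),
                 sum(dense[(s + 1):e]) * 1e6 / 400)
  }
  # linearity over disjoint regions
  a <- region_rpm(tr, interval_tbl("chr1", 0, 2500))
  b <- region_rpm(tr, interval_tbl("chr1", 2500, 5000))
  expect_equal(a + b, region_rpm(tr, interval_tbl("chr1", 0, 5000)))
  # doubling counts and library size leaves RPM unchanged
  tr2 <- coverage_track(dplyr::mutate(tibble::as_tibble(tr), count = count * 2),
                        library_size = 800)
  expect_equal(region_rpm(tr2, interval_tbl("chr1", 0, 5000)),
               region_rpm(tr, interval_tbl("chr1", 0, 5000)))
})

test_that("uniform coverage yields a flat metagene at the RPM level", {
  genes <- gene_tbl(c("g1", "g2"), "chr1", c("+", "-"),
                    c(10000, 40000), c(18000, 52000))
  tr <- flat_track("chr1", 0, 60000, value = 3, library_size = 1e6)
  mg <- metagene_profile(genes, tr, flank = 500)
  level <- 2 * 3 * 1e6 / 1e6  # both strands summed
  expect_true(all(abs(mg$rpm - level) / level < 1e-6))
})

test_that("a linear ramp body reproduces closed-form bin means", {
  L <- 12000; flank <- 500
  genes <- gene_tbl("g1", "chr1", "+", 0, L)
  body_len <- L - 2 * flank
  ramp <- tibble::tibble(chrom = "chr1", pos = seq(flank, L - flank - 1),
                         strand = "+", count = seq_len(body_len))
  tr <- coverage_track(ramp, library_size = 1e6)
  mg <- metagene_profile(genes, tr, flank = flank)
  got <- mg$rpm[mg$segment == "body"]
  # spline is exact on linear data: bin means of the line y(x) = x over [1, body_len]
  xout <- seq(1, body_len, length.out = 1000)
  want <- colMeans(matrix(xout, nrow = 10))
  expect_true(all(abs(got - want) / want < 0.01))
})

test_that("zero coverage gives an all-zero profile and short genes are excluded", {
  genes <- gene_tbl(c("g1", "short"), "chr1", "+", c(0, 30000), c(12000, 31000))
  tr <- coverage_track(tibble::tibble(chrom = "chr1", pos = 5, strand = "+", count = 0),
                       library_size = 100)
  mg <- metagene_profile(genes, tr, flank = 500)
  expect_true(all(mg$rpm == 0))
  expect_equal(attr(mg, "n_genes"), 1L)
  expect_equal(attr(mg, "n_excluded"), 1L)
  expect_error(metagene_profile(genes[2, ], tr, flank = 500), "long enough")
})

test_that("initiation rates are strand-aware and mirror-symmetric", {
  # + strand gene with 30 sense, 10 antisense reads at the TSS
  gp <- gene_tbl("gp", "chr1", "+", 5000, 15000)
  sp <- tibble::tibble(chrom = "chr1", start = c(4700, 4700), end = c(5300, 5300),
                       strand = c("+", "-"), reads = c(30, 10))
  trp <- make_track(sp, library_size = 1e6, seed = 5)
  rp <- initiation_rate(gp, trp)
  expect_equal(rp$sense_rpm, 30)
  expect_equal(rp$antisense_rpm, 10)
  # mirrored - strand gene: flip the genome around the TSS
  G <- 20000
  gm <- gene_tbl("gm", "chr1", "-", G - 15000, G - 5000)  # tss = G - 5001... see below
  # mirror positions: p -> G - 1 - p
  tagp <- tibble::as_tibble(trp)
  tagm <- dplyr::mutate(tagp, pos = G - 1 - pos,
                        strand = ifelse(strand == "+", "-", "+"))
  trm <- coverage_track(tagm, library_size = 1e6)
  rm_ <- initiation_rate(gm, trm)
  expect_equal(rm_$sense_rpm, rp$sense_rpm)
  expect_equal(rm_$antisense_rpm, rp$antisense_rpm)
})

test_that("pause ratio reproduces exact density arithmetic", {
  # 60 reads in the 600 bp TSS window (0.1/bp), 197 in a 19,700 bp body (0.01/bp)
  g <- gene_tbl("g1", "chr1", "+", 10000, 30001)  # L = 20001, body = 19700
  spec <- tibble::tibble(chrom = "chr1",
                         start = c(9700, 10300), end = c(10300, 30000),
                         strand = "+", reads = c(60, 197))
  tr <- make_track(spec, library_size = 1e6, seed = 9)
  ps <- pause_ratio(g, tr, pseudocount = 0)
  expect_equal(ps$pause_ratio, 10, tolerance = 1e-12)
  # zero body reads without pseudocount: undefined and flagged
  spec0 <- spec; spec0$reads <- c(60, 0)
  ps0 <- pause_ratio(g, make_track(spec0, library_size = 1e6, seed = 9),
                     pseudocount = 0)
  expect_true(ps0$flagged)
  expect_true(is.na(ps0$pause_ratio))
  # with the pseudocount the ratio is finite and monotone in the TSS counts
  ps1 <- pause_ratio(g, tr)
  spec2 <- spec; spec2$reads <- c(120, 197)
  ps2 <- pause_ratio(g, make_track(spec2, library_size = 1e6, seed = 9))
  expect_gt(ps2$pause_ratio, ps1$pause_ratio)
  # too-short genes are skipped with a flag
  tiny <- gene_tbl("tiny", "chr1", "+", 0, 500)
  expect_true(pause_ratio(tiny, tr)$flagged)
})

test_that("pause-ratio estimates recover true density ratios within 10%", {
  set.seed(33)
  for (r in c(1, 5, 20)) {
    n <- 60
    starts <- seq(0, by = 40000, length.out = n)
    genes <- gene_tbl(sprintf("g%d", 1:n), "chr1", "+", starts, starts + 20000)
    lam_body <- 0.05
    spec <- dplyr::bind_rows(
      tibble::tibble(chrom = "chr1", start = genes$tss - 300, end = genes$tss + 300,
                     strand = "+", reads = rpois(n, r * lam_body * 600)),
      tibble::tibble(chrom = "chr1", start = genes$tss + 300, end = genes$tx_end - 1,
                     strand = "+", reads = rpois(n, lam_body * (20000 - 301)))
    )
    tr <- make_track(spec, library_size = 2e6)
    ps <- pause_ratio(genes, tr)
    expect_lt(abs(median(ps$pause_ratio) / r - 1), 0.1)
  }
})

test_that("compare_conditions reports direction and paired significance", {
  set.seed(34)
  before <- tibble::tibble(gene_id = sprintf("g%d", 1:30),
                           pause_ratio = rlnorm(30, log(8), 0.3))
  same <- compare_conditions(before, before, "pause_ratio")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  doubled <- dplyr::mutate(before, pause_ratio = pause_ratio * 2)
  res <- compare_conditions(before, doubled, "pause_ratio")
  expect_equal(res$direction, "increase")
  expect_lt(res$p_value, 1e-6)
  expect_error(compare_conditions(before[1, ], before[1, ], "pause_ratio"),
               "fewer than 2")
})

test_that("raw-total pause mode drops the per-kb normalisation", {
  g <- gene_tbl("g1", "chr1", "+", 10000, 30001)
  spec <- tibble::tibble(chrom = "chr1", start = c(9700, 10300),
                         end = c(10300, 30000), strand = "+", reads = c(60, 197))
  tr <- make_track(spec, library_size = 1e6, seed = 9)
  raw <- pause_ratio(g, tr, pseudocount = 0, per_kb = FALSE)
  expect_equal(raw$pause_ratio, 60 / 197, tolerance = 1e-12)
})
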