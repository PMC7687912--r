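test_that("snp offsets are midpoint-relative and orientable", {
  tt <- tibble::tibble(id = c("a", "b"), contig = "chr1",
                       minus_pos = c(930L, 4930L), plus_pos = c(1070L, 5070L),
                       midpoint = c(1000L, 5000L), width = 140L,
                       class = "enhancer", dominant = c("+", "-"))
  snps <- tibble::tibble(contig = "chr1", pos = c(900L, 1500L, 5200L, 9000L))
  off <- snp_offsets(snps, tt)
  expect_equal(off$offset, c(-100L, 500L, 200L))  # 9000 is beyond the span
  expect_equal(off$element_id, c("a", "a", "b"))
  flipped <- snp_offsets(snps, tt, orient = TRUE)
  expect_equal(flipped$offset, c(-100L, 500L, -200L))
})

test_that("region partition covers every offset exactly once with precedence", {
  offs <- -2000:2000
  lab <- classify_region(offs, minus_off = -70, plus_off = 70)
  expect_equal(length(lab), length(offs))
  expect_true(all(lab %in% c("center", "core", "ncnc", "out", "far_out")))
  # worked positions
  expect_equal(classify_region(0L, -70, 70), "center")
  expect_equal(classify_region(70L, -70, 70), "core")
  expect_equal(classify_region(-70L, -70, 70), "core")
  expect_equal(classify_region(35L, -70, 70), "ncnc")
  expect_equal(classify_region(150L, -70, 70), "out")
  expect_equal(classify_region(1500L, -70, 70), "far_out")
  # center precedence at narrow elements whose cores overlap it
  expect_equal(classify_region(0L, -20, 20), "center")
  expect_error(classify_region(3000L, -70, 70), "window")

  # fuzz: random geometries still produce a complete partition
  set.seed(41)
  for (i in 1:20) {
    co <- sample(30:150, 1)
    lab <- classify_region(-2000:2000, -co, co,
                           out_margin = sample(c(0, 100, 200), 1))
    expect_false(anyNA(lab))
  }
})

test_that("regional frequencies and Fisher tests behave like the oracle", {
  # balanced table: odds ratio 1, p = 1
  snps <- tibble::tibble(
    region = rep(c("core", "far_out"), each = 20),
    is_qtl = rep(c(TRUE, FALSE, TRUE, FALSE), each = 10))
  out <- regional_frequency_test(snps)
  expect_equal(out$p[out$region == "core"], 1)

  # 2x2 (8,2;1,9) against an exhaustive hypergeometric-tail oracle
  snps2 <- tibble::tibble(
    region = rep(c("core", "far_out"), c(10, 10)),
    is_qtl = c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 1), rep(FALSE, 9)))
  out2 <- regional_frequency_test(snps2)
  # enumerate P(X = k) over all tables with the same margins
  prob <- dhyper(0:9, 9, 11, 10)
  p_oracle <- sum(prob[prob <= dhyper(8, 9, 11, 10) * (1 + 1e-7)])
  expect_equal(out2$p[out2$region == "core"], p_oracle, tolerance = 1e-12)

  # zero QTLs everywhere: frequencies zero, tests skipped
  snps3 <- tibble::tibble(region = rep(c("core", "far_out"), each = 5),
                          is_qtl = FALSE)
  out3 <- regional_frequency_test(snps3)
  expect_true(all(out3$frequency == 0))
  expect_true(all(is.na(out3$p)))
  expect_error(regional_frequency_test(snps3[snps3$region == "core", ]),
               "far_out")
})

test_that("Fisher p is symmetric under table transposition", {
  t1 <- matrix(c(8, 2, 1, 9), 2)
  expect_equal(fisher.test(t1)$p.value, fisher.test(t(t1))$p.value)
})

test_that("overlap enrichment computes folds and the hypergeometric p", {
  bg <- paste0("t", 1:40)
  ann <- paste0("t", c(1:10))
  # QTL set equal to background: fold 1
  expect_equal(overlap_enrichment(bg, ann, bg)$fold, 1)
  # disjoint annotation: fold 0
  expect_equal(overlap_enrichment(paste0("t", 11:20), ann, bg)$fold, 0)
  # synthetic 2x2 vs the hypergeometric oracle
  qtl <- paste0("t", c(1:6, 31:34))  # 6 of 10 overlap
  res <- overlap_enrichment(qtl, ann, bg)
  tab <- matrix(c(6, 4, 10, 30), 2, byrow = TRUE)
  expect_equal(res$p, fisher.test(tab)$p.value)
  expect_equal(res$fold, (6 / 10) / (10 / 40))
  expect_error(overlap_enrichment(qtl, ann, character()), "background")
})

test_that("QQ comparison matches the exact KS oracle and detects shifts", {
  # subset equal to the full set: D = 0, p = 1
  p <- runif(100, 0.2, 0.8)
  same <- qq_compare(p, p)
  expect_equal(same$ks_stat, 0)
  expect_equal(same$ks_p, 1)

  # n = 5 instance: D equals the hand-computed statistic
  a <- c(0.1, 0.2, 0.5, 0.7, 0.9)
  b <- c(0.15, 0.4, 0.6, 0.8, 0.95)
  qc <- qq_compare(a, b)
  d_oracle <- max(vapply(sort(c(a, b)), function(x)
    abs(mean(a <= x) - mean(b <= x)), numeric(1)))
  expect_equal(qc$ks_stat, d_oracle)

  # stochastically smaller subset sits above the diagonal
  set.seed(43)
  shifted <- qq_compare(rbeta(500, 0.3, 1), runif(5000))
  expect_lt(shifted$ks_p, 1e-6)
  expect_gt(mean(shifted$points$observed >= shifted$points$expected), 0.9)
  expect_error(qq_compare(numeric(), p), "non-empty")
})

test_that("element-gene correlation matches the covariance formula", {
  tt <- tibble::tibble(id = "t1", contig = "chr1", minus_pos = 930L,
                       plus_pos = 1070L, midpoint = 1000L, width = 140L,
                       class = "enhancer")
  genes <- tibble::tibble(gene = c("g1", "g2"), contig = "chr1",
                          position = c(2000L, 1500L), strand = c("+", "-"))
  x <- matrix(c(1, 3, 2, 5, 4), nrow = 1,
              dimnames = list("t1", paste0("i", 1:5)))
  y <- matrix(c(2, 4, 1, 6, 5, 1, 1, 2, 2, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("i", 1:5)))
  out <- ttre_gene_correlation(x, tt, y, genes)
  r_oracle <- sum((x[1, ] - mean(x[1, ])) * (y[1, ] - mean(y[1, ]))) /
    sqrt(sum((x[1, ] - mean(x[1, ]))^2) * sum((y[1, ] - mean(y[1, ]))^2))
  expect_equal(out$r[out$gene == "g1"], r_oracle)
  # identical vectors give r = 1
  y2 <- rbind(g1 = x[1, ], g2 = x[1, ])
  out2 <- ttre_gene_correlation(x, tt, y2, genes)
  expect_equal(out2$r, c(1, 1))
  # signed distance is strand-relative: g1(+) at 2000 has the element
  # 1000 bp upstream (negative); g2(-) at 1500 sees it downstream
  expect_equal(out$distance[out$gene == "g1"], -1000L)
  expect_equal(out$distance[out$gene == "g2"], 500L)

  # independent vectors across many pairs: mean r near 0
  set.seed(44)
  ttm <- tibble::tibble(id = paste0("t", 1:50), contig = "chr1",
                        minus_pos = seq(1000L, 50000L, by = 1000L)[1:50] - 70L,
                        plus_pos = seq(1000L, 50000L, by = 1000L)[1:50] + 70L,
                        midpoint = seq(1000L, 50000L, by = 1000L)[1:50],
                        width = 140L, class = "enhancer")
  gm <- tibble::tibble(gene = paste0("g", 1:20), contig = "chr1",
                       position = seq(2000L, 40000L, by = 2000L),
                       strand = "+")
  xm <- matrix(rnorm(50 * 67), 50, dimnames = list(ttm$id, paste0("i", 1:67)))
  ym <- matrix(rnorm(20 * 67), 20, dimnames = list(gm$gene, paste0("i", 1:67)))
  rr <- ttre_gene_correlation(xm, ttm, ym, gm)
  expect_gt(nrow(rr), 500)
  expect_lt(abs(mean(rr$r)), 0.02)
})

test_that("positional enrichment is calibrated under a uniform null", {
  set.seed(45)
  tt <- tibble::tibble(id = paste0("t", 1:10), contig = "chr1",
                       minus_pos = seq(5000L, 50000L, by = 5000L) - 70L,
                       plus_pos = seq(5000L, 50000L, by = 5000L) + 70L,
                       midpoint = seq(5000L, 50000L, by = 5000L),
                       width = 140L, class = "enhancer")
  all_snps <- tibble::tibble(
    contig = "chr1",
    pos = as.integer(rep(tt$midpoint, each = 200) +
                       sample(-2000:2000, 2000, replace = TRUE)))
  qtls <- all_snps[sample(nrow(all_snps), 100), ]
  prof <- positional_enrichment(qtls, tt, all_snps, n_resample = 2000,
                                bin = 100)
  # QTLs drawn uniformly from the background: ~99% of bins in the band
  inside <- mean(prof$observed >= prof$bg_lo & prof$observed <= prof$bg_hi)
  expect_gt(inside, 0.9)

  # all QTLs at offset zero: the central bin escapes the band
  qtls0 <- tibble::tibble(contig = "chr1", pos = tt$midpoint)
  prof0 <- positional_enrichment(qtls0, tt, all_snps, n_resample = 2000,
                                 bin = 100)
  central <- which.min(abs(prof0$offset))
  expect_gt(prof0$observed[central], prof0$bg_hi[central])
  expect_equal(profile_peak(prof0), prof0$offset[central])
})

test_that("warning fires when background is smaller than the QTL set", {
  tt <- tibble::tibble(id = "t", contig = "chr1", minus_pos = 930L,
                       plus_pos = 1070L, midpoint = 1000L, width = 140L,
                       class = "enhancer")
  bg <- tibble::tibble(contig = "chr1", pos = c(900L, 1100L))
  qtl <- tibble::tibble(contig = "chr1", pos = c(900L, 950L, 1050L))
  expect_warning(positional_enrichment(qtl, tt, bg, n_resample = 50),
                 "replacement")
})
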