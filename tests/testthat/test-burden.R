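# Exact 2x2 tests, odds-ratio conventions, burden statistics and the
# permutation grid.

test_that("exact test reproduces reference p-values, CMLE and CI on random
           tables", {
  set.seed(71)
  for (i in 1:60) {
    a <- rpois(1, 3); b <- rpois(1, 15); c_ <- rpois(1, 3)
    d <- rpois(1, 20)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0) next
    m <- matrix(c(a, b, c_, d), 2)
    fe <- fisherExact(a, b, c_, d)
    ft <- stats::fisher.test(m)
    expect_equal(fe$p_two, ft$p.value, tolerance = 1e-12)
    expect_equal(fe$p_one,
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    # reference implementation solves its unirooting at lower precision,
    # so bounds agree to ~0.5% relative
    if (is.finite(fe$or_cmle) && fe$or_cmle > 0)
      expect_equal(fe$or_cmle, unname(ft$estimate), tolerance = 5e-3)
    expect_equal(fe$ci95[1], ft$conf.int[1], tolerance = 1e-2)
    if (is.finite(fe$ci95[2]))
      expect_equal(fe$ci95[2], ft$conf.int[2], tolerance = 1e-2)
  }
})

test_that("exact test handles degenerate tables per the stated
           conventions", {
  # no carriers anywhere: p = 1, odds ratio undefined
  r <- fisherExact(0, 10, 0, 10)
  expect_identical(r$p_two, 1)
  expect_true(is.nan(r$or_sample))
  # all-zero table is an error
  expect_error(fisherExact(0, 0, 0, 0), "empty")
  # carrier count at its margin maximum: infinite upper CI bound
  r2 <- fisherExact(5, 5, 0, 10)
  expect_identical(r2$ci95[2], Inf)
  expect_identical(r2$or_sample, Inf)
})

test_that("sample odds ratio matches the printed-table arithmetic", {
  expect_equal(round(oddsRatioSample(74, 2649, 4, 344), 2), 2.40)
  expect_equal(round(oddsRatioSample(5, 136, 2, 346), 2), 6.36)
  expect_equal(oddsRatioSample(2, 8, 1, 9), 2.25)
  # transposition invariance and row-swap inversion
  set.seed(72)
  for (i in 1:25) {
    t4 <- rpois(4, 6) + 1
    or1 <- oddsRatioSample(t4[1], t4[2], t4[3], t4[4])
    expect_equal(oddsRatioSample(t4[1], t4[3], t4[2], t4[4]), or1)
    expect_equal(oddsRatioSample(t4[2], t4[1], t4[4], t4[3]), 1 / or1)
  }
})

test_that("Bonferroni thresholds report both precisions", {
  expect_identical(bonferroni(0.05, 63)$threshold_2sf, 0.00079)
  expect_identical(bonferroni(0.05, 1)$threshold, 0.05)
  expect_identical(bonferroni(0.05, 5)$threshold, 0.01)
})

test_that("per-sample burden statistics compute the seven measures with
           correct zero handling", {
  genes <- GenomicRanges::GRanges(
    "2", IRanges::IRanges(c(10e6, 30e6, 50e6), width = 5e6))
  S4Vectors::mcols(genes)$label <- paste0("g", 1:3)
  df <- data.frame(sample_id = c("sA", "sA", "sB"), chrom = "2",
                   start = c(11e6, 31e6, 80e6),
                   end = c(11e6 + 150e3 - 1, 31e6 + 250e3 - 1,
                           80e6 + 500e3 - 1),
                   cn = c(1L, 1L, 3L), n_markers = 3L)
  gr <- karyoCNV:::makeCnvCalls(df$sample_id, df$chrom, df$start, df$end,
                                df$cn, df$n_markers, "a")
  S4Vectors::mcols(gr)$length_bp <- width(gr)
  gr <- annotateCnvs(gr, genes)
  st <- burdenStatistics(gr, c("sA", "sB", "sC"))

  delA <- st[st$cnv_class == "deletion" & st$sample_id == "sA", ]
  expect_identical(delA$n_cnv, 2L)
  expect_equal(delA$total_kb, 400)
  expect_equal(delA$mean_length_kb, 200)
  expect_identical(delA$carrier, 1L)
  expect_equal(delA$genes_total, 2)
  expect_equal(delA$genes_per_cnv, 1)
  expect_equal(delA$n_genic, 2)

  # CNV-free sample: zero counts, NA per-CNV means
  allC <- st[st$cnv_class == "all" & st$sample_id == "sC", ]
  expect_identical(allC$carrier, 0L)
  expect_identical(allC$n_cnv, 0L)
  expect_identical(allC$total_kb, 0)
  expect_true(is.na(allC$mean_length_kb))

  # hand-computed genes-per-CNV across a small cohort
  allA <- st[st$cnv_class == "all" & st$sample_id == "sA", ]
  expect_equal(allA$genes_per_cnv, 1)     # 2 genes over 2 CNVs
  dupB <- st[st$cnv_class == "duplication" & st$sample_id == "sB", ]
  expect_equal(dupB$genes_per_cnv, 0)
})

test_that("permutation burden test is deterministic, add-one corrected,
           and hits the extreme-table limit", {
  v <- c(rep(5, 10), rep(0, 10))
  isCase <- rep(c(TRUE, FALSE), each = 10)
  r <- permutationBurden(v, isCase, nPerm = 999, seed = 5)
  expect_equal(r$perm_p, 1 / 1000)
  expect_equal(r$observed, 5)

  # deterministic under seed
  r2 <- permutationBurden(v, isCase, nPerm = 999, seed = 5)
  expect_identical(r, r2)

  # constant statistic gives p = 1
  r3 <- permutationBurden(rep(2, 20), isCase, nPerm = 99, seed = 1)
  expect_identical(r3$perm_p, 1)

  # doubling nPerm leaves the observed statistic unchanged
  r4 <- permutationBurden(v, isCase, nPerm = 1998, seed = 5)
  expect_identical(r4$observed, r$observed)
})

test_that("the burden grid enumerates 3 x 3 x 7 = 63 tests and applies the
           corrected threshold", {
  g <- burdenTestGrid()
  expect_identical(nrow(g), 63L)
  expect_identical(length(unique(g$test_id)), 63L)
  expect_identical(length(unique(g$contrast)), 3L)
  expect_identical(length(unique(g$cnv_class)), 3L)
  expect_identical(length(unique(g$statistic)), 7L)

  set.seed(73)
  sids <- sprintf("s%03d", 1:60)
  st <- do.call(rbind, lapply(c("all", "deletion", "duplication"),
    function(kl) data.frame(sample_id = sids, cnv_class = kl,
                            carrier = rbinom(60, 1, 0.3),
                            n_cnv = rpois(60, 1),
                            total_kb = rexp(60, 1 / 200),
                            mean_length_kb = rexp(60, 1 / 150),
                            genes_total = rpois(60, 2),
                            genes_per_cnv = runif(60, 0, 3),
                            n_genic = rpois(60, 1))))
  cohorts <- setNames(rep(c("case", "screened_control",
                            "population_control"), 20), sids)
  res <- runBurdenGrid(st, cohorts, nPerm = 99, seed = 9)
  expect_identical(nrow(res), 63L)
  expect_true(all(res$perm_p > 0 & res$perm_p <= 1))
  expect_equal(attr(res, "alpha_bonferroni"), 0.05 / 63)
  res2 <- runBurdenGrid(st, cohorts, nPerm = 99, seed = 9)
  expect_identical(res$perm_p, res2$perm_p)
})
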