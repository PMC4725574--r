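# Sample QC, multi-algorithm merging, filter tiers, rarity, annotation.

test_that("sample QC passes clean samples and cites the violated metric", {
  map <- testMap()
  cfg <- cohortConfig(n = c(case = 20), classProportions = c(XX = 1),
                      cnvRate = 0.5)
  sim <- simulateCohort(cfg, map, NoiseModel(), seed = 61)
  cs <- simulateCallsets(sim$truth, map, seed = 62)
  qc <- sampleQc(sim$profiles, cs)
  expect_gte(mean(qc$pass), 0.95)

  # doubled LRR noise fails with lrr_sd cited
  noisy <- simulateCohort(cfg, map, NoiseModel(lrrSd = 0.6), seed = 61)
  qc2 <- sampleQc(noisy$profiles, cs)
  expect_true(all(!qc2$pass))
  expect_true(all(grepl("lrr_sd", qc2$fail_reason)))

  # 100 calls from one algorithm against a ceiling of 30 fails
  many <- data.frame(sample_id = "case_0001",
                     chrom = rep(as.character(1:20), each = 5),
                     start = rep(seq(1e6, 41e6, by = 1e7), 20))
  many$end <- many$start + 2e6
  many$cn <- 1L
  many$n_markers <- 3L
  cs3 <- callsetsFrom(many, "pennCNV")
  qc3 <- sampleQc(sim$profiles, cs3)
  expect_false(qc3$pass[qc3$sample_id == "case_0001"])
  expect_match(qc3$fail_reason[qc3$sample_id == "case_0001"],
               "call_count")
})

test_that("merging groups same-state overlapping calls, honours support
           minima, and keeps intersection inside every member", {
  map <- testMap()
  one <- data.frame(sample_id = "s1", chrom = "2", start = 10e6,
                    end = 14e6, cn = 1L, n_markers = 5L)
  cs <- callsetsFrom(one)
  cons <- mergeCallsets(cs, map, minSupport = 3)
  expect_length(cons, 1)
  expect_identical(S4Vectors::mcols(cons)$n_support, 3L)
  expect_identical(S4Vectors::mcols(cons)$support,
                   "iPattern,pennCNV,quantiSNP")

  # single-algorithm support dropped under the three-algorithm rule
  solo <- callsetsFrom(one, "pennCNV")
  solo$quantiSNP <- solo$pennCNV[0]
  solo$iPattern <- solo$pennCNV[0]
  expect_length(mergeCallsets(solo, map, minSupport = 3), 0)
  expect_length(mergeCallsets(solo, map, minSupport = 1), 1)

  # deletions and duplications never merge even when overlapping
  mixed <- list(
    pennCNV = karyoCNV:::makeCnvCalls("s1", "2", 10e6, 14e6, 1L, 5L,
                                      "pennCNV"),
    quantiSNP = karyoCNV:::makeCnvCalls("s1", "2", 11e6, 15e6, 3L, 5L,
                                        "quantiSNP"))
  cons2 <- mergeCallsets(mixed, map, minSupport = 1)
  expect_length(cons2, 2)
  expect_setequal(S4Vectors::mcols(cons2)$state,
                  c("deletion", "duplication"))

  # jittered call sets: consensus count equals truth count and the strict
  # interval is contained in every contributing call
  cfg <- cohortConfig(n = c(case = 30), classProportions = c(XX = 1),
                      cnvRate = 1.5)
  sim <- simulateCohort(cfg, map, NoiseModel(), seed = 63)
  cs2 <- simulateCallsets(sim$truth, map,
                          error = list(fpRate = 0, fnRate = 0,
                                       jitterSd = 5000), seed = 64)
  cons3 <- mergeCallsets(cs2, map, minSupport = 3)
  expect_identical(length(cons3), nrow(truthCnvs(sim$truth)))
  allCalls <- unlist(GenomicRanges::GRangesList(lapply(cs2, function(g) {
    S4Vectors::mcols(g) <- S4Vectors::mcols(g)[c("sample_id", "state")]
    g
  })))
  bad <- 0L
  for (i in seq_along(cons3)) {
    member <- S4Vectors::mcols(allCalls)$sample_id ==
      S4Vectors::mcols(cons3)$sample_id[i] &
      S4Vectors::mcols(allCalls)$state == S4Vectors::mcols(cons3)$state[i]
    ov <- IRanges::subsetByOverlaps(allCalls[member], cons3[i])
    if (!all(start(ov) <= start(cons3[i]) & end(ov) >= end(cons3[i])))
      bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("merging is idempotent and invariant to call order", {
  map <- testMap()
  set.seed(65)
  df <- data.frame(sample_id = sample(c("s1", "s2"), 12, TRUE),
                   chrom = sample(c("3", "7"), 12, TRUE),
                   start = sample(seq(5e6, 60e6, by = 5e5), 12))
  df$end <- df$start + sample(c(1e6, 3e6), 12, TRUE)
  df$cn <- sample(c(1L, 3L), 12, TRUE)
  df$n_markers <- 4L
  cs <- list(pennCNV = callsetsFrom(df[1:6, ], "pennCNV")[[1]],
             quantiSNP = callsetsFrom(df[7:12, ], "quantiSNP")[[1]])
  cons <- mergeCallsets(cs, map, minSupport = 1)
  # remerge the consensus with itself: nothing changes
  again <- mergeCallsets(list(a = cons), map, minSupport = 1)
  expect_identical(granges(again), granges(cons))
  # shuffled input order gives the identical consensus
  perm <- list(pennCNV = cs$pennCNV[sample.int(6)],
               quantiSNP = cs$quantiSNP[sample.int(6)])
  cons2 <- mergeCallsets(perm, map, minSupport = 1)
  expect_identical(granges(cons2), granges(cons))
  expect_identical(S4Vectors::mcols(cons2)$sample_id,
                   S4Vectors::mcols(cons)$sample_id)
})

test_that("tier filters apply the strict and inclusive bounds exactly", {
  map <- testMap()
  df <- data.frame(
    sample_id = "s1", chrom = "1",
    start = c(1e6, 20e6, 40e6, 60e6),
    end = c(1e6 + 1200000 - 1,      # 1.2 Mb
            20e6 + 1000000 - 1,     # exactly 1 Mb
            40e6 + 120000 - 1,      # 120 kb
            60e6 + 90000 - 1),      # 90 kb
    cn = 1L, n_markers = c(150L, 150L, 10L, 50L))
  cs <- callsetsFrom(df)
  cons <- mergeCallsets(cs, map, minSupport = 1)
  # n_markers is recomputed from the map; force the fixture values to
  # isolate the filter logic
  S4Vectors::mcols(cons)$n_markers <-
    df$n_markers[match(start(cons), df$start)]
  large <- filterTier(cons, "large")
  expect_identical(start(large), 1000000L)       # only the 1.2 Mb call
  pheno <- filterTier(cons, "phenotype")
  # >100 kb with >=10 markers and 3 algorithms: the 1.2 Mb, 1 Mb and
  # 120 kb calls qualify; 90 kb fails the length bound
  expect_setequal(start(pheno), c(1e6, 20e6, 40e6))
  # marker bound is strict for large (=100 dropped), inclusive for
  # phenotype (=10 kept)
  S4Vectors::mcols(cons)$n_markers <- c(100L, 150L, 10L, 50L)
  expect_length(filterTier(cons, "large"), 0)
})

test_that("rarity classes come from reciprocal-overlap clusters", {
  map <- testMap()
  # a lone CNV is a singleton
  df1 <- data.frame(sample_id = "s1", chrom = "5", start = 1e6, end = 2e6,
                    cn = 1L, n_markers = 3L)
  c1 <- classifyRarity(mergeCallsets(callsetsFrom(df1), map), nSamples = 100)
  expect_identical(S4Vectors::mcols(c1)$rarity, "singleton")

  # identical CNV in 60% of samples is common
  df2 <- data.frame(sample_id = sprintf("s%02d", 1:60), chrom = "5",
                    start = 1e6, end = 2e6, cn = 1L, n_markers = 3L)
  c2 <- classifyRarity(mergeCallsets(callsetsFrom(df2), map),
                       nSamples = 100, commonFreq = 0.01)
  expect_true(all(S4Vectors::mcols(c2)$rarity == "common"))

  # 40% reciprocal overlap at a 50% threshold: separate singletons
  df3 <- data.frame(sample_id = c("s1", "s2"), chrom = "5",
                    start = c(1e6, 1.6e6), end = c(2e6, 2.6e6),
                    cn = 1L, n_markers = 3L)
  c3 <- classifyRarity(mergeCallsets(callsetsFrom(df3), map),
                       nSamples = 100, overlapFrac = 0.5)
  expect_identical(S4Vectors::mcols(c3)$rarity, c("singleton", "singleton"))
  c3b <- classifyRarity(mergeCallsets(callsetsFrom(df3), map),
                        nSamples = 100, overlapFrac = 0.3)
  expect_true(all(S4Vectors::mcols(c3b)$cluster_id == 1L))
})

test_that("rarity clustering matches a brute-force pairwise oracle", {
  map <- testMap()
  set.seed(66)
  n <- 60
  df <- data.frame(sample_id = sprintf("s%02d", sample.int(20, n, TRUE)),
                   chrom = sample(c("2", "9"), n, TRUE),
                   start = sample(seq(1e6, 100e6, by = 250e3), n, TRUE))
  df$end <- df$start + sample(c(5e5, 1e6, 2e6), n, TRUE)
  df$cn <- sample(c(1L, 3L), n, TRUE)
  df$n_markers <- 3L
  gr <- karyoCNV:::makeCnvCalls(df$sample_id, df$chrom, df$start, df$end,
                                df$cn, df$n_markers, "a")
  S4Vectors::mcols(gr)$length_bp <- width(gr)
  res <- classifyRarity(gr, nSamples = 20, overlapFrac = 0.5)
  # O(n^2) oracle: reciprocal overlap adjacency + transitive closure
  adj <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (df$chrom[i] != df$chrom[j]) next
    if ((df$cn[i] < 2) != (df$cn[j] < 2)) next
    ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]) + 1
    wi <- df$end[i] - df$start[i] + 1
    wj <- df$end[j] - df$start[j] + 1
    adj[i, j] <- ov >= 0.5 * wi && ov >= 0.5 * wj
  }
  reach <- adj
  for (k in 1:n) reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  oracleCluster <- apply(reach, 1, function(r) min(which(r)))
  got <- S4Vectors::mcols(res)$cluster_id
  # same partition (labels may differ)
  expect_identical(outer(got, got, "=="),
                   outer(oracleCluster, oracleCluster, "=="))
  oracleSingleton <- table(oracleCluster)[as.character(oracleCluster)] == 1
  expect_identical(S4Vectors::mcols(res)$rarity == "singleton",
                   as.vector(unname(oracleSingleton)))
})

test_that("gene and region annotation counts overlaps exactly", {
  genes <- GenomicRanges::GRanges(
    "15", IRanges::IRanges(c(1e6, 3e6, 5e6, 7e6, 9e6),
                           width = 1.5e6))
  S4Vectors::mcols(genes)$label <- paste0("g", 1:5)
  region <- GenomicRanges::GRanges("15",
                                   IRanges::IRanges(30900001, 32500000))
  S4Vectors::mcols(region)$label <- "15q13.3"
  cnv <- karyoCNV:::makeCnvCalls("s1", "15", 2e6, 6e6, 1L, 10L, "a")
  S4Vectors::mcols(cnv)$length_bp <- width(cnv)
  out <- annotateCnvs(cnv, genes, region)
  expect_identical(S4Vectors::mcols(out)$gene_count, 3L)   # g2, g3, g4
  expect_identical(S4Vectors::mcols(out)$region_hits, "")
  cnv2 <- karyoCNV:::makeCnvCalls("s1", "15", 31e6, 31.5e6, 3L, 10L, "a")
  out2 <- annotateCnvs(cnv2, genes, region)
  expect_identical(S4Vectors::mcols(out2)$region_hits, "15q13.3")
})

test_that("gene counts equal a brute-force interval-intersection oracle on
           random fixtures", {
  set.seed(67)
  nG <- 200
  gdf <- data.frame(chrom = sample(as.character(1:4), nG, TRUE),
                    start = sample.int(5e7, nG))
  gdf$end <- gdf$start + sample.int(2e6, nG)
  genes <- GenomicRanges::GRanges(gdf$chrom,
                                  IRanges::IRanges(gdf$start, gdf$end))
  S4Vectors::mcols(genes)$label <- paste0("g", seq_len(nG))
  nC <- 1000
  cdf <- data.frame(chrom = sample(as.character(1:4), nC, TRUE),
                    start = sample.int(5e7, nC))
  cdf$end <- cdf$start + sample.int(3e6, nC)
  cnvs <- GenomicRanges::GRanges(cdf$chrom,
                                 IRanges::IRanges(cdf$start, cdf$end))
  S4Vectors::mcols(cnvs)$sample_id <- "s1"
  out <- annotateCnvs(cnvs, genes)
  oracle <- vapply(seq_len(nC), function(i)
    sum(gdf$chrom == cdf$chrom[i] & gdf$start <= cdf$end[i] &
        gdf$end >= cdf$start[i]), 0L)
  expect_identical(S4Vectors::mcols(out)$gene_count, oracle)
})
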