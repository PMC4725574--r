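# Synthetic-array generator: marker maps, the BAF band model, cohort
# bookkeeping, caller emulation.

test_that("marker map has the requested size, is deterministic, and spreads
           markers evenly across autosomes", {
  map <- simulateMarkerMap(2200, 100, 20, seed = 1)
  expect_length(map, 2320)
  map2 <- simulateMarkerMap(2200, 100, 20, seed = 1)
  expect_identical(names(map), names(map2))
  expect_identical(start(map), start(map2))

  # binomial oracle: with uniform assignment each autosome holds
  # Binomial(n, 1/22) markers; at n = 22000 every count is within +/-20%
  # of n/22 with overwhelming probability
  big <- simulateMarkerMap(22000, 50, 20, seed = 9)
  counts <- table(as.character(seqnames(big)))[as.character(1:22)]
  expect_true(all(counts > 800 & counts < 1200))
})

test_that("BAF bands follow the mixture formula exactly in the noiseless
           limit", {
  map <- testMap()
  xIdx <- as.character(seqnames(map)) == "X"
  hetOf <- function(x) {
    b <- baf(x)[xIdx, 1]
    sort(unique(round(b[b > 1e-9 & b < 1 - 1e-9], 6)))
  }
  mk <- function(f) simulateSample(
    KaryotypeSpec("XX", mosaic = list(class = "monosomy_mosaic",
                                      target = "X", fraction = f)),
    map, noiselessModel(), seed = 11)

  # f = 0.5: heterozygous bands at exactly 1/3 and 2/3
  expect_equal(hetOf(mk(0.5)), round(c(1 / 3, 2 / 3), 6))
  # f = 0: bands at exactly 0.5; f = 1: no heterozygous band at all
  expect_equal(hetOf(mk(0)), 0.5)
  expect_length(hetOf(mk(1)), 0)

  # genome-wide triploid mosaic at f = 1: bands at 1/3 and 2/3 with LRR
  # equal to the copy-3 expectation on every autosome
  x3 <- simulateSample(
    KaryotypeSpec("XX", mosaic = list(class = "triploid_mosaic",
                                      target = "genome", fraction = 1)),
    map, noiselessModel(), seed = 12)
  aIdx <- as.character(seqnames(map)) %in% as.character(1:22)
  b <- baf(x3)[aIdx, 1]
  expect_true(all(round(b, 6) %in% round(c(0, 1 / 3, 2 / 3, 1), 6)))
  expect_equal(unique(lrr(x3)[aIdx, 1]), NoiseModel()@lrrMu[["3"]])
})

test_that("UPD chromosomes are homozygous except the distal recovery
           fraction", {
  map <- testMap()
  x <- simulateSample(KaryotypeSpec("XX",
                                    upd = data.frame(chrom = "4",
                                                     recovery = 0)),
                      map, noiselessModel(), seed = 13)
  i4 <- as.character(seqnames(map)) == "4"
  expect_true(all(baf(x)[i4, 1] %in% c(0, 1)))

  xr <- simulateSample(KaryotypeSpec("XX",
                                     upd = data.frame(chrom = "4",
                                                      recovery = 0.3)),
                       map, noiselessModel(), seed = 13)
  b4 <- baf(xr)[i4, 1]
  n4 <- length(b4)
  nRec <- floor(0.3 * n4)
  expect_true(all(b4[seq_len(n4 - nRec)] %in% c(0, 1)))
  expect_gt(mean(b4[(n4 - nRec + 1):n4] == 0.5), 0.15)
})

test_that("profiles contain no NaN, BAF stays in [0,1], and LRR orders by
           copy number", {
  map <- testMap()
  spec <- KaryotypeSpec("XY", cnvs = data.frame(
    chrom = c("2", "3"), start = c(1e6, 1e6), end = c(120e6, 120e6),
    cn = c(1L, 3L)))
  for (seed in 1:4) {
    x <- simulateSample(spec, map, NoiseModel(lrrSd = 0.3), seed = seed)
    expect_false(any(is.nan(lrr(x))))
    expect_false(any(is.nan(baf(x))))
    expect_true(all(baf(x) >= 0 & baf(x) <= 1))
    ch <- as.character(seqnames(map))
    mDel <- mean(lrr(x)[ch == "2", 1])
    mDip <- mean(lrr(x)[ch == "5", 1])
    mDup <- mean(lrr(x)[ch == "3", 1])
    expect_true(mDel < mDip && mDip < mDup)
  }
})

test_that("CNV intervals outside the mapped span are rejected", {
  map <- testMap()
  bad <- KaryotypeSpec("XX", cnvs = data.frame(
    chrom = "21", start = 49e6, end = 50e6, cn = 1L))
  # beyond the last chr21 marker (chr21 length 48 Mb in the map)
  expect_error(simulateSample(bad, map, NoiseModel(), seed = 1),
               "outside the mapped span")
})

test_that("cohort class proportions are applied deterministically and runs
           reproduce under the seed", {
  map <- testMap()
  cfg <- cohortConfig(n = c(case = 100),
                      classProportions = c(XX = 0.5, XY = 0.45,
                                           turner = 0.05),
                      cnvRate = 0.5)
  sim <- simulateCohort(cfg, map, NoiseModel(), seed = 21)
  tt <- truthSamples(sim$truth)
  expect_identical(sum(tt$karyotype_class == "turner"), 5L)
  expect_identical(nrow(tt), 100L)

  sim2 <- simulateCohort(cfg, map, NoiseModel(), seed = 21)
  expect_identical(lrr(sim$profiles), lrr(sim2$profiles))
  expect_identical(truthCnvs(sim$truth), truthCnvs(sim2$truth))

  # every true CNV appears exactly once (no same-sample duplicates)
  tc <- truthCnvs(sim$truth)
  if (nrow(tc))
    expect_false(anyDuplicated(tc[c("sample_id", "chrom", "start")]) > 0)

  # n = 0 gives empty outputs without error
  empty <- simulateCohort(cohortConfig(n = c(case = 0),
                                       classProportions = c(XX = 1)),
                          map, NoiseModel(), seed = 1)
  expect_identical(ncol(empty$profiles), 0L)
  expect_identical(nrow(truthSamples(empty$truth)), 0L)
})

test_that("X heterozygosity separates XX from 45,X by several SD", {
  map <- testMap()
  cfg <- cohortConfig(n = c(case = 200),
                      classProportions = c(XX = 0.5, turner = 0.5),
                      cnvRate = 0)
  sim <- simulateCohort(cfg, map, NoiseModel(), seed = 22)
  s <- summarizeChromosomes(sim$profiles)
  xhet <- s$baf_het_rate[s$chrom == "X"]
  klass <- truthSamples(sim$truth)$karyotype_class[
    match(s$sample_id[s$chrom == "X"], truthSamples(sim$truth)$sample_id)]
  mXX <- mean(xhet[klass == "XX"]); sXX <- sd(xhet[klass == "XX"])
  mX <- mean(xhet[klass == "turner"]); sX <- sd(xhet[klass == "turner"])
  expect_gt((mXX - mX) / max(sXX, sX), 5)
})

test_that("caller emulation degrades truth as configured", {
  map <- testMap()
  cfg <- cohortConfig(n = c(case = 40), classProportions = c(XX = 1),
                      cnvRate = 2)
  sim <- simulateCohort(cfg, map, NoiseModel(), seed = 31)
  truth <- sim$truth
  nTrue <- nrow(truthCnvs(truth))
  expect_gt(nTrue, 30)

  # noiseless limit: every call set identical to truth
  cs0 <- simulateCallsets(truth, map,
                          error = list(fpRate = 0, fnRate = 0,
                                       jitterSd = 0), seed = 5)
  for (cs in cs0) {
    expect_length(cs, nTrue)
    expect_identical(start(cs), as.integer(truthCnvs(truth)$start))
    expect_identical(S4Vectors::mcols(cs)$n_markers,
                     as.integer(truthCnvs(truth)$n_markers))
  }

  # fnRate = 1 silences every caller
  cs1 <- simulateCallsets(truth, map,
                          error = list(fpRate = 0, fnRate = 1,
                                       jitterSd = 0), seed = 5)
  expect_true(all(lengths(cs1) == 0))

  # Poisson oracle: fpRate 0.5 over 200 samples -> ~100 false calls per
  # algorithm (some fall in marker gaps and are dropped)
  cfgBig <- cohortConfig(n = c(case = 200), classProportions = c(XX = 1),
                         cnvRate = 0)
  simBig <- simulateCohort(cfgBig, map, NoiseModel(), seed = 32)
  csFp <- simulateCallsets(simBig$truth, map,
                           error = list(fpRate = 0.5, fnRate = 0,
                                        jitterSd = 0), seed = 6)
  expect_true(all(lengths(csFp) > 55 & lengths(csFp) < 145))
})
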