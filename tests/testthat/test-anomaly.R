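# Chromosome summaries, sex prediction, the anomaly decision table and
# mosaic-fraction inversion.

test_that("diploid samples stay unflagged: rare raw z excursions, no
           anomaly calls", {
  map <- testMap()
  cfg <- cohortConfig(n = c(case = 50),
                      classProportions = c(XX = 0.5, XY = 0.5),
                      cnvRate = 0)
  sim <- simulateCohort(cfg, map, NoiseModel(), seed = 41)
  s <- summarizeChromosomes(sim$profiles)
  auto <- s[s$chrom %in% as.character(1:22), ]
  # leave-one-out z against ~20 reference autosomes is t-like, so raw
  # 3-SD excursions occur at a small but nonzero rate
  expect_lt(mean(abs(auto$z_lrr) > 3, na.rm = TRUE), 0.02)
  an <- classifyAnomaly(sim$profiles)
  expect_true(all(an$class == "normal"))
})

test_that("a trisomic chromosome flags its own LRR z only", {
  map <- testMap()
  x <- simulateSample(
    KaryotypeSpec("XX", mosaic = list(class = "trisomy_mosaic",
                                      target = "21", fraction = 1)),
    map, NoiseModel(), seed = 43)
  s <- summarizeChromosomes(x)
  auto <- s[s$chrom %in% as.character(1:22), ]
  expect_gt(auto$z_lrr[auto$chrom == "21"], 3)
  expect_true(all(abs(auto$z_lrr[auto$chrom != "21"]) < 3))
  an <- classifyAnomaly(x)
  expect_identical(an$class[an$chrom == "21"], "trisomy")
  expect_true(all(an$class[an$chrom != "21"] == "normal"))
})

test_that("UPD heterozygosity collapses to zero in the noiseless limit", {
  map <- testMap()
  x <- simulateSample(KaryotypeSpec("XX",
                                    upd = data.frame(chrom = "4",
                                                     recovery = 0)),
                      map, noiselessModel(), seed = 44)
  s <- summarizeChromosomes(x)
  expect_identical(s$baf_het_rate[s$chrom == "4"], 0)
})

test_that("sex prediction resolves all five sex-chromosome classes and
           flags reported-sex discordance", {
  map <- testMap()
  # 20/20 recovery of 47,XXY at default noise
  combos <- vapply(1:20, function(i) {
    x <- simulateSample(KaryotypeSpec("XXY"), map, NoiseModel(),
                        seed = 100 + i)
    predictSex(summarizeChromosomes(x))$combined
  }, "")
  expect_identical(unique(combos), "XXY")

  # 45,X with reported female: combined X, concordance flag FALSE
  x <- simulateSample(KaryotypeSpec("X"), map, NoiseModel(), seed = 45,
                      sampleId = "t1")
  sx <- predictSex(summarizeChromosomes(x),
                   reportedSex = c(t1 = "female"))
  expect_identical(sx$combined, "X")
  expect_false(sx$concordant_with_reported)

  # noiseless 46,XX
  x0 <- simulateSample(KaryotypeSpec("XX"), map, noiselessModel(),
                       seed = 46)
  expect_identical(predictSex(summarizeChromosomes(x0))$combined, "XX")

  # prediction is deterministic
  s <- summarizeChromosomes(x)
  expect_identical(predictSex(s), predictSex(s))
})

test_that("the decision table recovers complete and partial-recovery UPD", {
  map <- testMap()
  x <- simulateSample(KaryotypeSpec("XY",
                                    upd = data.frame(chrom = "4",
                                                     recovery = 0)),
                      map, NoiseModel(), seed = 47)
  an <- classifyAnomaly(x)
  expect_identical(an$class[an$chrom == "4"], "upd_complete")
  expect_true(all(an$class[an$chrom != "4"] == "normal"))

  # distal heterozygosity recovery on 21q
  x2 <- simulateSample(KaryotypeSpec("XY",
                                     upd = data.frame(chrom = "21",
                                                      recovery = 0.2)),
                       map, NoiseModel(), seed = 48)
  an2 <- classifyAnomaly(x2)
  expect_identical(an2$class[an2$chrom == "21"], "upd_partial_recovery")
})

test_that("mosaic-fraction inversion matches the closed forms and rejects
           out-of-range displacement", {
  expect_equal(estimateMosaicFraction(1 / 6, "monosomy"), 0.5)
  expect_equal(estimateMosaicFraction(0, "monosomy"), 0)
  expect_equal(estimateMosaicFraction(0.5, "monosomy"), 1)
  expect_equal(estimateMosaicFraction(1 / 6, "trisomy"), 1)
  # monotone in f: displacement formulas invert consistently
  f <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  dMono <- f / (2 * (2 - f))
  expect_equal(estimateMosaicFraction(dMono, "monosomy"), f)
  dTri <- f / (2 * (2 + f))
  expect_equal(estimateMosaicFraction(dTri, "trisomy"), f)
  expect_error(estimateMosaicFraction(0.6, "monosomy"), "0.5")
  expect_error(estimateMosaicFraction(-0.1, "trisomy"), "0.5")
})

test_that("whole-sample classification identifies X mosaics and
           diploid/triploid mosaics with fraction estimates", {
  map <- testMap()
  x <- simulateSample(
    KaryotypeSpec("XX", mosaic = list(class = "monosomy_mosaic",
                                      target = "X", fraction = 0.5)),
    map, NoiseModel(), seed = 49)
  k <- classifyKaryotype(x)
  expect_identical(k$karyotype_class, "x_mosaic")
  fhat <- as.numeric(sub("f_hat=", "", k$detail))
  expect_lt(abs(fhat - 0.5), 0.1)

  x3 <- simulateSample(
    KaryotypeSpec("XX", mosaic = list(class = "triploid_mosaic",
                                      target = "genome", fraction = 0.5)),
    map, NoiseModel(), seed = 50)
  k3 <- classifyKaryotype(x3)
  expect_identical(k3$karyotype_class, "triploid_mosaic")
})

test_that("summaries reject empty input and skip thin chromosomes", {
  map <- testMap()
  x <- simulateSample(KaryotypeSpec("XX"), map, NoiseModel(), seed = 51)
  s <- summarizeChromosomes(x, anomalyThresholds(minMarkers = 1e6))
  expect_true(all(is.na(s$z_lrr)))
  lrrNA <- matrix(NA_real_, length(map), 1,
                  dimnames = list(names(map), "s1"))
  empty <- IntensitySet(lrrNA, lrrNA, map)
  expect_error(summarizeChromosomes(empty), "no observed LRR")
})
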