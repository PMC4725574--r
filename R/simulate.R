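# Synthetic SNP-array generator: renders karyotypes (aneuploidy, mosaicism,
# uniparental isodisomy, segmental CNVs) into per-marker LRR/BAF signal, and
# emulates multi-algorithm CNV callers with tunable error rates. This is the
# ground-truth engine the detection and statistical layers are tested
# against.
#
# Signal model. At a marker with genotype b B-alleles out of c copies in a
# non-mosaic cell population, BAF centres on b/c (uniform noise when c = 0)
# and LRR on lrrMu(c). In a mosaic with fraction f of cells carrying
# (b2, c2) against a background (b1, c1):
#     BAF centre = ((1-f) b1 + f b2) / ((1-f) c1 + f c2)
#     LRR centre = lrrMu evaluated at (1-f) c1 + f c2 (linear interpolation)
# UPD chromosomes are fully homozygous (both copies identical) except for a
# distal fraction of markers that revert to population heterozygosity.

# hg19-like chromosome lengths (bp), used for marker placement.
CHROM_LENGTHS <- c(
  `1` = 249e6, `2` = 243e6, `3` = 198e6, `4` = 191e6, `5` = 181e6,
  `6` = 171e6, `7` = 159e6, `8` = 146e6, `9` = 141e6, `10` = 136e6,
  `11` = 135e6, `12` = 134e6, `13` = 115e6, `14` = 107e6, `15` = 103e6,
  `16` = 90e6, `17` = 81e6, `18` = 78e6, `19` = 59e6, `20` = 63e6,
  `21` = 48e6, `22` = 51e6, X = 155e6, Y = 59e6)

#' Simulate a marker map
#'
#' Places `nAutosomal` markers uniformly at random across the 22 autosomes
#' (each autosome equally likely), plus `nX` / `nY` markers on X and Y, with
#' positions uniform over hg19-like chromosome lengths, then sorts. Each
#' marker receives a fixed population B-allele frequency drawn from
#' Uniform(0.05, 0.95), stored in `mcols(map)$paf` and reused by every
#' downstream simulation over this map.
#'
#' @param nAutosomal,nX,nY marker counts (each >= 1).
#' @param seed RNG seed; identical seeds give identical maps.
#' @return a validated marker-map `GRanges` (width-1, named, sorted).
#' @examples
#' map <- simulateMarkerMap(2200, 100, 20, seed = 1)
#' length(map)  # 2320
#' @export
simulateMarkerMap <- function(nAutosomal, nX, nY, seed) {
  stopifnot(nAutosomal >= 1, nX >= 1, nY >= 1)
  withSeed(seed, {
    chrom <- c(sample(AUTOSOMES, nAutosomal, replace = TRUE),
               rep("X", nX), rep("Y", nY))
    pos <- floor(runif(length(chrom), 1, CHROM_LENGTHS[chrom]))
    # resolve position collisions deterministically
    repeat {
      dup <- duplicated(paste(chrom, pos))
      if (!any(dup)) break
      pos[dup] <- pos[dup] + 1
    }
    ids <- sprintf("mk%06d", seq_along(chrom))
    makeMarkerMap(ids, chrom, pos,
                  paf = runif(length(chrom), 0.05, 0.95),
                  seqlengths = CHROM_LENGTHS)
  })
}

# Per-marker copy number of the constitutional karyotype (before CNVs).
.baseCopy <- function(spec, chrom) {
  sx <- strsplit(spec@sexChromosomes, "")[[1]]
  nx <- sum(sx == "X")
  ny <- sum(sx == "Y")
  cn <- rep(2L, length(chrom))
  cn[chrom == "X"] <- nx
  cn[chrom == "Y"] <- ny
  cn
}

# Draw B-allele counts b for copy numbers c given population B freq p.
# Copy gains duplicate a uniformly chosen existing allele (so a heterozygote
# moves to AAB or ABB, never to new hom states).
.drawGenotype <- function(cn, p) {
  n <- length(cn)
  b <- integer(n)
  g2 <- rbinom(n, 2, p)
  u <- runif(n)
  i <- cn == 2L; b[i] <- g2[i]
  i <- cn == 1L; b[i] <- rbinom(sum(i), 1, p[i])
  i <- cn == 3L; b[i] <- g2[i] + as.integer(u[i] < g2[i] / 2)
  i <- cn == 4L; b[i] <- g2[i] + 2L * as.integer(u[i] < g2[i] / 2)
  b
}

# Remove (delta = -1) or duplicate (delta = +1) one uniformly chosen allele.
.shiftAllele <- function(b, cn, delta) {
  pick <- runif(length(b)) < ifelse(cn > 0, b / pmax(cn, 1L), 0)
  as.integer(b + delta * pick)
}

# Core renderer; assumes the RNG is already seeded by the caller.
.simulateProfile <- function(spec, map, noise) {
  validObject(spec)
  validObject(noise)
  chrom <- as.character(seqnames(map))
  pos <- start(map)
  p <- mcols(map)$paf
  if (is.null(p))
    stopf("marker map lacks mcols(map)$paf (population B-allele freqs); %s",
          "use simulateMarkerMap() or add a paf column")
  n <- length(map)

  c1 <- .baseCopy(spec, chrom)

  updFlag <- rep(FALSE, n)
  updRecovered <- rep(FALSE, n)
  if (nrow(spec@upd)) for (k in seq_len(nrow(spec@upd))) {
    uch <- normChrom(spec@upd$chrom[k])
    idx <- which(chrom == uch)
    if (!length(idx)) stopf("UPD chromosome %s not in marker map", uch)
    updFlag[idx] <- TRUE
    rec <- spec@upd$recovery[k]
    if (rec > 0) {
      nrec <- floor(rec * length(idx))
      if (nrec > 0) updRecovered[idx[seq(length(idx) - nrec + 1,
                                         length(idx))]] <- TRUE
    }
  }

  if (nrow(spec@cnvs)) for (k in seq_len(nrow(spec@cnvs))) {
    cv <- spec@cnvs[k, ]
    cch <- normChrom(cv$chrom)
    onchr <- which(chrom == cch)
    if (!length(onchr))
      stopf("CNV interval on chromosome %s outside marker map", cch)
    if (cv$start > max(pos[onchr]) || cv$end < min(pos[onchr]))
      stopf("CNV interval %s:%d-%d outside the mapped span of chromosome %s",
            cch, cv$start, cv$end, cch)
    idx <- onchr[pos[onchr] >= cv$start & pos[onchr] <= cv$end]
    c1[idx] <- as.integer(cv$cn)
  }

  b1 <- .drawGenotype(c1, p)
  # UPD: both copies identical -> genotype is c1 copies of one allele
  # (except markers in the recovered distal segment).
  i <- updFlag & !updRecovered
  if (any(i)) b1[i] <- c1[i] * rbinom(sum(i), 1, p[i])

  f <- 0
  c2 <- c1
  b2 <- b1
  tsel <- rep(FALSE, n)
  if (length(spec@mosaic)) {
    mo <- spec@mosaic
    f <- mo$fraction
    if (identical(mo$class, "triploid_mosaic")) {
      tsel <- chrom != "Y" & c1 >= 1L
      c2[tsel] <- c1[tsel] + 1L
      b2[tsel] <- .shiftAllele(b1[tsel], c1[tsel], +1L)
    } else {
      tch <- normChrom(mo$target)
      tsel <- chrom == tch & c1 >= 1L
      if (!any(chrom == tch))
        stopf("mosaic target chromosome %s not in marker map", tch)
      if (identical(mo$class, "monosomy_mosaic")) {
        c2[tsel] <- c1[tsel] - 1L
        b2[tsel] <- .shiftAllele(b1[tsel], c1[tsel], -1L)
      } else {
        c2[tsel] <- c1[tsel] + 1L
        b2[tsel] <- .shiftAllele(b1[tsel], c1[tsel], +1L)
      }
    }
  }

  fEff <- ifelse(tsel, f, 0)
  ce <- (1 - fEff) * c1 + fEff * c2
  bNum <- (1 - fEff) * b1 + fEff * b2
  bafMean <- ifelse(ce > 0, bNum / ce, NA_real_)

  mu <- noise@lrrMu
  lrrMean <- approx(x = 0:4, y = mu, xout = pmin(ce, 4), rule = 2)$y
  lrrOut <- lrrMean + rnorm(n, 0, noise@lrrSd)

  het <- !is.na(bafMean) & bafMean > 0 & bafMean < 1
  sdv <- ifelse(het, noise@bafSd, noise@bafSd / 2)
  bafOut <- pmin(pmax(bafMean + rnorm(n, 0, sdv), 0), 1)
  zero <- ce == 0
  if (any(zero)) bafOut[zero] <- runif(sum(zero))

  list(lrr = lrrOut, baf = bafOut)
}

#' Simulate one sample's intensity profile
#'
#' Renders a [KaryotypeSpec-class] into per-marker LRR/BAF signal over a
#' marker map under a [NoiseModel-class]; see the band model described in
#' the package vignette. XY males carry X at copy 1 (no heterozygous band);
#' Y markers in samples without a Y emit copy-0 background (LRR centred on
#' `lrrMu["0"]`, uniform BAF).
#'
#' @param spec a [KaryotypeSpec-class].
#' @param map a marker map with `paf` metadata (see [simulateMarkerMap()]).
#' @param noise a [NoiseModel-class].
#' @param seed RNG seed.
#' @param sampleId column name for the returned single-sample set.
#' @return an [IntensitySet-class] with one column.
#' @examples
#' map <- simulateMarkerMap(500, 100, 20, seed = 1)
#' x <- simulateSample(KaryotypeSpec("XXY"), map, NoiseModel(), seed = 7)
#' @export
simulateSample <- function(spec, map, noise = NoiseModel(), seed,
                           sampleId = "sample1") {
  validateMarkerMap(map)
  prof <- withSeed(seed, .simulateProfile(spec, map, noise))
  IntensitySet(matrix(prof$lrr, ncol = 1,
                      dimnames = list(names(map), sampleId)),
               matrix(prof$baf, ncol = 1), map)
}

KARYOTYPE_CLASSES <- c("XX", "XY", "turner", "klinefelter", "triple_x",
                       "x_mosaic", "triploid_mosaic", "upd", "upd_partial",
                       "autosomal_trisomy_mosaic")

#' Cohort configuration for the array simulator
#'
#' @param n named integer vector: samples per cohort arm (`case`,
#'   `screened_control`, `population_control`). Arms may be omitted.
#' @param classProportions named proportions (summing to 1) over karyotype
#'   classes `XX`, `XY`, `turner` (45,X), `klinefelter` (47,XXY),
#'   `triple_x` (47,XXX), `x_mosaic` (45,X/46,XX), `triploid_mosaic`
#'   (diploid/triploid), `upd`, `upd_partial`,
#'   `autosomal_trisomy_mosaic`. Proportions are applied deterministically
#'   (largest-remainder apportionment), so class counts are exact.
#' @param mosaicFraction abnormal cell fraction f for mosaic classes.
#' @param updRecovery distal heterozygosity-recovery fraction for the
#'   `upd_partial` class.
#' @param cnvRate mean number of segmental CNVs per sample (Poisson).
#' @param cnvRateMultiplier optional named per-arm multiplier on `cnvRate`
#'   (to plant case/control burden differences).
#' @param cnvSizeRange CNV length range in bp (log-uniform draw).
#' @param delProb probability a simulated CNV is a deletion (cn 1) rather
#'   than a duplication (cn 3).
#' @param minMarkersPerCnv minimum markers a simulated CNV must span.
#' @return a list of class `cohortConfig`.
#' @export
cohortConfig <- function(n = c(case = 100, screened_control = 50,
                               population_control = 100),
                         classProportions = c(XX = 0.5, XY = 0.5),
                         mosaicFraction = 0.5,
                         updRecovery = 0.2,
                         cnvRate = 1,
                         cnvRateMultiplier = NULL,
                         cnvSizeRange = c(5e4, 5e6),
                         delProb = 0.5,
                         minMarkersPerCnv = 3) {
  bad <- setdiff(names(classProportions), KARYOTYPE_CLASSES)
  if (length(bad))
    stopf("unknown karyotype class(es): %s", paste(bad, collapse = ", "))
  if (abs(sum(classProportions) - 1) > 1e-8)
    stopf("classProportions must sum to 1")
  structure(list(n = n, classProportions = classProportions,
                 mosaicFraction = mosaicFraction, updRecovery = updRecovery,
                 cnvRate = cnvRate, cnvRateMultiplier = cnvRateMultiplier,
                 cnvSizeRange = cnvSizeRange, delProb = delProb,
                 minMarkersPerCnv = minMarkersPerCnv),
            class = "cohortConfig")
}

# Build the KaryotypeSpec for one sample of a given class. Assumes seeded
# RNG. Returns list(spec, reported_sex, truth fields).
.classToSpec <- function(klass, config) {
  f <- config$mosaicFraction
  switch(klass,
    XX = list(spec = KaryotypeSpec("XX"), sex = "female"),
    XY = list(spec = KaryotypeSpec("XY"), sex = "male"),
    turner = list(spec = KaryotypeSpec("X"), sex = "female"),
    klinefelter = list(spec = KaryotypeSpec("XXY"), sex = "male"),
    triple_x = list(spec = KaryotypeSpec("XXX"), sex = "female"),
    x_mosaic = list(
      spec = KaryotypeSpec("XX", mosaic = list(class = "monosomy_mosaic",
                                               target = "X", fraction = f)),
      sex = "female", mosaic_class = "monosomy_mosaic",
      mosaic_target = "X", mosaic_fraction = f),
    triploid_mosaic = list(
      spec = KaryotypeSpec("XX", mosaic = list(class = "triploid_mosaic",
                                               target = "genome",
                                               fraction = f)),
      sex = "female", mosaic_class = "triploid_mosaic",
      mosaic_target = "genome", mosaic_fraction = f),
    autosomal_trisomy_mosaic = {
      tch <- sample(AUTOSOMES, 1)
      list(spec = KaryotypeSpec(sample(c("XX", "XY"), 1),
                                mosaic = list(class = "trisomy_mosaic",
                                              target = tch, fraction = f)),
           sex = NA, mosaic_class = "trisomy_mosaic", mosaic_target = tch,
           mosaic_fraction = f)
    },
    upd = {
      uch <- sample(AUTOSOMES, 1)
      sx <- sample(c("XX", "XY"), 1)
      list(spec = KaryotypeSpec(sx, upd = data.frame(chrom = uch,
                                                     recovery = 0)),
           sex = if (sx == "XX") "female" else "male", upd_chrom = uch,
           upd_recovery = 0)
    },
    upd_partial = {
      uch <- sample(AUTOSOMES, 1)
      sx <- sample(c("XX", "XY"), 1)
      list(spec = KaryotypeSpec(sx,
                                upd = data.frame(chrom = uch,
                                                 recovery =
                                                   config$updRecovery)),
           sex = if (sx == "XX") "female" else "male", upd_chrom = uch,
           upd_recovery = config$updRecovery)
    },
    stopf("unknown karyotype class '%s'", klass))
}

# Draw one random segmental CNV on an autosome with >= minMarkers markers.
.drawCnv <- function(map, config) {
  chrom <- as.character(seqnames(map))
  pos <- start(map)
  for (try in 1:25) {
    ch <- sample(AUTOSOMES, 1)
    len <- floor(10^runif(1, log10(config$cnvSizeRange[1]),
                          log10(config$cnvSizeRange[2])))
    L <- CHROM_LENGTHS[[ch]]
    if (len >= L) next
    s <- floor(runif(1, 1, L - len))
    e <- s + len - 1
    nm <- sum(chrom == ch & pos >= s & pos <= e)
    if (nm >= config$minMarkersPerCnv) {
      cn <- if (runif(1) < config$delProb) 1L else 3L
      return(list(chrom = ch, start = s, end = e, cn = cn, n_markers = nm))
    }
  }
  NULL
}

#' Simulate a cohort with known ground truth
#'
#' Generates an [IntensitySet-class] for a multi-arm cohort whose karyotype
#' class mix follows `config$classProportions` exactly (deterministic
#' apportionment), plus Poisson-distributed segmental CNVs, and returns the
#' complete [TruthTable-class]. Each sample is rendered under its own
#' deterministically derived child seed, so individual samples are
#' reproducible independently of cohort size.
#'
#' @param config a [cohortConfig()].
#' @param map marker map (see [simulateMarkerMap()]).
#' @param noise a [NoiseModel-class].
#' @param seed RNG seed.
#' @return `list(profiles = IntensitySet, truth = TruthTable)`; with total
#'   n = 0, an empty set and empty truth.
#' @examples
#' map <- simulateMarkerMap(440, 60, 12, seed = 1)
#' cfg <- cohortConfig(n = c(case = 6), classProportions = c(XX = .5, XY = .5))
#' sim <- simulateCohort(cfg, map, NoiseModel(), seed = 3)
#' truthSamples(sim$truth)
#' @export
simulateCohort <- function(config, map, noise = NoiseModel(), seed) {
  stopifnot(inherits(config, "cohortConfig"))
  validateMarkerMap(map)
  arms <- names(config$n)
  total <- sum(config$n)
  sampDf <- data.frame(sample_id = character(), cohort = character(),
                       reported_sex = character(),
                       karyotype_class = character(),
                       mosaic_class = character(),
                       mosaic_target = character(),
                       mosaic_fraction = numeric(),
                       upd_chrom = character(), upd_recovery = numeric(),
                       stringsAsFactors = FALSE)
  cnvDf <- data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(), cn = integer(),
                      n_markers = integer(), stringsAsFactors = FALSE)
  if (total == 0) {
    empty <- IntensitySet(matrix(numeric(), length(map), 0),
                          matrix(numeric(), length(map), 0), map)
    return(list(profiles = empty,
                truth = new("TruthTable", samples = sampDf, cnvs = cnvDf,
                            params = list(config = config, seed = seed))))
  }
  lrrM <- matrix(NA_real_, length(map), total)
  bafM <- matrix(NA_real_, length(map), total)
  ids <- character(total)
  col <- 0L
  cnvRows <- list()
  for (arm in arms) {
    nArm <- config$n[[arm]]
    if (nArm == 0) next
    counts <- apportion(nArm, config$classProportions)
    classes <- rep(names(config$classProportions), counts)
    mult <- 1
    if (!is.null(config$cnvRateMultiplier) &&
        arm %in% names(config$cnvRateMultiplier))
      mult <- config$cnvRateMultiplier[[arm]]
    for (i in seq_len(nArm)) {
      col <- col + 1L
      sid <- sprintf("%s_%04d", arm, i)
      ids[col] <- sid
      cseed <- childSeed(seed, col)
      res <- withSeed(cseed, {
        info <- .classToSpec(classes[i], config)
        spec <- info$spec
        ncnv <- rpois(1, config$cnvRate * mult)
        cnvs <- list()
        if (ncnv > 0) for (k in seq_len(ncnv)) {
          cv <- .drawCnv(map, config)
          if (is.null(cv)) next
          # one event per locus per sample: reject overlapping draws so
          # every true CNV appears exactly once in the truth table
          clash <- any(vapply(cnvs, function(o)
            o$chrom == cv$chrom && o$start <= cv$end && cv$start <= o$end,
            TRUE))
          if (!clash) cnvs[[length(cnvs) + 1L]] <- cv
        }
        if (length(cnvs)) {
          cnvTab <- do.call(rbind, lapply(cnvs, as.data.frame))
          spec@cnvs <- cnvTab[c("chrom", "start", "end", "cn")]
        }
        prof <- .simulateProfile(spec, map, noise)
        list(info = info, cnvs = cnvs, prof = prof)
      })
      lrrM[, col] <- res$prof$lrr
      bafM[, col] <- res$prof$baf
      info <- res$info
      sex <- info$sex
      if (is.na(sex))
        sex <- if (info$spec@sexChromosomes == "XX") "female" else "male"
      sampDf[col, ] <- list(sid, arm, sex, classes[i],
                            info$mosaic_class %||% NA_character_,
                            info$mosaic_target %||% NA_character_,
                            info$mosaic_fraction %||% NA_real_,
                            info$upd_chrom %||% NA_character_,
                            info$upd_recovery %||% NA_real_)
      if (length(res$cnvs))
        cnvRows[[length(cnvRows) + 1L]] <- cbind(
          sample_id = sid, do.call(rbind, lapply(res$cnvs, as.data.frame)))
    }
  }
  if (length(cnvRows)) cnvDf <- do.call(rbind, cnvRows)
  colnames(lrrM) <- colnames(bafM) <- ids
  list(profiles = IntensitySet(lrrM, bafM, map),
       truth = new("TruthTable", samples = sampDf,
                   cnvs = cnvDf[order(cnvDf$sample_id), , drop = FALSE],
                   params = list(config = config, noise = noise,
                                 seed = seed)))
}

#' Simulate per-algorithm CNV call sets from ground truth
#'
#' Emulates the disagreement between independent CNV callers: each true CNV
#' is emitted per algorithm with probability `1 - fnRate`, with endpoints
#' jittered by Gaussian noise; false-positive calls are added per sample at
#' Poisson rate `fpRate`, anchored on a uniformly chosen autosomal marker
#' (callers only emit calls that span markers) with sizes drawn
#' log-uniformly from 20-500 kb. Marker counts are recomputed from the map
#' after jitter; calls left covering no markers are dropped.
#'
#' @param truth a [TruthTable-class] (from [simulateCohort()]).
#' @param map the marker map the truth was simulated over.
#' @param algorithms character vector of caller labels (default three).
#' @param error `list(fpRate=, fnRate=, jitterSd=)`: false-positive rate per
#'   sample, per-call false-negative rate, endpoint jitter SD in bp.
#' @param seed RNG seed.
#' @return a named list (one element per algorithm) of CNV-call `GRanges`
#'   in the [readCnvCalls()] layout.
#' @export
simulateCallsets <- function(truth, map,
                             algorithms = c("pennCNV", "quantiSNP",
                                            "iPattern"),
                             error = list(fpRate = 0.1, fnRate = 0.05,
                                          jitterSd = 5000),
                             seed) {
  stopifnot(is(truth, "TruthTable"))
  validateMarkerMap(map)
  stopifnot(error$fpRate >= 0, error$fnRate >= 0, error$fnRate <= 1,
            error$jitterSd >= 0)
  chrom <- as.character(seqnames(map))
  pos <- start(map)
  countMk <- function(ch, s, e) sum(chrom == ch & pos >= s & pos <= e)
  tc <- truthCnvs(truth)
  sids <- truthSamples(truth)$sample_id
  withSeed(seed, {
    out <- list()
    for (alg in algorithms) {
      rows <- list()
      if (nrow(tc)) for (k in seq_len(nrow(tc))) {
        if (runif(1) < error$fnRate) next
        s <- tc$start[k] + round(rnorm(1, 0, error$jitterSd))
        e <- tc$end[k] + round(rnorm(1, 0, error$jitterSd))
        if (s > e) { tmp <- s; s <- e; e <- tmp }
        s <- max(1, s)
        nm <- countMk(tc$chrom[k], s, e)
        if (nm < 1) next
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = tc$sample_id[k], chrom = tc$chrom[k], start = s,
          end = e, cn = tc$cn[k], n_markers = nm,
          score = round(runif(1, 10, 50), 2))
      }
      autoIdx <- which(chrom %in% AUTOSOMES)
      for (sid in sids) {
        nfp <- rpois(1, error$fpRate)
        if (nfp == 0) next
        for (j in seq_len(nfp)) {
          anchor <- autoIdx[sample.int(length(autoIdx), 1)]
          ch <- chrom[anchor]
          len <- floor(10^runif(1, log10(2e4), log10(5e5)))
          s <- max(1, floor(pos[anchor] - runif(1) * (len - 1)))
          e <- s + len - 1
          nm <- countMk(ch, s, e)
          if (nm < 1) next
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, chrom = ch, start = s, end = e,
            cn = sample(c(1L, 3L), 1), n_markers = nm,
            score = round(runif(1, 5, 20), 2))
        }
      }
      if (length(rows)) {
        df <- do.call(rbind, rows)
        out[[alg]] <- makeCnvCalls(df$sample_id, df$chrom, df$start, df$end,
                                   df$cn, df$n_markers, alg, df$score)
      } else {
        out[[alg]] <- makeCnvCalls(character(), character(), integer(),
                                   integer(), integer(), integer(),
                                   character())
      }
    }
    out
  })
}

#' Simulate toy gene and region annotation sets
#'
#' Places `n` non-adjudicated intervals uniformly on the autosomes, for use
#' as gene models (`sizeRange` defaulting to gene-scale) or as
#' disease-associated regions (pass Mb-scale sizes). Labels are
#' `prefix_0001` style.
#'
#' @param n number of intervals.
#' @param seed RNG seed.
#' @param sizeRange interval length range in bp (log-uniform).
#' @param prefix label prefix.
#' @return a region `GRanges` with mcols `label`.
#' @export
simulateGenes <- function(n, seed, sizeRange = c(1e4, 2e5),
                          prefix = "gene") {
  stopifnot(n >= 1)
  withSeed(seed, {
    ch <- sample(AUTOSOMES, n, replace = TRUE)
    len <- floor(10^runif(n, log10(sizeRange[1]), log10(sizeRange[2])))
    s <- floor(runif(n, 1, CHROM_LENGTHS[ch] - len))
    gr <- GRanges(ch, IRanges(s, s + len - 1))
    mcols(gr)$label <- sprintf("%s_%04d", prefix, seq_len(n))
    sort(gr)
  })
}
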