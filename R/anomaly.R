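# Chromosome-level anomaly detection from per-chromosome LRR/BAF summaries:
# sex-chromosome and autosomal aneuploidy, whole-chromosome uniparental
# isodisomy (complete and with distal heterozygosity recovery), and
# mosaicism with fraction estimation by inversion of the BAF band model.
#
# The screening statistic is the >3 SD rule: for each chromosome, the LRR
# mean and BAF heterozygosity rate are converted to z-scores against the
# mean/SD of that statistic across all other autosomes of the same sample
# (leave-one-out, so a large anomaly cannot inflate its own reference).
# Flags are then resolved by an explicit decision table (in place of visual
# inspection) that additionally requires the absolute signal to be
# consistent with the flagged class: a minimum LRR shift and, for mosaic
# classes, a measurable displacement d of the heterozygous BAF band from
# 0.5. The band displacement inverts to the abnormal cell fraction f:
#   monosomy mosaic:  d = f / (2 (2 - f))   =>  f = 4d / (1 + 2d)
#   trisomy mosaic:   d = f / (2 (2 + f))   =>  f = 4d / (1 - 2d)

#' Detection thresholds for chromosome-anomaly calling
#'
#' All thresholds of the anomaly layer in one config object. Defaults are
#' calibrated on the simulator at default noise (see the vignette).
#'
#' @param hetWindow BAF window counting a marker as heterozygous.
#' @param minMarkers marker floor below which a chromosome gets no z-scores.
#' @param hetXThreshold X heterozygosity rate below which a single X is
#'   predicted.
#' @param yLrrThreshold Y LRR mean above which a Y is predicted present.
#' @param zXxx X-dosage z-score (X LRR mean vs autosomes) above which a
#'   double-X sample becomes a 47,XXX candidate.
#' @param zCn max |LRR z| for a copy-neutral (UPD) interpretation; a
#'   chromosome also counts as copy-neutral when `|lrr_mean| <= lrrCnMax`
#'   regardless of z (the absolute criterion is more stable on dense
#'   chromosomes, whose leave-one-out z has unit variance even when the
#'   mean shift is negligible).
#' @param lrrCnMax absolute LRR mean bound for the copy-neutral criterion.
#' @param updEntryHetMax maximum chromosome heterozygosity rate for the
#'   isodisomy branch to be considered at all (a chance z-flag on a
#'   chromosome with normal heterozygosity is never a UPD candidate).
#' @param zHet BAF-heterozygosity z below `-zHet` flags heterozygosity loss.
#' @param zAneuploidy |LRR z| beyond which copy-number change is flagged.
#' @param updHetMax max heterozygosity rate for complete isodisomy.
#' @param rMin minimum markers in a distal run regaining heterozygosity for
#'   the partial-recovery UPD class.
#' @param recoveryHetMin minimum het rate inside that distal run.
#' @param gMin minimum number of autosomes with a split heterozygous band to
#'   call genome-wide diploid/triploid mosaicism.
#' @param dSplit band displacement above which a band counts as split.
#' @param lrrGainMin,lrrLossMax minimum absolute LRR shift corroborating a
#'   gain / loss flag (guards the 3 SD rule against multiplicity).
#' @param dMin minimum band displacement corroborating a mosaic call.
#' @param fFull estimated fraction at or above which a mosaic is reported
#'   as full aneuploidy.
#' @param interiorWindow BAF window isolating band (non-homozygous) markers.
#' @param minInterior minimum interior markers for band estimation; below
#'   this a loss is treated as complete (no residual band).
#' @param bafSd assumed platform BAF noise SD at heterozygous bands, used to
#'   de-bias the band-displacement estimator (folded-normal inversion).
#' @return a list of class `anomalyThresholds`.
#' @export
anomalyThresholds <- function(hetWindow = c(0.25, 0.75), minMarkers = 10,
                              hetXThreshold = 0.05, yLrrThreshold = -1,
                              zXxx = 3, zCn = 2.5, lrrCnMax = 0.1,
                              zHet = 3,
                              zAneuploidy = 3, updHetMax = 0.02,
                              updEntryHetMax = 0.2, rMin = 10,
                              recoveryHetMin = 0.12, gMin = 10,
                              dSplit = 0.05, lrrGainMin = 0.1,
                              lrrLossMax = -0.1, dMin = 0.04, fFull = 0.95,
                              interiorWindow = c(0.05, 0.95),
                              minInterior = 10, bafSd = 0.03) {
  structure(as.list(environment()), class = "anomalyThresholds")
}

#' Per-chromosome LRR/BAF summaries with leave-one-out z-scores
#'
#' For every sample and chromosome: the LRR mean over observed markers, the
#' BAF heterozygosity rate (fraction of markers with BAF inside
#' `hetWindow`), and z-scores of both statistics against the mean/SD of the
#' statistic across all *other* autosomes of the same sample. Sex
#' chromosomes are scored against the full autosomal reference.
#' Chromosomes below the marker floor carry `NA` z-scores.
#'
#' @param x an [IntensitySet-class].
#' @param thresholds an [anomalyThresholds()] list (uses `hetWindow`,
#'   `minMarkers`).
#' @return a data.frame with columns `sample_id`, `chrom`, `n_markers`,
#'   `lrr_mean`, `baf_het_rate`, `z_lrr`, `z_het`.
#' @export
summarizeChromosomes <- function(x, thresholds = anomalyThresholds()) {
  stopifnot(is(x, "IntensitySet"))
  if (nrow(x) == 0L || ncol(x) == 0L)
    stopf("empty intensity profile")
  chrom <- as.character(seqnames(rowRanges(x)))
  chromLevels <- intersect(ALLOWED_CHROMS, unique(chrom))
  idxByChr <- split(seq_len(nrow(x)), factor(chrom, chromLevels))
  lo <- thresholds$hetWindow[1]
  hi <- thresholds$hetWindow[2]
  L <- lrr(x)
  B <- baf(x)
  out <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    lj <- L[, j]
    bj <- B[, j]
    if (all(is.na(lj)))
      stopf("sample %s has no observed LRR values", colnames(x)[j])
    nMk <- vapply(idxByChr, function(i) sum(!is.na(lj[i])), 0L)
    lm_ <- vapply(idxByChr, function(i) mean(lj[i], na.rm = TRUE), 0)
    hr <- vapply(idxByChr, function(i) {
      b <- bj[i][!is.na(bj[i])]
      if (!length(b)) NA_real_ else mean(b >= lo & b <= hi)
    }, 0)
    ok <- nMk >= thresholds$minMarkers
    isAuto <- chromLevels %in% AUTOSOMES
    zl <- zh <- rep(NA_real_, length(chromLevels))
    refIdx <- which(isAuto & ok)
    if (length(refIdx) >= 3) {
      loo <- function(v, k) {
        r <- setdiff(refIdx, k)
        c(mean(v[r]), sd(v[r]))
      }
      for (k in seq_along(chromLevels)) {
        if (!ok[k]) next
        ms <- loo(lm_, k)
        if (is.finite(ms[2]) && ms[2] > 0) zl[k] <- (lm_[k] - ms[1]) / ms[2]
        ms <- loo(hr, k)
        if (is.finite(ms[2]) && ms[2] > 0) zh[k] <- (hr[k] - ms[1]) / ms[2]
      }
    }
    out[[j]] <- data.frame(sample_id = colnames(x)[j],
                           chrom = chromLevels, n_markers = nMk,
                           lrr_mean = lm_, baf_het_rate = hr, z_lrr = zl,
                           z_het = zh, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Predict sex-chromosome complement from X heterozygosity and Y intensity
#'
#' Two independent predictions per sample: `x_pred` (`single_X` iff the X
#' BAF heterozygosity rate is below `hetXThreshold`) and `y_pred`
#' (`Y_present` iff the Y LRR mean exceeds `yLrrThreshold`). The combined
#' call resolves the four combinations to XX / XY / X (Turner) / XXY
#' (Klinefelter), with double-X samples promoted to `XXX_candidate` when
#' the X-dosage z-score (X LRR mean against the autosomal reference)
#' exceeds `zXxx`. Discordance with a reported sex is flagged, never
#' auto-corrected. Samples without X or Y markers get an explicit
#' `undetermined` call.
#'
#' @param summaries output of [summarizeChromosomes()].
#' @param reportedSex optional data.frame (`sample_id`, `reported_sex`
#'   in male/female) or named character vector.
#' @param thresholds an [anomalyThresholds()] list.
#' @return a data.frame with one row per sample: `sample_id`, `x_het_rate`,
#'   `y_lrr_mean`, `x_dosage_z`, `x_pred`, `y_pred`, `combined`,
#'   `concordant_with_reported`.
#' @export
predictSex <- function(summaries, reportedSex = NULL,
                       thresholds = anomalyThresholds()) {
  if (is.data.frame(reportedSex))
    reportedSex <- setNames(reportedSex$reported_sex,
                            reportedSex$sample_id)
  res <- lapply(split(summaries, summaries$sample_id), function(ss) {
    xi <- ss[ss$chrom == "X", ]
    yi <- ss[ss$chrom == "Y", ]
    sid <- ss$sample_id[1]
    if (nrow(xi) == 0L || nrow(yi) == 0L || xi$n_markers == 0 ||
        yi$n_markers == 0)
      return(data.frame(sample_id = sid, x_het_rate = NA_real_,
                        y_lrr_mean = NA_real_, x_dosage_z = NA_real_,
                        x_pred = NA_character_, y_pred = NA_character_,
                        combined = "undetermined",
                        concordant_with_reported = NA))
    auto <- ss[ss$chrom %in% AUTOSOMES & is.finite(ss$lrr_mean) &
               ss$n_markers >= thresholds$minMarkers, ]
    xz <- if (nrow(auto) >= 3 && sd(auto$lrr_mean) > 0)
      (xi$lrr_mean - mean(auto$lrr_mean)) / sd(auto$lrr_mean)
    else NA_real_
    xp <- if (xi$baf_het_rate < thresholds$hetXThreshold) "single_X"
          else "double_X_or_more"
    yp <- if (yi$lrr_mean > thresholds$yLrrThreshold) "Y_present"
          else "Y_absent"
    comb <- if (xp == "single_X" && yp == "Y_present") "XY"
      else if (xp == "single_X") "X"
      else if (yp == "Y_present") "XXY"
      else if (is.finite(xz) && xz > thresholds$zXxx) "XXX_candidate"
      else "XX"
    data.frame(sample_id = sid, x_het_rate = xi$baf_het_rate,
               y_lrr_mean = yi$lrr_mean, x_dosage_z = xz, x_pred = xp,
               y_pred = yp, combined = comb,
               concordant_with_reported = NA)
  })
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  if (!is.null(reportedSex)) {
    rep_ <- reportedSex[out$sample_id]
    out$concordant_with_reported <-
      (rep_ == "female" & out$combined == "XX") |
      (rep_ == "male" & out$combined == "XY")
  }
  out
}

#' Invert the BAF band displacement to a mosaic cell fraction
#'
#' For a mosaic with abnormal cell fraction f, the heterozygous BAF band
#' sits at distance d from 0.5 with d = f/(2(2-f)) for monosomy mosaics and
#' d = f/(2(2+f)) for trisomy (and diploid/triploid) mosaics. This inverts
#' those relations: f = 4d/(1+2d) (monosomy) or f = 4d/(1-2d) capped at 1
#' (trisomy).
#'
#' @param d band displacement(s) in \[0, 0.5\].
#' @param klass `"monosomy"` or `"trisomy"` (triploid uses the trisomy
#'   form).
#' @return estimated fraction(s) f in \[0, 1\].
#' @examples
#' estimateMosaicFraction(1/6, "monosomy")  # 0.5
#' estimateMosaicFraction(1/6, "trisomy")   # 1
#' @export
estimateMosaicFraction <- function(d, klass = c("monosomy", "trisomy")) {
  klass <- match.arg(klass)
  if (any(!is.finite(d)) || any(d < 0) || any(d > 0.5))
    stopf("band displacement d must lie in [0, 0.5]")
  if (klass == "monosomy") 4 * d / (1 + 2 * d)
  else pmin(4 * d / pmax(1 - 2 * d, 1e-12), 1)
}

# E|X - 0.5| for X ~ N(0.5 +/- d, sigma): folded-normal mean. Monotone
# increasing in d; inverted numerically to de-bias the naive mean-absolute
# displacement when d is comparable to sigma.
.foldedMean <- function(d, sigma) {
  sigma * sqrt(2 / pi) * exp(-d^2 / (2 * sigma^2)) +
    d * (1 - 2 * pnorm(-d / sigma))
}

# Estimate band displacement d from interior BAF values.
.bandDeviation <- function(bafs, thr) {
  b <- bafs[!is.na(bafs) & bafs > thr$interiorWindow[1] &
            bafs < thr$interiorWindow[2]]
  if (length(b) < thr$minInterior)
    return(list(n = length(b), d = NA_real_))
  mAbs <- mean(abs(b - 0.5))
  s <- thr$bafSd
  if (mAbs <= .foldedMean(0, s)) return(list(n = length(b), d = 0))
  if (mAbs >= .foldedMean(0.5, s)) return(list(n = length(b), d = 0.5))
  d <- uniroot(function(dd) .foldedMean(dd, s) - mAbs, c(0, 0.5),
               tol = 1e-7)$root
  list(n = length(b), d = d)
}

# Detect a distal run of markers regaining heterozygosity on an otherwise
# homozygous chromosome. het: logical vector in position order.
.distalRecovery <- function(het, thr) {
  n <- length(het)
  if (n < thr$rMin * 2) return(NULL)
  csum <- cumsum(het)
  tot <- csum[n]
  # candidate boundaries: suffix of length rMin .. n/2
  sufLen <- thr$rMin:floor(n / 2)
  s <- n - sufLen + 1
  prefHet <- csum[s - 1] / (s - 1)
  sufHet <- (tot - csum[s - 1]) / sufLen
  feas <- prefHet < thr$updHetMax & sufHet >= thr$recoveryHetMin
  if (!any(feas)) return(NULL)
  # the longest feasible suffix = earliest boundary
  k <- max(sufLen[feas])
  list(run = k, frac = k / n)
}

#' Classify chromosome-level anomalies for each sample
#'
#' Applies the decision table described in the vignette to every autosome
#' (and optionally X) of every sample: uniparental isodisomy (copy-neutral
#' LRR with chromosome-wide heterozygosity loss, complete or with a distal
#' recovery run), full and mosaic trisomy/monosomy (LRR shift beyond the
#' `zAneuploidy` SD rule, corroborated by the absolute LRR shift and the
#' heterozygous-band displacement, which also yields the mosaic fraction
#' estimate), and genome-wide diploid/triploid mosaicism (split
#' heterozygous band on at least `gMin` autosomes with no per-chromosome
#' z-flag, since a genome-wide shift cancels in the within-sample
#' reference). Contradictory evidence is reported as the LRR-driven class
#' with `warning_flag = TRUE`, never silently dropped.
#'
#' @param x an [IntensitySet-class].
#' @param thresholds an [anomalyThresholds()] list.
#' @param summaries optional precomputed [summarizeChromosomes()] output.
#' @param includeX also score chromosome X against the autosomal reference
#'   (used by [classifyKaryotype()] for 45,X/46,XX mosaics; X is skipped
#'   for samples whose X heterozygosity indicates a single X).
#' @return a data.frame with one row per scored sample-chromosome (plus one
#'   `genome` row per triploid-mosaic sample): `sample_id`, `chrom`,
#'   `class`, `mosaic_fraction`, `z_lrr`, `z_het`, `band_deviation`,
#'   `warning_flag`. `class` is one of `normal`, `monosomy`, `trisomy`,
#'   `mosaic_monosomy`, `mosaic_trisomy`, `upd_complete`,
#'   `upd_partial_recovery`, `triploid_mosaic`.
#' @export
classifyAnomaly <- function(x, thresholds = anomalyThresholds(),
                            summaries = NULL, includeX = FALSE) {
  stopifnot(is(x, "IntensitySet"))
  if (is.null(summaries)) summaries <- summarizeChromosomes(x, thresholds)
  thr <- thresholds
  chrom <- as.character(seqnames(rowRanges(x)))
  ord <- order(match(chrom, ALLOWED_CHROMS), start(rowRanges(x)))
  B <- baf(x)
  rows <- list()
  for (sid in colnames(x)) {
    ss <- summaries[summaries$sample_id == sid, ]
    bj <- B[, sid]
    dAll <- numeric(0)       # band displacement per scored autosome
    scanChroms <- AUTOSOMES
    if (includeX) {
      xr <- ss[ss$chrom == "X", ]
      if (nrow(xr) == 1 && is.finite(xr$baf_het_rate) &&
          xr$baf_het_rate >= thr$hetXThreshold)
        scanChroms <- c(scanChroms, "X")
    }
    for (ch in scanChroms) {
      sc <- ss[ss$chrom == ch, ]
      if (nrow(sc) != 1 || sc$n_markers < thr$minMarkers) next
      zl <- sc$z_lrr
      zh <- sc$z_het
      if (ch == "X") {
        # X scored against the full autosomal reference
        auto <- ss[ss$chrom %in% AUTOSOMES &
                   ss$n_markers >= thr$minMarkers, ]
        if (nrow(auto) >= 3) {
          zl <- (sc$lrr_mean - mean(auto$lrr_mean)) / sd(auto$lrr_mean)
          zh <- (sc$baf_het_rate - mean(auto$baf_het_rate)) /
            sd(auto$baf_het_rate)
        }
      }
      if (!is.finite(zl)) next
      idx <- ord[chrom[ord] == ch]
      bd <- .bandDeviation(bj[idx], thr)
      klass <- "normal"
      fHat <- NA_real_
      warn <- FALSE
      copyNeutral <- abs(zl) <= thr$zCn || abs(sc$lrr_mean) <= thr$lrrCnMax
      if (zl > thr$zAneuploidy && sc$lrr_mean >= thr$lrrGainMin) {
        if (!is.na(bd$d) && bd$d >= thr$dMin) {
          fHat <- estimateMosaicFraction(bd$d, "trisomy")
          klass <- if (fHat >= thr$fFull) "trisomy" else "mosaic_trisomy"
          if (fHat >= thr$fFull) fHat <- NA_real_
        } else {
          klass <- "trisomy"; warn <- TRUE
        }
      } else if (zl < -thr$zAneuploidy && sc$lrr_mean <= thr$lrrLossMax) {
        if (is.na(bd$d)) {
          # no residual interior band: complete loss
          klass <- "monosomy"
        } else if (bd$d >= thr$dMin) {
          fHat <- estimateMosaicFraction(bd$d, "monosomy")
          klass <- if (fHat >= thr$fFull) "monosomy" else "mosaic_monosomy"
          if (fHat >= thr$fFull) fHat <- NA_real_
        } else {
          # mean shift without chromosome-wide band displacement: most
          # likely a segmental loss; LRR-driven class kept, but flagged
          klass <- "monosomy"; warn <- TRUE
        }
      } else if (copyNeutral && is.finite(zh) && zh <= -thr$zHet &&
                 sc$baf_het_rate < thr$updEntryHetMax) {
        # copy-neutral heterozygosity loss: isodisomy
        if (sc$baf_het_rate < thr$updHetMax) {
          klass <- "upd_complete"
        } else {
          hetv <- bj[idx]
          hetv <- !is.na(hetv) & hetv >= thr$hetWindow[1] &
            hetv <= thr$hetWindow[2]
          rec <- .distalRecovery(hetv, thr)
          if (!is.null(rec)) klass <- "upd_partial_recovery"
          else warn <- TRUE  # partial het loss without distal structure
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, chrom = ch, class = klass, mosaic_fraction = fHat,
        z_lrr = zl, z_het = zh, band_deviation = bd$d, warning_flag = warn)
      if (ch %in% AUTOSOMES && klass == "normal" && !is.na(bd$d))
        dAll <- c(dAll, bd$d)
    }
    # genome-wide diploid/triploid mosaic: split het band at near-diploid
    # LRR on many autosomes (invisible to the within-sample z reference)
    nSplit <- sum(dAll >= thr$dSplit)
    if (nSplit >= thr$gMin) {
      dMed <- stats::median(dAll[dAll >= thr$dSplit])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, chrom = "genome", class = "triploid_mosaic",
        mosaic_fraction = estimateMosaicFraction(dMed, "trisomy"),
        z_lrr = NA_real_, z_het = NA_real_, band_deviation = dMed,
        warning_flag = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sample_id = character(), chrom = character(),
                      class = character(), mosaic_fraction = numeric(),
                      z_lrr = numeric(), z_het = numeric(),
                      band_deviation = numeric(), warning_flag = logical()))
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Whole-sample karyotype classification
#'
#' Combines [predictSex()] and [classifyAnomaly()] (with X included) into a
#' single predicted karyotype class per sample, using the same class labels
#' as the cohort simulator: `XX`, `XY`, `turner`, `klinefelter`,
#' `triple_x`, `x_mosaic`, `triploid_mosaic`, `upd`, `upd_partial`,
#' `autosomal_trisomy_mosaic` (plus `autosomal_monosomy_mosaic`,
#' `autosomal_trisomy`, `autosomal_monosomy` for completeness).
#' Genome-wide triploid mosaicism takes priority, then X mosaicism, then
#' autosomal UPD / aneuploidy, then the sex-chromosome call.
#'
#' @param x an [IntensitySet-class].
#' @param thresholds an [anomalyThresholds()] list.
#' @return a data.frame: `sample_id`, `karyotype_class`, `sex_combined`,
#'   `detail` (chromosome and estimated mosaic fraction where relevant).
#' @export
classifyKaryotype <- function(x, thresholds = anomalyThresholds()) {
  summaries <- summarizeChromosomes(x, thresholds)
  sex <- predictSex(summaries, thresholds = thresholds)
  anom <- classifyAnomaly(x, thresholds, summaries = summaries,
                          includeX = TRUE)
  out <- lapply(colnames(x), function(sid) {
    sx <- sex[sex$sample_id == sid, ]
    # warning-flagged calls (contradictory evidence, typically segmental
    # CNVs masquerading as chromosome-level shifts) never set the sample
    # karyotype
    an <- anom[anom$sample_id == sid & anom$class != "normal" &
               !anom$warning_flag, ]
    klass <- switch(sx$combined, XX = "XX", XY = "XY", X = "turner",
                    XXY = "klinefelter", XXX_candidate = "triple_x",
                    "undetermined")
    detail <- ""
    anAuto <- an[an$chrom %in% AUTOSOMES, ]
    anX <- an[an$chrom == "X", ]
    if (nrow(an) && any(an$class == "triploid_mosaic" &
                        an$chrom == "genome")) {
      g <- an[an$class == "triploid_mosaic" & an$chrom == "genome", ][1, ]
      klass <- "triploid_mosaic"
      detail <- sprintf("f_hat=%.3f", g$mosaic_fraction)
    } else if (nrow(anX) && any(anX$class == "mosaic_monosomy") &&
               sx$combined == "XX") {
      g <- anX[anX$class == "mosaic_monosomy", ][1, ]
      klass <- "x_mosaic"
      detail <- sprintf("f_hat=%.3f", g$mosaic_fraction)
    } else if (nrow(anAuto) && any(anAuto$class == "upd_partial_recovery")) {
      g <- anAuto[anAuto$class == "upd_partial_recovery", ][1, ]
      klass <- "upd_partial"
      detail <- sprintf("chr%s", g$chrom)
    } else if (nrow(anAuto) && any(anAuto$class == "upd_complete")) {
      g <- anAuto[anAuto$class == "upd_complete", ][1, ]
      klass <- "upd"
      detail <- sprintf("chr%s", g$chrom)
    } else if (nrow(anAuto)) {
      # X aneuploidy is already captured by the sex-chromosome call;
      # only autosomal events relabel the sample here
      g <- anAuto[1, ]
      klass <- switch(g$class,
                      mosaic_trisomy = "autosomal_trisomy_mosaic",
                      mosaic_monosomy = "autosomal_monosomy_mosaic",
                      trisomy = "autosomal_trisomy",
                      monosomy = "autosomal_monosomy", klass)
      detail <- sprintf("chr%s", g$chrom)
    }
    data.frame(sample_id = sid, karyotype_class = klass,
               sex_combined = sx$combined, detail = detail)
  })
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
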