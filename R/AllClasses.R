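#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#'   findOverlaps countOverlaps reduce pintersect
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges colData
#' @importFrom stats dhyper rnorm runif rbinom rpois sd var quantile lm pf qf
#'   pnorm qnorm uniroot setNames complete.cases coef rexp eigen na.omit
#' @importFrom utils read.delim write.table head
NULL

#' IntensitySet: per-marker LRR/BAF intensities for a set of samples
#'
#' An `IntensitySet` is a
#' [SummarizedExperiment::RangedSummarizedExperiment] with exactly two
#' assays, `lrr` (log R ratio, log2 units; `NA` = missing) and `baf`
#' (B allele frequency, clipped to \[0, 1\]; `NA` = missing), whose rows are
#' the markers of a marker map (see [simulateMarkerMap()], [readMarkerMap()])
#' and whose columns are samples.
#'
#' @slot .  inherits all slots from `RangedSummarizedExperiment`.
#' @seealso [IntensitySet()], [lrr()], [baf()], [markerMap()]
#' @export
setClass("IntensitySet", contains = "RangedSummarizedExperiment")

setValidity("IntensitySet", function(object) {
  msg <- character()
  if (!identical(sort(SummarizedExperiment::assayNames(object)),
                 c("baf", "lrr")))
    msg <- c(msg, "assays must be named 'lrr' and 'baf'")
  else {
    b <- assay(object, "baf")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "baf values must lie in [0, 1] (or NA)")
    l <- assay(object, "lrr")
    if (any(is.infinite(l)))
      msg <- c(msg, "lrr values must be finite or NA")
  }
  rr <- rowRanges(object)
  if (is.null(names(rr)) || anyDuplicated(names(rr)))
    msg <- c(msg, "markers must carry unique ids as rowRanges names")
  if (length(msg)) msg else TRUE
})

#' Construct an IntensitySet
#'
#' @param lrr,baf numeric matrices (markers x samples) of log R ratios and
#'   B allele frequencies, with identical dimensions.
#' @param markers a marker map `GRanges` (width-1 positions, unique names) as
#'   returned by [simulateMarkerMap()] or [readMarkerMap()]; one range per
#'   row of `lrr`.
#' @return an [IntensitySet-class] object.
#' @examples
#' map <- simulateMarkerMap(200, 20, 5, seed = 1)
#' x <- simulateSample(KaryotypeSpec("XX"), map, NoiseModel(), seed = 2)
#' is(x, "IntensitySet")
#' @export
IntensitySet <- function(lrr, baf, markers) {
  lrr <- as.matrix(lrr)
  baf <- as.matrix(baf)
  if (!identical(dim(lrr), dim(baf)))
    stopf("lrr and baf must have identical dimensions")
  validateMarkerMap(markers)
  if (length(markers) != nrow(lrr))
    stopf("marker map length (%d) != number of intensity rows (%d)",
          length(markers), nrow(lrr))
  rownames(lrr) <- rownames(baf) <- names(markers)
  se <- SummarizedExperiment(
    assays = list(lrr = lrr, baf = baf), rowRanges = markers)
  new("IntensitySet", se)
}

#' @describeIn IntensitySet extract the LRR matrix.
#' @param x an `IntensitySet`.
#' @export
setGeneric("lrr", function(x) standardGeneric("lrr"))

#' @rdname IntensitySet
#' @export
setMethod("lrr", "IntensitySet", function(x) assay(x, "lrr"))

#' @describeIn IntensitySet extract the BAF matrix.
#' @export
setGeneric("baf", function(x) standardGeneric("baf"))

#' @rdname IntensitySet
#' @export
setMethod("baf", "IntensitySet", function(x) assay(x, "baf"))

#' @describeIn IntensitySet extract the marker map (`GRanges`).
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname IntensitySet
#' @export
setMethod("markerMap", "IntensitySet", function(x) rowRanges(x))

setMethod("show", "IntensitySet", function(object) {
  cat(sprintf("IntensitySet: %d markers x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  chromosomes: %s\n",
              paste(S4Vectors::runValue(seqnames(rowRanges(object))),
                    collapse = ", ")))
  callNextMethod()
})

#' KaryotypeSpec: ground-truth karyotype of one simulated sample
#'
#' Describes the constitutional (and, for mosaics, the mixed) karyotype that
#' [simulateSample()] renders into LRR/BAF signal.
#'
#' @slot sexChromosomes one of `"XX"`, `"XY"`, `"X"` (Turner), `"XXY"`
#'   (Klinefelter), `"XXX"` (triple X).
#' @slot mosaic empty list, or `list(class=, target=, fraction=)` where
#'   `class` is one of `"monosomy_mosaic"`, `"trisomy_mosaic"`,
#'   `"triploid_mosaic"`; `target` is a chromosome label or `"genome"`
#'   (required and forced for `triploid_mosaic`); `fraction` is the abnormal
#'   cell fraction f in \[0, 1\]. f = 0 reduces to the unmodified karyotype,
#'   f = 1 is the full anomaly.
#' @slot upd data.frame with columns `chrom` and `recovery`: chromosomes
#'   carrying whole-chromosome uniparental isodisomy (copy number 2, fully
#'   homozygous) with a distal fraction `recovery` in \[0, 1) of markers that
#'   revert to population heterozygosity (partial recombination).
#' @slot cnvs data.frame with columns `chrom`, `start`, `end`, `cn`:
#'   segmental deletions/duplications (integer copy number in 0..4).
#' @seealso [KaryotypeSpec()]
#' @export
setClass("KaryotypeSpec", representation(
  sexChromosomes = "character",
  mosaic = "list",
  upd = "data.frame",
  cnvs = "data.frame"))

setValidity("KaryotypeSpec", function(object) {
  msg <- character()
  if (!object@sexChromosomes %in% c("XX", "XY", "X", "XXY", "XXX"))
    msg <- c(msg, "sexChromosomes must be one of XX, XY, X, XXY, XXX")
  m <- object@mosaic
  if (length(m)) {
    if (!all(c("class", "target", "fraction") %in% names(m)))
      msg <- c(msg, "mosaic needs class, target, fraction")
    else {
      if (!m$class %in% c("monosomy_mosaic", "trisomy_mosaic",
                          "triploid_mosaic"))
        msg <- c(msg, "unknown mosaic class")
      if (m$fraction < 0 || m$fraction > 1)
        msg <- c(msg, "mosaic fraction must lie in [0, 1]")
      if (identical(m$class, "triploid_mosaic") &&
          !identical(m$target, "genome"))
        msg <- c(msg, "triploid_mosaic must target 'genome'")
    }
  }
  u <- object@upd
  if (nrow(u)) {
    if (!all(c("chrom", "recovery") %in% names(u)))
      msg <- c(msg, "upd needs chrom and recovery columns")
    else if (any(u$recovery < 0 | u$recovery >= 1))
      msg <- c(msg, "upd recovery fractions must lie in [0, 1)")
  }
  cv <- object@cnvs
  if (nrow(cv)) {
    need <- c("chrom", "start", "end", "cn")
    if (!all(need %in% names(cv)))
      msg <- c(msg, "cnvs needs chrom, start, end, cn columns")
    else {
      if (any(cv$start > cv$end)) msg <- c(msg, "cnv start > end")
      if (!all(cv$cn %in% 0:4)) msg <- c(msg, "cnv cn must be in 0..4")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a KaryotypeSpec
#'
#' @param sexChromosomes sex-chromosome complement; see
#'   [KaryotypeSpec-class].
#' @param mosaic optional mosaic description
#'   `list(class=, target=, fraction=)`.
#' @param upd data.frame (`chrom`, `recovery`) of uniparental-isodisomy
#'   chromosomes; default none.
#' @param cnvs data.frame (`chrom`, `start`, `end`, `cn`) of segmental CNVs;
#'   default none.
#' @return a validated [KaryotypeSpec-class] object.
#' @examples
#' KaryotypeSpec("X")                                        # 45,X
#' KaryotypeSpec("XX", mosaic = list(class = "monosomy_mosaic",
#'                                   target = "X", fraction = 0.5))
#' @export
KaryotypeSpec <- function(sexChromosomes = "XX", mosaic = list(),
                          upd = data.frame(chrom = character(),
                                           recovery = numeric()),
                          cnvs = data.frame(chrom = character(),
                                            start = integer(),
                                            end = integer(),
                                            cn = integer())) {
  new("KaryotypeSpec", sexChromosomes = sexChromosomes, mosaic = mosaic,
      upd = upd, cnvs = cnvs)
}

setMethod("show", "KaryotypeSpec", function(object) {
  cat("KaryotypeSpec:", object@sexChromosomes)
  if (length(object@mosaic))
    cat(sprintf(" | mosaic %s on %s, f = %.2f", object@mosaic$class,
                object@mosaic$target, object@mosaic$fraction))
  if (nrow(object@upd))
    cat(" | UPD:", paste(object@upd$chrom, collapse = ","))
  if (nrow(object@cnvs)) cat(sprintf(" | %d CNV(s)", nrow(object@cnvs)))
  cat("\n")
})

#' NoiseModel: per-marker signal model for the array simulator
#'
#' @slot lrrSd per-marker LRR noise SD (log2 units).
#' @slot bafSd per-marker BAF noise SD at heterozygous bands; homozygous
#'   bands use half this SD, clipped at the 0/1 boundary.
#' @slot lrrMu named numeric mapping copy number `"0".."4"` to mean LRR;
#'   strictly increasing with `lrrMu["2"] == 0`. Non-integer effective copy
#'   numbers (mosaics) are linearly interpolated.
#' @details Defaults (`lrrSd = 0.20`, `bafSd = 0.03`,
#'   `lrrMu = c(-3.5, -0.66, 0, 0.40, 0.68)`) reflect canonical Illumina
#'   array expectations for blood-derived DNA.
#' @seealso [NoiseModel()], [simulateSample()]
#' @export
setClass("NoiseModel", representation(
  lrrSd = "numeric", bafSd = "numeric", lrrMu = "numeric"))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@lrrSd < 0 || object@bafSd < 0)
    msg <- c(msg, "noise SDs must be non-negative")
  mu <- object@lrrMu
  if (!identical(names(mu), as.character(0:4)))
    msg <- c(msg, "lrrMu must be named '0'..'4'")
  else {
    if (any(diff(mu) <= 0))
      msg <- c(msg, "lrrMu must be strictly increasing in copy number")
    if (abs(mu[["2"]]) > 1e-12) msg <- c(msg, "lrrMu['2'] must be 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a NoiseModel
#'
#' @param lrrSd,bafSd per-marker noise SDs; see [NoiseModel-class].
#' @param lrrMu named numeric, mean LRR per copy number `"0".."4"`.
#' @return a validated [NoiseModel-class] object.
#' @examples
#' NoiseModel()                  # defaults
#' NoiseModel(lrrSd = 0.3)      # noisier array
#' @export
NoiseModel <- function(lrrSd = 0.20, bafSd = 0.03,
                       lrrMu = c(`0` = -3.5, `1` = -0.66, `2` = 0,
                                 `3` = 0.40, `4` = 0.68)) {
  new("NoiseModel", lrrSd = lrrSd, bafSd = bafSd, lrrMu = lrrMu)
}

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: lrrSd = %.3g, bafSd = %.3g, lrrMu = [%s]\n",
              object@lrrSd, object@bafSd,
              paste(sprintf("%g", object@lrrMu), collapse = ", ")))
})

#' TruthTable: complete ground truth of a simulated cohort
#'
#' @slot samples data.frame, one row per sample: `sample_id`, `cohort`
#'   (`case` / `screened_control` / `population_control`), `reported_sex`,
#'   `karyotype_class`, plus mosaic / UPD bookkeeping columns.
#' @slot cnvs data.frame, one row per simulated segmental CNV: `sample_id`,
#'   `chrom`, `start`, `end`, `cn`, `n_markers`.
#' @slot params list of every generator parameter used (noise, error rates,
#'   seeds), for provenance.
#' @seealso [simulateCohort()]
#' @export
setClass("TruthTable", representation(
  samples = "data.frame", cnvs = "data.frame", params = "list"))

setMethod("show", "TruthTable", function(object) {
  cat(sprintf("TruthTable: %d samples (%s), %d true CNVs\n",
              nrow(object@samples),
              paste(sprintf("%s=%d", names(table(object@samples$cohort)),
                            table(object@samples$cohort)), collapse = ", "),
              nrow(object@cnvs)))
})

#' @describeIn TruthTable the per-sample truth data.frame.
#' @param x a `TruthTable`.
#' @export
setGeneric("truthSamples", function(x) standardGeneric("truthSamples"))

#' @rdname TruthTable
#' @export
setMethod("truthSamples", "TruthTable", function(x) x@samples)

#' @describeIn TruthTable the per-CNV truth data.frame.
#' @export
setGeneric("truthCnvs", function(x) standardGeneric("truthCnvs"))

#' @rdname TruthTable
#' @export
setMethod("truthCnvs", "TruthTable", function(x) x@cnvs)
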