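# Per-sample QC, multi-algorithm CNV merging, filter tiers, rarity classes
# and gene/region annotation. Calls from different algorithms on the same
# sample with the same state (deletion vs duplication) are grouped by
# transitive >= 1 bp overlap; mixed-state overlaps are never merged. The
# consensus interval is the intersection of the group (conservative against
# boundary over-call) or its union, and groups supported by fewer than
# `minSupport` algorithms are dropped.

#' Per-sample quality-control thresholds
#'
#' @param lrrSdMax maximum genome-wide LRR SD (noisy DNA fails).
#' @param bafDriftMax maximum BAF drift: fraction of BAF values inside
#'   (0.2, 0.25) or (0.75, 0.8), i.e. adrift between the canonical bands.
#' @param maxCalls maximum CNV calls from any single algorithm (excess
#'   calls indicate artefactual waviness).
#' @return a list of class `qcThresholds`.
#' @export
qcThresholds <- function(lrrSdMax = 0.30, bafDriftMax = 0.01,
                         maxCalls = 30) {
  structure(list(lrrSdMax = lrrSdMax, bafDriftMax = bafDriftMax,
                 maxCalls = maxCalls), class = "qcThresholds")
}

#' Per-sample quality control
#'
#' Computes the sample-wide metrics (autosomal LRR SD, autosomal BAF
#' drift, CNV call count per algorithm) and applies the pass rule
#' `lrr_sd <= lrrSdMax & baf_drift <= bafDriftMax & max call count <=
#' maxCalls`. The thresholds actually applied are recorded as attributes of
#' the result.
#'
#' @param x an [IntensitySet-class].
#' @param callsets named list of per-algorithm CNV-call `GRanges`.
#' @param thresholds a [qcThresholds()] list.
#' @return a data.frame: `sample_id`, `lrr_sd`, `baf_drift`, one
#'   `calls_<algorithm>` column per call set, `max_call_count`, `pass`,
#'   and a `fail_reason` column naming the violated metric(s).
#' @export
sampleQc <- function(x, callsets, thresholds = qcThresholds()) {
  stopifnot(is(x, "IntensitySet"), length(callsets) >= 1)
  # metrics over autosomes only: sex-chromosome dosage (e.g. copy-0 Y
  # background in females) is karyotype, not assay quality
  auto <- as.character(seqnames(rowRanges(x))) %in% AUTOSOMES
  L <- lrr(x)[auto, , drop = FALSE]
  B <- baf(x)[auto, , drop = FALSE]
  lrrSd <- apply(L, 2, sd, na.rm = TRUE)
  drift <- apply(B, 2, function(b) {
    b <- b[!is.na(b)]
    mean((b > 0.2 & b < 0.25) | (b > 0.75 & b < 0.8))
  })
  counts <- vapply(callsets, function(cs) {
    as.integer(table(factor(mcols(cs)$sample_id, levels = colnames(x))))
  }, integer(ncol(x)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = ncol(x))
  colnames(counts) <- paste0("calls_", names(callsets))
  maxCall <- apply(counts, 1, max)
  reason <- character(ncol(x))
  r1 <- lrrSd > thresholds$lrrSdMax
  r2 <- drift > thresholds$bafDriftMax
  r3 <- maxCall > thresholds$maxCalls
  reason <- trimws(paste(ifelse(r1, "lrr_sd", ""),
                         ifelse(r2, "baf_drift", ""),
                         ifelse(r3, "call_count", "")))
  out <- data.frame(sample_id = colnames(x), lrr_sd = lrrSd,
                    baf_drift = drift, counts,
                    max_call_count = maxCall,
                    pass = !(r1 | r2 | r3),
                    fail_reason = reason, row.names = NULL)
  attr(out, "thresholds") <- thresholds
  out
}

#' Merge per-algorithm CNV call sets into consensus CNVs
#'
#' Same-sample, same-state calls whose intervals overlap by at least 1 bp
#' are grouped transitively across algorithms. Each group with at least
#' `minSupport` distinct supporting algorithms yields one consensus CNV
#' whose interval is the intersection of the group (`boundaryRule =
#' "strict"`, default) or its union (`"outer"`). When a transitive group
#' has no common core the strict rule falls back to the union with
#' `core_empty = TRUE`. Deletions and duplications never merge. Marker
#' counts are recomputed from the map over the consensus interval; the
#' consensus copy number is the modal `cn` of the group (ties resolved
#' toward the more extreme state).
#'
#' @param callsets named list of per-algorithm CNV-call `GRanges` (see
#'   [readCnvCalls()]).
#' @param map marker map used to recompute `n_markers`.
#' @param minSupport minimum number of distinct supporting algorithms.
#' @param boundaryRule `"strict"` (intersection) or `"outer"` (union).
#' @return a consensus `GRanges` with mcols `sample_id`, `cn`, `state`,
#'   `n_markers`, `support` (comma-joined algorithm labels), `n_support`,
#'   `length_bp`, `core_empty`.
#' @export
mergeCallsets <- function(callsets, map, minSupport = 1,
                          boundaryRule = c("strict", "outer")) {
  boundaryRule <- match.arg(boundaryRule)
  stopifnot(length(callsets) >= 1)
  validateMarkerMap(map)
  all_ <- unlist(GenomicRanges::GRangesList(lapply(callsets, granges)))
  meta <- do.call(rbind, lapply(names(callsets), function(a) {
    cs <- callsets[[a]]
    # consensus sets re-entering the merge carry 'support' instead of a
    # per-call 'algorithm' (keeps the operation idempotent)
    alg <- mcols(cs)$algorithm %||% mcols(cs)$support %||%
      rep(a, length(cs))
    data.frame(sample_id = mcols(cs)$sample_id, cn = mcols(cs)$cn,
               state = mcols(cs)$state, algorithm = alg)
  }))
  if (length(all_) == 0L)
    return(makeConsensus(data.frame()))
  mcols(all_) <- meta
  names(all_) <- NULL
  groups <- split(seq_along(all_),
                  paste(meta$sample_id, meta$state, sep = "\r"))
  rows <- list()
  for (g in groups) {
    gr <- all_[g]
    red <- reduce(granges(gr), min.gapwidth = 0L)
    hit <- findOverlaps(granges(gr), red)
    clust <- split(g[S4Vectors::queryHits(hit)],
                   S4Vectors::subjectHits(hit))
    for (cl in clust) {
      algs <- sort(unique(unlist(strsplit(meta$algorithm[cl], ","))))
      if (length(algs) < minSupport) next
      ch <- as.character(seqnames(all_[cl[1]]))
      sMax <- max(start(all_[cl]))
      eMin <- min(end(all_[cl]))
      coreEmpty <- FALSE
      if (boundaryRule == "strict" && sMax <= eMin) {
        s <- sMax; e <- eMin
      } else {
        if (boundaryRule == "strict") coreEmpty <- TRUE
        s <- min(start(all_[cl])); e <- max(end(all_[cl]))
      }
      cns <- meta$cn[cl]
      tab <- sort(table(cns), decreasing = TRUE)
      top <- as.integer(names(tab)[tab == max(tab)])
      cn <- if (meta$state[cl[1]] == "deletion") min(top) else max(top)
      nm <- sum(as.character(seqnames(map)) == ch & start(map) >= s &
                start(map) <= e)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = meta$sample_id[cl[1]], chrom = ch, start = s, end = e,
        cn = cn, state = meta$state[cl[1]], n_markers = nm,
        support = paste(algs, collapse = ","),
        n_support = length(algs), core_empty = coreEmpty)
    }
  }
  makeConsensus(if (length(rows)) do.call(rbind, rows) else data.frame())
}

# Internal: consensus data.frame -> GRanges with canonical mcols.
#' @noRd
makeConsensus <- function(df) {
  if (nrow(df) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(sample_id = character(), cn = integer(),
                           state = character(), n_markers = integer(),
                           support = character(), n_support = integer(),
                           length_bp = integer(), core_empty = logical(),
                           rarity = character(), gene_count = integer(),
                           region_hits = character())[0, ]
    return(gr)
  }
  o <- order(df$sample_id, .chromOrder(df$chrom), df$start)
  df <- df[o, ]
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(gr)$sample_id <- df$sample_id
  mcols(gr)$cn <- as.integer(df$cn)
  mcols(gr)$state <- df$state
  mcols(gr)$n_markers <- as.integer(df$n_markers)
  mcols(gr)$support <- df$support
  mcols(gr)$n_support <- as.integer(df$n_support)
  mcols(gr)$length_bp <- width(gr)
  mcols(gr)$core_empty <- df$core_empty
  gr
}

#' Filter a consensus CNV set to an analysis tier
#'
#' Two tiers mirror the two analysis layers of the study design:
#' \describe{
#'   \item{`large`}{length strictly > 1 Mb and called with strictly > 100
#'     markers; no multi-algorithm requirement (all calls pooled).}
#'   \item{`phenotype`}{length > 100 kb, at least 10 markers, and support
#'     from all three algorithms.}
#' }
#' Bounds are configurable; the defaults apply the strict/inclusive
#' inequalities exactly as stated above.
#'
#' @param cnvs a consensus `GRanges` (see [mergeCallsets()]).
#' @param tier `"large"` or `"phenotype"`.
#' @param largeMinBp,largeMinMarkers strict lower bounds for the large
#'   tier.
#' @param phenoMinBp strict lower length bound for the phenotype tier.
#' @param phenoMinMarkers inclusive marker floor for the phenotype tier.
#' @param phenoMinSupport minimum supporting algorithms for the phenotype
#'   tier.
#' @return the filtered `GRanges`.
#' @export
filterTier <- function(cnvs, tier = c("large", "phenotype"),
                       largeMinBp = 1e6, largeMinMarkers = 100,
                       phenoMinBp = 1e5, phenoMinMarkers = 10,
                       phenoMinSupport = 3) {
  tier <- match.arg(tier)
  if (length(cnvs) == 0L) return(cnvs)
  len <- mcols(cnvs)$length_bp %||% width(cnvs)
  nm <- mcols(cnvs)$n_markers
  if (is.null(nm)) stopf("consensus CNVs lack n_markers")
  keep <- if (tier == "large")
    len > largeMinBp & nm > largeMinMarkers
  else
    len > phenoMinBp & nm >= phenoMinMarkers &
      (mcols(cnvs)$n_support %||% rep(1L, length(cnvs))) >= phenoMinSupport
  cnvs[keep]
}

# Minimal union-find with path halving.
.unionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  list(find = find, union = union)
}

#' Classify cohort-level CNV rarity
#'
#' Clusters CNVs across the whole cohort by same state and reciprocal
#' overlap of at least `overlapFrac` (transitive closure), then labels each
#' CNV: `singleton` (its cluster holds one event), `common` (the cluster
#' spans more than `commonFreq` of cohort samples), else `rare`.
#'
#' @param cnvs a consensus `GRanges`.
#' @param nSamples cohort size used for the frequency denominator.
#' @param overlapFrac reciprocal-overlap threshold in (0, 1\].
#' @param commonFreq sample-frequency threshold for the common class.
#' @return `cnvs` with mcols `rarity` (and `cluster_id`) added.
#' @export
classifyRarity <- function(cnvs, nSamples, overlapFrac = 0.5,
                           commonFreq = 0.01) {
  stopifnot(overlapFrac > 0, overlapFrac <= 1, nSamples >= 1)
  n <- length(cnvs)
  if (n == 0L) {
    mcols(cnvs)$rarity <- character(0)
    return(cnvs)
  }
  uf <- .unionFind(n)
  hit <- findOverlaps(cnvs, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hit)) {
    q <- S4Vectors::queryHits(hit)
    s <- S4Vectors::subjectHits(hit)
    ow <- width(pintersect(cnvs[q], cnvs[s]))
    recip <- ow / width(cnvs)[q] >= overlapFrac &
             ow / width(cnvs)[s] >= overlapFrac
    same <- mcols(cnvs)$state[q] == mcols(cnvs)$state[s]
    for (k in which(recip & same)) uf$union(q[k], s[k])
  }
  root <- vapply(seq_len(n), uf$find, 0L)
  cid <- match(root, unique(root))
  size <- table(cid)[as.character(cid)]
  nsamp <- vapply(split(mcols(cnvs)$sample_id, cid),
                  function(s) length(unique(s)), 0L)[as.character(cid)]
  rarity <- ifelse(size == 1, "singleton",
                   ifelse(nsamp / nSamples > commonFreq, "common", "rare"))
  mcols(cnvs)$cluster_id <- as.integer(cid)
  mcols(cnvs)$rarity <- as.character(rarity)
  cnvs
}

#' Annotate consensus CNVs with gene counts and region hits
#'
#' `gene_count` is the number of gene intervals overlapping each CNV by at
#' least 1 bp; `region_hits` the comma-joined labels of associated-region
#' intervals overlapped by at least 1 bp (empty string when none).
#'
#' @param cnvs a consensus `GRanges`.
#' @param genes gene `GRanges` with mcols `label` (or `NULL` to skip).
#' @param regions associated-region `GRanges` with mcols `label` (or
#'   `NULL`).
#' @return `cnvs` with mcols `gene_count` and `region_hits` added.
#' @export
annotateCnvs <- function(cnvs, genes = NULL, regions = NULL) {
  if (!is.null(genes))
    mcols(cnvs)$gene_count <- countOverlaps(cnvs, genes)
  if (!is.null(regions)) {
    hits <- findOverlaps(cnvs, regions)
    lab <- rep("", length(cnvs))
    if (length(hits)) {
      sp <- split(mcols(regions)$label[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
      lab[as.integer(names(sp))] <-
        vapply(sp, function(v) paste(sort(unique(v)), collapse = ","), "")
    }
    mcols(cnvs)$region_hits <- lab
  }
  cnvs
}

#' Write / read a consensus CNV table
#'
#' Canonical TSV serialization of a consensus `GRanges` (all mcols kept).
#'
#' @param cnvs a consensus `GRanges`.
#' @param path file path.
#' @export
writeConsensus <- function(cnvs, path) {
  df <- cbind(data.frame(chrom = as.character(seqnames(cnvs)),
                         start = start(cnvs), end = end(cnvs)),
              as.data.frame(mcols(cnvs)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConsensus
#' @export
readConsensus <- function(path) {
  df <- .readTsv(path, "consensus CNV")
  .requireCols(df, c("chrom", "start", "end", "sample_id", "cn", "state",
                     "n_markers"), path)
  gr <- GRanges(normChrom(df$chrom), IRanges(df$start, df$end))
  for (cl in setdiff(names(df), c("chrom", "start", "end")))
    mcols(gr)[[cl]] <- df[[cl]]
  if (is.null(mcols(gr)$length_bp)) mcols(gr)$length_bp <- width(gr)
  gr
}
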