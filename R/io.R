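# Readers/writers for the on-disk formats the pipeline touches. All formats
# are tab-delimited UTF-8 with a header row. In-memory coordinates are
# 1-based inclusive everywhere; the BED boundary (0-based half-open) is
# converted only at the I/O boundary. Readers reject malformed input rather
# than coercing it, and error messages name the file, line and field.

.readTsv <- function(path, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "#")
}

.requireCols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("file %s: missing required column(s): %s", path,
          paste(miss, collapse = ", "))
}

.chromOrder <- function(chrom) match(chrom, ALLOWED_CHROMS)

# Build a validated marker-map GRanges from vectors.
#' @noRd
makeMarkerMap <- function(marker_id, chrom, pos, paf = NULL,
                          seqlengths = NULL) {
  chrom <- normChrom(chrom, "marker chromosome")
  if (anyDuplicated(marker_id))
    stopf("duplicate marker id(s): %s",
          paste(head(unique(marker_id[duplicated(marker_id)]), 5),
                collapse = ", "))
  if (any(is.na(pos)) || any(pos < 1))
    stopf("marker positions must be positive 1-based integers")
  o <- order(.chromOrder(chrom), pos)
  gr <- GRanges(factor(chrom[o], levels = intersect(ALLOWED_CHROMS,
                                                    unique(chrom))),
                IRanges(start = as.integer(pos[o]), width = 1L))
  names(gr) <- marker_id[o]
  if (!is.null(paf)) mcols(gr)$paf <- paf[o]
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <-
      seqlengths[GenomeInfoDb::seqlevels(gr)]
  validateMarkerMap(gr)
  gr
}

#' Validate a marker map
#'
#' Checks the marker-map contract used throughout the package: a width-1
#' `GRanges` with unique marker ids as names, chromosome labels restricted
#' to 1-22/X/Y, and strictly increasing positions within each chromosome.
#'
#' @param map a `GRanges`.
#' @return `map`, invisibly; errors describe the first violation.
#' @export
validateMarkerMap <- function(map) {
  if (!is(map, "GRanges")) stopf("marker map must be a GRanges")
  if (length(map) == 0L) stopf("marker map is empty")
  if (is.null(names(map)) || anyDuplicated(names(map)))
    stopf("marker ids (names) must be present and unique")
  if (any(width(map) != 1L)) stopf("marker map ranges must have width 1")
  lv <- GenomeInfoDb::seqlevels(map)
  bad <- setdiff(lv, ALLOWED_CHROMS)
  if (length(bad))
    stopf("invalid chromosome label(s) in marker map: %s",
          paste(bad, collapse = ", "))
  byChr <- split(start(map), as.character(seqnames(map)))
  for (ch in names(byChr))
    if (is.unsorted(byChr[[ch]], strictly = TRUE))
      stopf("marker positions not strictly increasing on chromosome %s", ch)
  invisible(map)
}

#' Read / write a marker map
#'
#' TSV with columns `marker_id`, `chrom`, `pos` (1-based). Markers are
#' sorted by chromosome and position on read and validated (unique ids,
#' allowed chromosomes, strictly increasing positions). An optional `paf`
#' column carries the per-marker population B-allele frequency used by the
#' simulator.
#'
#' @param path file path.
#' @return `readMarkerMap`: a validated `GRanges` marker map.
#' @seealso [validateMarkerMap()], [simulateMarkerMap()]
#' @export
readMarkerMap <- function(path) {
  df <- .readTsv(path, "marker map")
  .requireCols(df, c("marker_id", "chrom", "pos"), path)
  pos <- suppressWarnings(as.numeric(df$pos))
  if (anyNA(pos))
    stopf("file %s, line %d: non-numeric pos field",
          path, which(is.na(pos))[1] + 1L)
  makeMarkerMap(as.character(df$marker_id), df$chrom, pos,
                paf = if ("paf" %in% names(df)) as.numeric(df$paf))
}

#' @rdname readMarkerMap
#' @param map a marker-map `GRanges`.
#' @export
writeMarkerMap <- function(map, path) {
  validateMarkerMap(map)
  df <- data.frame(marker_id = names(map),
                   chrom = as.character(seqnames(map)),
                   pos = start(map))
  if (!is.null(mcols(map)$paf)) df$paf <- round(mcols(map)$paf, 6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-marker intensity data
#'
#' Long-format TSV with columns `sample_id`, `marker_id`, `lrr`, `baf` (one
#' row per sample x marker). On read, profiles are aligned to the order of
#' `map`; markers present in the file but absent from the map are a hard
#' error, markers absent from the file are marked missing (`NA`). Duplicate
#' (sample, marker) rows and non-numeric values are hard errors naming the
#' offending line.
#'
#' @param path file path.
#' @param map a validated marker-map `GRanges`.
#' @return `readIntensity`: an [IntensitySet-class].
#' @export
readIntensity <- function(path, map) {
  validateMarkerMap(map)
  df <- .readTsv(path, "intensity")
  .requireCols(df, c("sample_id", "marker_id", "lrr", "baf"), path)
  unknown <- setdiff(unique(df$marker_id), names(map))
  if (length(unknown))
    stopf("file %s: marker id(s) not in map: %s", path,
          paste(head(unknown, 5), collapse = ", "))
  key <- paste(df$sample_id, df$marker_id, sep = "\r")
  if (anyDuplicated(key)) {
    ln <- which(duplicated(key))[1]
    stopf("file %s, line %d: duplicate (sample, marker) row (%s, %s)",
          path, ln + 1L, df$sample_id[ln], df$marker_id[ln])
  }
  for (fld in c("lrr", "baf")) {
    v <- df[[fld]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "NA" & v != "")
    if (length(bad))
      stopf("file %s, line %d: non-numeric %s field '%s'",
            path, bad[1] + 1L, fld, v[bad[1]])
    df[[fld]] <- num
  }
  samples <- unique(df$sample_id)
  nmk <- length(map)
  lrrM <- matrix(NA_real_, nmk, length(samples),
                 dimnames = list(names(map), samples))
  bafM <- lrrM
  ridx <- match(df$marker_id, names(map))
  cidx <- match(df$sample_id, samples)
  lrrM[cbind(ridx, cidx)] <- df$lrr
  bafM[cbind(ridx, cidx)] <- pmin(pmax(df$baf, 0), 1)
  IntensitySet(lrrM, bafM, map)
}

#' @rdname readIntensity
#' @param x an [IntensitySet-class].
#' @param digits decimal places written for real values (default 6; the
#'   round-trip contract is 6-decimal fidelity).
#' @export
writeIntensity <- function(x, path, digits = 6) {
  stopifnot(is(x, "IntensitySet"))
  ids <- names(rowRanges(x))
  df <- data.frame(
    sample_id = rep(colnames(x), each = nrow(x)),
    marker_id = rep(ids, times = ncol(x)),
    lrr = round(as.vector(lrr(x)), digits),
    baf = round(as.vector(baf(x)), digits))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.cnToState <- function(cn) ifelse(cn < 2, "deletion", "duplication")

# Build a validated CNV-call GRanges (the CnvCall container: one range per
# call with sample_id, cn, state, n_markers, algorithm, score in mcols).
#' @noRd
makeCnvCalls <- function(sample_id, chrom, start, end, cn, n_markers,
                         algorithm, score = NA_real_) {
  chrom <- normChrom(chrom, "CNV chromosome")
  if (any(end < start)) stopf("CNV call with end < start")
  cn <- as.integer(cn)
  if (!all(cn %in% c(0L, 1L, 3L, 4L)))
    stopf("CNV copy number must be in {0,1,3,4}, got: %s",
          paste(setdiff(unique(cn), c(0, 1, 3, 4)), collapse = ", "))
  if (any(n_markers < 1)) stopf("CNV n_markers must be >= 1")
  gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)))
  rec <- function(v) rep(v, length.out = length(gr))
  mcols(gr)$sample_id <- rec(as.character(sample_id))
  mcols(gr)$cn <- rec(cn)
  mcols(gr)$state <- rec(.cnToState(cn))
  mcols(gr)$n_markers <- rec(as.integer(n_markers))
  mcols(gr)$algorithm <- rec(as.character(algorithm))
  mcols(gr)$score <- rec(as.numeric(score))
  gr
}

#' Read / write CNV call files
#'
#' Two dialects are supported (declared, never auto-sniffed):
#' \describe{
#'   \item{`canonical_tsv`}{TSV with header `sample_id`, `chrom`, `start`,
#'     `end`, `cn`, `n_markers`, `algorithm`, `score`; coordinates 1-based
#'     inclusive.}
#'   \item{`pennCNV_like`}{whitespace-delimited caller text, one call per
#'     line: `chr1:1000-5000  numsnp=12  length=4001  state2,cn=1  SAMPLE
#'     startsnp=... endsnp=... conf=15.07` (conf optional).}
#' }
#' State tokens are mapped to integer copy number (deletion < 2 <
#' duplication); `end < start` and unknown state tokens are hard errors.
#' Row order is preserved.
#'
#' @param path file path.
#' @param dialect `"canonical_tsv"` or `"pennCNV_like"`.
#' @return a CNV-call `GRanges` with mcols `sample_id`, `cn`, `state`,
#'   `n_markers`, `algorithm`, `score`.
#' @export
readCnvCalls <- function(path, dialect = c("canonical_tsv", "pennCNV_like")) {
  dialect <- match.arg(dialect)
  if (dialect == "canonical_tsv") {
    df <- .readTsv(path, "CNV call")
    .requireCols(df, c("sample_id", "chrom", "start", "end", "cn",
                       "n_markers", "algorithm"), path)
    if (nrow(df) == 0L) return(makeCnvCalls(character(), character(),
                                            integer(), integer(), integer(),
                                            integer(), character()))
    bad <- which(df$end < df$start)
    if (length(bad))
      stopf("file %s, line %d: end < start", path, bad[1] + 1L)
    makeCnvCalls(df$sample_id, df$chrom, df$start, df$end, df$cn,
                 df$n_markers, df$algorithm,
                 if ("score" %in% names(df)) df$score else NA_real_)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(makeCnvCalls(character(), character(),
                                            integer(), integer(), integer(),
                                            integer(), character()))
    parse1 <- function(i) {
      ln <- lines[i]
      tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      m <- regmatches(tok[1],
                      regexec("^(chr)?([0-9XY]+):([0-9]+)-([0-9]+)$",
                              tok[1]))[[1]]
      if (length(m) == 0L)
        stopf("file %s, line %d: cannot parse locus field '%s'",
              path, i, tok[1])
      getkv <- function(key) {
        hit <- grep(paste0("^", key, "="), tok, value = TRUE)
        if (!length(hit)) stopf("file %s, line %d: missing %s field",
                                path, i, key)
        sub(paste0("^", key, "="), "", hit[1])
      }
      st <- grep("^state[0-9]+,cn=[0-9]+$", tok, value = TRUE)
      if (!length(st))
        stopf("file %s, line %d: missing/unknown state token", path, i)
      cn <- as.integer(sub("^state[0-9]+,cn=", "", st[1]))
      smp <- tok[!grepl("[=:]", tok)]
      if (!length(smp))
        stopf("file %s, line %d: missing sample field", path, i)
      conf <- grep("^conf=", tok, value = TRUE)
      list(chrom = m[3], start = as.integer(m[4]), end = as.integer(m[5]),
           numsnp = as.integer(getkv("numsnp")), cn = cn, sample = smp[1],
           score = if (length(conf))
             as.numeric(sub("^conf=", "", conf[1])) else NA_real_)
    }
    ps <- lapply(seq_along(lines), parse1)
    starts <- vapply(ps, `[[`, 0L, "start")
    ends <- vapply(ps, `[[`, 0L, "end")
    bad <- which(ends < starts)
    if (length(bad)) stopf("file %s, line %d: end < start", path, bad[1])
    makeCnvCalls(vapply(ps, `[[`, "", "sample"),
                 vapply(ps, `[[`, "", "chrom"), starts, ends,
                 vapply(ps, `[[`, 0L, "cn"),
                 vapply(ps, `[[`, 0L, "numsnp"),
                 "pennCNV", vapply(ps, `[[`, 0, "score"))
  }
}

#' @rdname readCnvCalls
#' @param calls a CNV-call `GRanges`.
#' @export
writeCnvCalls <- function(calls, path) {
  df <- data.frame(sample_id = mcols(calls)$sample_id,
                   chrom = as.character(seqnames(calls)),
                   start = start(calls), end = end(calls),
                   cn = mcols(calls)$cn,
                   n_markers = mcols(calls)$n_markers,
                   algorithm = mcols(calls)$algorithm,
                   score = round(mcols(calls)$score, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write genomic region sets (BED4)
#'
#' 4-column BED (`chrom`, `start`, `end`, `label`), 0-based half-open on
#' disk, converted to 1-based inclusive in memory (`start + 1`, `end`).
#' Leading `chr` prefixes are stripped on read and re-added on BED export.
#' Overlapping intervals are preserved, never merged. `start >= end` on
#' disk is a hard error.
#'
#' @param path file path.
#' @param name region-set name stored in `metadata(x)$name`.
#' @return `readRegionsBed`: a `GRanges` with mcols `label`.
#' @export
readRegionsBed <- function(path, name = basename(path)) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines)) {
    gr <- GRanges()
    metadata(gr)$name <- name
    return(gr)
  }
  parts <- strsplit(lines, "\t")
  nfld <- lengths(parts)
  if (any(nfld < 4))
    stopf("file %s, line %d: BED4 requires 4 fields", path,
          which(nfld < 4)[1])
  chrom <- vapply(parts, `[[`, "", 1)
  s0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  e0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  lab <- vapply(parts, `[[`, "", 4)
  if (anyNA(s0) || anyNA(e0))
    stopf("file %s, line %d: non-numeric coordinate", path,
          which(is.na(s0) | is.na(e0))[1])
  if (any(s0 < 0)) stopf("file %s: negative BED start", path)
  bad <- which(s0 >= e0)
  if (length(bad))
    stopf("file %s, line %d: start >= end", path, bad[1])
  if (any(!nzchar(lab))) stopf("file %s: empty region label", path)
  gr <- GRanges(normChrom(chrom, "region chromosome"),
                IRanges(as.integer(s0) + 1L, as.integer(e0)))
  mcols(gr)$label <- lab
  metadata(gr)$name <- name
  gr
}

#' @rdname readRegionsBed
#' @param regions a region `GRanges` (1-based inclusive, mcols `label`).
#' @export
writeRegionsBed <- function(regions, path) {
  df <- data.frame(chrom = paste0("chr", as.character(seqnames(regions))),
                   start = start(regions) - 1L, end = end(regions),
                   label = mcols(regions)$label)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

PHENOTYPE_COLS <- c("age_of_onset", "duration_worst_episode", "neuroticism",
                    "extraversion", "psychoticism")

#' Read / write a phenotype table
#'
#' TSV with columns `sample_id`, `sex` (`male`/`female`), `cohort`
#' (`case`/`screened_control`/`population_control`) and the five clinical
#' phenotypes: `age_of_onset` (years), `duration_worst_episode` (weeks),
#' `neuroticism`, `extraversion`, `psychoticism` (questionnaire scores).
#' Missing values are encoded explicitly as `NA`, never silently zero.
#' Duplicate sample ids are a hard error.
#'
#' @param path file path.
#' @return `readPhenotypes`: a data.frame keyed by `sample_id`.
#' @export
readPhenotypes <- function(path) {
  df <- .readTsv(path, "phenotype")
  .requireCols(df, c("sample_id", "sex", "cohort"), path)
  if (anyDuplicated(df$sample_id))
    stopf("file %s: duplicate sample_id '%s'", path,
          df$sample_id[duplicated(df$sample_id)][1])
  badSex <- setdiff(unique(na.omit(df$sex)), c("male", "female"))
  if (length(badSex))
    stopf("file %s: invalid sex value(s): %s", path,
          paste(badSex, collapse = ", "))
  badCo <- setdiff(unique(na.omit(df$cohort)),
                   c("case", "screened_control", "population_control"))
  if (length(badCo))
    stopf("file %s: invalid cohort value(s): %s", path,
          paste(badCo, collapse = ", "))
  for (ph in intersect(PHENOTYPE_COLS, names(df)))
    df[[ph]] <- suppressWarnings(as.numeric(df[[ph]]))
  df
}

#' @rdname readPhenotypes
#' @param pheno a phenotype data.frame.
#' @export
writePhenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
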