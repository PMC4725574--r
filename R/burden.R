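# Case-control statistical layer: exact 2x2 tests with sample and
# conditional-MLE odds ratios, per-sample CNV burden statistics, and
# label-permutation burden testing over the 3 contrasts x 3 CNV classes x
# 7 statistics grid with Bonferroni control.
#
# Table convention: rows are carriers / non-carriers, columns cases /
# controls, so for counts (a, b, c, d) = (case carriers, case
# non-carriers, control carriers, control non-carriers) the sample odds
# ratio is (a d) / (b c). With margins fixed, the carrier count among
# cases follows the (noncentral) hypergeometric distribution; the exact
# test enumerates it.

# Hypergeometric machinery for a 2x2 with cases m = a + b, controls
# n = c + d, carriers k = a + c. Support of X = case carriers.
.hyperSupport <- function(m, n, k) max(0L, k - n):min(k, m)

# Noncentral hypergeometric pmf over the support, at odds ratio psi.
.nchyperPmf <- function(logdc, support, psi) {
  lw <- logdc + support * log(psi)
  w <- exp(lw - max(lw))
  w / sum(w)
}

.nchyperMean <- function(logdc, support, psi)
  sum(support * .nchyperPmf(logdc, support, psi))

#' Exact test for a 2x2 carrier-by-cohort table
#'
#' Enumerates the hypergeometric distribution of the case-carrier count
#' with all margins fixed. The two-sided p-value sums the probabilities of
#' all tables at most as probable as the observed one (the standard
#' exact-distribution convention); the one-sided p-value is the upper
#' (enrichment-in-cases) tail. Both the cross-product (sample) odds ratio
#' and the conditional-MLE odds ratio (maximizing the noncentral
#' hypergeometric likelihood) are returned, with a 95% confidence interval
#' from inverting the exact test at tail probability 0.025 per side (the
#' upper bound is `Inf` when the case-carrier count is at its margin
#' maximum).
#'
#' @param a,b,c,d case carriers, case non-carriers, control carriers,
#'   control non-carriers. Alternatively pass a 2x2 matrix
#'   `rbind(c(a, c), c(b, d))` as `a`.
#' @param conf compute the conditional-MLE odds ratio and exact confidence
#'   interval (set `FALSE` to return p-values and the sample odds ratio
#'   only, much faster in bulk).
#' @return an object of class `FisherResult`: list with `p_one`, `p_two`,
#'   `or_sample`, `or_cmle`, `ci95` (length-2, `Inf` allowed), `table`.
#'   A zero cross-product both ways leaves the odds ratio `NaN`
#'   (undefined), reported as such.
#' @examples
#' fisherExact(3, 2194, 3, 17035)   # p_two ~ .023, OR ~ 7.76
#' @export
fisherExact <- function(a, b = NULL, c = NULL, d = NULL, conf = TRUE) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    d <- a[2, 2]; c <- a[1, 2]; b <- a[2, 1]; a <- a[1, 1]
  }
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    stopf("table counts must be non-negative integers")
  if (sum(cnt) == 0) stopf("empty 2x2 table")
  m <- a + b          # cases
  n <- c + d          # controls
  k <- a + c          # carriers
  support <- .hyperSupport(m, n, k)
  dens <- dhyper(support, m, n, k)
  obs <- dens[match(a, support)]
  relErr <- 1 + 1e-07
  p_two <- min(1, sum(dens[dens <= obs * relErr]))
  p_one <- min(1, sum(dens[support >= a]))

  or_sample <- if (b * c == 0 && a * d == 0) NaN
    else if (b * c == 0) Inf
    else (a * d) / (b * c)

  if (!conf)
    return(structure(list(p_one = p_one, p_two = p_two,
                          or_sample = or_sample, or_cmle = NA_real_,
                          ci95 = c(NA_real_, NA_real_),
                          table = matrix(c(a, b, c, d), 2)),
                     class = "FisherResult"))

  logdc <- dhyper(support, m, n, k, log = TRUE)
  lo <- support[1]
  hi <- support[length(support)]
  or_cmle <- if (length(support) == 1L) NaN
    else if (a == lo) 0
    else if (a == hi) Inf
    else {
      f <- function(t) .nchyperMean(logdc, support, exp(t)) - a
      exp(uniroot(f, c(-50, 50), tol = 1e-10)$root)
    }

  pUpper <- function(psi) sum(.nchyperPmf(logdc, support, psi)[support >= a])
  pLower <- function(psi) sum(.nchyperPmf(logdc, support, psi)[support <= a])
  ciLo <- if (a == lo || length(support) == 1L) 0 else
    exp(uniroot(function(t) pUpper(exp(t)) - 0.025, c(-75, 75),
                tol = 1e-10)$root)
  ciHi <- if (a == hi || length(support) == 1L) Inf else
    exp(uniroot(function(t) pLower(exp(t)) - 0.025, c(-75, 75),
                tol = 1e-10)$root)

  structure(list(p_one = p_one, p_two = p_two, or_sample = or_sample,
                 or_cmle = or_cmle, ci95 = c(ciLo, ciHi),
                 table = matrix(c(a, b, c, d), 2,
                                dimnames = list(c("carrier", "non_carrier"),
                                                c("case", "control")))),
            class = "FisherResult")
}

#' @export
print.FisherResult <- function(x, ...) {
  cat(sprintf(
    "Exact 2x2 test: p_one = %.4g, p_two = %.4g\n  OR (sample) = %.4g, OR (CMLE) = %.4g, 95%% CI [%.4g, %.4g]\n",
    x$p_one, x$p_two, x$or_sample, x$or_cmle, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Cross-product (sample) odds ratio
#'
#' `(a d) / (b c)` with the conventions: `Inf` when `b c = 0` with
#' `a d > 0`; `NaN` (undefined) when both cross products are zero.
#'
#' @inheritParams fisherExact
#' @return a single number.
#' @examples
#' oddsRatioSample(74, 2649, 4, 344)  # 2.40
#' @export
oddsRatioSample <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stopf("table counts must be non-negative")
  if (b * c == 0) {
    if (a * d == 0) return(NaN)
    return(Inf)
  }
  (a * d) / (b * c)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param nTests number of tests.
#' @return list with `threshold` (full precision `alpha / nTests`) and
#'   `threshold_2sf` (rounded to 2 significant figures, the conventional
#'   reporting precision).
#' @examples
#' bonferroni(0.05, 63)$threshold_2sf   # 0.00079
#' @export
bonferroni <- function(alpha, nTests) {
  stopifnot(alpha > 0, alpha < 1, nTests >= 1)
  thr <- alpha / nTests
  list(threshold = thr, threshold_2sf = signif(thr, 2))
}

BURDEN_STATISTICS <- c("carrier", "n_cnv", "total_kb", "mean_length_kb",
                       "genes_total", "genes_per_cnv", "n_genic")

#' Per-sample CNV burden statistics
#'
#' Computes, for every sample and CNV class (`all`, `deletion`,
#' `duplication`), the seven burden statistics used by the permutation
#' grid: (1) `carrier` -- indicator of at least one CNV; (2) `n_cnv` --
#' CNV count; (3) `total_kb` -- summed CNV length in kb; (4)
#' `mean_length_kb` -- mean CNV length in kb; (5) `genes_total` -- genes
#' covered by the sample's CNVs; (6) `genes_per_cnv` -- mean genes per
#' CNV; (7) `n_genic` -- count of CNVs overlapping at least one gene.
#' CNV-free samples contribute 0 to counts/kb and `NA` to the per-CNV
#' means (excluded from those tests' averages).
#'
#' @param cnvs an annotated consensus `GRanges` (needs mcols `sample_id`,
#'   `state`, `length_bp`, `gene_count`; see [annotateCnvs()]).
#' @param sampleIds character vector of all cohort samples (zero-CNV
#'   samples must be represented).
#' @return a long data.frame: `sample_id`, `cnv_class`, then the seven
#'   statistic columns.
#' @export
burdenStatistics <- function(cnvs, sampleIds) {
  if (length(cnvs) && is.null(mcols(cnvs)$gene_count))
    stopf("CNVs must be annotated with gene_count first (annotateCnvs)")
  perClass <- function(klass) {
    sel <- if (klass == "all") seq_along(cnvs)
           else which(mcols(cnvs)$state == klass)
    sid <- factor(mcols(cnvs)$sample_id[sel], levels = sampleIds)
    lenKb <- (mcols(cnvs)$length_bp[sel]) / 1000
    gc_ <- mcols(cnvs)$gene_count[sel]
    nC <- as.integer(table(sid))
    sumKb <- vapply(split(lenKb, sid), sum, 0)
    sumG <- vapply(split(gc_, sid), function(v) sum(v), 0)
    nGenic <- vapply(split(gc_, sid), function(v) sum(v > 0), 0)
    data.frame(sample_id = sampleIds, cnv_class = klass,
               carrier = as.integer(nC > 0), n_cnv = nC,
               total_kb = unname(sumKb),
               mean_length_kb = ifelse(nC > 0, unname(sumKb) / nC,
                                       NA_real_),
               genes_total = unname(sumG),
               genes_per_cnv = ifelse(nC > 0, unname(sumG) / nC,
                                      NA_real_),
               n_genic = unname(nGenic), row.names = NULL)
  }
  out <- rbind(perClass("all"), perClass("deletion"),
               perClass("duplication"))
  row.names(out) <- NULL
  out
}

#' One-sided label-permutation burden test
#'
#' The observed statistic is the difference in arm means (cases minus
#' controls, `NA` values excluded as in per-CNV means of CNV-free
#' samples). Labels are permuted `nPerm` times preserving arm sizes; the
#' empirical p-value uses the add-one correction
#' `p = (1 + #\{perm >= observed\}) / (nPerm + 1)`, so p is never zero.
#' A constant statistic returns `perm_p = 1`.
#'
#' @param values per-sample statistic (numeric; `NA` allowed).
#' @param isCase logical vector, `TRUE` for case samples.
#' @param nPerm number of permutations.
#' @param seed RNG seed (results deterministic given the seed).
#' @param alternative `"greater"` (case burden exceeds control burden,
#'   the default one-sided hypothesis) or `"less"`.
#' @return list with `observed`, `perm_p`, `n_perm`, `n_case`,
#'   `n_control`.
#' @export
permutationBurden <- function(values, isCase, nPerm = 10000, seed,
                              alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values) == length(isCase), sum(isCase) >= 2,
            sum(!isCase) >= 2)
  sgn <- if (alternative == "greater") 1 else -1
  armDiff <- function(cs)
    mean(values[cs], na.rm = TRUE) - mean(values[!cs], na.rm = TRUE)
  obsRaw <- armDiff(isCase)
  obs <- sgn * obsRaw
  nv <- values[!is.na(values)]
  if (length(unique(nv)) <= 1L || !is.finite(obs))
    return(list(observed = obsRaw, perm_p = 1, n_perm = nPerm,
                n_case = sum(isCase), n_control = sum(!isCase)))
  n <- length(values)
  n1 <- sum(isCase)
  hits <- withSeed(seed, {
    cnt <- 0L
    for (i in seq_len(nPerm)) {
      perm <- logical(n)
      perm[sample.int(n, n1)] <- TRUE
      pd <- sgn * armDiff(perm)
      # a permuted arm can be all-NA for per-CNV means; count only
      # defined exceedances
      if (!is.na(pd) && pd >= obs - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  list(observed = obsRaw, perm_p = (1 + hits) / (nPerm + 1),
       n_perm = nPerm, n_case = sum(isCase), n_control = sum(!isCase))
}

#' The 3 x 3 x 7 burden-test grid
#'
#' Generates the full grid of burden tests: 3 case-control contrasts
#' (cases vs all controls, vs screened controls, vs population/WTCCC2
#' controls) x 3 CNV classes (all, deletions, duplications) x the 7
#' statistics of [burdenStatistics()] -- 63 tests in total, matching the
#' Bonferroni denominator `bonferroni(alpha, 63)`.
#'
#' @return a data.frame with columns `test_id`, `contrast`, `cnv_class`,
#'   `statistic` (63 rows).
#' @export
burdenTestGrid <- function() {
  g <- expand.grid(
    contrast = c("case_vs_all_controls", "case_vs_screened",
                 "case_vs_population"),
    cnv_class = c("all", "deletion", "duplication"),
    statistic = BURDEN_STATISTICS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[order(g$contrast, g$cnv_class, g$statistic), ]
  g$test_id <- paste(g$contrast, g$cnv_class, g$statistic, sep = ".")
  row.names(g) <- NULL
  g[c("test_id", "contrast", "cnv_class", "statistic")]
}

#' Run the full permutation burden grid
#'
#' Executes every test of [burdenTestGrid()] on a per-sample burden table,
#' with a deterministically derived child seed per test, and applies the
#' Bonferroni threshold `alpha / 63`.
#'
#' @param stats output of [burdenStatistics()].
#' @param cohorts named character vector or data.frame (`sample_id`,
#'   `cohort`) assigning each sample to `case`, `screened_control` or
#'   `population_control`.
#' @param nPerm permutations per test.
#' @param seed RNG seed.
#' @param alpha family-wise error rate for the Bonferroni rule.
#' @return a data.frame: the grid plus `observed`, `perm_p`, `n_perm`,
#'   `passes_bonferroni`, and attributes `alpha_bonferroni`.
#' @export
runBurdenGrid <- function(stats, cohorts, nPerm = 1000, seed,
                          alpha = 0.05) {
  if (is.data.frame(cohorts))
    cohorts <- setNames(cohorts$cohort, cohorts$sample_id)
  grid <- burdenTestGrid()
  thr <- bonferroni(alpha, nrow(grid))$threshold
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sub <- stats[stats$cnv_class == g$cnv_class, ]
    co <- cohorts[sub$sample_id]
    keep <- switch(g$contrast,
      case_vs_all_controls = !is.na(co),
      case_vs_screened = co %in% c("case", "screened_control"),
      case_vs_population = co %in% c("case", "population_control"))
    sub <- sub[keep, ]
    isCase <- cohorts[sub$sample_id] == "case"
    pb <- permutationBurden(sub[[g$statistic]], isCase, nPerm = nPerm,
                            seed = childSeed(seed, i))
    res[[i]] <- data.frame(g, observed = pb$observed, perm_p = pb$perm_p,
                           n_perm = pb$n_perm,
                           passes_bonferroni = pb$perm_p < thr)
  }
  out <- do.call(rbind, res)
  attr(out, "alpha_bonferroni") <- thr
  row.names(out) <- NULL
  out
}
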