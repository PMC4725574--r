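# Genotype-phenotype association layer: ordinary least-squares regression
# of clinical phenotypes on per-sample CNV burden, multiple-testing
# correction by spectral decomposition of the phenotype correlation matrix
# (effective number of independent tests), and the two power designs used
# for study planning: the 1-numerator-df noncentral-F linear model and the
# two-proportion carrier-frequency comparison.

#' Linear regression of a phenotype on CNV burden
#'
#' Ordinary least squares of `phenotype` on `burden` (plus optional
#' covariates) with listwise deletion of missing values. Reports the
#' burden coefficient, its standard error, t statistic, two-sided p-value
#' from the t distribution with n - k residual degrees of freedom, and
#' the complete-case count n.
#'
#' @param phenotype numeric response.
#' @param burden numeric per-sample burden (e.g. CNV count).
#' @param covariates optional data.frame of additional regressors.
#' @param minN minimum complete cases (default 10).
#' @return a one-row data.frame: `beta`, `se`, `t`, `p`, `n`.
#' @examples
#' set.seed(1)
#' b <- rpois(50, 1)
#' regressBurden(2 * b + rnorm(50, 0, 0.1), b)
#' @export
regressBurden <- function(phenotype, burden, covariates = NULL,
                          minN = 10) {
  df <- data.frame(y = phenotype, burden = burden)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < minN)
    stopf("fewer than %d complete cases (%d)", minN, nrow(df))
  if (length(unique(df$burden)) <= 1L)
    stopf("no variance in predictor")
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  data.frame(beta = sm["burden", 1], se = sm["burden", 2],
             t = sm["burden", 3], p = sm["burden", 4], n = nrow(df))
}

#' Phenotype x CNV-class association grid
#'
#' Regresses each of the five clinical phenotypes on per-sample CNV burden
#' for each CNV class (`all`, `deletion`, `duplication`), mirroring the
#' phenotype-association table layout (phenotype, CNV type, n, t, p).
#'
#' @param pheno a phenotype data.frame (see [readPhenotypes()]).
#' @param stats a [burdenStatistics()] table for the same samples.
#' @param statistic which burden statistic to regress on (default
#'   `"n_cnv"`).
#' @param phenotypes phenotype columns to test.
#' @return a data.frame: `phenotype`, `cnv_class`, `n`, `beta`, `se`,
#'   `t`, `p` (rows with insufficient data carry `NA`).
#' @export
runPhenotypeAssociation <- function(pheno, stats, statistic = "n_cnv",
                                    phenotypes = PHENOTYPE_COLS) {
  out <- list()
  for (ph in phenotypes) {
    if (!ph %in% names(pheno)) next
    for (kl in c("all", "deletion", "duplication")) {
      sub <- stats[stats$cnv_class == kl, ]
      b <- sub[[statistic]][match(pheno$sample_id, sub$sample_id)]
      row <- tryCatch(
        regressBurden(pheno[[ph]], b),
        error = function(e) data.frame(beta = NA_real_, se = NA_real_,
                                       t = NA_real_, p = NA_real_,
                                       n = sum(complete.cases(
                                         data.frame(pheno[[ph]], b)))))
      out[[length(out) + 1L]] <- cbind(
        data.frame(phenotype = ph, cnv_class = kl), row)
    }
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res[c("phenotype", "cnv_class", "n", "beta", "se", "t", "p")]
}

#' Effective number of independent tests by spectral decomposition
#'
#' Eigendecomposes a phenotype correlation matrix and reports two
#' effective-test counts: the eigenvalue-dispersion estimate
#' `v_eff = 1 + (M - 1) (1 - Var(lambda) / M)` (Nyholt) and the
#' integer/fractional partition `v_eff = sum_i h(lambda_i)` with
#' `h(x) = 1\{x >= 1\} + (x - floor(x))` (Li-Ji), together with the
#' corrected per-test significance thresholds `alpha / v_eff` and the
#' Sidak variant `1 - (1 - alpha)^(1 / v_eff)`.
#'
#' @param corMat symmetric correlation matrix (unit diagonal, positive
#'   semi-definite within `tol`).
#' @param alpha initial family-wise error rate.
#' @param tol tolerance for the symmetry/PSD/diagonal checks.
#' @return an object of class `MatSpDResult`: list with `eigenvalues`,
#'   `v_eff_nyholt`, `v_eff_liji`, `alpha_nyholt`, `alpha_liji`,
#'   `alpha_sidak_nyholt`.
#' @examples
#' matSpD(diag(5))$v_eff_nyholt        # 5 (independent traits)
#' matSpD(matrix(1, 5, 5))$v_eff_nyholt  # 1 (perfectly correlated)
#' @export
matSpD <- function(corMat, alpha = 0.05, tol = 1e-8) {
  corMat <- as.matrix(corMat)
  M <- nrow(corMat)
  if (M != ncol(corMat) || max(abs(corMat - t(corMat))) > tol)
    stopf("correlation matrix must be square and symmetric")
  if (max(abs(diag(corMat) - 1)) > tol)
    stopf("correlation matrix must have unit diagonal")
  ev <- eigen(corMat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    stopf("correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
          min(ev))
  ev <- pmax(ev, 0)
  vNyholt <- 1 + (M - 1) * (1 - var(ev) / M)
  vLiJi <- sum(as.numeric(ev >= 1) + (ev - floor(ev)))
  structure(list(eigenvalues = ev, v_eff_nyholt = vNyholt,
                 v_eff_liji = vLiJi,
                 alpha_nyholt = alpha / vNyholt,
                 alpha_liji = alpha / vLiJi,
                 alpha_sidak_nyholt = 1 - (1 - alpha)^(1 / vNyholt)),
            class = "MatSpDResult")
}

#' @export
print.MatSpDResult <- function(x, ...) {
  cat(sprintf(
    "Spectral decomposition of %d traits:\n  v_eff = %.4g (dispersion) / %.4g (partition)\n  corrected alpha = %.4g / %.4g\n",
    length(x$eigenvalues), x$v_eff_nyholt, x$v_eff_liji, x$alpha_nyholt,
    x$alpha_liji))
  invisible(x)
}

#' Power of the 1-df linear-model F test
#'
#' Power to detect a regression effect of size f2 (Cohen's f-squared) with
#' n samples at level alpha, via the noncentral F distribution:
#' `P(F'(1, n - 2; ncp = f2 n) > F_(1-alpha)(1, n - 2))`.
#'
#' @param f2 effect size (f-squared, > 0).
#' @param n sample size (> 2).
#' @param alpha type 1 error probability.
#' @return power in (0, 1).
#' @examples
#' powerLinear(0.005, 1940, 0.05)   # ~0.88
#' @export
powerLinear <- function(f2, n, alpha = 0.05) {
  stopifnot(f2 > 0, alpha > 0, alpha < 1)
  if (n <= 2) stopf("n must exceed 2")
  df2 <- n - 2
  crit <- qf(1 - alpha, 1, df2)
  1 - pf(crit, 1, df2, ncp = f2 * n)
}

#' Power of a two-proportion (carrier frequency) comparison
#'
#' `normal_approx` uses the standard two-proportion z formula (pooled null
#' SE, unpooled alternative SE, two-sided). `exact_sim` simulates binomial
#' carrier counts in both arms and applies [fisherExact()], returning the
#' rejection rate with its Monte Carlo standard error. When the expected
#' carrier count is below 1 in both arms a warning is attached (the
#' approximation is unreliable there).
#'
#' @param pCase,pControl carrier rates in (0, 1).
#' @param nCase,nControl arm sizes.
#' @param alpha significance level (two-sided).
#' @param method `"normal_approx"` or `"exact_sim"`.
#' @param nSim simulated cohorts for `exact_sim`.
#' @param seed RNG seed for `exact_sim`.
#' @return list with `power`, `mc_se` (`NA` for the closed form), and
#'   `reliable` (`FALSE` when carriers are expected to be absent).
#' @export
powerTwoProportion <- function(pCase, pControl, nCase, nControl,
                               alpha = 0.05,
                               method = c("normal_approx", "exact_sim"),
                               nSim = 2000, seed = 1) {
  method <- match.arg(method)
  stopifnot(pCase > 0, pCase < 1, pControl > 0, pControl < 1,
            nCase >= 2, nControl >= 2)
  reliable <- (pCase * nCase >= 1) || (pControl * nControl >= 1)
  if (!reliable)
    warning("expected carrier count < 1 in both arms; power estimate unreliable")
  if (method == "normal_approx") {
    pbar <- (pCase * nCase + pControl * nControl) / (nCase + nControl)
    se0 <- sqrt(pbar * (1 - pbar) * (1 / nCase + 1 / nControl))
    se1 <- sqrt(pCase * (1 - pCase) / nCase +
                pControl * (1 - pControl) / nControl)
    z <- qnorm(1 - alpha / 2)
    delta <- abs(pCase - pControl)
    pow <- pnorm((delta - z * se0) / se1) +
           pnorm((-delta - z * se0) / se1)
    list(power = pow, mc_se = NA_real_, reliable = reliable)
  } else {
    rej <- withSeed(seed, {
      x1 <- rbinom(nSim, nCase, pCase)
      x2 <- rbinom(nSim, nControl, pControl)
      key <- paste(x1, x2)
      uniq <- !duplicated(key)
      pv <- vapply(which(uniq), function(i)
        fisherExact(x1[i], nCase - x1[i], x2[i], nControl - x2[i])$p_two,
        0)
      names(pv) <- key[uniq]
      unname(pv[key]) <= alpha
    })
    pow <- mean(rej)
    list(power = pow, mc_se = sqrt(pow * (1 - pow) / nSim),
         reliable = reliable)
  }
}

# Default trait correlation structure for the synthetic phenotype
# generator: personality traits moderately inter-correlated, onset and
# episode duration weakly coupled to them.
.defaultTraitCor <- function() {
  R <- diag(5)
  dimnames(R) <- list(PHENOTYPE_COLS, PHENOTYPE_COLS)
  R["neuroticism", "extraversion"] <- R["extraversion", "neuroticism"] <- -0.3
  R["neuroticism", "psychoticism"] <- R["psychoticism", "neuroticism"] <- 0.25
  R["extraversion", "psychoticism"] <- R["psychoticism", "extraversion"] <- -0.1
  R["age_of_onset", "neuroticism"] <- R["neuroticism", "age_of_onset"] <- -0.15
  R["age_of_onset", "duration_worst_episode"] <-
    R["duration_worst_episode", "age_of_onset"] <- -0.1
  R
}

#' Simulate clinical phenotypes with a planted burden effect
#'
#' Generates the five clinical phenotypes for a cohort as correlated
#' Gaussian traits (correlation `traitCor`) plus a linear effect of the
#' per-sample CNV burden with per-trait coefficients `beta`, then rescales
#' to plausible clinical units (onset age in years, episode duration in
#' weeks, questionnaire scores) and applies missingness at rate
#' `missingRate` per trait. With `burden` standardized, trait SD 1 and a
#' single nonzero `beta`, the planted effect size is approximately
#' `f2 = beta^2 var(burden)`.
#'
#' @param truth a [TruthTable-class] (supplies sample ids, cohorts,
#'   reported sex).
#' @param burden numeric per-sample burden aligned with the truth samples
#'   (e.g. `n_cnv` from [burdenStatistics()]).
#' @param beta named per-trait burden coefficients (default: no effect).
#' @param traitCor 5x5 trait correlation matrix.
#' @param missingRate per-trait missingness probability.
#' @param seed RNG seed.
#' @return a phenotype data.frame in the [readPhenotypes()] layout.
#' @export
simulatePhenotypes <- function(truth, burden,
                               beta = setNames(numeric(5), PHENOTYPE_COLS),
                               traitCor = .defaultTraitCor(),
                               missingRate = 0.05, seed) {
  stopifnot(is(truth, "TruthTable"))
  samp <- truthSamples(truth)
  n <- nrow(samp)
  stopifnot(length(burden) == n)
  scale_ <- c(age_of_onset = 8, duration_worst_episode = 10,
              neuroticism = 5, extraversion = 5, psychoticism = 3)
  centre <- c(age_of_onset = 35, duration_worst_episode = 26,
              neuroticism = 12, extraversion = 13, psychoticism = 6)
  withSeed(seed, {
    Z <- MASS::mvrnorm(n, mu = rep(0, 5), Sigma = traitCor)
    colnames(Z) <- PHENOTYPE_COLS
    out <- data.frame(sample_id = samp$sample_id, sex = samp$reported_sex,
                      cohort = samp$cohort)
    for (ph in PHENOTYPE_COLS) {
      bph <- if (ph %in% names(beta)) beta[[ph]] else 0
      v <- centre[[ph]] + scale_[[ph]] * (Z[, ph] + bph * burden)
      v[runif(n) < missingRate] <- NA
      out[[ph]] <- round(v, 1)
    }
    out
  })
}
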