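# Internal helpers shared across modules.

ALLOWED_CHROMS <- c(as.character(1:22), "X", "Y")
AUTOSOMES <- as.character(1:22)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this, so results
# are reproducible and calls never perturb the global random stream.
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-unit child seed derivation (kept below 2^31).
#' @noRd
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

# Normalize chromosome labels: strip a leading "chr", validate against the
# allowed set (1-22, X, Y).
#' @noRd
normChrom <- function(chrom, context = "chromosome") {
  chrom <- sub("^chr", "", as.character(chrom))
  bad <- setdiff(unique(chrom), ALLOWED_CHROMS)
  if (length(bad) > 0L)
    stop(sprintf("invalid %s label(s): %s", context,
                 paste(bad, collapse = ", ")), call. = FALSE)
  chrom
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Deterministic largest-remainder apportionment of n into round(p*n) counts
# that sum exactly to n. Used so cohort class proportions give exact counts.
#' @noRd
apportion <- function(n, props) {
  stopifnot(abs(sum(props) - 1) < 1e-8, n >= 0)
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' @noRd
isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
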