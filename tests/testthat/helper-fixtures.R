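# Shared fixtures, built once per session. The standard test map carries
# ~100 markers per autosome (reduced density relative to a production
# array), which is what the default detection thresholds are calibrated
# for.

.fixtureEnv <- new.env(parent = emptyenv())

testMap <- function() {
  if (is.null(.fixtureEnv$map))
    .fixtureEnv$map <- simulateMarkerMap(2200, 150, 40, seed = 1)
  .fixtureEnv$map
}

# Dense map (~500 markers per autosome) for band-estimation properties.
denseMap <- function() {
  if (is.null(.fixtureEnv$dense))
    .fixtureEnv$dense <- simulateMarkerMap(11000, 400, 80, seed = 2)
  .fixtureEnv$dense
}

noiselessModel <- function() NoiseModel(lrrSd = 0, bafSd = 0)

# Three identical call sets built from a data.frame of calls.
callsetsFrom <- function(df, algorithms = c("pennCNV", "quantiSNP",
                                            "iPattern")) {
  out <- lapply(algorithms, function(a)
    karyoCNV:::makeCnvCalls(df$sample_id, df$chrom, df$start, df$end,
                            df$cn, df$n_markers, a,
                            df$score %||% NA_real_))
  names(out) <- algorithms
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
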