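## Shared fixtures: a shortened acquisition protocol and a small phantom
## grid keeping unit tests fast; the acceptance tests use full sizes.

smallProtocol <- function(...) {
  acquisitionProtocol(fastVolumes = 12L, slowVolumes = 10L, slowDST = 20,
                      ...)
}

smallPhantom <- function(seed = 1L, ...) {
  phantomConfig(gridShape = c(8L, 8L, 4L), seed = seed, ...)
}

## A constant-plasma boxcar input starting at t = 0, handy for closed forms.
boxcarVif <- function(c0 = 1, tStart = 0, tEnd = 600) {
  generateVif("boxcar", list(c0 = c0, tStart = tStart, tEnd = tEnd),
              injectionTime = tStart)
}

## Build a single-sequence ConcentrationSeries from a voxel x time matrix.
concFromMatrix <- function(mat, times, tag = "fast", nBaseline = 1L,
                           dims = NULL) {
  if (is.null(dims)) dims <- c(nrow(mat), 1L, 1L)
  concentrationSeries(array(mat, dim = c(dims, ncol(mat))), times,
                      provenance = rep(tag, ncol(mat)),
                      baseline = seq_len(ncol(mat)) <= nBaseline)
}

sampleSkewness <- function(x) {
  mean((x - mean(x))^3) / sd(x)^3
}
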