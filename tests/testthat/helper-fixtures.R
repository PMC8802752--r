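## Fixture builders shared across test files.

## A BoldSeries built directly from a time x voxel matrix (full-grid mask by
## default), with chosen provenance flags -- used to exercise the metric
## contracts on hand-constructed signals.
makeSeries <- function(data, trS = 3, mask = NULL, flags = character(),
                       origMean = NULL, gridShape = NULL) {
  data <- as.matrix(data)
  V <- ncol(data)
  if (is.null(mask)) {
    if (is.null(gridShape)) gridShape <- c(V, 1, 1)
    mask <- array(TRUE, gridShape)
  }
  fl <- stats::setNames(rep(FALSE, 4), c("volumesDiscarded", "detrended",
                                         "nuisanceRegressed", "filtered"))
  fl[flags] <- TRUE
  if (is.null(origMean)) origMean <- colMeans(data)
  new("BoldSeries", data = data, mask = mask, trS = trS,
      voxelSizeMm = c(3, 3, 3), flags = fl, origMean = origMean)
}

allFlags <- c("volumesDiscarded", "detrended", "nuisanceRegressed", "filtered")
unfilteredFlags <- allFlags[1:3]

## Seeded random series on a small grid, for oracle-equivalence checks
randomSeries <- function(gridShape = c(6, 6, 6), n = 40, trS = 3, seed = 42,
                         flags = allFlags) {
  set.seed(seed)
  V <- prod(gridShape)
  makeSeries(matrix(rnorm(n * V), n, V), trS = trS,
             mask = array(TRUE, gridShape), flags = flags)
}

## A sinusoid sampled on the TR grid
sinusoid <- function(freqHz, n, trS, amp = 1, phase = 0) {
  amp * cos(2 * pi * freqHz * (0:(n - 1)) * trS + phase)
}
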