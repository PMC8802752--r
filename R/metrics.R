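#' Metric configuration
#'
#' @param bandLowHz,bandHighHz ALFF/fALFF band in Hz.
#' @param rehoK ReHo neighbourhood size, one of 7, 19, 27 (27 = the study
#'   default: a voxel and its 26 nearest neighbours).
#' @param dcThreshold correlation threshold r0 for degree centrality.
#' @param dcMode "binarized" (count) or "weighted" (sum of suprathreshold r).
#' @param smoothFwhmMm Gaussian smoothing kernel FWHM in mm.
#' @param standardization "mean" (divide by global in-mask mean) or "z".
#' @return A validated list of settings.
#' @export
metricConfig <- function(bandLowHz = 0.01, bandHighHz = 0.08, rehoK = 27,
                         dcThreshold = 0.25, dcMode = "binarized",
                         smoothFwhmMm = 4, standardization = "mean") {
  stopifnot(rehoK %in% c(7, 19, 27), dcThreshold > 0, dcThreshold < 1,
            smoothFwhmMm >= 0, dcMode %in% c("binarized", "weighted"),
            standardization %in% c("mean", "z"))
  list(bandLowHz = bandLowHz, bandHighHz = bandHighHz, rehoK = rehoK,
       dcThreshold = dcThreshold, dcMode = dcMode,
       smoothFwhmMm = smoothFwhmMm, standardization = standardization)
}

## Single-sided amplitude spectrum of each column: 2|F_k|/n for
## k = 1..floor(n/2), with bin frequencies k/(n*tr).
.ampSpectrum <- function(data, trS) {
  n <- nrow(data)
  k <- seq_len(floor(n / 2))
  F <- stats::mvfft(data)
  list(freq = k / (n * trS), amp = 2 * Mod(F[k + 1L, , drop = FALSE]) / n)
}

.checkUnfiltered <- function(series, what) {
  .requireFlags(series, c("volumesDiscarded", "detrended", "nuisanceRegressed"),
                what = what)
  if (series@flags["filtered"])
    stop(sprintf(
      "%s must be computed on the unfiltered series: its definition already restricts to the band",
      what), call. = FALSE)
}

#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' Per voxel: fast Fourier transform, power spectrum, square root at each
#' frequency bin, mean over the bins inside the band. Requires the
#' preprocessed-but-unfiltered series (band-passing first would make the
#' in-band restriction vacuous and is rejected).
#'
#' @param series unfiltered, nuisance-regressed [BoldSeries-class].
#' @param bandLowHz,bandHighHz band in Hz (inclusive bin rule).
#' @return A [MetricMap-class] named "ALFF".
#' @export
computeALFF <- function(series, bandLowHz = 0.01, bandHighHz = 0.08) {
  .checkUnfiltered(series, "computeALFF")
  sp <- .ampSpectrum(series@data, series@trS)
  band <- sp$freq >= bandLowHz & sp$freq <= bandHighHz
  if (!any(band)) stop("no frequency bin falls inside the band")
  alff <- colMeans(sp$amp[band, , drop = FALSE])
  .newMetricMap(.unmask(alff, series@mask), "ALFF", series@mask,
                series@voxelSizeMm)
}

#' Fractional ALFF (fALFF)
#'
#' Ratio of the summed amplitude over in-band bins to the summed amplitude
#' over all positive-frequency bins (DC excluded); 0/0 is defined as 0.
#' Values lie in `[0, 1]`.
#'
#' @inheritParams computeALFF
#' @return A [MetricMap-class] named "fALFF".
#' @export
computeFALFF <- function(series, bandLowHz = 0.01, bandHighHz = 0.08) {
  .checkUnfiltered(series, "computeFALFF")
  sp <- .ampSpectrum(series@data, series@trS)
  band <- sp$freq >= bandLowHz & sp$freq <= bandHighHz
  if (!any(band)) stop("no frequency bin falls inside the band")
  num <- colSums(sp$amp[band, , drop = FALSE])
  den <- colSums(sp$amp)
  falff <- ifelse(den > 0, num / den, 0)
  .newMetricMap(.unmask(falff, series@mask), "fALFF", series@mask,
                series@voxelSizeMm)
}

#' Percent amplitude of fluctuation of one series
#'
#' `PerAF = (1/n) sum |X_i - mu| / mu * 100`, with `mu` the series mean.
#'
#' @param x numeric vector (raw-scale signal with its mean intact).
#' @return PerAF in percent (`NA` when `mu <= 0`).
#' @examples perafSeries(c(90, 110))  # 10
#' @export
perafSeries <- function(x) {
  mu <- mean(x)
  if (mu <= 0) return(NA_real_)
  mean(abs(x - mu)) / mu * 100
}

#' Percent amplitude of fluctuation (PerAF)
#'
#' Mean absolute deviation of the voxel series from its mean, as a
#' percentage of that mean. Band-pass filtering removes the mean, so the
#' voxel's original raw-scale mean (captured at the volume-discard stage) is
#' restored before applying the formula. Voxels whose restored mean is not
#' positive are set to 0 and counted in the `nNonpositiveMean` attribute.
#'
#' @param series filtered [BoldSeries-class] whose `origMean` is available.
#' @return A [MetricMap-class] named "PerAF" (units: percent).
#' @export
computePerAF <- function(series) {
  .requireFlags(series, c("volumesDiscarded", "filtered"), what = "computePerAF")
  if (anyNA(series@origMean))
    stop("original voxel means are unavailable; run discardInitialVolumes first")
  x <- series@data
  mu <- colMeans(x) + series@origMean   # mean of the restored-scale series
  dev <- colMeans(abs(sweep(x, 2, colMeans(x))))
  bad <- mu <= 0
  peraf <- ifelse(bad, 0, dev / mu * 100)
  if (any(bad))
    message(sum(bad), " voxel(s) with non-positive mean set to PerAF = 0")
  out <- .newMetricMap(.unmask(peraf, series@mask), "PerAF", series@mask,
                       series@voxelSizeMm)
  attr(out, "nNonpositiveMean") <- sum(bad)
  out
}

## Neighbourhood offsets for the three ReHo cluster sizes.
.rehoOffsets <- function(K) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  cheb <- pmax(abs(g[, 1]), abs(g[, 2]), abs(g[, 3]))
  manh <- abs(g[, 1]) + abs(g[, 2]) + abs(g[, 3])
  switch(as.character(K),
         "7" = g[manh <= 1, , drop = FALSE],
         "19" = g[manh <= 2 & cheb <= 1, , drop = FALSE],
         "27" = g[cheb <= 1, , drop = FALSE],
         stop("K must be 7, 19 or 27"))
}

#' Regional homogeneity (ReHo)
#'
#' Kendall's coefficient of concordance of each voxel's time series with its
#' neighbourhood (K = 7, 19 or 27 series including the voxel itself):
#' `W = (sum R_i^2 - n Rbar^2) / ((1/12) K^2 (n^3 - n))`, where `R_i` is the
#' across-series rank sum at time i and ranks use average tie handling. At
#' mask edges only in-mask neighbours participate and K is reduced to the
#' actual member count; interior voxels use the full K. W is clipped into
#' `[0, 1]`.
#'
#' @param series filtered [BoldSeries-class] with >= 3 time points.
#' @param K neighbourhood size, one of 7, 19, 27.
#' @return A [MetricMap-class] named "ReHo".
#' @export
computeReHo <- function(series, K = 27) {
  .requireFlags(series, "filtered", what = "computeReHo")
  n <- nVolumes(series)
  if (n < 3) stop("ReHo needs at least 3 time points")
  offs <- .rehoOffsets(K)
  mask <- series@mask
  dims <- dim(mask)
  maskIdx <- which(mask)
  V <- length(maskIdx)
  colIndex <- array(0L, dims)
  colIndex[maskIdx] <- seq_len(V)
  coords <- .maskCoords(mask)

  ranks <- apply(series@data, 2, rank)  # n x V, average ties
  S <- matrix(0, n, V)
  cnt <- integer(V)
  for (o in seq_len(nrow(offs))) {
    nx <- coords[, 1] + offs[o, 1]
    ny <- coords[, 2] + offs[o, 2]
    nz <- coords[, 3] + offs[o, 3]
    ok <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] &
      nz >= 1 & nz <= dims[3]
    nc <- integer(V)
    nc[ok] <- colIndex[cbind(nx[ok], ny[ok], nz[ok])]
    ok <- nc > 0L
    S[, ok] <- S[, ok] + ranks[, nc[ok], drop = FALSE]
    cnt <- cnt + ok
  }
  rbar <- (n + 1) * cnt / 2
  W <- (colSums(S^2) - n * rbar^2) / (cnt^2 * (n^3 - n) / 12)
  W <- pmin(pmax(W, 0), 1)
  .newMetricMap(.unmask(W, series@mask), "ReHo", series@mask,
                series@voxelSizeMm)
}

#' Degree centrality (DC)
#'
#' Pearson correlation of every in-mask voxel pair; binarized DC counts the
#' voxels whose correlation with the index voxel strictly exceeds the
#' threshold (positive correlations only, self excluded), weighted DC sums
#' those correlations. Correlations are computed block-wise so the full
#' voxel-by-voxel matrix is never materialised; results are independent of
#' the block size. Correlations involving a zero-variance voxel are defined
#' as 0 (never counted) and such voxels are reported in the
#' `nZeroVariance` attribute.
#'
#' @param series filtered [BoldSeries-class] with >= 3 time points.
#' @param r0 correlation threshold in (0, 1).
#' @param mode "binarized" or "weighted".
#' @param blockSize voxels per block.
#' @return A [MetricMap-class] named "DC".
#' @export
computeDC <- function(series, r0 = 0.25, mode = c("binarized", "weighted"),
                      blockSize = 2048L) {
  mode <- match.arg(mode)
  .requireFlags(series, "filtered", what = "computeDC")
  n <- nVolumes(series)
  V <- nVoxels(series)
  if (n < 3) stop("DC needs at least 3 time points")
  if (V < 2) stop("DC needs at least 2 in-mask voxels")
  U <- sweep(series@data, 2, colMeans(series@data))
  ss <- sqrt(colSums(U^2))
  zeroVar <- ss == 0
  if (any(zeroVar)) {
    message(sum(zeroVar), " zero-variance voxel(s): correlations set to 0")
    ss[zeroVar] <- 1
  }
  U <- sweep(U, 2, ss, "/")
  U[, zeroVar] <- 0
  dc <- numeric(V)
  for (start in seq(1L, V, by = blockSize)) {
    blk <- start:min(start + blockSize - 1L, V)
    R <- crossprod(U[, blk, drop = FALSE], U)     # |blk| x V
    selfR <- R[cbind(seq_along(blk), blk)]
    if (mode == "binarized") {
      dc[blk] <- rowSums(R > r0) - (selfR > r0)
    } else {
      dc[blk] <- rowSums(R * (R > r0)) - selfR * (selfR > r0)
    }
  }
  out <- .newMetricMap(.unmask(dc, series@mask), "DC", series@mask,
                       series@voxelSizeMm)
  attr(out, "nZeroVariance") <- sum(zeroVar)
  out
}

#' Standardize a metric map by its global mean
#'
#' Default "mean" mode divides every voxel by the global in-mask mean (the
#' m-map convention), so the standardized map has in-mask mean exactly 1.
#' The alternative "z" mode subtracts the in-mask mean and divides by the
#' in-mask SD.
#'
#' @param map a [MetricMap-class].
#' @param mode "mean" or "z".
#' @return Standardized map with the `standardized` flag set.
#' @export
standardizeByGlobalMean <- function(map, mode = c("mean", "z")) {
  mode <- match.arg(mode)
  v <- map@values[map@mask]
  m <- mean(v)
  if (mode == "mean") {
    if (m == 0) stop("global in-mask mean is zero; cannot standardize")
    map@values[map@mask] <- v / m
  } else {
    s <- stats::sd(v)
    if (s == 0) stop("global in-mask SD is zero; cannot z-standardize")
    map@values[map@mask] <- (v - m) / s
  }
  map@standardized <- TRUE
  map
}

## 1D convolution of a 3D array along one axis (zero-padded edges).
.convAxis <- function(a, kern, axis) {
  d <- dim(a)
  half <- (length(kern) - 1L) %/% 2L
  out <- array(0, d)
  for (j in seq_along(kern)) {
    off <- j - 1L - half
    src <- seq_len(d[axis]) + off
    ok <- src >= 1L & src <= d[axis]
    if (!any(ok)) next
    di <- seq_len(d[axis])[ok]; si <- src[ok]
    if (axis == 1L) out[di, , ] <- out[di, , ] + kern[j] * a[si, , ]
    else if (axis == 2L) out[, di, ] <- out[, di, ] + kern[j] * a[, si, ]
    else out[, , di] <- out[, , di] + kern[j] * a[, , si]
  }
  out
}

#' Gaussian spatial smoothing of a metric map
#'
#' Separable 3D Gaussian convolution over the full grid (kernel truncated at
#' 4 sigma and normalised to unit sum, zero-padded edges), then re-masked.
#' `sigma_voxels = fwhm / (voxel size * 2 sqrt(2 ln 2))` per axis. Smoothing
#' an already-smoothed map is an error (the metrics-then-smooth order is
#' enforced); `fwhmMm = 0` is the identity.
#'
#' @param map an unsmoothed [MetricMap-class].
#' @param fwhmMm kernel full width at half maximum in mm (default 4).
#' @return Smoothed map with the `smoothed` flag set.
#' @export
gaussianSmooth <- function(map, fwhmMm = 4) {
  if (map@smoothed)
    stop("map is already smoothed; smoothing is applied once, after metric calculation",
         call. = FALSE)
  if (fwhmMm > 0) {
    a <- map@values
    for (axis in 1:3) {
      sigma <- fwhmMm / (map@voxelSizeMm[axis] * 2 * sqrt(2 * log(2)))
      r <- max(1L, ceiling(4 * sigma))
      kern <- stats::dnorm(-r:r, sd = sigma)
      kern <- kern / sum(kern)
      a <- .convAxis(a, kern, axis)
    }
    a[!map@mask] <- 0
    map@values <- a
  }
  map@smoothed <- TRUE
  map
}

#' Compute all five metric maps for one preprocessed subject
#'
#' ALFF and fALFF from the unfiltered series; PerAF, ReHo and DC from the
#' band-passed series. Each metric is standardized (global-mean division)
#' and smoothed; the unstandardized-but-smoothed PerAF branch is kept as
#' well, mirroring the study's sensitivity analysis.
#'
#' @param prep output of [preprocessSubject()].
#' @param config a [metricConfig()] list.
#' @return named list of [MetricMap-class] objects: ALFF, fALFF, PerAF,
#'   ReHo, DC (standardized + smoothed) and PerAF_unstd (smoothed only).
#' @export
computeAllMetrics <- function(prep, config = metricConfig()) {
  raw <- list(
    ALFF = computeALFF(prep$unfiltered, config$bandLowHz, config$bandHighHz),
    fALFF = computeFALFF(prep$unfiltered, config$bandLowHz, config$bandHighHz),
    PerAF = computePerAF(prep$filtered),
    ReHo = computeReHo(prep$filtered, config$rehoK),
    DC = computeDC(prep$filtered, config$dcThreshold, config$dcMode))
  out <- lapply(raw, function(m)
    gaussianSmooth(standardizeByGlobalMean(m, config$standardization),
                   config$smoothFwhmMm))
  out$PerAF_unstd <- gaussianSmooth(raw$PerAF, config$smoothFwhmMm)
  out
}
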