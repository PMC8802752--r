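#' Temporal preprocessing configuration
#'
#' Defaults follow the study protocol: discard the first 10 volumes,
#' band-pass 0.01-0.08 Hz, and exclude subjects exceeding 3 mm translation
#' or 3 degrees rotation.
#'
#' @param nDiscard initial volumes to discard.
#' @param bandLowHz,bandHighHz band-pass edges in Hz.
#' @param motionLimitMm,motionLimitDeg motion-exclusion limits.
#' @param headRadiusMm head radius for framewise displacement.
#' @return A validated list of settings.
#' @export
preprocConfig <- function(nDiscard = 10, bandLowHz = 0.01, bandHighHz = 0.08,
                          motionLimitMm = 3, motionLimitDeg = 3,
                          headRadiusMm = 50) {
  stopifnot(nDiscard >= 0, bandLowHz >= 0, bandLowHz < bandHighHz,
            motionLimitMm > 0, motionLimitDeg > 0, headRadiusMm > 0)
  list(nDiscard = nDiscard, bandLowHz = bandLowHz, bandHighHz = bandHighHz,
       motionLimitMm = motionLimitMm, motionLimitDeg = motionLimitDeg,
       headRadiusMm = headRadiusMm)
}

#' Discard initial volumes
#'
#' Drops the first `nDiscard` time points (scanner stabilisation period) and
#' records the per-voxel mean of the retained raw-scale series in `origMean`
#' for later use by PerAF.
#'
#' @param series a [BoldSeries-class].
#' @param nDiscard number of volumes to drop (default 10).
#' @return The shortened series with the `volumesDiscarded` flag set.
#' @export
discardInitialVolumes <- function(series, nDiscard = 10) {
  if (nVolumes(series) <= nDiscard)
    stop(sprintf("cannot discard %d volumes from a %d-volume series",
                 nDiscard, nVolumes(series)), call. = FALSE)
  if (nDiscard > 0) series@data <- series@data[-seq_len(nDiscard), , drop = FALSE]
  series@origMean <- colMeans(series@data)
  series <- .setFlag(series, "volumesDiscarded")
  validObject(series)
  series
}

#' Remove per-voxel linear trends
#'
#' Ordinary least-squares line (intercept + slope over time) removed from
#' every voxel series; residuals have exactly zero mean and zero slope.
#'
#' @param series a [BoldSeries-class] with volumes discarded.
#' @return Detrended series with the `detrended` flag set.
#' @export
linearDetrend <- function(series) {
  .requireFlags(series, "volumesDiscarded", what = "linearDetrend")
  n <- nVolumes(series)
  if (n < 3) stop("linear detrend needs at least 3 time points")
  X <- cbind(1, seq_len(n))
  series@data <- .olsResid(X, series@data)
  .setFlag(series, "detrended")
}

#' Friston-24 motion regressor expansion
#'
#' For each of the 6 rigid-body parameters p: current value p(t), its square
#' p(t)^2, the one-volume lag p(t-1), and the squared lag p(t-1)^2 (24
#' columns total). The lagged row at t = 1 is zero-padded.
#'
#' @param motion a [MotionTrace-class].
#' @return numeric matrix, volumes x 24, with descriptive column names.
#' @export
friston24Expand <- function(motion) {
  p <- motionParams(motion)
  n <- nrow(p)
  lag <- rbind(0, p[-n, , drop = FALSE])
  out <- matrix(0, n, 24)
  nm <- character(24)
  base <- colnames(p)
  for (j in 1:6) {
    out[, 4 * j - 3] <- p[, j]
    out[, 4 * j - 2] <- p[, j]^2
    out[, 4 * j - 1] <- lag[, j]
    out[, 4 * j] <- lag[, j]^2
    nm[(4 * j - 3):(4 * j)] <- paste0(base[j], c("", "_sq", "_lag", "_lag_sq"))
  }
  colnames(out) <- nm
  out
}

#' Mean tissue time courses
#'
#' Per-volume spatial mean of the series over a white-matter and a
#' cerebrospinal-fluid mask (restricted to in-brain voxels).
#'
#' @param series a [BoldSeries-class].
#' @param wmMask,csfMask 3D logical arrays on the series grid.
#' @return matrix, volumes x 2, columns "wm" and "csf".
#' @export
extractNuisanceSignals <- function(series, wmMask, csfMask) {
  maskIdx <- which(series@mask)
  course <- function(m, label) {
    cols <- match(which(m & series@mask), maskIdx)
    cols <- cols[!is.na(cols)]
    if (!length(cols))
      stop(sprintf("%s mask is empty inside the brain mask", label),
           call. = FALSE)
    rowMeans(series@data[, cols, drop = FALSE])
  }
  cbind(wm = course(wmMask, "white-matter"),
        csf = course(csfMask, "cerebrospinal-fluid"))
}

#' Regress nuisance covariates out of every voxel
#'
#' Ordinary least squares of each voxel series on an intercept plus the
#' supplied nuisance matrix (typically Friston-24 columns and WM/CSF mean
#' signals); residuals are returned. Collinear columns are dropped with a
#' warning before fitting.
#'
#' @param series a detrended [BoldSeries-class].
#' @param nuisance numeric matrix, volumes x regressors, with column names.
#' @return Residual series with the `nuisanceRegressed` flag set.
#' @export
nuisanceRegress <- function(series, nuisance) {
  .requireFlags(series, c("volumesDiscarded", "detrended"),
                forbid = "filtered", what = "nuisanceRegress")
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nVolumes(series))
    stop("nuisance rows must match the number of volumes")
  X <- cbind(intercept = 1, nuisance)
  qx <- qr(X)
  if (qx$rank >= nVolumes(series))
    stop(sprintf(
      "nuisance design rank (%d) saturates the %d time points; residuals would be zero (series too short for this regressor set)",
      qx$rank, nVolumes(series)), call. = FALSE)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("dropping collinear nuisance column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  series@data <- .olsResid(X, series@data)
  .setFlag(series, "nuisanceRegressed")
}

#' Ideal frequency-domain band-pass filter
#'
#' Discrete-Fourier boxcar (REST/DPABI convention): bins whose frequency f
#' satisfies `low <= f <= high` (inclusive) are retained, all others —
#' including the DC bin — are zeroed, and the inverse transform is returned.
#' The operation is a projection: applying it twice equals applying it once.
#'
#' @param series a nuisance-regressed [BoldSeries-class].
#' @param lowHz,highHz band edges in Hz; must satisfy
#'   `0 <= low < high < 1/(2 TR)`.
#' @return Filtered series with the `filtered` flag set.
#' @export
idealBandpass <- function(series, lowHz = 0.01, highHz = 0.08) {
  .requireFlags(series, c("volumesDiscarded", "detrended", "nuisanceRegressed"),
                what = "idealBandpass")
  nyquist <- 1 / (2 * series@trS)
  if (!(lowHz >= 0 && lowHz < highHz && highHz < nyquist))
    stop(sprintf(
      "band [%g, %g] Hz must satisfy 0 <= low < high < Nyquist (%g Hz)",
      lowHz, highHz, nyquist), call. = FALSE)
  n <- nVolumes(series)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * series@trS)
  keep <- f >= lowHz & f <= highHz & k != 0L  # DC always removed
  F <- stats::mvfft(series@data)
  F[!keep, ] <- 0
  series@data <- Re(stats::mvfft(F, inverse = TRUE)) / n
  .setFlag(series, "filtered")
}

#' Framewise displacement (Power convention)
#'
#' `FD(t) = sum |delta translations| + r * sum |delta rotations|` with head
#' radius r (default 50 mm) converting radians to arc length; the first
#' volume's FD is 0 by convention.
#'
#' @param motion a [MotionTrace-class] (rotations in radians).
#' @param headRadiusMm head radius in mm.
#' @return list with `fd` (per-volume, mm) and `meanFd` (mm).
#' @export
framewiseDisplacement <- function(motion, headRadiusMm = 50) {
  p <- motionParams(motion)
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               headRadiusMm * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, meanFd = mean(fd))
}

#' Motion quality control
#'
#' Excludes a subject if any translation exceeds `limitMm` mm or any
#' rotation exceeds `limitDeg` degrees (strict inequalities; a maximum of
#' exactly 3 mm is included). Rotations are stored in radians and converted
#' to degrees for the rule.
#'
#' @param motion a [MotionTrace-class].
#' @param limitMm,limitDeg exclusion limits.
#' @return list with `include` (logical), `maxTranslationMm`,
#'   `maxRotationDeg`.
#' @export
motionQC <- function(motion, limitMm = 3, limitDeg = 3) {
  p <- motionParams(motion)
  maxT <- max(abs(p[, 1:3]))
  maxRdeg <- max(abs(p[, 4:6])) * 180 / pi
  list(include = !(maxT > limitMm || maxRdeg > limitDeg),
       maxTranslationMm = maxT, maxRotationDeg = maxRdeg)
}

#' Run the full temporal preprocessing chain for one subject
#'
#' Fixed stage order: discard initial volumes, linear detrend, Friston-24 +
#' WM/CSF nuisance regression, ideal band-pass. The motion trace is
#' truncated to match the discard. Both the band-passed series (for PerAF,
#' ReHo, DC) and the preprocessed-but-unfiltered series (for ALFF and fALFF,
#' whose definitions include the spectral step) are returned.
#'
#' @param subject list with elements `bold`, `motion`, `wmMask`, `csfMask`
#'   (as produced by [generateCohort()]).
#' @param config a [preprocConfig()] list.
#' @return list with `unfiltered`, `filtered` ([BoldSeries-class]), `motion`
#'   (truncated [MotionTrace-class]) and `fd` (framewise displacement list).
#' @export
preprocessSubject <- function(subject, config = preprocConfig()) {
  series <- discardInitialVolumes(subject$bold, config$nDiscard)
  p <- motionParams(subject$motion)
  if (config$nDiscard > 0) p <- p[-seq_len(config$nDiscard), , drop = FALSE]
  motion <- motionTrace(p)
  series <- linearDetrend(series)
  nuis <- cbind(friston24Expand(motion),
                extractNuisanceSignals(series, subject$wmMask, subject$csfMask))
  allZero <- colSums(abs(nuis)) == 0
  if (any(allZero)) {
    message("dropping empty nuisance column(s): ",
            paste(colnames(nuis)[allZero], collapse = ", "))
    nuis <- nuis[, !allZero, drop = FALSE]
  }
  series <- if (ncol(nuis)) nuisanceRegress(series, nuis) else .setFlag(series, "nuisanceRegressed")
  filtered <- idealBandpass(series, config$bandLowHz, config$bandHighHz)
  list(unfiltered = series, filtered = filtered, motion = motion,
       fd = framewiseDisplacement(motion, config$headRadiusMm))
}
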