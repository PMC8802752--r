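## Internal helpers: seed substreams, voxel indexing, constructors.

.SEED_MOD <- 2147483647  # 2^31 - 1; derived seeds stay valid R integers

#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' substreams (e.g. "bold", "motion", "scores") plus an index, so that
#' regenerating any one component is reproducible independently of the
#' others.
#'
#' @param root integer root seed.
#' @param name substream name.
#' @param index nonnegative integer distinguishing draws within a substream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substreamSeed <- function(root, name, index = 0L) {
  h <- as.numeric(root) %% .SEED_MOD
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% .SEED_MOD
  h <- (h * 31 + as.numeric(index) + 1) %% .SEED_MOD
  as.integer(h %% (.SEED_MOD - 2) + 1)
}

## linear index <-> 3D coordinate helpers (column-major, 1-based)
.maskCoords <- function(mask) {
  arrayInd(which(mask), dim(mask))
}

## Place a vector of in-mask values into a zero-filled 3D array.
.unmask <- function(values, mask) {
  out <- array(0, dim = dim(mask))
  out[mask] <- values
  out
}

.newBoldSeries <- function(data, mask, trS, voxelSizeMm = c(3, 3, 3),
                           flags = NULL, origMean = NULL) {
  if (is.null(flags)) {
    flags <- stats::setNames(rep(FALSE, 4L), .BOLD_FLAGS)
  }
  if (is.null(origMean)) origMean <- rep(NA_real_, ncol(data))
  new("BoldSeries", data = data, mask = mask, trS = trS,
      voxelSizeMm = voxelSizeMm, flags = flags, origMean = origMean)
}

.newMetricMap <- function(values, metric, mask, voxelSizeMm,
                          standardized = FALSE, smoothed = FALSE) {
  new("MetricMap", values = values, metric = metric, mask = mask,
      voxelSizeMm = voxelSizeMm, standardized = standardized,
      smoothed = smoothed)
}

#' Construct a motion trace from a volumes-by-6 matrix
#'
#' @param params numeric matrix with one row per volume and columns
#'   tx, ty, tz (mm), rx, ry, rz (radians).
#' @return A [MotionTrace-class] object.
#' @export
motionTrace <- function(params) {
  params <- as.matrix(params)
  colnames(params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  new("MotionTrace", params = params)
}

.requireFlags <- function(series, need, forbid = character(), what = "operation") {
  fl <- series@flags
  missing <- need[!fl[need]]
  if (length(missing))
    stop(sprintf("%s requires stage(s) %s to have been applied first",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  bad <- forbid[fl[forbid]]
  if (length(bad))
    stop(sprintf("%s must not be applied after stage(s) %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

.setFlag <- function(series, flag) {
  series@flags[flag] <- TRUE
  series
}

## OLS residuals of (possibly many) response columns on a design matrix.
## Cholesky on the normal equations (fast, BLAS-bound); falls back to QR
## when the design is ill-conditioned.
.olsResid <- function(X, Y) {
  R <- tryCatch(chol(crossprod(X)), error = function(e) NULL)
  if (is.null(R)) return(qr.resid(qr(X), Y))
  Y - X %*% backsolve(R, forwardsolve(t(R), crossprod(X, Y)))
}
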