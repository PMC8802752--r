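#' @import methods
NULL

## Provenance flags a BoldSeries acquires, in pipeline order.
.BOLD_FLAGS <- c("volumesDiscarded", "detrended", "nuisanceRegressed", "filtered")

#' Masked 4D BOLD time series
#'
#' Central container for a subject's resting-state BOLD data. The time series
#' are stored as a time-by-voxel matrix restricted to in-mask voxels
#' (column-major order of `which(mask)`), alongside the 3D brain mask, the
#' repetition time, and provenance flags recording which temporal
#' preprocessing stages have been applied. `origMean` keeps the per-voxel
#' mean intensity of the raw-scale (post-discard) series so that PerAF, which
#' needs the mean signal intensity, survives detrending and filtering.
#'
#' @slot data numeric matrix, time points x in-mask voxels.
#' @slot mask 3D logical array, the brain mask.
#' @slot trS repetition time in seconds.
#' @slot voxelSizeMm length-3 numeric, voxel edge lengths in mm.
#' @slot flags named logical vector of preprocessing provenance flags.
#' @slot origMean per-voxel mean of the raw-scale series (same order as
#'   columns of `data`); `NA` until volumes have been discarded.
#'
#' @export
setClass("BoldSeries",
  representation(
    data = "matrix",
    mask = "array",
    trS = "numeric",
    voxelSizeMm = "numeric",
    flags = "logical",
    origMean = "numeric"
  )
)

setValidity("BoldSeries", function(object) {
  msg <- character()
  if (nrow(object@data) < 2L)
    msg <- c(msg, "time dimension must be >= 2")
  if (length(object@trS) != 1L || object@trS <= 0)
    msg <- c(msg, "trS must be a single positive number")
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 3D logical array")
  if (ncol(object@data) != sum(object@mask))
    msg <- c(msg, "data columns must match number of in-mask voxels")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    msg <- c(msg, "voxelSizeMm must be 3 positive numbers")
  if (!identical(names(object@flags), .BOLD_FLAGS))
    msg <- c(msg, "flags must be named volumesDiscarded, detrended, nuisanceRegressed, filtered")
  if (length(object@origMean) != ncol(object@data))
    msg <- c(msg, "origMean length must equal number of in-mask voxels")
  if (length(msg)) msg else TRUE
})

#' Rigid-body head-motion trace
#'
#' Per-volume 6-parameter rigid-body motion record in the SPM `rp_*.txt`
#' dialect: three translations in mm followed by three rotations in radians.
#'
#' @slot params numeric matrix, volumes x 6 (tx, ty, tz in mm; rx, ry, rz in
#'   radians).
#'
#' @export
setClass("MotionTrace", representation(params = "matrix"))

setValidity("MotionTrace", function(object) {
  msg <- character()
  if (ncol(object@params) != 6L)
    msg <- c(msg, "params must have 6 columns (3 translations mm, 3 rotations rad)")
  if (nrow(object@params) < 2L)
    msg <- c(msg, "at least 2 volumes required")
  if (length(msg)) msg else TRUE
})

#' Per-voxel 3D metric map
#'
#' A single subject's 3D map of one intrinsic-activity metric, with the mask
#' it was computed in and state flags recording whether the map has been
#' standardized (global-mean division) and/or spatially smoothed.
#'
#' @slot values 3D numeric array; out-of-mask voxels are zero.
#' @slot metric one of "ALFF", "fALFF", "PerAF", "ReHo", "DC".
#' @slot mask 3D logical array.
#' @slot voxelSizeMm length-3 numeric, mm.
#' @slot standardized,smoothed logical state flags.
#'
#' @export
setClass("MetricMap",
  representation(
    values = "array",
    metric = "character",
    mask = "array",
    voxelSizeMm = "numeric",
    standardized = "logical",
    smoothed = "logical"
  )
)

setValidity("MetricMap", function(object) {
  msg <- character()
  if (!object@metric %in% c("ALFF", "fALFF", "PerAF", "ReHo", "DC"))
    msg <- c(msg, "metric must be one of ALFF, fALFF, PerAF, ReHo, DC")
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must share dimensions")
  if (length(msg)) msg else TRUE
})

#' Voxelwise group-comparison statistic map
#'
#' Result of the voxelwise two-sample GLM: the t map for the group contrast,
#' its degrees of freedom, and the residual stack (subjects x in-mask voxels)
#' retained for random-field smoothness estimation.
#'
#' @slot tValues 3D numeric array of t statistics (zero outside mask).
#' @slot df residual degrees of freedom (subjects - rank of design).
#' @slot residuals numeric matrix, subjects x in-mask voxels.
#' @slot mask 3D logical array.
#' @slot voxelSizeMm length-3 numeric, mm.
#'
#' @export
setClass("StatMap",
  representation(
    tValues = "array",
    df = "numeric",
    residuals = "matrix",
    mask = "array",
    voxelSizeMm = "numeric"
  )
)

setValidity("StatMap", function(object) {
  msg <- character()
  if (!identical(dim(object@tValues), dim(object@mask)))
    msg <- c(msg, "tValues and mask must share dimensions")
  if (object@df < 1)
    msg <- c(msg, "df must be >= 1")
  if (any(!is.finite(object@tValues[object@mask])))
    msg <- c(msg, "t values must be finite inside the mask")
  if (length(msg)) msg else TRUE
})

#' Random-field smoothness estimate
#'
#' Per-axis FWHM of the residual field and the resulting resel counts used by
#' the Gaussian-random-field cluster correction.
#'
#' @slot fwhmMm length-3 numeric, estimated FWHM per axis in mm.
#' @slot resels length-4 numeric, resel counts of dimension 0..3 (box
#'   approximation of the search region).
#' @slot voxelSizeMm length-3 numeric, mm.
#' @slot nMaskVoxels number of voxels in the search region.
#'
#' @export
setClass("SmoothnessEstimate",
  representation(
    fwhmMm = "numeric",
    resels = "numeric",
    voxelSizeMm = "numeric",
    nMaskVoxels = "numeric"
  )
)

setValidity("SmoothnessEstimate", function(object) {
  msg <- character()
  if (length(object@fwhmMm) != 3L || any(object@fwhmMm <= 0))
    msg <- c(msg, "fwhmMm must be 3 positive numbers")
  if (length(object@resels) != 4L || object@resels[4] <= 0)
    msg <- c(msg, "resels must have 4 entries with positive 3D count")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' Describes a two-group synthetic BOLD cohort: grid, acquisition timing,
#' site structure, planted effect regions, noise level and the root seed.
#' Acquisition presets of interest are TR 3.0 s with 197 volumes and TR
#' 0.607 s with 976 volumes; the default is a desk-scale 24^3 grid with 120
#' volumes at TR 3 s.
#'
#' @slot nPerGroup subjects per group.
#' @slot gridShape length-3 integer voxel grid.
#' @slot trS repetition time (s).
#' @slot nVolumes number of time points.
#' @slot sites data.frame with columns site, offset, noise_scale.
#' @slot effects list of effect regions (see [effectRegion()]).
#' @slot noiseSd baseline Gaussian noise SD.
#' @slot baselineMean mean BOLD intensity (> 0, arbitrary units).
#' @slot ampTotal total low-frequency oscillation amplitude per voxel.
#' @slot bandLowHz,bandHighHz frequency band the oscillations populate.
#' @slot voxelSizeMm length-3 numeric, mm.
#' @slot seed integer root seed.
#'
#' @export
setClass("CohortSpec",
  representation(
    nPerGroup = "numeric",
    gridShape = "numeric",
    trS = "numeric",
    nVolumes = "numeric",
    sites = "data.frame",
    effects = "list",
    noiseSd = "numeric",
    baselineMean = "numeric",
    ampTotal = "numeric",
    bandLowHz = "numeric",
    bandHighHz = "numeric",
    voxelSizeMm = "numeric",
    seed = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 2)
    msg <- c(msg, "nPerGroup must be >= 2")
  if (object@nVolumes <= 10)
    msg <- c(msg, "nVolumes must exceed 10 (initial-volume discard)")
  if (object@baselineMean <= 0)
    msg <- c(msg, "baselineMean must be > 0")
  if (object@bandHighHz >= 1 / (2 * object@trS))
    msg <- c(msg, sprintf(
      "band upper edge %.4f Hz must be below the Nyquist frequency %.4f Hz",
      object@bandHighHz, 1 / (2 * object@trS)))
  if (!all(c("site", "offset", "noise_scale") %in% names(object@sites)))
    msg <- c(msg, "sites must have columns site, offset, noise_scale")
  for (eff in object@effects) {
    lo <- eff$center - eff$radius
    hi <- eff$center + eff$radius
    if (any(lo < 1) || any(hi > object@gridShape))
      msg <- c(msg, sprintf("effect region at (%s) radius %d exceeds the grid",
                            paste(eff$center, collapse = ","), eff$radius))
    if (eff$radius < 1) msg <- c(msg, "effect radius must be >= 1")
    if (eff$group_ratio <= 0) msg <- c(msg, "group_ratio must be > 0")
    if (!eff$kind %in% c("amplitude", "synchrony", "hub"))
      msg <- c(msg, "effect kind must be amplitude, synchrony or hub")
  }
  if (length(msg)) msg else TRUE
})
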