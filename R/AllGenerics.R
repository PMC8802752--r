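#' Accessors for restiba data objects
#'
#' Small accessor family for the S4 containers: `boldMatrix` returns the
#' time-by-voxel data matrix, `brainMask` the 3D logical mask, `nVolumes` and
#' `nVoxels` the dimensions, `repetitionTime` the TR in seconds,
#' `seriesFlags` the preprocessing provenance flags, `metricValues` the 3D
#' array of a metric map, and `motionParams` the volumes-by-6 motion matrix.
#'
#' @param x a `BoldSeries`, `MetricMap`, `StatMap` or `MotionTrace` object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("boldMatrix", function(x) standardGeneric("boldMatrix"))
#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("seriesFlags", function(x) standardGeneric("seriesFlags"))
#' @rdname accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
#' @rdname accessors
#' @export
setGeneric("motionParams", function(x) standardGeneric("motionParams"))

#' @rdname accessors
setMethod("boldMatrix", "BoldSeries", function(x) x@data)
#' @rdname accessors
setMethod("brainMask", "BoldSeries", function(x) x@mask)
#' @rdname accessors
setMethod("brainMask", "MetricMap", function(x) x@mask)
#' @rdname accessors
setMethod("brainMask", "StatMap", function(x) x@mask)
#' @rdname accessors
setMethod("nVolumes", "BoldSeries", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nVolumes", "MotionTrace", function(x) nrow(x@params))
#' @rdname accessors
setMethod("nVoxels", "BoldSeries", function(x) ncol(x@data))
#' @rdname accessors
setMethod("repetitionTime", "BoldSeries", function(x) x@trS)
#' @rdname accessors
setMethod("seriesFlags", "BoldSeries", function(x) x@flags)
#' @rdname accessors
setMethod("metricValues", "MetricMap", function(x) x@values)
#' @rdname accessors
setMethod("motionParams", "MotionTrace", function(x) x@params)

setMethod("show", "BoldSeries", function(object) {
  cat(sprintf(
    "BoldSeries: %d volumes x %d in-mask voxels (grid %s), TR %.3f s\n",
    nrow(object@data), ncol(object@data),
    paste(dim(object@mask), collapse = "x"), object@trS))
  on <- names(object@flags)[object@flags]
  cat("  stages applied:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
})

setMethod("show", "MetricMap", function(object) {
  cat(sprintf(
    "MetricMap <%s>: grid %s, %d in-mask voxels%s%s\n",
    object@metric, paste(dim(object@values), collapse = "x"),
    sum(object@mask),
    if (object@standardized) ", standardized" else "",
    if (object@smoothed) ", smoothed" else ""))
  v <- object@values[object@mask]
  cat(sprintf("  in-mask range [%.4g, %.4g], mean %.4g\n",
              min(v), max(v), mean(v)))
})

setMethod("show", "StatMap", function(object) {
  tv <- object@tValues[object@mask]
  cat(sprintf("StatMap: grid %s, df %.0f, t range [%.3f, %.3f]\n",
              paste(dim(object@tValues), collapse = "x"), object@df,
              min(tv), max(tv)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d/group, grid %s, %d volumes @ TR %.3f s, %d site(s), %d effect(s), noise SD %.3g, seed %d\n",
    object@nPerGroup, paste(object@gridShape, collapse = "x"),
    object@nVolumes, object@trS, nrow(object@sites),
    length(object@effects), object@noiseSd, object@seed))
})
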