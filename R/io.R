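#' NIfTI and text I/O for pipeline artifacts
#'
#' Thin wrappers over RNifti for 4D BOLD volumes, 3D masks and metric maps
#' (diagonal affine from the voxel size), SPM-dialect motion parameter text
#' files (6 whitespace-delimited columns: translations in mm, rotations in
#' radians), and TSV cluster tables.
#'
#' @name restiba-io
NULL

.asNiftiArray <- function(arr, voxelSizeMm, trS = NULL) {
  img <- RNifti::asNifti(arr)
  pd <- if (is.null(trS)) voxelSizeMm else c(voxelSizeMm, trS)
  RNifti::pixdim(img) <- pd
  img
}

#' @rdname restiba-io
#' @param series a [BoldSeries-class].
#' @param path output/input file path (`.nii` or `.nii.gz`).
#' @export
writeBoldNifti <- function(series, path) {
  dims <- dim(series@mask)
  n <- nVolumes(series)
  arr <- array(0, c(dims, n))
  full <- matrix(0, prod(dims), n)
  full[which(series@mask), ] <- t(series@data)
  arr[] <- full
  RNifti::writeNifti(.asNiftiArray(arr, series@voxelSizeMm, series@trS), path)
  invisible(path)
}

#' @rdname restiba-io
#' @param mask 3D logical array.
#' @param voxelSizeMm length-3 numeric, mm.
#' @export
writeMaskNifti <- function(mask, voxelSizeMm, path) {
  RNifti::writeNifti(.asNiftiArray(array(as.integer(mask), dim(mask)),
                                   voxelSizeMm), path)
  invisible(path)
}

#' @rdname restiba-io
#' @param map a [MetricMap-class].
#' @export
writeMetricNifti <- function(map, path) {
  RNifti::writeNifti(.asNiftiArray(map@values, map@voxelSizeMm), path)
  invisible(path)
}

#' @rdname restiba-io
#' @param maskPath path to a 3D brain-mask NIfTI (nonzero = in mask).
#' @param trS repetition time in seconds; when `NULL`, taken from the
#'   image's 4th pixdim entry.
#' @export
readBoldNifti <- function(path, maskPath, trS = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  stopifnot(length(dim(arr)) == 4)
  mask <- as.array(RNifti::readNifti(maskPath)) != 0
  hdr <- RNifti::niftiHeader(img)
  if (is.null(trS)) trS <- hdr$pixdim[5]
  voxelSizeMm <- hdr$pixdim[2:4]
  dims <- dim(arr)
  full <- matrix(arr, prod(dims[1:3]), dims[4])
  .newBoldSeries(t(full[which(mask), , drop = FALSE]), mask, trS, voxelSizeMm)
}

#' @rdname restiba-io
#' @param motion a [MotionTrace-class].
#' @export
writeMotionFile <- function(motion, path) {
  utils::write.table(format(motionParams(motion), digits = 10,
                            scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname restiba-io
#' @export
readMotionFile <- function(path) {
  motionTrace(as.matrix(utils::read.table(path)))
}

#' @rdname restiba-io
#' @param clusters cluster table from [grfClusterInference()].
#' @export
writeClusterTable <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
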