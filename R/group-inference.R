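#' Build the group-comparison design matrix
#'
#' Columns: intercept, group indicator (reverter-like = 1, control = 0),
#' mean framewise displacement (mean-centered), and k-1 site dummy columns
#' (reference level dropped). The contrast vector selects the group column.
#'
#' @param covariates data.frame with columns `subject_id`, `group`
#'   ("reverter"/"control"), `mean_fd`, `site`.
#' @return list with `design` (matrix), `contrast` (numeric vector),
#'   `covariates` (the input rows, in design order).
#' @export
buildDesignMatrix <- function(covariates) {
  stopifnot(all(c("subject_id", "group", "mean_fd", "site") %in%
                  names(covariates)))
  g <- as.integer(covariates$group == "reverter")
  if (sum(g) < 2 || sum(1 - g) < 2)
    stop("need at least 2 subjects per group")
  bad <- names(which(tapply(g, covariates$site,
                            function(x) length(unique(x)) < 2)))
  if (length(bad))
    stop("site(s) ", paste(bad, collapse = ", "),
         " contain only one group; run matchFilterCohort first",
         call. = FALSE)
  X <- cbind(intercept = 1, group = g,
             mean_fd = covariates$mean_fd - mean(covariates$mean_fd))
  sites <- sort(unique(covariates$site))
  if (length(sites) > 1) {
    dummies <- vapply(sites[-1], function(s)
      as.numeric(covariates$site == s), numeric(nrow(covariates)))
    colnames(dummies) <- paste0("site_", sites[-1])
    X <- cbind(X, dummies)
  }
  contrast <- as.numeric(colnames(X) == "group")
  list(design = X, contrast = contrast, covariates = covariates)
}

#' Voxelwise two-sample GLM t map
#'
#' Ordinary least squares of each voxel's metric value on the design; the t
#' statistic for the group contrast is `c'beta / SE`, positive when the
#' reverter-like group exceeds controls after covariate adjustment. With
#' covariates orthogonal to group this reduces to the classic pooled
#' two-sample t. Residuals are retained for smoothness estimation.
#'
#' @param maps list of [MetricMap-class] (one per subject, consistent grid
#'   and processing state), in the design's row order.
#' @param design output of [buildDesignMatrix()].
#' @return A [StatMap-class].
#' @export
glmTwoSampleT <- function(maps, design) {
  X <- design$design
  n <- nrow(X)
  if (length(maps) != n) stop("one map per design row required")
  if (n < ncol(X) + 1)
    stop("fewer subjects than design columns + 1")
  mask <- maps[[1]]@mask
  for (m in maps) {
    if (!identical(dim(m@mask), dim(mask)) || !identical(which(m@mask), which(mask)))
      stop("all maps must share the same grid and mask")
    if (!identical(c(m@standardized, m@smoothed),
                   c(maps[[1]]@standardized, maps[[1]]@smoothed)))
      stop("all maps must share the same standardization/smoothing state")
  }
  Y <- t(vapply(maps, function(m) m@values[mask], numeric(sum(mask))))
  qx <- qr(X)
  df <- n - qx$rank
  beta <- qr.coef(qx, Y)
  beta[is.na(beta)] <- 0
  resid <- qr.resid(qx, Y)
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  cvar <- drop(t(design$contrast) %*% XtXinv %*% design$contrast)
  b <- drop(design$contrast %*% beta)
  se <- sqrt(sigma2 * cvar)
  tval <- ifelse(se > 0, b / se, 0)
  new("StatMap", tValues = .unmask(tval, mask), df = df, residuals = resid,
      mask = mask, voxelSizeMm = maps[[1]]@voxelSizeMm)
}

#' Estimate residual-field smoothness
#'
#' Per-axis FWHM from the variance of spatial derivatives of the normalised
#' GLM residuals: each voxel's residual vector is scaled to unit norm, the
#' mean squared difference `lambda` between adjacent in-mask voxels is taken
#' per axis, and `FWHM = sqrt(4 ln 2 / lambda)` voxels. Resel counts use a
#' cube of equivalent volume as the search-region approximation, giving the
#' dimension-0..3 resel vector for the expected-Euler-characteristic
#' expansion.
#'
#' @param residuals numeric matrix, volumes (subjects) x in-mask voxels, or
#'   a [StatMap-class] (its residual stack is used).
#' @param mask 3D logical array (ignored when `residuals` is a StatMap).
#' @param voxelSizeMm length-3 numeric, mm.
#' @return A [SmoothnessEstimate-class].
#' @export
estimateSmoothness <- function(residuals, mask = NULL, voxelSizeMm = NULL) {
  if (is(residuals, "StatMap")) {
    mask <- residuals@mask
    voxelSizeMm <- residuals@voxelSizeMm
    residuals <- residuals@residuals
  }
  if (nrow(residuals) < 3) stop("need at least 3 residual volumes")
  norms <- sqrt(colSums(residuals^2))
  if (all(norms == 0)) stop("residuals are constant; smoothness undefined")
  ok <- norms > 0
  u <- sweep(residuals, 2, pmax(norms, .Machine$double.xmin), "/")
  dims <- dim(mask)
  V <- sum(mask)
  colIndex <- array(0L, dims)
  colIndex[mask] <- seq_len(V)
  coords <- .maskCoords(mask)
  fwhmVox <- numeric(3)
  for (axis in 1:3) {
    nb <- coords
    nb[, axis] <- nb[, axis] + 1L
    inside <- nb[, axis] <= dims[axis]
    nc <- integer(nrow(coords))
    nc[inside] <- colIndex[nb[inside, , drop = FALSE]]
    pa <- which(nc > 0L & ok & ok[pmax(nc, 1L)])
    pb <- nc[pa]
    if (!length(pa)) stop("mask has no adjacent voxel pairs along axis ", axis)
    lambda <- mean(colSums((u[, pa, drop = FALSE] - u[, pb, drop = FALSE])^2))
    if (lambda <= 0) stop("degenerate residual field along axis ", axis)
    fwhmVox[axis] <- sqrt(4 * log(2) / lambda)
  }
  side <- V^(1 / 3)
  a <- side / fwhmVox
  resels <- c(1, sum(a), a[1] * a[2] + a[1] * a[3] + a[2] * a[3], prod(a))
  new("SmoothnessEstimate", fwhmMm = fwhmVox * voxelSizeMm, resels = resels,
      voxelSizeMm = voxelSizeMm, nMaskVoxels = V)
}

## Gaussian expected-Euler-characteristic densities, dimensions 0..3,
## at threshold u, per resel (FWHM units).
.ecDensities <- function(u) {
  c(stats::pnorm(u, lower.tail = FALSE),
    (4 * log(2))^0.5 / (2 * pi) * exp(-u^2 / 2),
    (4 * log(2)) / (2 * pi)^1.5 * u * exp(-u^2 / 2),
    (4 * log(2))^1.5 / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2))
}

## Cluster-level corrected p for a cluster of k voxels at Gaussianized
## threshold u in a region of S voxels with the given resel vector.
.grfClusterP <- function(k, u, resels, S) {
  Em <- max(sum(resels * .ecDensities(u)), .Machine$double.xmin)
  En <- S * stats::pnorm(u, lower.tail = FALSE)
  beta <- (gamma(5 / 2) * Em / En)^(2 / 3)
  Pk <- exp(-beta * k^(2 / 3))
  min(1, max(1 - exp(-Em * Pk), .Machine$double.xmin))
}

#' Label connected suprathreshold clusters
#'
#' Flood-fill labelling of `TRUE` voxels using 26-, 18- or 6-neighbour
#' connectivity.
#'
#' @param supra 3D logical array.
#' @param connectivity 6, 18 or 26 (default 26, the DPABI convention).
#' @return integer array of cluster labels (0 = background).
#' @export
labelClusters <- function(supra, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manh <- rowSums(abs(g))
  g <- g[manh > 0 & manh <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  dims <- dim(supra)
  labels <- array(0L, dims)
  todo <- which(supra)
  lab <- 0L
  for (v in todo) {
    if (labels[v] != 0L) next
    lab <- lab + 1L
    queue <- v
    labels[v] <- lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, dims)
      nb <- sweep(g, 2, as.integer(cc), "+")
      okr <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[okr, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      lin <- lin[supra[lin] & labels[lin] == 0L]
      labels[lin] <- lab
      queue <- c(queue, lin)
    }
  }
  labels
}

## mm coordinate of a grid voxel: signed, origin at the grid center.
.gridToMm <- function(ijk, dims, voxelSizeMm) {
  (ijk - (dims + 1) / 2) * voxelSizeMm
}

#' Gaussian-random-field cluster-level inference
#'
#' Two-tailed procedure: positive and negative excursion sets are formed
#' separately at the per-tail voxel threshold (`voxelP / 2` each when
#' two-tailed), clusters are defined by 26-connectivity, and each cluster's
#' corrected p comes from the classical random-field expected-cluster-count
#' and cluster-extent formulas at the Gaussianized threshold. Clusters with
#' corrected p below `clusterP` are retained.
#'
#' @param stat a [StatMap-class].
#' @param smooth a [SmoothnessEstimate-class] (from the same GLM residuals).
#' @param voxelP voxel-level threshold (two-tailed when `twoTailed`).
#' @param clusterP cluster-level corrected threshold.
#' @param twoTailed logical.
#' @param connectivity cluster-forming connectivity (6, 18 or 26).
#' @return data.frame with columns cluster_id, size_voxels, peak_i/j/k
#'   (grid), peak_x/y/z_mm, peak_t, sign, corrected_p; the per-cluster
#'   logical masks are attached as the `masks` attribute. Empty when no
#'   cluster survives.
#' @export
grfClusterInference <- function(stat, smooth, voxelP = 0.05, clusterP = 0.05,
                                twoTailed = TRUE, connectivity = 26) {
  if (stat@df < 1) stop("degrees of freedom must be >= 1")
  pTail <- if (twoTailed) voxelP / 2 else voxelP
  tThresh <- stats::qt(pTail, df = stat@df, lower.tail = FALSE)
  u <- stats::qnorm(pTail, lower.tail = FALSE)
  dims <- dim(stat@tValues)
  S <- smooth@nMaskVoxels
  rows <- list()
  masks <- list()
  id <- 0L
  for (sgn in c(1, -1)) {
    if (sgn == -1 && !twoTailed) next
    supra <- (sgn * stat@tValues > tThresh) & stat@mask
    if (!any(supra)) next
    labels <- labelClusters(supra, connectivity)
    for (lab in seq_len(max(labels))) {
      vox <- which(labels == lab)
      k <- length(vox)
      p <- .grfClusterP(k, u, smooth@resels, S)
      if (p >= clusterP) next
      id <- id + 1L
      peak <- vox[which.max(sgn * stat@tValues[vox])]
      ijk <- drop(arrayInd(peak, dims))
      mm <- .gridToMm(ijk, dims, stat@voxelSizeMm)
      rows[[id]] <- data.frame(
        cluster_id = id, size_voxels = k,
        peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
        peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3],
        peak_t = stat@tValues[peak],
        sign = if (sgn > 0) "positive" else "negative",
        corrected_p = p, stringsAsFactors = FALSE)
      cm <- array(FALSE, dims)
      cm[vox] <- TRUE
      masks[[id]] <- cm
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    cluster_id = integer(), size_voxels = integer(), peak_i = integer(),
    peak_j = integer(), peak_k = integer(), peak_x_mm = numeric(),
    peak_y_mm = numeric(), peak_z_mm = numeric(), peak_t = numeric(),
    sign = character(), corrected_p = numeric(), stringsAsFactors = FALSE)
  attr(out, "masks") <- masks
  out
}

#' Site-coverage and motion filtering of a cohort
#'
#' Removes subjects failing motion QC, then all subjects from any site that
#' does not contain both groups (considering only QC survivors), mirroring
#' the study's site-coverage exclusion. The exclusion log (subject, reason
#' from \{motion, site-coverage\}) is attached as the `exclusions`
#' attribute.
#'
#' @param records data.frame with columns `subject_id`, `group`, `site` and
#'   optionally `qc_exclude` (logical motion-QC failure flag).
#' @return The surviving rows.
#' @export
matchFilterCohort <- function(records) {
  stopifnot(all(c("subject_id", "group", "site") %in% names(records)))
  excl <- data.frame(subject_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  keep <- records
  if ("qc_exclude" %in% names(records)) {
    bad <- records$qc_exclude
    if (any(bad))
      excl <- rbind(excl, data.frame(subject_id = records$subject_id[bad],
                                     reason = "motion",
                                     stringsAsFactors = FALSE))
    keep <- records[!bad, , drop = FALSE]
  }
  nGroups <- tapply(keep$group, keep$site, function(x) length(unique(x)))
  badSites <- names(nGroups)[nGroups < 2]
  if (length(badSites)) {
    drop <- keep$site %in% badSites
    excl <- rbind(excl, data.frame(subject_id = keep$subject_id[drop],
                                   reason = "site-coverage",
                                   stringsAsFactors = FALSE))
    keep <- keep[!drop, , drop = FALSE]
  }
  attr(keep, "exclusions") <- excl
  keep
}
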