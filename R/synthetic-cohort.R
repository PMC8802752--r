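#' Planted effect region
#'
#' Describes a spherical region of the grid carrying a group effect: an
#' `amplitude` region multiplies the low-frequency oscillation amplitude in
#' group 1 ("reverter") by `group_ratio`; a `synchrony` region couples its
#' voxels to one shared latent time course (more strongly in group 1); a
#' `hub` region couples its voxels to a latent course shared with many
#' distant "satellite" voxels, making it a connectivity hub.
#'
#' @param center length-3 integer voxel coordinate of the region center.
#' @param radius region radius in voxels (Euclidean ball, >= 1).
#' @param kind one of "amplitude", "synchrony", "hub".
#' @param group_ratio multiplicative effect in group 1 vs group 2 (> 0);
#'   e.g. 1.5 means 50\% stronger in group 1.
#' @return A list with the four fields, used inside [cohortSpec()].
#' @export
effectRegion <- function(center, radius, kind = c("amplitude", "synchrony", "hub"),
                         group_ratio = 1.5) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 3L, radius >= 1, group_ratio > 0)
  list(center = as.integer(center), radius = as.integer(radius),
       kind = kind, group_ratio = group_ratio)
}

#' Default two-site table
#'
#' Two acquisition sites with a small additive intensity offset and a
#' multiplicative noise-scale difference, giving the group GLM a genuine
#' site covariate to absorb.
#'
#' @return data.frame with columns site, offset, noise_scale.
#' @export
defaultSites <- function() {
  data.frame(site = c("siteA", "siteB"),
             offset = c(0, 25),
             noise_scale = c(1, 1.25),
             stringsAsFactors = FALSE)
}

#' Construct a synthetic cohort specification
#'
#' The default is a desk-scale cohort: 24^3 grid, 120 volumes at TR 3 s,
#' two sites, one amplitude effect region of ratio 1.5, baseline intensity
#' 1000 with oscillation amplitude 20 and noise SD 10. The acquisition
#' presets of the emulated protocols (TR 3.0 s / 197 volumes and TR 0.607 s /
#' 976 volumes) are available by overriding `trS`/`nVolumes`.
#'
#' @param nPerGroup subjects per group (>= 2).
#' @param gridShape length-3 voxel grid dimensions.
#' @param trS repetition time in seconds.
#' @param nVolumes number of time points (> 10).
#' @param sites site table as from [defaultSites()].
#' @param effects list of [effectRegion()] descriptions.
#' @param noiseSd baseline white-noise SD (site noise_scale multiplies it).
#' @param baselineMean mean BOLD intensity, arbitrary units (> 0).
#' @param ampTotal total in-band oscillation amplitude per voxel.
#' @param bandLowHz,bandHighHz band the planted oscillations populate (Hz).
#' @param voxelSizeMm voxel edge lengths in mm.
#' @param seed integer root seed; every random draw in the cohort flows from
#'   it through named substreams.
#' @return A validated [CohortSpec-class] object. A spec whose band upper
#'   edge reaches the Nyquist frequency `1/(2 trS)` is rejected.
#' @examples
#' spec <- cohortSpec(nPerGroup = 3, gridShape = c(12, 12, 12), nVolumes = 40)
#' spec
#' @export
cohortSpec <- function(nPerGroup = 12,
                       gridShape = c(24, 24, 24),
                       trS = 3.0,
                       nVolumes = 120,
                       sites = defaultSites(),
                       effects = list(effectRegion(round(gridShape / 2), 3,
                                                   "amplitude", 1.5)),
                       noiseSd = 10,
                       baselineMean = 1000,
                       ampTotal = 20,
                       bandLowHz = 0.01,
                       bandHighHz = 0.08,
                       voxelSizeMm = c(3, 3, 3),
                       seed = 1L) {
  new("CohortSpec", nPerGroup = nPerGroup, gridShape = as.integer(gridShape),
      trS = trS, nVolumes = as.integer(nVolumes), sites = sites,
      effects = effects, noiseSd = noiseSd, baselineMean = baselineMean,
      ampTotal = ampTotal, bandLowHz = bandLowHz, bandHighHz = bandHighHz,
      voxelSizeMm = voxelSizeMm, seed = as.integer(seed))
}

## Spherical region mask (Euclidean ball) on the grid.
.regionMask <- function(gridShape, center, radius) {
  d2 <- outer(outer((seq_len(gridShape[1]) - center[1])^2,
                    (seq_len(gridShape[2]) - center[2])^2, "+"),
              (seq_len(gridShape[3]) - center[3])^2, "+")
  array(d2 <= radius^2, dim = gridShape)
}

#' Tissue masks for a synthetic grid
#'
#' Brain mask: grid interior with a one-voxel border excluded. WM and CSF
#' masks: small cubic regions near opposite corners of the interior, stand-ins
#' for eroded tissue maps, used only to supply nuisance time courses.
#'
#' @param gridShape length-3 voxel grid dimensions.
#' @return list with logical arrays `brain`, `wm`, `csf`.
#' @export
makeTissueMasks <- function(gridShape) {
  g <- as.integer(gridShape)
  stopifnot(all(g >= 6L))
  brain <- array(FALSE, g)
  brain[2:(g[1] - 1), 2:(g[2] - 1), 2:(g[3] - 1)] <- TRUE
  box <- function(center, r) {
    m <- array(FALSE, g)
    lo <- pmax(2L, center - r); hi <- pmin(g - 1L, center + r)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  }
  wm <- box(pmax(2L, round(g / 4)), 1L)
  csf <- box(pmin(g - 1L, round(3 * g / 4)), 1L)
  list(brain = brain, wm = wm, csf = csf)
}

## Satellite voxels for a hub region: a deterministic subset of in-mask
## voxels at Chebyshev distance > 2*radius from the hub center, shared by
## every subject of the cohort (seeded from the spec's root seed).
.hubSatellites <- function(spec, brain, effIndex) {
  eff <- spec@effects[[effIndex]]
  coords <- .maskCoords(brain)
  cheb <- pmax(abs(coords[, 1] - eff$center[1]),
               abs(coords[, 2] - eff$center[2]),
               abs(coords[, 3] - eff$center[3]))
  candidates <- which(cheb > 2 * eff$radius)
  nSat <- max(10L, round(0.15 * length(candidates)))
  set.seed(substreamSeed(spec@seed, "satellites", effIndex))
  sort(sample(candidates, min(nSat, length(candidates))))
}

#' Generate one subject's synthetic BOLD series
#'
#' The signal model is `baseline + site offset + oscillation + noise`: each
#' voxel carries 3-8 in-band sinusoids whose frequencies are drawn uniformly
#' in the band and snapped to DFT bins of the series (one shared frequency
#' set per subject), with voxel-specific random phases and random weights
#' normalised so the total amplitude is `ampTotal`. Bin alignment makes the
#' in-band spectral amplitude of a noiseless voxel exactly proportional to
#' its planted multiplier. Effect regions then modify the oscillation:
#' amplitude regions scale it, synchrony regions mix in one shared latent
#' course, hub regions mix in a latent course shared with distant satellite
#' voxels. White Gaussian noise (site-scaled) is added last.
#'
#' @param spec a [CohortSpec-class].
#' @param group group label; the planted `group_ratio` applies when the
#'   label equals "reverter".
#' @param site site label, must appear in `spec@sites`.
#' @param seed integer seed for this subject; the same (spec, group, site,
#'   seed) always produces bit-identical data.
#' @return list with elements `bold` ([BoldSeries-class]), `wmMask`,
#'   `csfMask` (3D logical arrays).
#' @export
generateBoldSubject <- function(spec, group, site, seed) {
  validObject(spec)
  siteRow <- match(site, spec@sites$site)
  if (is.na(siteRow)) stop("unknown site: ", site)
  masks <- makeTissueMasks(spec@gridShape)
  brain <- masks$brain
  V <- sum(brain)
  n <- spec@nVolumes
  tr <- spec@trS
  tt <- seq_len(n) - 1L

  ## in-band DFT bins of the full series
  kAll <- seq_len(floor(n / 2))
  freqAll <- kAll / (n * tr)
  kBand <- kAll[freqAll >= spec@bandLowHz & freqAll <= spec@bandHighHz]
  if (!length(kBand))
    stop("no DFT bin falls inside the requested band; series too short")

  set.seed(substreamSeed(seed, "bold"))
  nFreq <- sample(3:8, 1L)
  nFreq <- min(nFreq, length(kBand))
  bins <- sort(sample(kBand, nFreq))
  freqs <- bins / (n * tr)

  ## basis: cos/sin at each selected frequency
  ang <- outer(tt * (2 * pi / n), bins)         # n x nFreq
  C <- cos(ang); S <- sin(ang)

  ## per-voxel weights (sum to ampTotal) and phases
  w <- matrix(stats::runif(nFreq * V), nFreq, V)
  w <- sweep(w, 2, colSums(w), "/") * spec@ampTotal
  phi <- matrix(stats::runif(nFreq * V, 0, 2 * pi), nFreq, V)
  ## a*cos(ang + phi) = a*cos(phi)*cos(ang) - a*sin(phi)*sin(ang)
  osc <- C %*% (w * cos(phi)) - S %*% (w * sin(phi))

  ## latent courses per effect region (shared phases, equal weights)
  maskIdx <- which(brain)
  isGroup1 <- identical(group, "reverter")
  for (e in seq_along(spec@effects)) {
    eff <- spec@effects[[e]]
    regionCols <- match(which(.regionMask(spec@gridShape, eff$center,
                                          eff$radius) & brain), maskIdx)
    regionCols <- regionCols[!is.na(regionCols)]
    if (!length(regionCols)) next
    r <- if (isGroup1) eff$group_ratio else 1
    if (eff$kind == "amplitude") {
      osc[, regionCols] <- osc[, regionCols] * r
    } else {
      latPhi <- stats::runif(nFreq, 0, 2 * pi)
      lat <- C %*% ((spec@ampTotal / nFreq) * cos(latPhi)) -
             S %*% ((spec@ampTotal / nFreq) * sin(latPhi))
      lat <- as.numeric(lat)
      if (eff$kind == "synchrony") {
        lam <- min(0.95, 0.55 * r)
        osc[, regionCols] <- (1 - lam) * osc[, regionCols] +
          lam * matrix(lat, n, length(regionCols))
      } else {  # hub
        kap <- min(0.95, 0.6 * r)
        sat <- .hubSatellites(spec, brain, e)
        sat <- setdiff(sat, regionCols)
        osc[, sat] <- 0.6 * osc[, sat] + 0.4 * matrix(lat, n, length(sat))
        osc[, regionCols] <- (1 - kap) * osc[, regionCols] +
          kap * matrix(lat, n, length(regionCols))
      }
    }
  }

  sd <- spec@noiseSd * spec@sites$noise_scale[siteRow]
  noise <- if (sd > 0) matrix(stats::rnorm(n * V, 0, sd), n, V) else 0
  data <- spec@baselineMean + spec@sites$offset[siteRow] + osc + noise

  bold <- .newBoldSeries(data, brain, tr, spec@voxelSizeMm)
  list(bold = bold, wmMask = masks$wm, csfMask = masks$csf)
}

#' Generate a random-walk head-motion trace
#'
#' Six rigid-body parameters evolve as independent Gaussian random walks
#' starting at zero; `severity` scales the per-step SD (0.02 mm for
#' translations, 0.0004 rad for rotations at severity 1). `severity = 0`
#' yields an exactly all-zero trace.
#'
#' @param nVolumes number of volumes (>= 2).
#' @param severity nonnegative scale of the walk.
#' @param seed integer seed.
#' @return A [MotionTrace-class].
#' @export
generateMotionTrace <- function(nVolumes, severity = 1, seed = 1L) {
  stopifnot(nVolumes >= 2, severity >= 0)
  set.seed(substreamSeed(seed, "motion"))
  stepSd <- severity * c(rep(0.02, 3), rep(4e-4, 3))
  params <- vapply(stepSd, function(s) {
    cumsum(c(0, stats::rnorm(nVolumes - 1L, 0, s)))
  }, numeric(nVolumes))
  motionTrace(params)
}

#' Generate a full two-group synthetic cohort
#'
#' Produces `2 * nPerGroup` subjects ("reverter" and "control" groups)
#' distributed round-robin over the spec's sites (so every site contains
#' both groups whenever `nPerGroup >=` number of sites), each with BOLD
#' data, tissue masks, a motion trace, and a covariate row (demographics,
#' LM/MMSE visit scores, mean FD). Optionally writes NIfTI volumes, SPM-style
#' motion text files and the covariate CSV to `outDir`.
#'
#' @param spec a [CohortSpec-class].
#' @param motionSeverity severity passed to [generateMotionTrace()].
#' @param siteAssignment optional character vector (length `2 * nPerGroup`,
#'   subject order: all reverter-like then all control) overriding the
#'   round-robin site assignment, e.g. to force a one-group site for
#'   testing the site-coverage filter.
#' @param outDir optional directory to write files into.
#' @return list with `subjects` (list of per-subject lists: id, group, site,
#'   bold, motion, wmMask, csfMask) and `covariates` (data.frame, one row
#'   per subject).
#' @export
generateCohort <- function(spec, motionSeverity = 0.5, siteAssignment = NULL,
                           outDir = NULL) {
  validObject(spec)
  groups <- rep(c("reverter", "control"), each = spec@nPerGroup)
  nTot <- length(groups)
  siteNames <- spec@sites$site
  sites <- if (is.null(siteAssignment)) {
    siteNames[((seq_len(spec@nPerGroup) - 1L) %% length(siteNames)) + 1L][
      rep(seq_len(spec@nPerGroup), 2L)]
  } else {
    stopifnot(length(siteAssignment) == nTot)
    siteAssignment
  }
  ids <- sprintf("S%03d", seq_len(nTot))

  set.seed(substreamSeed(spec@seed, "covariates"))
  age <- round(stats::rnorm(nTot, 74, 7), 1)
  sex <- sample(c("M", "F"), nTot, replace = TRUE)
  edu <- round(stats::rnorm(nTot, 16.7, 2.4), 1)
  isRev <- groups == "reverter"
  lmV1 <- ifelse(isRev, sample(3:8, nTot, TRUE), sample(12:18, nTot, TRUE))
  lmV2 <- sample(12:18, nTot, TRUE)
  mmseV1 <- ifelse(isRev, sample(24:28, nTot, TRUE), sample(28:30, nTot, TRUE))
  mmseV2 <- sample(26:30, nTot, TRUE)

  subjects <- vector("list", nTot)
  meanFd <- numeric(nTot)
  for (i in seq_len(nTot)) {
    sub <- generateBoldSubject(spec, groups[i], sites[i],
                               substreamSeed(spec@seed, "subject", i))
    motion <- generateMotionTrace(spec@nVolumes, motionSeverity,
                                  substreamSeed(spec@seed, "motionsub", i))
    meanFd[i] <- framewiseDisplacement(motion)$meanFd
    subjects[[i]] <- list(id = ids[i], group = groups[i], site = sites[i],
                          bold = sub$bold, motion = motion,
                          wmMask = sub$wmMask, csfMask = sub$csfMask)
  }
  covariates <- data.frame(
    subject_id = ids, group = groups, site = sites, age = age, sex = sex,
    education_years = edu, lm_v1 = lmV1, lm_v2 = lmV2,
    mmse_v1 = mmseV1, mmse_v2 = mmseV2, mean_fd = meanFd,
    stringsAsFactors = FALSE)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (s in subjects) {
      writeBoldNifti(s$bold, file.path(outDir, paste0(s$id, "_bold.nii.gz")))
      writeMaskNifti(s$bold@mask, s$bold@voxelSizeMm,
                     file.path(outDir, paste0(s$id, "_brainmask.nii.gz")))
      writeMotionFile(s$motion, file.path(outDir, paste0("rp_", s$id, ".txt")))
    }
    utils::write.csv(covariates, file.path(outDir, "covariates.csv"),
                     row.names = FALSE)
  }
  list(subjects = subjects, covariates = covariates)
}

#' Per-subject planted effect magnitudes
#'
#' The realized multiplier each subject carries in a given effect region:
#' `group_ratio` for the "reverter" group, 1 for controls.
#'
#' @param spec a [CohortSpec-class].
#' @param groups character vector of group labels (one per subject).
#' @param effIndex which effect region (default first).
#' @return numeric vector of multipliers.
#' @export
plantedMagnitudes <- function(spec, groups, effIndex = 1L) {
  eff <- spec@effects[[effIndex]]
  ifelse(groups == "reverter", eff$group_ratio, 1)
}

#' Generate behavioral scores linearly tied to an effect magnitude
#'
#' Scores are `intercept + slope * magnitude + noise`. Passing each
#' subject's measured region-mean metric as `magnitude` with `noiseSd = 0`
#' produces a score whose partial correlation with that metric is exactly 1;
#' passing [plantedMagnitudes()] ties the score to the ground-truth effect
#' instead.
#'
#' @param magnitude per-subject effect magnitude (numeric vector).
#' @param slope,intercept linear coefficients.
#' @param noiseSd SD of additive Gaussian score noise.
#' @param seed integer seed (deterministic per seed).
#' @return numeric vector of scores, same length and names as `magnitude`.
#' @export
generateBehavioralScores <- function(magnitude, slope = 1, intercept = 0,
                                     noiseSd = 0, seed = 1L) {
  set.seed(substreamSeed(seed, "scores"))
  out <- intercept + slope * magnitude +
    if (noiseSd > 0) stats::rnorm(length(magnitude), 0, noiseSd) else 0
  names(out) <- names(magnitude)
  out
}
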