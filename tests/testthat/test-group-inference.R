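## covariate table for n1 + n2 subjects over the given sites
makeCovariates <- function(n1, n2, sites = c("siteA", "siteB"), seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("reverter", "control"), c(n1, n2)),
    mean_fd = runif(n, 0.02, 0.2),
    site = sites[((seq_len(n) - 1L) %% length(sites)) + 1L],
    stringsAsFactors = FALSE)
}

## subject metric maps from a matrix of values (subjects x voxels)
mapsFromMatrix <- function(Y, gridShape) {
  mask <- array(TRUE, gridShape)
  lapply(seq_len(nrow(Y)), function(i)
    new("MetricMap", values = array(Y[i, ], gridShape), metric = "ALFF",
        mask = mask, voxelSizeMm = c(3, 3, 3), standardized = TRUE,
        smoothed = TRUE))
}

test_that("design matrix has intercept, group, FD and k-1 site dummies", {
  cov <- makeCovariates(5, 5)
  d <- buildDesignMatrix(cov)
  expect_equal(dim(d$design), c(10, 4))
  expect_equal(colnames(d$design), c("intercept", "group", "mean_fd", "site_siteB"))
  expect_equal(sum(d$design[, "group"]), 5)
  expect_equal(unname(d$contrast), c(0, 1, 0, 0))
  ## centered continuous covariate
  expect_equal(mean(d$design[, "mean_fd"]), 0)

  one <- makeCovariates(4, 4, sites = "siteA")
  expect_equal(colnames(buildDesignMatrix(one)$design),
               c("intercept", "group", "mean_fd"))

  lop <- makeCovariates(4, 4)
  lop$site <- rep(c("siteA", "siteB"), c(4, 4))  # siteA all reverter
  expect_error(buildDesignMatrix(lop), "matchFilterCohort")
  expect_error(buildDesignMatrix(makeCovariates(1, 5)), "2 subjects per group")
})

test_that("GLM t equals the pooled two-sample t when covariates are orthogonal to group", {
  set.seed(2)
  n1 <- 6; n2 <- 6
  cov <- makeCovariates(n1, n2, sites = "siteA")
  ## balance mean FD exactly across groups so it is orthogonal to the contrast
  fd <- runif(n1)
  cov$mean_fd <- c(fd, fd)
  Y <- matrix(rnorm(12 * 27), 12, 27)
  ## make FD genuinely uninformative
  d <- buildDesignMatrix(cov)
  d$design[, "mean_fd"] <- 0
  d$design <- d$design[, c("intercept", "group"), drop = FALSE]
  d$contrast <- c(0, 1)
  stat <- glmTwoSampleT(mapsFromMatrix(Y, c(3, 3, 3)), d)
  for (j in c(1, 14, 27)) {
    tt <- pooledTwoSampleT(Y[1:n1, j], Y[n1 + 1:n2, j])
    expect_equal(as.numeric(stat@tValues)[j], tt$t, tolerance = 1e-8)
  }
  expect_equal(stat@df, 10)

  ## identical maps in both groups -> t = 0 everywhere
  Yc <- rbind(Y[1:6, ], Y[1:6, ])
  stat0 <- glmTwoSampleT(mapsFromMatrix(Yc, c(3, 3, 3)), d)
  expect_equal(max(abs(stat0@tValues)), 0)
})

test_that("t maps are invariant to permuting subjects with their design rows", {
  set.seed(3)
  cov <- makeCovariates(5, 6)
  Y <- matrix(rnorm(11 * 8), 11, 8)
  d <- buildDesignMatrix(cov)
  s1 <- glmTwoSampleT(mapsFromMatrix(Y, c(2, 2, 2)), d)
  perm <- sample(11)
  d2 <- buildDesignMatrix(cov[perm, ])
  s2 <- glmTwoSampleT(mapsFromMatrix(Y[perm, ], c(2, 2, 2)), d2)
  expect_equal(s1@tValues, s2@tValues, tolerance = 1e-10)

  ## site relabeling does not change the t map
  cov3 <- cov
  cov3$site <- c(siteA = "Z9", siteB = "A1")[cov$site]
  s3 <- glmTwoSampleT(mapsFromMatrix(Y, c(2, 2, 2)), buildDesignMatrix(cov3))
  expect_equal(s1@tValues, s3@tValues, tolerance = 1e-10)
})

test_that("smoothness estimation recovers a known kernel and respects units", {
  set.seed(5)
  g <- c(48, 48, 48); nVol <- 20
  mask <- array(TRUE, g)
  ## white noise smoothed with a known 6 mm FWHM kernel (3 mm voxels)
  resid <- matrix(0, nVol, prod(g))
  for (i in seq_len(nVol)) {
    m <- new("MetricMap", values = array(rnorm(prod(g)), g), metric = "ALFF",
             mask = mask, voxelSizeMm = c(3, 3, 3), standardized = FALSE,
             smoothed = FALSE)
    resid[i, ] <- as.numeric(metricValues(gaussianSmooth(m, 6)))
  }
  est <- estimateSmoothness(resid, mask, c(3, 3, 3))
  expect_true(all(abs(est@fwhmMm - 6) / 6 < 0.2))

  ## doubling the voxel size doubles FWHM in mm, resels unchanged
  est2 <- estimateSmoothness(resid, mask, c(6, 6, 6))
  expect_equal(est2@fwhmMm, 2 * est@fwhmMm)
  expect_equal(est2@resels, est@resels)

  ## unsmoothed white noise: FWHM on the voxel scale, above half a voxel
  raw <- matrix(rnorm(nVol * 16^3), nVol, 16^3)
  est3 <- estimateSmoothness(raw, array(TRUE, c(16, 16, 16)), c(3, 3, 3))
  expect_true(all(est3@fwhmMm > 1.5 & est3@fwhmMm < 6))

  expect_error(estimateSmoothness(matrix(0, 5, 8), array(TRUE, c(2, 2, 2)),
                                  c(3, 3, 3)), "constant")
})

test_that("cluster labelling respects the chosen connectivity", {
  a <- array(FALSE, c(4, 4, 4))
  a[1, 1, 1] <- TRUE; a[2, 2, 2] <- TRUE   # diagonal neighbours
  a[4, 4, 4] <- TRUE
  l26 <- labelClusters(a, 26)
  expect_equal(l26[1, 1, 1], l26[2, 2, 2])
  expect_false(l26[4, 4, 4] == l26[1, 1, 1])
  expect_equal(max(l26), 2)
  l6 <- labelClusters(a, 6)
  expect_equal(max(l6), 3)                 # diagonal pair splits under 6-conn
})

test_that("GRF inference returns an empty table on a null map and finds a planted cluster", {
  g <- c(12, 12, 12)
  mask <- array(TRUE, g)
  zeroStat <- new("StatMap", tValues = array(0, g), df = 20,
                  residuals = matrix(rnorm(22 * prod(g)), 22), mask = mask,
                  voxelSizeMm = c(3, 3, 3))
  sm <- estimateSmoothness(zeroStat)
  tab <- grfClusterInference(zeroStat, sm)
  expect_equal(nrow(tab), 0)

  ## single coherent planted effect, noiseless cohort -> exactly one positive
  ## cluster covering the planted region
  spec <- cohortSpec(
    nPerGroup = 5, gridShape = c(14, 14, 14), nVolumes = 60, noiseSd = 2,
    sites = data.frame(site = "siteA", offset = 0, noise_scale = 1),
    effects = list(effectRegion(c(7, 7, 7), 3, "amplitude", 2.5)), seed = 31)
  co <- generateCohort(spec, motionSeverity = 0.2)
  preps <- lapply(co$subjects, function(s) suppressMessages(preprocessSubject(s)))
  maps <- lapply(preps, function(p)
    gaussianSmooth(standardizeByGlobalMean(computeALFF(p$unfiltered)), 4))
  cov <- co$covariates
  cov$mean_fd <- vapply(preps, function(p) p$fd$meanFd, numeric(1))
  stat <- glmTwoSampleT(maps, buildDesignMatrix(cov))
  tab2 <- grfClusterInference(stat, estimateSmoothness(stat))
  expect_equal(sum(tab2$sign == "positive"), 1)
  cm <- attr(tab2, "masks")[[which(tab2$sign == "positive")]]
  planted <- restiba:::.regionMask(spec@gridShape, c(7, 7, 7), 3) &
    brainMask(preps[[1]]$filtered)
  expect_gt(sum(cm & planted) / sum(planted), 0.5)
  ## peak mm coordinates follow the centered affine
  expect_true(all(abs(tab2[, c("peak_x_mm", "peak_y_mm", "peak_z_mm")]) <=
                    (14 - 1) / 2 * 3))
  expect_true(all(tab2$corrected_p > 0 & tab2$corrected_p < 0.05))
})

test_that("site/motion cohort filtering reproduces hand-computed survivors", {
  rec <- data.frame(
    subject_id = sprintf("S%d", 1:8),
    group = c("reverter", "reverter", "control", "control",
              "reverter", "control", "reverter", "control"),
    site = c("A", "A", "A", "A", "B", "A", "B", "B"),
    qc_exclude = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  ## S3 fails QC; site B has 2 reverters + 1 control -> balanced, stays;
  ## make it one-group instead:
  rec$group[8] <- "reverter"
  kept <- matchFilterCohort(rec)
  expect_equal(kept$subject_id, c("S1", "S2", "S4", "S6"))
  excl <- attr(kept, "exclusions")
  expect_equal(excl$reason[excl$subject_id == "S3"], "motion")
  expect_equal(sort(excl$subject_id[excl$reason == "site-coverage"]),
               c("S5", "S7", "S8"))

  balanced <- rec[rec$site == "A" & !rec$qc_exclude, ]
  expect_equal(matchFilterCohort(balanced)$subject_id, balanced$subject_id)
})
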