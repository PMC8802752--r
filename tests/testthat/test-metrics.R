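test_that("all five metrics match naive per-voxel oracles on a seeded volume", {
  g <- c(6, 6, 6); n <- 40; tr <- 3
  unf <- randomSeries(g, n, tr, seed = 42, flags = unfilteredFlags)
  fil <- idealBandpass(unf, 0.01, 0.08)
  fil@origMean <- rep(100, nVoxels(fil))   # raw-scale means for PerAF

  alff <- metricValues(computeALFF(unf))[unf@mask]
  falff <- metricValues(computeFALFF(unf))[unf@mask]
  for (j in c(1, 57, 216)) {
    expect_lt(abs(alff[j] - oracleALFF(unf@data[, j], tr)), 1e-8)
    expect_lt(abs(falff[j] - oracleFALFF(unf@data[, j], tr)), 1e-8)
  }

  peraf <- metricValues(computePerAF(fil))[fil@mask]
  orcPeraf <- apply(fil@data + 100, 2, oraclePerAF)
  expect_lt(max(abs(peraf - orcPeraf)), 1e-8)

  reho <- metricValues(computeReHo(fil, 27))[fil@mask]
  expect_lt(max(abs(reho - oracleReHo(fil@data, fil@mask, 27))), 1e-10)
  reho19 <- metricValues(computeReHo(fil, 19))[fil@mask]
  expect_lt(max(abs(reho19 - oracleReHo(fil@data, fil@mask, 19))), 1e-10)

  dc <- metricValues(computeDC(fil, 0.25))[fil@mask]
  expect_lt(max(abs(dc - oracleDC(fil@data, 0.25))), 1e-10)
  dcw <- metricValues(computeDC(fil, 0.25, "weighted"))[fil@mask]
  expect_lt(max(abs(dcw - oracleDC(fil@data, 0.25, "weighted"))), 1e-10)
})

test_that("DC results are independent of the block size", {
  fil <- randomSeries(c(5, 5, 4), 30, 3, seed = 5)
  full <- metricValues(computeDC(fil, 0.25, blockSize = 4096L))
  for (bs in c(7L, 32L)) {
    expect_equal(metricValues(computeDC(fil, 0.25, blockSize = bs)), full)
  }
})

test_that("ALFF scales linearly and vanishes for constant series", {
  n <- 60
  x <- sinusoid(0.05, n, 3) + sinusoid(0.02, n, 3, amp = 0.5)
  s <- makeSeries(cbind(rep(5, n), x, 2 * x), flags = unfilteredFlags)
  alff <- metricValues(computeALFF(s))[s@mask]
  expect_equal(alff[1], 0)
  expect_equal(alff[3], 2 * alff[2], tolerance = 1e-10)
  expect_lt(abs(alff[2] - oracleALFF(x, 3)), 1e-8)
})

test_that("fALFF closed-form identities hold", {
  n <- 120; tr <- 3
  inband <- sinusoid(18 / (n * tr), n, tr) + sinusoid(25 / (n * tr), n, tr, amp = 2)
  outband <- sinusoid(45 / (n * tr), n, tr)     # 0.125 Hz
  pair <- sinusoid(18 / (n * tr), n, tr) + sinusoid(45 / (n * tr), n, tr)
  s <- makeSeries(cbind(inband, outband, pair), trS = tr,
                  flags = unfilteredFlags)
  falff <- metricValues(computeFALFF(s))[s@mask]
  expect_equal(falff[1], 1, tolerance = 1e-8)        # all power in band
  expect_lt(falff[2], 1e-8)                          # none in band
  expect_equal(falff[3], 0.5, tolerance = 1e-6)      # equal split
})

test_that("ALFF and fALFF reject band-passed input", {
  fil <- randomSeries(c(4, 4, 2), 30, 3, seed = 2, flags = allFlags)
  expect_error(computeALFF(fil), "unfiltered")
  expect_error(computeFALFF(fil), "unfiltered")
  unf <- randomSeries(c(4, 4, 2), 30, 3, seed = 2, flags = unfilteredFlags)
  expect_error(computeReHo(unf), "filtered")
  expect_error(computeDC(unf), "filtered")
  expect_error(computePerAF(unf), "filtered")
})

test_that("PerAF matches the printed formula and is scale invariant", {
  expect_equal(perafSeries(c(90, 110)), 10)
  expect_equal(perafSeries(rep(7, 10)), 0)
  set.seed(3)
  x <- rnorm(50, mean = 100, sd = 5)
  expect_equal(perafSeries(3 * x), perafSeries(x), tolerance = 1e-12)

  ## computePerAF restores the stored raw-scale mean before the formula
  xc <- x - mean(x)
  s <- makeSeries(cbind(xc), flags = allFlags, origMean = mean(x))
  expect_equal(metricValues(computePerAF(s))[1], oraclePerAF(x),
               tolerance = 1e-10)

  ## non-positive mean -> 0, logged
  s2 <- makeSeries(cbind(xc, xc), flags = allFlags, origMean = c(-5, mean(x)))
  expect_message(out <- computePerAF(s2), "non-positive")
  expect_equal(metricValues(out)[1], 0)
  expect_equal(attr(out, "nNonpositiveMean"), 1)
})

test_that("ReHo closed-form identities hold", {
  ## 27 identical strictly monotone series -> W = 1 at the interior voxel
  g <- c(3, 3, 3); n <- 12
  mono <- seq_len(n) + 0.3 * sin(seq_len(n))
  s <- makeSeries(matrix(mono, n, 27), mask = array(TRUE, g), flags = allFlags)
  W <- metricValues(computeReHo(s, 27))
  expect_equal(W[2, 2, 2], 1, tolerance = 1e-12)

  ## K = 2 with opposite ranks -> W = 0 (hand evaluation: R_i all equal)
  expect_equal(oracleKCC(cbind(c(1, 2, 3), c(3, 2, 1))), 0)
  m2 <- makeSeries(cbind(c(1, 2, 3), c(3, 2, 1)), mask = array(TRUE, c(2, 1, 1)),
                   flags = allFlags)
  W2 <- metricValues(computeReHo(m2, 27))   # edge rule: only 2 members each
  expect_equal(unname(W2[, 1, 1]), c(0, 0))
})

test_that("DC identities: shared-course voxels count each other, orthogonal voxels do not", {
  n <- 30
  set.seed(8)
  shared <- rnorm(n)
  orth <- residuals(lm(rnorm(n) ~ shared))
  data <- cbind(shared, shared * 2 + 1e-8 * rnorm(n), shared + 1e-8 * rnorm(n), orth)
  s <- makeSeries(data, mask = array(TRUE, c(4, 1, 1)), flags = allFlags)
  dc <- as.numeric(metricValues(computeDC(s, 0.25)))
  expect_equal(dc, c(2, 2, 2, 0))

  ## identical voxels: DC = n - 1 everywhere
  s2 <- makeSeries(matrix(shared, n, 8), mask = array(TRUE, c(2, 2, 2)),
                   flags = allFlags)
  expect_equal(as.numeric(metricValues(computeDC(s2, 0.25))), rep(7, 8))

  ## near-unattainable threshold on independent noise
  s3 <- randomSeries(c(4, 4, 2), 40, seed = 10)
  expect_equal(sum(metricValues(computeDC(s3, 0.9999))), 0)

  ## zero-variance voxel never counted
  s4 <- makeSeries(cbind(shared, shared, rep(1, n)),
                   mask = array(TRUE, c(3, 1, 1)), flags = allFlags)
  expect_message(dc4 <- computeDC(s4, 0.25), "zero-variance")
  expect_equal(as.numeric(metricValues(dc4)), c(1, 1, 0))
})

test_that("global-mean standardization divides by the in-mask mean", {
  mask <- array(FALSE, c(3, 1, 1)); mask[1:3, 1, 1] <- TRUE
  vals <- array(c(1, 2, 3), c(3, 1, 1))
  m <- new("MetricMap", values = vals, metric = "ALFF", mask = mask,
           voxelSizeMm = c(3, 3, 3), standardized = FALSE, smoothed = FALSE)
  out <- standardizeByGlobalMean(m)
  expect_equal(as.numeric(metricValues(out)), c(0.5, 1, 1.5))
  expect_equal(mean(metricValues(out)[mask]), 1)
  expect_true(out@standardized)
  ## idempotent under division mode; constant map -> all ones
  expect_equal(metricValues(standardizeByGlobalMean(out)), metricValues(out))
  mc <- m; mc@values[] <- 4
  expect_equal(as.numeric(metricValues(standardizeByGlobalMean(mc))), rep(1, 3))
  ## z mode: in-mask mean 0, SD 1
  z <- standardizeByGlobalMean(m, "z")
  expect_equal(mean(metricValues(z)[mask]), 0)
  expect_equal(sd(metricValues(z)[mask]), 1)
  expect_error(standardizeByGlobalMean(new("MetricMap",
    values = array(0, c(3, 1, 1)), metric = "ALFF", mask = mask,
    voxelSizeMm = c(3, 3, 3), standardized = FALSE, smoothed = FALSE)), "zero")
})

test_that("Gaussian smoothing conserves an interior impulse and matches the closed form", {
  g <- c(15, 15, 15)
  mask <- array(TRUE, g)
  vals <- array(0, g); vals[8, 8, 8] <- 1
  m <- new("MetricMap", values = vals, metric = "ALFF", mask = mask,
           voxelSizeMm = c(3, 3, 3), standardized = FALSE, smoothed = FALSE)
  sm <- gaussianSmooth(m, 4)
  expect_equal(sum(metricValues(sm)), 1, tolerance = 1e-6)   # unit kernel sum
  sigma <- 4 / (3 * 2 * sqrt(2 * log(2)))
  expect_equal(sigma, 0.566, tolerance = 0.001)
  ## impulse response along an axis matches the normalised closed-form kernel
  r <- 2
  prof <- metricValues(sm)[(8 - r):(8 + r), 8, 8]
  centre <- metricValues(sm)[8, 8, 8]
  expect_equal(prof / centre, dnorm(-r:r, sd = sigma) / dnorm(0, sd = sigma),
               tolerance = 0.02)

  expect_error(gaussianSmooth(sm, 4), "already smoothed")
  m0 <- gaussianSmooth(m, 0)
  expect_equal(metricValues(m0), vals)
  expect_true(m0@smoothed)
})

test_that("planted effects land in the right tail of their metric", {
  spec <- cohortSpec(
    nPerGroup = 2, gridShape = c(14, 14, 14), nVolumes = 60, noiseSd = 0,
    sites = data.frame(site = "siteA", offset = 0, noise_scale = 1),
    effects = list(effectRegion(c(5, 5, 5), 2, "amplitude", 2),
                   effectRegion(c(10, 10, 5), 2, "synchrony", 1.6),
                   effectRegion(c(7, 7, 11), 2, "hub", 1.5)),
    seed = 21)
  sub <- generateBoldSubject(spec, "reverter", "siteA", 4)
  sub$motion <- generateMotionTrace(60, 0, 4)
  prep <- suppressMessages(preprocessSubject(sub, preprocConfig()))
  mask <- brainMask(prep$filtered)

  regionIdx <- function(i) {
    eff <- spec@effects[[i]]
    which(restiba:::.regionMask(spec@gridShape, eff$center, eff$radius)[mask])
  }
  topShare <- function(vals, idx, q = 0.95) {
    mean(vals[idx] > quantile(vals, q))
  }
  alff <- metricValues(computeALFF(prep$unfiltered))[mask]
  expect_gt(mean(alff[regionIdx(1)]) / mean(alff[-regionIdx(1)]), 1.8)

  reho <- metricValues(computeReHo(prep$filtered))[mask]
  expect_gt(mean(reho[regionIdx(2)]), quantile(reho[-regionIdx(2)], 0.95))

  dc <- metricValues(computeDC(prep$filtered))[mask]
  expect_gt(mean(dc[regionIdx(3)]), quantile(dc[-regionIdx(3)], 0.95))
})

test_that("computeAllMetrics yields both PerAF branches with consistent states", {
  spec <- cohortSpec(nPerGroup = 2, gridShape = c(10, 10, 10), nVolumes = 40,
                     noiseSd = 5, seed = 12)
  sub <- generateBoldSubject(spec, "control", "siteA", 6)
  sub$motion <- generateMotionTrace(40, 0.5, 6)
  prep <- suppressMessages(preprocessSubject(sub))
  ms <- suppressMessages(computeAllMetrics(prep))
  expect_setequal(names(ms), c("ALFF", "fALFF", "PerAF", "ReHo", "DC", "PerAF_unstd"))
  for (nm in c("ALFF", "fALFF", "PerAF", "ReHo", "DC")) {
    expect_true(ms[[nm]]@standardized)
    expect_true(ms[[nm]]@smoothed)
  }
  expect_false(ms$PerAF_unstd@standardized)
  expect_true(ms$PerAF_unstd@smoothed)
  ## the unstandardized branch is the standardized one times the global mean
  mask <- ms$PerAF@mask
  ratio <- ms$PerAF_unstd@values[mask] / ms$PerAF@values[mask]
  expect_lt(diff(range(ratio)), 1e-8)
})
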