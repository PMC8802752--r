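#' Pooled-variance two-sample t test
#'
#' Classic pooled t with `df = n1 + n2 - 2` and a two-tailed p, accepting
#' either raw value vectors or `(n, mean, sd)` summary statistics (as
#' printed in demographic tables). With zero pooled variance the t is 0 /
#' p = 1 for equal means and +-Inf / p = 0 for unequal means.
#'
#' @param x,y numeric vectors of raw values, or named numeric vectors
#'   `c(n = , mean = , sd = )`.
#' @return list with `t`, `df`, `p`.
#' @examples
#' pooledTwoSampleT(c(n = 32, mean = 75.38, sd = 7.91),
#'                  c(n = 37, mean = 73.38, sd = 7.00))
#' @export
pooledTwoSampleT <- function(x, y) {
  summ <- function(v) {
    if (!is.null(names(v)) && all(c("n", "mean", "sd") %in% names(v)))
      list(n = v[["n"]], mean = v[["mean"]], sd = v[["sd"]])
    else list(n = length(v), mean = mean(v), sd = stats::sd(v))
  }
  a <- summ(x); b <- summ(y)
  if (a$n < 2 || b$n < 2) stop("need at least 2 observations per group")
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  tstat <- if (se > 0) (a$mean - b$mean) / se
           else if (a$mean == b$mean) 0 else sign(a$mean - b$mean) * Inf
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Pearson chi-square test of independence (2 x 2)
#'
#' Without Yates continuity correction, df = 1 (the convention that
#' reproduces printed sex-distribution p values from count tables).
#'
#' @param counts 2 x 2 numeric matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chiSquareIndependence <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal total")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop("expected counts must be positive")
  res <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Partial correlation by residualization
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on the covariates
#' (factors expanded to dummy columns); with no covariates this is the plain
#' Pearson correlation. The p value uses the t transform with
#' `df = n - 2 - #covariate columns`.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame or matrix of covariates.
#' @return list with `r`, `df`, `p` (`r = NA` with a warning when a
#'   residual is constant).
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    Z <- matrix(1, n, 1)
    nc <- 0L
  } else {
    covariates <- as.data.frame(covariates)
    Z <- stats::model.matrix(~ ., data = covariates)
    nc <- ncol(Z) - 1L
  }
  if (n <= nc + 2) stop("need n > #covariates + 2 observations")
  qz <- qr(Z)
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  tol <- function(v, r) stats::sd(r) <= 1e-12 * max(1, abs(mean(v)), stats::sd(v))
  if (tol(x, rx) || tol(y, ry)) {
    warning("constant residual; partial correlation undefined")
    return(list(r = NA_real_, df = n - 2L - nc, p = NA_real_))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - nc
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.xmin))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure; returns the monotone adjusted p values and the
#' rejection set at level `q`.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `adjusted` (same order as `p`) and `reject` (logical).
#' @export
bhFdr <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Classify an MCI-to-normal reverter from score trajectories
#'
#' A subject is a reverter iff the first-visit logical-memory (LM) score is
#' below the normal cutoff (MCI range) and some later visit has LM at or
#' above the cutoff with MMSE strictly greater than 24 at that same visit.
#' The earliest qualifying visit is returned. Visits with a missing LM or
#' MMSE score are skipped (and counted in `skippedVisits`). The
#' education-adjusted LM cutoff is study configuration and must be supplied.
#'
#' @param lm numeric vector of LM scores per visit (visit 1 = first scan).
#' @param mmse numeric vector of MMSE scores per visit (same length).
#' @param cutoff LM normal-level cutoff for the subject's education stratum.
#' @return list with `reverter` (logical), `visit` (earliest qualifying
#'   visit index or `NA`), `skippedVisits` (count).
#' @export
classifyReverter <- function(lm, mmse, cutoff) {
  stopifnot(length(lm) == length(mmse), length(lm) >= 2, length(cutoff) == 1)
  skipped <- 0L
  if (is.na(lm[1]) || lm[1] >= cutoff)
    return(list(reverter = FALSE, visit = NA_integer_, skippedVisits = skipped))
  for (j in 2:length(lm)) {
    if (is.na(lm[j]) || is.na(mmse[j])) {
      skipped <- skipped + 1L
      next
    }
    if (lm[j] >= cutoff && mmse[j] > 24)
      return(list(reverter = TRUE, visit = j, skippedVisits = skipped))
  }
  list(reverter = FALSE, visit = NA_integer_, skippedVisits = skipped)
}

#' Cluster-wise partial correlations with cognitive scores
#'
#' For each surviving cluster and each score column: the per-subject mean of
#' the subject's metric map inside the cluster mask is partially correlated
#' with the score, controlling for the covariates (site by default, with
#' age/sex/education available as the extended set); BH-FDR adjusted p
#' values are added across all (cluster, scale) pairs. Missing scores are
#' dropped pairwise.
#'
#' @param maps list of [MetricMap-class], one per subject.
#' @param clusters cluster table from [grfClusterInference()] (with its
#'   `masks` attribute).
#' @param scores data.frame of cognitive score columns (one row per
#'   subject).
#' @param covariates data.frame of control covariates (one row per subject),
#'   e.g. site; may include age, sex, education.
#' @return data.frame with columns region, scale, r, p, p_fdr.
#' @export
clusterScoreCorrelations <- function(maps, clusters, scores, covariates) {
  masks <- attr(clusters, "masks")
  if (is.null(masks) || !length(masks))
    return(data.frame(region = character(), scale = character(),
                      r = numeric(), p = numeric(), p_fdr = numeric(),
                      stringsAsFactors = FALSE))
  rows <- list()
  for (ci in seq_along(masks)) {
    cm <- masks[[ci]]
    vals <- vapply(maps, function(m) mean(m@values[cm]), numeric(1))
    region <- sprintf("cluster%02d_%s", clusters$cluster_id[ci],
                      clusters$sign[ci])
    for (sc in names(scores)) {
      y <- scores[[sc]]
      okRows <- !is.na(y) & !is.na(vals)
      pc <- partialCorrelation(vals[okRows], y[okRows],
                               covariates[okRows, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, scale = sc, r = pc$r, p = pc$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- bhFdr(out$p)$adjusted
  out
}
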