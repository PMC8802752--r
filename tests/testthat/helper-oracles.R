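## Independent naive reference implementations used as oracles.
## These deliberately use per-voxel loops and explicit DFT sums so they share
## no code path with the package implementations they check.

## Explicit DFT amplitude spectrum of one series: 2|X_k|/n, k = 1..floor(n/2)
oracleAmpSpectrum <- function(x, trS) {
  n <- length(x)
  ks <- seq_len(floor(n / 2))
  amp <- vapply(ks, function(k) {
    s <- sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
    2 * Mod(s) / n
  }, numeric(1))
  list(freq = ks / (n * trS), amp = amp)
}

oracleALFF <- function(x, trS, lo = 0.01, hi = 0.08) {
  sp <- oracleAmpSpectrum(x, trS)
  mean(sp$amp[sp$freq >= lo & sp$freq <= hi])
}

oracleFALFF <- function(x, trS, lo = 0.01, hi = 0.08) {
  sp <- oracleAmpSpectrum(x, trS)
  num <- sum(sp$amp[sp$freq >= lo & sp$freq <= hi])
  den <- sum(sp$amp)
  if (den == 0) 0 else num / den
}

oraclePerAF <- function(x) {
  mu <- mean(x)
  mean(abs(x - mu)) / mu * 100
}

## Kendall's W of a time-by-series matrix, straight from the formula
oracleKCC <- function(mat) {
  n <- nrow(mat)
  K <- ncol(mat)
  ranks <- apply(mat, 2, rank)
  Ri <- rowSums(ranks)
  W <- (sum(Ri^2) - n * mean(Ri)^2) / (K^2 * (n^3 - n) / 12)
  min(max(W, 0), 1)
}

## Naive ReHo over a masked series matrix (time x voxels): per-voxel loop,
## in-mask neighbours only, K = actual member count.
oracleReHo <- function(data, mask, K = 27) {
  dims <- dim(mask)
  maskIdx <- which(mask)
  coords <- arrayInd(maskIdx, dims)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- switch(as.character(K),
                 "7"  = offs[rowSums(abs(offs)) <= 1, ],
                 "19" = offs[rowSums(abs(offs)) <= 2 &
                               apply(abs(offs), 1, max) <= 1, ],
                 "27" = offs)
  out <- numeric(length(maskIdx))
  for (v in seq_along(maskIdx)) {
    members <- integer(0)
    for (o in seq_len(nrow(offs))) {
      cc <- coords[v, ] + offs[o, ]
      if (any(cc < 1) || any(cc > dims)) next
      lin <- cc[1] + (cc[2] - 1) * dims[1] + (cc[3] - 1) * dims[1] * dims[2]
      if (mask[lin]) members <- c(members, match(lin, maskIdx))
    }
    out[v] <- oracleKCC(data[, members, drop = FALSE])
  }
  out
}

## Naive DC via the full correlation matrix
oracleDC <- function(data, r0 = 0.25, mode = "binarized") {
  R <- suppressWarnings(stats::cor(data))
  R[!is.finite(R)] <- 0
  diag(R) <- 0
  if (mode == "binarized") rowSums(R > r0) else rowSums(R * (R > r0))
}

## Normal-equations OLS residuals (explicit inverse)
oracleOlsResid <- function(X, y) {
  y - X %*% (solve(t(X) %*% X) %*% (t(X) %*% y))
}

## Brute-force Benjamini-Hochberg rejection set: largest k with
## p_(k) <= k q / m, reject everything at or below p_(k).
oracleBhReject <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ks <- which(ps <= seq_len(m) * q / m)
  if (!length(ks)) return(rep(FALSE, m))
  p <= ps[max(ks)]
}

## Closed-form first-order partial correlation
oraclePartialR1 <- function(rxy, rxz, ryz) {
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}
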