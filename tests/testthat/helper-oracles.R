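# Independent oracles used by the tests. These are deliberately written
# from first principles (quadrature, brute force) and never call the code
# paths they check.

# FWHM of the projected-ring (arcsine) density of radius r convolved with
# a Gaussian of SD sigma, by direct quadrature on a fine grid.
ringConvolutionFwhm <- function(r = 12.5, sigma = 3.5, lim = 60,
                                dx = 0.01) {
  x <- seq(-lim, lim, dx)
  th <- seq(0, pi, length.out = 4001)[-c(1, 4001)]
  f <- rowMeans(outer(x, r * cos(th), function(a, b) dnorm(a - b, 0,
                                                           sigma)))
  pk <- which.max(f)
  half <- f[pk] / 2
  li <- max(which(f[seq_len(pk)] < half))
  ri <- pk - 1L + min(which(f[pk:length(f)] < half))
  xl <- approx(f[c(li, li + 1)], x[c(li, li + 1)], half)$y
  xr <- approx(f[c(ri - 1, ri)], x[c(ri - 1, ri)], half)$y
  xr - xl
}

# O(L^2) brute-force Kapur maximum-entropy threshold over an image's
# histogram: recomputes both class entropies by direct summation at every
# candidate split.
bruteForceMaxEntropy <- function(img, nBins = 256L) {
  v <- as.numeric(img)
  breaks <- seq(min(v), max(v), length.out = nBins + 1L)
  bi <- findInterval(v, breaks, rightmost.closed = TRUE)
  bi[bi > nBins] <- nBins
  p <- tabulate(bi, nBins) / length(v)
  best <- -Inf
  bestT <- 1L
  for (t in seq_len(nBins - 1L)) {
    p0 <- p[seq_len(t)]
    p1 <- p[(t + 1L):nBins]
    P0 <- sum(p0); P1 <- sum(p1)
    if (P0 <= 0 || P1 <= 0) next
    q0 <- p0[p0 > 0] / P0
    q1 <- p1[p1 > 0] / P1
    h <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    if (h > best) { best <- h; bestT <- t }
  }
  breaks[bestT + 1L]
}

# full simulate -> render -> centerline -> FWHM pipeline for one filament;
# the threshold quantile and ridge scale follow the apparent filament
# width (see the methods vignette)
pipelineFwhm <- function(mode, seed, nLoc = 2000, sigma = 3.5) {
  spec <- filamentSpec(polyline = cbind(c(0, 1000), c(0, 0)),
                       labelingMode = mode, sigmaXY = sigma,
                       nLocalizations = nLoc)
  tab <- simulateMinflux(spec, seed = seed)
  map <- renderDensity(tab, voxelSize = 1, origin = c(-30, -500),
                       fieldDim = c(1060, 1000))
  scale <- if (mode == "axial") 15 else 35
  q <- if (mode == "axial") 0.98 else 0.95
  cls <- extractCenterlines(map, minLength = 300, scale = scale,
                            thresholdQuantile = q)
  if (!length(cls)) return(NA_real_)
  lens <- vapply(cls, function(m) sum(sqrt(rowSums(diff(m)^2))),
                 numeric(1))
  filamentFWHM(map, cls[[which.max(lens)]])$fwhm
}

# build a noiseless protofilament trace with a kink at axial coordinate zk
# (lattice along +z at radius R, circular-arc flare of curvature kappa)
makeKinkedTrace <- function(zk, R = 12.5, kappa = 0.01, spacing = 4,
                            latticeLen = 40, arcLen = 40) {
  s <- seq(spacing, arcLen, by = spacing)
  rbind(cbind(R, 0, seq(zk - latticeLen, zk, spacing)),
        cbind(R + (1 - cos(kappa * s)) / kappa, 0,
              zk + sin(kappa * s) / kappa))
}
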