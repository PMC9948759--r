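# EB1 comet counting: rolling-ball background subtraction,
# maximum-entropy (Kapur) thresholding, 8-connected particle analysis.

ballElement <- function(radius) {
  d <- seq(-radius, radius)
  r2 <- outer(d, d, function(a, b) radius^2 - a^2 - b^2)
  h <- sqrt(pmax(r2, 0))
  h[r2 < 0] <- NA_real_
  h
}

# grayscale erosion/dilation with a non-flat structuring element
grayErode <- function(img, se) {
  r <- (nrow(se) - 1L) %/% 2L
  out <- matrix(Inf, nrow(img), ncol(img))
  for (i in seq_len(nrow(se))) for (j in seq_len(ncol(se))) {
    h <- se[i, j]
    if (is.na(h)) next
    out <- pmin(out, shiftMat(img, i - r - 1L, j - r - 1L) - h)
  }
  out
}

grayDilate <- function(img, se) {
  r <- (nrow(se) - 1L) %/% 2L
  out <- matrix(-Inf, nrow(img), ncol(img))
  for (i in seq_len(nrow(se))) for (j in seq_len(ncol(se))) {
    h <- se[i, j]
    if (is.na(h)) next
    out <- pmax(out, shiftMat(img, i - r - 1L, j - r - 1L) + h)
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' ball-shaped (non-flat, hemispherical) structuring element of the given
#' radius — the rolling-ball algorithm: the background is the surface
#' traced by a ball rolled under the intensity landscape, so features
#' narrower than the ball survive subtraction while smooth background is
#' removed. Output is clipped at 0.
#'
#' @param img 2D numeric matrix.
#' @param radius ball radius in pixels.
#' @return background-subtracted matrix (same size, >= 0).
#' @examples
#' img <- matrix(5, 64, 64); img[30:32, 30:32] <- 50
#' sub <- rollingBallSubtract(img, 10)
#' max(sub)   # peak preserved, flat background removed
#' @export
rollingBallSubtract <- function(img, radius = 10) {
  stopifnot(is.matrix(img))
  if (radius < 1) stop("radius must be >= 1")
  if (2 * radius + 1 > min(dim(img)))
    stop("ball radius larger than the image")
  se <- ballElement(radius)
  background <- grayDilate(grayErode(img, se), se)
  pmax(img - background, 0)
}

#' Maximum-entropy (Kapur) threshold
#'
#' Computes the Kapur maximum-entropy threshold of a grayscale image: the
#' histogram (256 bins over the image min-max range by default) is split
#' at each candidate level and the gray level maximizing the sum of the
#' Shannon entropies of the background and foreground class distributions
#' is returned. Pixels strictly above the returned value are foreground.
#'
#' @param img 2D numeric matrix with at least two distinct values.
#' @param nBins number of histogram bins.
#' @return the threshold gray value.
#' @export
maxEntropyThreshold <- function(img, nBins = 256L) {
  v <- as.numeric(img)
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("constant image: threshold undefined")
  breaks <- seq(lo, hi, length.out = nBins + 1L)
  bi <- findInterval(v, breaks, rightmost.closed = TRUE)
  bi[bi > nBins] <- nBins
  p <- tabulate(bi, nBins) / length(v)
  P <- cumsum(p)
  # entropy accumulators: S1(t) = -sum_{i<=t} p log p, vectorized
  plogp <- ifelse(p > 0, p * log(p), 0)
  S <- cumsum(plogp)
  Stot <- S[nBins]
  best <- -Inf; bestT <- 1L
  for (t in seq_len(nBins - 1L)) {
    P0 <- P[t]; P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    H0 <- log(P0) - S[t] / P0
    H1 <- log(P1) - (Stot - S[t]) / P1
    if (H0 + H1 > best) { best <- H0 + H1; bestT <- t }
  }
  breaks[bestT + 1L]   # upper edge of the chosen bin
}

#' Detection configuration for comet counting
#'
#' @param pixelSize µm per pixel (> 0).
#' @param rollingBallRadius background-subtraction ball radius, px.
#' @param minArea minimum particle area, µm² (components below it are
#'   discarded).
#' @param connectivity 8 (default, ImageJ particle-analysis convention)
#'   or 4.
#' @return list of class `"DetectionConfig"`.
#' @export
detectionConfig <- function(pixelSize, rollingBallRadius = 10,
                            minArea = 0.10, connectivity = 8L) {
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  if (rollingBallRadius < 1) stop("rollingBallRadius must be >= 1")
  if (minArea <= 0) stop("minArea must be > 0")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(pixelSize = pixelSize,
                 rollingBallRadius = rollingBallRadius,
                 minArea = minArea,
                 connectivity = as.integer(connectivity)),
            class = "DetectionConfig")
}

#' Count comets in a spot image
#'
#' The full counting pipeline: rolling-ball background subtraction,
#' maximum-entropy thresholding, connected-component particle analysis,
#' and an area cut-off; counts are optionally normalized to comets per
#' 100 µm² of cell area.
#'
#' @param img 2D numeric matrix.
#' @param config a [detectionConfig()].
#' @param cellArea cell area in µm² for density normalization, or `NULL`.
#' @return list: `threshold`, `count`, `comets` (data.frame `label`,
#'   `area_um2`, `x`, `y` centroids in px), `per100um2` (`NA` without
#'   `cellArea`).
#' @export
countComets <- function(img, config, cellArea = NULL) {
  stopifnot(inherits(config, "DetectionConfig"))
  sub <- rollingBallSubtract(img, config$rollingBallRadius)
  thr <- maxEntropyThreshold(sub)
  mask <- sub > thr
  lab <- labelComponents(mask, config$connectivity)
  n <- max(lab)
  comets <- data.frame(label = integer(0), area_um2 = numeric(0),
                       x = numeric(0), y = numeric(0))
  if (n > 0) {
    px <- tabulate(lab[lab > 0], n)
    area <- px * config$pixelSize^2
    idx <- which(lab > 0)
    ri <- ((idx - 1L) %% nrow(lab)) + 1L
    ci <- ((idx - 1L) %/% nrow(lab)) + 1L
    lv <- lab[idx]
    comets <- data.frame(
      label = seq_len(n), area_um2 = area,
      x = as.numeric(tapply(ri, lv, mean)),
      y = as.numeric(tapply(ci, lv, mean)))
    comets <- comets[comets$area_um2 >= config$minArea, , drop = FALSE]
    rownames(comets) <- NULL
  }
  list(threshold = thr, count = nrow(comets), comets = comets,
       per100um2 = if (is.null(cellArea)) NA_real_ else
         nrow(comets) * 100 / cellArea)
}
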