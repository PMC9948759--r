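#' Specification for a synthetic comet image
#'
#' Renders fluorescent spots (EB-comet-like blobs) as filled discs of
#' requested areas on an uneven background (constant offset plus a linear
#' gradient), with optional Gaussian noise. Blob elongation is irrelevant
#' to area-threshold counting, so discs suffice.
#'
#' @param imageShape image size in pixels, `c(rows, cols)`.
#' @param pixelSize µm per pixel.
#' @param blobTable data.frame with columns `x`, `y` (pixel centers),
#'   `area_um2` (> 0) and `peak` (intensity above background).
#' @param background `c(offset, slope)`: offset plus `slope * column`.
#' @param noiseSd additive Gaussian noise SD.
#' @return list of class `"CometImageSpec"`.
#' @export
cometImageSpec <- function(imageShape = c(200, 200), pixelSize = 0.05,
                           blobTable = data.frame(x = numeric(0),
                                                  y = numeric(0),
                                                  area_um2 = numeric(0),
                                                  peak = numeric(0)),
                           background = c(offset = 10, slope = 0),
                           noiseSd = 0) {
  if (any(imageShape < 8)) stop("image too small")
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  if (nrow(blobTable) && any(blobTable$area_um2 <= 0))
    stop("blob areas must be > 0")
  if (nrow(blobTable)) {
    r <- sqrt(blobTable$area_um2 / pi) / pixelSize
    if (any(blobTable$x - r < 1 | blobTable$x + r > imageShape[1] |
            blobTable$y - r < 1 | blobTable$y + r > imageShape[2]))
      stop("blobs must lie fully inside the image bounds")
  }
  structure(list(imageShape = imageShape, pixelSize = pixelSize,
                 blobTable = blobTable, background = background,
                 noiseSd = noiseSd),
            class = "CometImageSpec")
}

#' Simulate a spot image with ground truth
#'
#' Renders the blobs of a [cometImageSpec()] as filled discs on the
#' background. Overlapping blobs are flagged in the ground-truth table
#' (with a warning): overlapping discs would merge into one connected
#' component and break the count correspondence.
#'
#' @param spec a [cometImageSpec()].
#' @param seed RNG seed for the noise.
#' @return list: `image` (matrix), `truth` (the blob table plus
#'   `radius_px`, `above` = area >= 0.10 µm², `overlaps`), `spec`.
#' @export
simulateCometImage <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "CometImageSpec"))
  withSeed(seed, {
    sh <- spec$imageShape
    img <- matrix(spec$background[1], sh[1], sh[2]) +
      matrix(rep(spec$background[2] * (seq_len(sh[2]) - 1),
                 each = sh[1]), sh[1], sh[2])
    tb <- spec$blobTable
    overlaps <- rep(FALSE, nrow(tb))
    if (nrow(tb)) {
      r <- sqrt(tb$area_um2 / pi) / spec$pixelSize
      if (nrow(tb) >= 2L) {
        for (i in seq_len(nrow(tb) - 1L)) for (j in (i + 1L):nrow(tb)) {
          d <- sqrt((tb$x[i] - tb$x[j])^2 + (tb$y[i] - tb$y[j])^2)
          if (d < r[i] + r[j] + 1)
            overlaps[c(i, j)] <- TRUE
        }
        if (any(overlaps)) warning("overlapping blobs flagged in truth")
      }
      rows <- matrix(seq_len(sh[1]), sh[1], sh[2])
      cols <- matrix(rep(seq_len(sh[2]), each = sh[1]), sh[1], sh[2])
      for (i in seq_len(nrow(tb))) {
        disc <- (rows - tb$x[i])^2 + (cols - tb$y[i])^2 <= r[i]^2
        img[disc] <- img[disc] + tb$peak[i]
      }
      tb$radius_px <- r
      tb$above <- tb$area_um2 >= 0.10
      tb$overlaps <- overlaps
    }
    if (spec$noiseSd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noiseSd),
                          sh[1], sh[2])
    list(image = img, truth = tb, spec = spec)
  })
}
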