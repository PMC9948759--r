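# Centerline extraction from rendered density maps:
# ridge enhancement (Gaussian filter at the expected filament scale),
# quantile threshold, Zhang-Suen skeletonization, spur pruning, and
# ordered-polyline extraction.

# one Zhang-Suen thinning pass; m is a 0/1 matrix, step is 1 or 2
zsPass <- function(m, step) {
  P2 <- shiftMat0(m, 1, 0);  P3 <- shiftMat0(m, 1, 1)
  P4 <- shiftMat0(m, 0, 1);  P5 <- shiftMat0(m, -1, 1)
  P6 <- shiftMat0(m, -1, 0); P7 <- shiftMat0(m, -1, -1)
  P8 <- shiftMat0(m, 0, -1); P9 <- shiftMat0(m, 1, -1)
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
       (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
       (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
  if (step == 1L) {
    cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
      (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
  } else {
    cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
      (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
  }
  m[cond] <- 0
  m
}

skeletonize <- function(mask) {
  m <- mask * 1
  repeat {
    before <- sum(m)
    m <- zsPass(m, 1L)
    m <- zsPass(m, 2L)
    if (sum(m) == before) break
  }
  m
}

neighborCount <- function(m) {
  shiftMat0(m, 1, 0) + shiftMat0(m, 1, 1) + shiftMat0(m, 0, 1) +
    shiftMat0(m, -1, 1) + shiftMat0(m, -1, 0) + shiftMat0(m, -1, -1) +
    shiftMat0(m, 0, -1) + shiftMat0(m, 1, -1)
}

# remove skeleton spurs shorter than prunePx (walk endpoint -> junction)
pruneSpurs <- function(m, prunePx) {
  if (prunePx < 1) return(m)
  nr <- nrow(m)
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  repeat {
    nb <- neighborCount(m)
    junctions <- which(m == 1 & nb >= 3)
    if (!length(junctions)) return(m)
    endpoints <- which(m == 1 & nb <= 1)
    removedAny <- FALSE
    for (e in endpoints) {
      path <- e; cur <- e; prev <- -1L
      repeat {
        nbs <- cur + off
        nbs <- nbs[nbs >= 1 & nbs <= length(m)]
        # guard against wrap-around between columns
        ci <- ((cur - 1L) %% nr) + 1L
        nbs <- nbs[abs(((nbs - 1L) %% nr) + 1L - ci) <= 1L]
        nbs <- nbs[m[nbs] == 1 & nbs != prev]
        if (length(nbs) != 1L) break    # junction, isolated, or fork
        prev <- cur; cur <- nbs
        if (cur %in% junctions) break
        path <- c(path, cur)
        if (length(path) > prunePx) break
      }
      if (length(path) <= prunePx &&
          (length(path) < 2L || cur %in% junctions)) {
        m[path] <- 0
        removedAny <- TRUE
      }
    }
    if (!removedAny) return(m)
    m <- skeletonize(m)   # re-thin after pruning
  }
}

# Smooth a skeleton path into a centerline. Pixel-level jitter and the
# skeleton's tendency to follow local density noise both bias downstream
# perpendicular-distance profiles narrow, so the path is refit with a
# low-degree-of-freedom smoothing spline of the transverse coordinate
# against arc position in the path's principal-axis frame (falling back to
# a moving average for short or strongly hooked paths).
refineCenterline <- function(xy, smoothWindow) {
  movAvg <- function(m, w) {
    w <- min(w, nrow(m))
    if (w < 3) return(m)
    sm1 <- function(v) {
      n <- length(v)
      vapply(seq_len(n), function(i) {
        h <- min((w - 1) %/% 2, i - 1L, n - i)
        mean(v[(i - h):(i + h)])
      }, numeric(1))
    }
    cbind(sm1(m[, 1]), sm1(m[, 2]))
  }
  n <- nrow(xy)
  if (n < 10L) return(movAvg(xy, smoothWindow))
  ctr <- colMeans(xy)
  pc <- stats::prcomp(xy, center = TRUE)
  s <- (xy[, 1] - ctr[1]) * pc$rotation[1, 1] +
    (xy[, 2] - ctr[2]) * pc$rotation[2, 1]
  d <- (xy[, 1] - ctr[1]) * pc$rotation[1, 2] +
    (xy[, 2] - ctr[2]) * pc$rotation[2, 2]
  # the spline needs the transverse offset to be a function of arc
  # position; hooked paths keep the moving-average smoothing instead
  if (abs(stats::cor(s, seq_len(n))) < 0.98 ||
      length(unique(s)) < 8L)
    return(movAvg(xy, smoothWindow))
  len <- diff(range(s))
  df <- min(max(3, ceiling(len / 300)), 10)
  sp <- tryCatch(stats::smooth.spline(s, d, df = df),
                 error = function(e) NULL)
  if (is.null(sp)) return(movAvg(xy, smoothWindow))
  sGrid <- seq(min(s), max(s), length.out = max(2L, ceiling(len / 5)))
  dHat <- stats::predict(sp, sGrid)$y
  cbind(ctr[1] + sGrid * pc$rotation[1, 1] + dHat * pc$rotation[1, 2],
        ctr[2] + sGrid * pc$rotation[2, 1] + dHat * pc$rotation[2, 2])
}

# order the pixels of a thin 8-connected component into a path
orderPath <- function(m, pixels) {
  nr <- nrow(m)
  sub <- matrix(0, nr, ncol(m))
  sub[pixels] <- 1
  nb <- neighborCount(sub)
  ends <- pixels[nb[pixels] == 1]
  start <- if (length(ends)) ends[1] else pixels[1]
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  path <- integer(0); cur <- start
  visited <- sub * 0
  repeat {
    path <- c(path, cur); visited[cur] <- 1
    ci <- ((cur - 1L) %% nr) + 1L
    nbs <- cur + off
    nbs <- nbs[nbs >= 1 & nbs <= length(m)]
    nbs <- nbs[abs(((nbs - 1L) %% nr) + 1L - ci) <= 1L]
    nbs <- nbs[sub[nbs] == 1 & visited[nbs] == 0]
    if (!length(nbs)) break
    cur <- nbs[1]
  }
  path
}

#' Extract filament centerlines from a density map
#'
#' Segments line-like structures in a 2D density map and extracts their
#' centerlines: the map is ridge-enhanced with a Gaussian filter matched
#' to the expected filament width, thresholded at a quantile of the
#' filtered image, skeletonized (Zhang-Suen thinning), pruned of short
#' branches, and each remaining skeleton is ordered into a polyline in nm
#' coordinates. Polylines are lightly smoothed (moving average) to remove
#' single-voxel staircase jitter.
#'
#' The default threshold quantile (0.98 over the whole filtered image)
#' presumes sparse fields in which filaments occupy a few percent of the
#' area, as in typical acquisitions; for tightly cropped maps, lower it.
#'
#' @param map a 2D [DensityMap-class].
#' @param minLength minimum centerline length, nm.
#' @param scale expected filament width in voxels (filter scale).
#' @param thresholdQuantile segmentation threshold quantile of the
#'   filtered image.
#' @param prunePx prune skeleton branches shorter than this many voxels.
#' @param smoothWindow moving-average window (voxels) for polyline
#'   smoothing.
#' @return list of centerline matrices (n x 2, nm), possibly empty.
#' @export
extractCenterlines <- function(map, minLength = 100, scale = 15,
                               thresholdQuantile = 0.98, prunePx = 10,
                               smoothWindow = 31) {
  stopifnot(is(map, "DensityMap"))
  cnt <- mapCounts(map)
  if (length(dim(cnt)) != 2L)
    stop("centerline extraction expects a 2D map; project 3D maps first")
  if (sum(cnt) == 0) return(list())
  sigma <- scale / (2 * sqrt(2 * log(2)))   # scale taken as a FWHM
  sm <- EBImage::imageData(EBImage::gblur(cnt, sigma = sigma))
  thr <- stats::quantile(sm, thresholdQuantile)
  if (thr <= 0) thr <- min(sm[sm > 0])
  mask <- (sm > thr) * 1
  if (!sum(mask)) return(list())
  # thin only the occupied region: crop to the foreground bounding box
  fg <- which(mask == 1, arr.ind = TRUE)
  i0 <- max(1L, min(fg[, 1]) - 2L); i1 <- min(nrow(mask), max(fg[, 1]) + 2L)
  j0 <- max(1L, min(fg[, 2]) - 2L); j1 <- min(ncol(mask), max(fg[, 2]) + 2L)
  cropped <- mask[i0:i1, j0:j1, drop = FALSE]
  skel <- pruneSpurs(skeletonize(cropped), prunePx)
  if (!sum(skel)) return(list())
  lab <- labelComponents(skel == 1, 8L)
  vs <- mapVoxelSize(map); orig <- mapOrigin(map)
  out <- list()
  for (l in seq_len(max(lab))) {
    pix <- which(lab == l)
    if (length(pix) < 2L) next
    path <- orderPath(skel, pix)
    if (length(path) < 2L) next
    nr <- nrow(skel)
    ij <- cbind(((path - 1L) %% nr) + 1L, ((path - 1L) %/% nr) + 1L)
    xy <- cbind(orig[1] + (i0 - 1L + ij[, 1] - 0.5) * vs,
                orig[2] + (j0 - 1L + ij[, 2] - 0.5) * vs)
    xy <- refineCenterline(xy, smoothWindow)
    len <- sum(sqrt(rowSums(diff(xy)^2)))
    if (len >= minLength) out[[length(out) + 1L]] <- xy
  }
  out
}
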