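#' Specification of a simulated MINFLUX filament measurement
#'
#' Describes a line-like filament decorated with fluorophores either on its
#' axis (luminal labeling), on a cylinder surface of `surfaceRadius`
#' (lattice-bound labeling, projected to the imaging plane as a ring-edge
#' profile), or outside the cylinder (e.g. antibody labeling at
#' `surfaceRadius + outsideOffset`). Each fluorophore emits a burst of
#' consecutive localizations sharing a trace id, with i.i.d. Gaussian
#' localization error per axis, and a detector-channel-ratio value drawn
#' from a two-component Gaussian mixture.
#'
#' @param polyline numeric matrix (n x 2 or n x 3) of control points, nm.
#' @param labelingMode `"axial"`, `"surface"` or `"outside"`.
#' @param surfaceRadius cylinder radius, nm (12.5 for the MT lattice).
#' @param outsideOffset extra radial offset for `"outside"` labeling, nm.
#' @param sigmaXY lateral localization SD per axis, nm.
#' @param sigmaZ axial (optical z) localization SD, nm; used when
#'   `dims = 3`.
#' @param nLocalizations total number of filament localizations.
#' @param backgroundDensity unspecific localizations per µm² of field.
#' @param dcrComponents numeric vector `(mu1, s1, w1, mu2, s2, w2)` of the
#'   dcr mixture; weights must sum to 1 and `0 <= mu1 < mu2 <= 1`.
#' @param traceGroupSize mean number of localizations per fluorophore.
#' @param dims 2 or 3 output dimensionality.
#' @return list of class `"FilamentSpec"`.
#' @export
filamentSpec <- function(polyline = cbind(x = c(0, 1000), y = c(0, 0)),
                         labelingMode = c("axial", "surface", "outside"),
                         surfaceRadius = 12.5, outsideOffset = 10,
                         sigmaXY = 3.5, sigmaZ = 5,
                         nLocalizations = 2000, backgroundDensity = 0,
                         dcrComponents = c(0.30, 0.05, 0.5,
                                           0.80, 0.05, 0.5),
                         traceGroupSize = 5, dims = 2) {
  labelingMode <- match.arg(labelingMode)
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least 2 points")
  if (surfaceRadius <= 0) stop("surfaceRadius must be > 0")
  if (sigmaXY < 0 || sigmaZ < 0) stop("localization SDs must be >= 0")
  if (nLocalizations < 1) stop("nLocalizations must be >= 1")
  dc <- dcrComponents
  if (length(dc) != 6 || dc[1] < 0 || dc[1] >= dc[4] || dc[4] > 1)
    stop("dcrComponents must be (mu1, s1, w1, mu2, s2, w2) with 0 <= mu1 < mu2 <= 1")
  if (abs(dc[3] + dc[6] - 1) > 1e-9) stop("dcr weights must sum to 1")
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  structure(list(polyline = polyline, labelingMode = labelingMode,
                 surfaceRadius = surfaceRadius,
                 outsideOffset = outsideOffset, sigmaXY = sigmaXY,
                 sigmaZ = sigmaZ, nLocalizations = nLocalizations,
                 backgroundDensity = backgroundDensity,
                 dcrComponents = dc, traceGroupSize = traceGroupSize,
                 dims = dims),
            class = "FilamentSpec")
}

sampleDcr <- function(n, dc) {
  comp <- stats::rbinom(n, 1L, dc[6]) + 1L   # 1 or 2
  mu <- c(dc[1], dc[4])[comp]
  s <- c(dc[2], dc[5])[comp]
  pmin(pmax(stats::rnorm(n, mu, s), 0), 1)
}

#' Simulate a MINFLUX localization table for a labeled filament
#'
#' Draws fluorophore ground positions along the filament according to the
#' labeling mode, lets each fluorophore emit a group of consecutive
#' localizations with Gaussian localization error, attaches dcr values from
#' the configured two-component mixture and adds uniform background
#' localizations over the field. Ground truth (fluorophore positions,
#' signed perpendicular offsets of the underlying binding sites, background
#' flags) is stored in the metadata.
#'
#' For `"surface"` labeling in 2D, fluorophores sit on the cylinder at a
#' uniform azimuthal angle and are projected to the imaging plane, so their
#' perpendicular offsets follow the ring-edge (arcsine) profile supported
#' on ±`surfaceRadius`. With `dims = 3` the full cylinder position is kept
#' and optical-z error `sigmaZ` is applied.
#'
#' @param spec a [filamentSpec()].
#' @param seed RNG seed.
#' @return A [LocalizationTable-class]; metadata fields: `spec`, `seed`,
#'   `truth` (data.frame with per-row `isBackground`, `perpOffset`,
#'   fluorophore id).
#' @examples
#' tab <- simulateMinflux(filamentSpec(nLocalizations = 200), seed = 1)
#' tab
#' @export
simulateMinflux <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "FilamentSpec"))
  withSeed(seed, {
    pl <- spec$polyline[, 1:2, drop = FALSE]
    segs <- diff(pl)
    segLen <- sqrt(rowSums(segs^2))
    if (all(segLen == 0)) stop("degenerate polyline")
    L <- sum(segLen)
    cumLen <- c(0, cumsum(segLen))

    # group sizes per fluorophore until the localization budget is filled
    n <- spec$nLocalizations
    sizes <- integer(0)
    while (sum(sizes) < n) {
      draw <- pmax(stats::rpois(64, spec$traceGroupSize), 1L)
      sizes <- c(sizes, draw)
    }
    k <- which(cumsum(sizes) >= n)[1L]
    sizes <- sizes[seq_len(k)]
    sizes[k] <- sizes[k] - (sum(sizes) - n)
    nf <- length(sizes)

    # fluorophore anchor points, arc-length uniform, with local tangent
    s <- stats::runif(nf, 0, L)
    seg <- findInterval(s, cumLen, rightmost.closed = TRUE)
    seg <- pmin(pmax(seg, 1L), nrow(segs))
    frac <- (s - cumLen[seg]) / segLen[seg]
    base <- pl[seg, , drop = FALSE] + segs[seg, , drop = FALSE] * frac
    tangent <- segs[seg, , drop = FALSE] / segLen[seg]
    normal <- cbind(-tangent[, 2], tangent[, 1])

    theta <- stats::runif(nf, 0, 2 * pi)
    radial <- switch(spec$labelingMode,
      axial = rep(0, nf),
      surface = spec$surfaceRadius * cos(theta),
      outside = (spec$surfaceRadius + spec$outsideOffset) * cos(theta))
    zTrue <- switch(spec$labelingMode,
      axial = rep(0, nf),
      surface = spec$surfaceRadius * sin(theta),
      outside = (spec$surfaceRadius + spec$outsideOffset) * sin(theta))
    fluor <- base + normal * radial

    fid <- rep(seq_len(nf), sizes)
    locs <- fluor[fid, , drop = FALSE] +
      matrix(stats::rnorm(2L * n, 0, spec$sigmaXY), ncol = 2)
    z <- if (spec$dims == 3)
      zTrue[fid] + stats::rnorm(n, 0, spec$sigmaZ) else rep(0, n)

    # uniform background over the bounding field (+50 nm margin)
    bb <- apply(rbind(pl + 50, pl - 50), 2, range)
    areaUm2 <- prod(bb[2, ] - bb[1, ]) / 1e6
    nbg <- round(spec$backgroundDensity * areaUm2)
    if (nbg > 0) {
      bx <- stats::runif(nbg, bb[1, 1], bb[2, 1])
      by <- stats::runif(nbg, bb[1, 2], bb[2, 2])
      bz <- if (spec$dims == 3)
        stats::runif(nbg, -spec$surfaceRadius * 4, spec$surfaceRadius * 4)
      else rep(0, nbg)
      locs <- rbind(locs, cbind(bx, by))
      z <- c(z, bz)
      fid <- c(fid, nf + seq_len(nbg))
    }
    total <- n + max(nbg, 0)
    d <- data.frame(tid = fid, t = seq_len(total) * 1e-3,
                    x = locs[, 1], y = locs[, 2], z = z,
                    dcr = sampleDcr(total, spec$dcrComponents),
                    channel = NA_integer_)
    truth <- data.frame(
      isBackground = c(rep(FALSE, n), rep(TRUE, max(nbg, 0))),
      perpOffset = c(radial[rep(seq_len(nf), sizes)],
                     rep(NA_real_, max(nbg, 0))),
      fluorophore = fid)
    LocalizationTable(d, metadata = list(
      spec = spec, seed = seed, truth = truth,
      fluorophores = cbind(fluor, zTrue)))
  })
}
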