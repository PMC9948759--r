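#' Specification for simulated protofilament flares
#'
#' Generates microtubule ends as a ring of protofilaments on the lattice
#' cylinder: each protofilament runs straight along the axis up to a
#' deflection point whose axial coordinate is Normal(0, raggednessSd²),
#' then curls outward with a constant per-protofilament curvature over a
#' drawn flare length. Coordinates are in a microtubule frame with the
#' axis along +z.
#'
#' @param nProtofilaments protofilaments per end (13 for the B-lattice).
#' @param latticeRadius lattice cylinder radius, nm.
#' @param flareLengthMean,flareLengthSd flare arc length, nm.
#' @param curvatureMean,curvatureSd flare curvature, degrees per 8 nm of
#'   arc (8 nm = one tubulin dimer).
#' @param raggednessSd SD of the deflection-point axial coordinates, nm
#'   (the ground-truth end raggedness).
#' @param pointSpacing sampling interval along each trace, nm.
#' @param noiseSd isotropic coordinate noise, nm.
#' @param latticeLength length of the straight pre-deflection segment, nm.
#' @param nEnds number of microtubule ends to generate.
#' @return list of class `"FlareSimSpec"`.
#' @export
flareSimSpec <- function(nProtofilaments = 13, latticeRadius = 12.5,
                         flareLengthMean = 40, flareLengthSd = 10,
                         curvatureMean = 4.58, curvatureSd = 1,
                         raggednessSd = 12, pointSpacing = 4,
                         noiseSd = 1, latticeLength = 50, nEnds = 1) {
  if (nProtofilaments < 2) stop("need at least 2 protofilaments")
  if (latticeRadius <= 0 || pointSpacing <= 0 || latticeLength <= 0)
    stop("geometry parameters must be > 0")
  if (any(c(flareLengthSd, curvatureSd, raggednessSd, noiseSd) < 0))
    stop("all SDs must be >= 0")
  if (flareLengthMean < 0 || curvatureMean < 0)
    stop("flare length and curvature must be >= 0")
  structure(list(nProtofilaments = nProtofilaments,
                 latticeRadius = latticeRadius,
                 flareLengthMean = flareLengthMean,
                 flareLengthSd = flareLengthSd,
                 curvatureMean = curvatureMean,
                 curvatureSd = curvatureSd, raggednessSd = raggednessSd,
                 pointSpacing = pointSpacing, noiseSd = noiseSd,
                 latticeLength = latticeLength, nEnds = nEnds),
            class = "FlareSimSpec")
}

#' Simulate protofilament flares at microtubule ends
#'
#' See [flareSimSpec()]. Per-protofilament ground truth (deflection point
#' index and axial coordinate, realized flare arc length, curvature in
#' degrees per 8 nm and total curvature) is stored in `metadata$truth`;
#' truth refers to the noiseless geometry of the sampled polyline.
#'
#' @param spec a [flareSimSpec()].
#' @param seed RNG seed.
#' @return A [ProtofilamentSet-class] with `mt_id` = end index.
#' @examples
#' pf <- simulateFlares(flareSimSpec(nEnds = 2), seed = 1)
#' pf
#' @export
simulateFlares <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "FlareSimSpec"))
  withSeed(seed, {
    rows <- list(); truth <- list()
    for (e in seq_len(spec$nEnds)) {
      for (j in seq_len(spec$nProtofilaments)) {
        phi <- 2 * pi * (j - 1) / spec$nProtofilaments
        radial <- c(cos(phi), sin(phi))
        zDefl <- stats::rnorm(1, 0, spec$raggednessSd)
        flareLen <- max(stats::rnorm(1, spec$flareLengthMean,
                                     spec$flareLengthSd),
                        spec$pointSpacing)
        curvDeg8 <- max(stats::rnorm(1, spec$curvatureMean,
                                     spec$curvatureSd), 0)
        kappa <- curvDeg8 * pi / 180 / 8   # rad per nm of arc

        zLat <- zDefl - rev(seq(0, spec$latticeLength,
                                by = spec$pointSpacing))
        lat <- cbind(spec$latticeRadius * radial[1],
                     spec$latticeRadius * radial[2], zLat)
        deflIdx <- nrow(lat)
        s <- seq(spec$pointSpacing, flareLen, by = spec$pointSpacing)
        if (kappa > 0) {
          dz <- sin(kappa * s) / kappa
          dr <- (1 - cos(kappa * s)) / kappa
        } else {
          dz <- s
          dr <- rep(0, length(s))
        }
        fl <- cbind((spec$latticeRadius + dr) * radial[1],
                    (spec$latticeRadius + dr) * radial[2],
                    zDefl + dz)
        pts <- rbind(lat, fl)
        arc <- if (length(s)) max(s) else 0
        if (spec$noiseSd > 0)
          pts <- pts + matrix(stats::rnorm(length(pts), 0, spec$noiseSd),
                              ncol = 3)
        rows[[length(rows) + 1L]] <- data.frame(
          mt_id = e, pf_id = j, point_idx = seq_len(nrow(pts)),
          x = pts[, 1], y = pts[, 2], z = pts[, 3])
        truth[[length(truth) + 1L]] <- data.frame(
          mt_id = e, pf_id = j, deflection_index = deflIdx,
          first_off_index = deflIdx + (length(s) > 0),
          deflection_z = zDefl, flare_length = arc,
          curvature_deg_per_8nm = curvDeg8,
          total_curvature_deg = kappa * arc * 180 / pi)
      }
    }
    ProtofilamentSet(do.call(rbind, rows),
                     latticeRadius = spec$latticeRadius,
                     metadata = list(spec = spec, seed = seed,
                                     truth = do.call(rbind, truth)))
  })
}
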