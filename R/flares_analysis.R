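# Protofilament flare geometry: deflection points, flare length and
# curvature, end raggedness, and lattice-annotation summaries.

# resolve the MT axis for a trace: unit vector + center point
resolveAxis <- function(trace, axis) {
  if (is.character(axis) && axis == "z")
    return(list(dir = c(0, 0, 1), center = c(0, 0, 0)))
  if (is.character(axis) && axis == "fit") {
    ctr <- colMeans(trace)
    pc <- stats::prcomp(trace, center = TRUE)
    dir <- pc$rotation[, 1]
    if (dir[3] < 0) dir <- -dir     # orient toward the tip (+z-ish)
    return(list(dir = dir, center = ctr))
  }
  if (is.numeric(axis) && length(axis) == 3L)
    return(list(dir = axis / sqrt(sum(axis^2)), center = c(0, 0, 0)))
  stop("axis must be \"z\", \"fit\", or a numeric direction vector")
}

#' Find the first deflection point of a protofilament trace
#'
#' The deflection point is the first trace point whose radial distance
#' from the microtubule axis exceeds `latticeRadius + tol` and stays above
#' it for all subsequent points (a sustained departure from the lattice
#' cylinder, robust to transient noise excursions). Traces that never
#' leave the cylinder are blunt: the deflection point is the last point
#' and the flare has zero length.
#'
#' @param trace n x 3 matrix of ordered points, nm (lattice first, tip
#'   last).
#' @param latticeRadius lattice cylinder radius, nm.
#' @param tol radial excess tolerance, nm.
#' @param axis `"z"` (default: coordinates are in an axis-aligned MT
#'   frame), `"fit"` (principal axis of the trace points), or a numeric
#'   direction vector.
#' @return list: `index`, `axial` (coordinate along the axis, nm),
#'   `radial` (radial distances of all points), `blunt` flag.
#' @export
findDeflectionPoint <- function(trace, latticeRadius = 12.5, tol = 1.5,
                                axis = "z") {
  trace <- as.matrix(trace)
  if (nrow(trace) < 3L) stop("trace needs at least 3 points")
  ax <- resolveAxis(trace, axis)
  rel <- sweep(trace, 2, ax$center)
  axial <- as.numeric(rel %*% ax$dir)
  radial <- sqrt(pmax(rowSums(rel^2) - axial^2, 0))
  above <- radial > latticeRadius + tol
  sustained <- rev(cumprod(rev(above))) == 1   # TRUE through to the tip
  idx <- if (any(sustained)) which(sustained)[1L] else nrow(trace)
  blunt <- !any(sustained)
  # sub-sample estimate of where the trace crossed the cylinder: linear
  # interpolation of the radial coordinate between idx-1 and idx removes
  # the point-spacing quantization of the axial coordinate
  axialAt <- axial[idx]
  if (!blunt && idx > 1L && radial[idx - 1L] <= latticeRadius + tol &&
      radial[idx] > radial[idx - 1L]) {
    f <- (latticeRadius + tol - radial[idx - 1L]) /
      (radial[idx] - radial[idx - 1L])
    axialAt <- axial[idx - 1L] + f * (axial[idx] - axial[idx - 1L])
  }
  list(index = idx, axial = axialAt, radial = radial, blunt = blunt)
}

#' Length and curvature metrics of a protofilament flare
#'
#' Computes, over the trace from the deflection point to the tip: the 3D
#' arc length; the total curvature as the sum of turning angles between
#' consecutive segments (degrees); and the terminal curvature as the mean
#' turning per 8 nm of arc over the final `terminalWindow` nm (8 nm = one
#' tubulin dimer, the conventional normalization).
#'
#' @param trace n x 3 matrix of ordered points, nm.
#' @param deflectionIndex index of the deflection point (from
#'   [findDeflectionPoint()]).
#' @param terminalWindow arc window for terminal curvature, nm.
#' @return list: `flareLength` (nm), `totalCurvature` (degrees),
#'   `terminalCurvature` (degrees per 8 nm; `NA` when the flare has fewer
#'   than 3 points).
#' @examples
#' # quarter circle of radius 100 nm in the x-z plane
#' th <- seq(0, pi / 2, length.out = 40)
#' arc <- cbind(100 * (1 - cos(th)), 0, 100 * sin(th))
#' flareMetrics(arc, 1)$totalCurvature   # ~90 degrees
#' @export
flareMetrics <- function(trace, deflectionIndex, terminalWindow = 24) {
  trace <- as.matrix(trace)
  fl <- trace[deflectionIndex:nrow(trace), , drop = FALSE]
  if (nrow(fl) < 2L)
    return(list(flareLength = 0, totalCurvature = 0,
                terminalCurvature = NA_real_))
  segs <- diff(fl)
  segLen <- sqrt(rowSums(segs^2))
  flareLength <- sum(segLen)
  if (nrow(fl) < 3L)
    return(list(flareLength = flareLength, totalCurvature = NA_real_,
                terminalCurvature = NA_real_))
  u <- segs / segLen
  dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  turn <- acos(pmin(pmax(dots, -1), 1)) * 180 / pi   # per interior vertex
  totalCurvature <- sum(turn)
  # arc position of each interior vertex, measured from the deflection pt
  sVert <- cumsum(segLen)[-length(segLen)]
  sTip <- flareLength
  wStart <- max(sTip - terminalWindow, 0)
  inWin <- sVert >= wStart
  terminalCurvature <- if (any(inWin) && sTip > wStart)
    sum(turn[inWin]) / (sTip - wStart) * 8 else NA_real_
  list(flareLength = flareLength, totalCurvature = totalCurvature,
       terminalCurvature = terminalCurvature)
}

#' End raggedness and per-flare metrics for microtubule ends
#'
#' For each microtubule end, locates every protofilament's first
#' deflection point and summarizes the end: raggedness is the sample SD
#' (denominator n-1) of the deflection points' coordinates along the MT
#' axis — the standard measure of end taper. Ends with fewer than two
#' protofilaments have undefined raggedness (`NA`).
#'
#' @param x a [ProtofilamentSet-class], or a list of n x 3 trace matrices
#'   for a single end.
#' @param tol,axis passed to [findDeflectionPoint()].
#' @param terminalWindow passed to [flareMetrics()].
#' @param latticeRadius lattice radius, nm; defaults to the set's.
#' @return list with `ends` (data.frame: `mt_id`, `raggedness_nm`,
#'   `n_protofilaments`) and `flares` (per-protofilament data.frame with
#'   deflection and curvature metrics).
#' @examples
#' pf <- simulateFlares(flareSimSpec(raggednessSd = 0, noiseSd = 0),
#'                      seed = 1)
#' endRaggedness(pf)$ends$raggedness_nm   # 0
#' @export
endRaggedness <- function(x, tol = 1.5, axis = "z", terminalWindow = 24,
                          latticeRadius = NULL) {
  if (is(x, "ProtofilamentSet")) {
    if (is.null(latticeRadius)) latticeRadius <- pfLatticeRadius(x)
    traces <- pfTraces(x)
    p <- pfPoints(x)
    key <- unique(data.frame(key = paste(p$mt_id, p$pf_id, sep = "."),
                             mt_id = p$mt_id, pf_id = p$pf_id))
    meta <- key[match(names(traces), key$key), ]
  } else {
    if (is.null(latticeRadius)) latticeRadius <- 12.5
    traces <- lapply(x, as.matrix)
    meta <- data.frame(mt_id = 1L, pf_id = seq_along(traces))
  }
  fl <- lapply(seq_along(traces), function(i) {
    dp <- findDeflectionPoint(traces[[i]], latticeRadius, tol, axis)
    fm <- flareMetrics(traces[[i]], dp$index, terminalWindow)
    data.frame(mt_id = meta$mt_id[i], pf_id = meta$pf_id[i],
               deflection_index = dp$index, deflection_axial = dp$axial,
               blunt = dp$blunt, flare_length = fm$flareLength,
               total_curvature = fm$totalCurvature,
               terminal_curvature = fm$terminalCurvature)
  })
  flares <- do.call(rbind, fl)
  ends <- do.call(rbind, lapply(split(flares, flares$mt_id), function(g)
    data.frame(mt_id = g$mt_id[1],
               raggedness_nm = if (nrow(g) >= 2L)
                 stats::sd(g$deflection_axial) else NA_real_,
               n_protofilaments = nrow(g))))
  rownames(ends) <- NULL
  list(ends = ends, flares = flares)
}

#' Lattice-annotation summaries: defects per µm and percent ILP-positive
#'
#' Summarizes per-microtubule lattice annotations per tomogram and across
#' tomograms: defect density is the total defect count divided by the
#' total annotated microtubule length in each tomogram; the ILP fraction
#' is the percentage of microtubules containing intraluminal particles.
#' Across tomograms, means and sample SDs (denominator n-1) are reported,
#' matching how such quantifications are presented (one point per
#' tomogram).
#'
#' @param annotations data.frame with columns `tomogram_id`, `mt_id`,
#'   `length_um` (> 0), `n_defects` (>= 0), `has_ilp` (logical).
#' @return list: `perTomogram` (data.frame `tomogram_id`,
#'   `defects_per_um`, `pct_ilp`, `n_mts`), `defectsPerUm` (mean, sd),
#'   `pctIlp` (mean, sd).
#' @examples
#' ann <- data.frame(tomogram_id = c(1, 1, 2, 2),
#'                   mt_id = 1:4, length_um = c(2, 2, 3, 1),
#'                   n_defects = c(1, 1, 0, 3),
#'                   has_ilp = c(TRUE, FALSE, TRUE, TRUE))
#' latticeSummaries(ann)$perTomogram
#' @export
latticeSummaries <- function(annotations) {
  need <- c("tomogram_id", "mt_id", "length_um", "n_defects", "has_ilp")
  if (!all(need %in% names(annotations)))
    stop("annotations must contain: ", paste(need, collapse = ", "))
  if (!nrow(annotations)) stop("empty annotation table")
  if (any(annotations$length_um <= 0)) stop("lengths must be > 0")
  if (any(annotations$n_defects < 0)) stop("defect counts must be >= 0")
  per <- do.call(rbind, lapply(split(annotations,
                                     annotations$tomogram_id),
    function(g) data.frame(
      tomogram_id = g$tomogram_id[1],
      defects_per_um = sum(g$n_defects) / sum(g$length_um),
      pct_ilp = 100 * mean(as.logical(g$has_ilp)),
      n_mts = nrow(g))))
  rownames(per) <- NULL
  list(perTomogram = per,
       defectsPerUm = c(mean = mean(per$defects_per_um),
                        sd = if (nrow(per) >= 2L)
                          stats::sd(per$defects_per_um) else NA_real_),
       pctIlp = c(mean = mean(per$pct_ilp),
                  sd = if (nrow(per) >= 2L) stats::sd(per$pct_ilp) else
                    NA_real_))
}
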