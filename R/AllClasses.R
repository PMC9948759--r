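#' TipTrajectory: a time-ordered microtubule tip trace
#'
#' Container for a single microtubule tip trajectory: sampling times (s),
#' tip positions (µm above the seed) and, for simulated data, the
#' ground-truth dynamic state of each sample. The `metadata` list carries
#' the generating configuration and the continuous-time state record when
#' the object comes from [simulateDynamics()].
#'
#' @slot time numeric, strictly increasing sampling times in seconds.
#' @slot position numeric, tip positions in µm (never below 0).
#' @slot state character, per-sample state in `"growth"`, `"pause"`,
#'   `"shrinkage"`; may be empty for user-traced data.
#' @slot metadata list of provenance information (config, seed, continuous
#'   segment record, death time for depolymerized seeds).
#'
#' @seealso [simulateDynamics()], [classifyEvents()]
#' @export
setClass("TipTrajectory",
  representation(time = "numeric", position = "numeric",
                 state = "character", metadata = "list"),
  prototype(state = character(0), metadata = list()))

setValidity("TipTrajectory", function(object) {
  msg <- character(0)
  if (length(object@time) != length(object@position))
    msg <- c(msg, "time and position must have equal length")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(object@position) && any(object@position < -1e-9))
    msg <- c(msg, "positions must be >= 0")
  if (length(object@state) &&
      length(object@state) != length(object@time))
    msg <- c(msg, "state must be empty or match time in length")
  if (length(object@state) &&
      !all(object@state %in% c("growth", "pause", "shrinkage")))
    msg <- c(msg, "states must be growth/pause/shrinkage")
  if (length(msg)) msg else TRUE
})

#' Construct a TipTrajectory
#'
#' @param time sampling times (s), strictly increasing.
#' @param position tip positions (µm), non-negative.
#' @param state optional per-sample state labels.
#' @param metadata optional provenance list.
#' @return A [TipTrajectory-class] object.
#' @export
TipTrajectory <- function(time, position, state = character(0),
                          metadata = list()) {
  new("TipTrajectory", time = as.numeric(time),
      position = as.numeric(position), state = as.character(state),
      metadata = metadata)
}

#' @describeIn TipTrajectory-class sampling times in seconds
#' @param x a `TipTrajectory`
#' @export
trajTime <- function(x) x@time

#' @describeIn TipTrajectory-class tip positions in µm
#' @export
trajPosition <- function(x) x@position

#' @describeIn TipTrajectory-class per-sample ground-truth states
#' @export
trajState <- function(x) x@state

#' @describeIn TipTrajectory-class provenance metadata list
#' @export
trajMetadata <- function(x) x@metadata

setMethod("show", "TipTrajectory", function(object) {
  n <- length(object@time)
  cat("TipTrajectory with", n, "samples\n")
  if (n) {
    cat(sprintf("  time: %.3g .. %.3g s, position: %.3g .. %.3g um\n",
                object@time[1], object@time[n],
                min(object@position), max(object@position)))
    if (length(object@state))
      cat("  states:", paste(sprintf("%s=%d", names(table(object@state)),
                                     table(object@state)), collapse = ", "),
          "\n")
  }
})

#' LocalizationTable: MINFLUX localization records
#'
#' A table of single-molecule localizations with trace id, timestamp,
#' coordinates in nm and the detector channel ratio (dcr). After
#' [assignChannels()] the `channel` column holds 1, 2 or `NA` (unassigned).
#' Metadata carries simulation ground truth when produced by
#' [simulateMinflux()].
#'
#' @slot data data.frame with columns `tid`, `t`, `x`, `y`, `z`, `dcr`,
#'   `channel`.
#' @slot metadata list (ground truth, spec, seed).
#' @export
setClass("LocalizationTable",
  representation(data = "data.frame", metadata = "list"),
  prototype(metadata = list()))

setValidity("LocalizationTable", function(object) {
  msg <- character(0)
  need <- c("tid", "t", "x", "y", "z", "dcr", "channel")
  if (!all(need %in% names(object@data)))
    msg <- c(msg, paste("data must contain columns:",
                        paste(need, collapse = ", ")))
  else {
    dcr <- object@data$dcr
    if (any(dcr < -1e-12 | dcr > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "dcr values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LocalizationTable
#'
#' @param data data.frame with columns `tid`, `t`, `x`, `y`, `z`, `dcr` and
#'   optionally `channel`.
#' @param metadata optional provenance list.
#' @return A [LocalizationTable-class].
#' @export
LocalizationTable <- function(data, metadata = list()) {
  if (is.null(data$z)) data$z <- 0
  if (is.null(data$channel)) data$channel <- NA_integer_
  new("LocalizationTable", data = as.data.frame(data), metadata = metadata)
}

#' @describeIn LocalizationTable-class the localization data.frame
#' @param x a `LocalizationTable`
#' @export
locData <- function(x) x@data

#' @describeIn LocalizationTable-class number of localization records
#' @export
nLocalizations <- function(x) nrow(x@data)

#' @describeIn LocalizationTable-class provenance metadata list
#' @export
locMetadata <- function(x) x@metadata

setMethod("show", "LocalizationTable", function(object) {
  d <- object@data
  cat("LocalizationTable with", nrow(d), "localizations,",
      length(unique(d$tid)), "traces\n")
  if (nrow(d)) {
    cat(sprintf("  x: %.1f..%.1f nm, y: %.1f..%.1f nm, dcr: %.2f..%.2f\n",
                min(d$x), max(d$x), min(d$y), max(d$y),
                min(d$dcr), max(d$dcr)))
    ch <- table(factor(ifelse(is.na(d$channel), "unassigned",
                              as.character(d$channel))))
    cat("  channels:", paste(names(ch), ch, sep = "=", collapse = ", "), "\n")
  }
})

#' DensityMap: a localization count histogram on a regular grid
#'
#' Rendered MINFLUX image: localization counts per voxel on a regular 2D
#' (or 3D) grid. Voxel `[i, j]` covers the half-open coordinate interval
#' `origin + (i-1..i) * voxelSize` along x, etc. The sum over all voxels
#' equals the number of rendered localizations.
#'
#' @slot counts numeric matrix (2D) or array (3D); dimension 1 is x,
#'   dimension 2 is y.
#' @slot voxelSize voxel edge in nm.
#' @slot origin nm coordinate of the low corner of voxel `[1, 1(, 1)]`.
#' @export
setClass("DensityMap",
  representation(counts = "array", voxelSize = "numeric", origin = "numeric"))

setValidity("DensityMap", function(object) {
  msg <- character(0)
  nd <- length(dim(object@counts))
  if (!nd %in% c(2L, 3L)) msg <- c(msg, "counts must be 2D or 3D")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number")
  if (length(object@origin) != nd)
    msg <- c(msg, "origin length must match dimensionality")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn DensityMap-class voxel count array
#' @param x a `DensityMap`
#' @export
mapCounts <- function(x) x@counts

#' @describeIn DensityMap-class voxel edge length in nm
#' @export
mapVoxelSize <- function(x) x@voxelSize

#' @describeIn DensityMap-class nm coordinates of the grid origin
#' @export
mapOrigin <- function(x) x@origin

setMethod("show", "DensityMap", function(object) {
  cat("DensityMap:", paste(dim(object@counts), collapse = " x "),
      "voxels of", object@voxelSize, "nm;",
      sum(object@counts), "localizations\n")
})

#' DcrMixtureFit: two-component Gaussian mixture over dcr values
#'
#' Result of [fitDcrMixture()]: a 1D two-component Gaussian mixture fitted
#' by expectation-maximization to detector-channel-ratio values, with
#' components ordered by mean.
#'
#' @slot mu component means (mu1 < mu2).
#' @slot sigma component standard deviations (> 0).
#' @slot weight mixing weights (sum to 1).
#' @slot logLik final log-likelihood.
#' @slot nIter number of EM iterations performed.
#' @slot converged whether the log-likelihood change fell below tolerance.
#' @export
setClass("DcrMixtureFit",
  representation(mu = "numeric", sigma = "numeric", weight = "numeric",
                 logLik = "numeric", nIter = "integer",
                 converged = "logical"))

setValidity("DcrMixtureFit", function(object) {
  msg <- character(0)
  if (length(object@mu) != 2L || length(object@sigma) != 2L ||
      length(object@weight) != 2L)
    msg <- c(msg, "mu, sigma, weight must have length 2")
  else {
    if (object@mu[1] >= object@mu[2])
      msg <- c(msg, "components must be ordered mu1 < mu2")
    if (any(object@sigma <= 0)) msg <- c(msg, "sigmas must be > 0")
    if (abs(sum(object@weight) - 1) > 1e-6)
      msg <- c(msg, "weights must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DcrMixtureFit", function(object) {
  cat("DcrMixtureFit (2-component Gaussian mixture)\n")
  cat(sprintf("  comp 1: mu=%.4f sigma=%.4f w=%.3f\n",
              object@mu[1], object@sigma[1], object@weight[1]))
  cat(sprintf("  comp 2: mu=%.4f sigma=%.4f w=%.3f\n",
              object@mu[2], object@sigma[2], object@weight[2]))
  cat(sprintf("  logLik=%.2f, %d iterations, converged: %s\n",
              object@logLik, object@nIter, object@converged))
})

#' ProtofilamentSet: 3D protofilament traces at microtubule ends
#'
#' Ordered 3D point traces of terminal protofilaments, one trace per
#' (`mt_id`, `pf_id`) pair, in a microtubule frame whose axis runs along +z
#' unless an axis is supplied to the analysis functions. Simulated sets
#' from [simulateFlares()] carry per-protofilament ground truth in
#' `metadata$truth`.
#'
#' @slot points data.frame with columns `mt_id`, `pf_id`, `point_idx`,
#'   `x`, `y`, `z` (nm), ordered from lattice toward the tip.
#' @slot latticeRadius nominal lattice radius in nm (12.5 for a 13-pf MT).
#' @slot metadata list (simulation spec and ground truth).
#' @export
setClass("ProtofilamentSet",
  representation(points = "data.frame", latticeRadius = "numeric",
                 metadata = "list"),
  prototype(latticeRadius = 12.5, metadata = list()))

setValidity("ProtofilamentSet", function(object) {
  msg <- character(0)
  need <- c("mt_id", "pf_id", "point_idx", "x", "y", "z")
  if (!all(need %in% names(object@points)))
    msg <- c(msg, paste("points must contain columns:",
                        paste(need, collapse = ", ")))
  if (length(object@latticeRadius) != 1L || object@latticeRadius <= 0)
    msg <- c(msg, "latticeRadius must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a ProtofilamentSet
#'
#' @param points data.frame with columns `mt_id`, `pf_id`, `point_idx`,
#'   `x`, `y`, `z` in nm.
#' @param latticeRadius lattice radius in nm.
#' @param metadata optional provenance list.
#' @return A [ProtofilamentSet-class].
#' @export
ProtofilamentSet <- function(points, latticeRadius = 12.5,
                             metadata = list()) {
  new("ProtofilamentSet", points = as.data.frame(points),
      latticeRadius = latticeRadius, metadata = metadata)
}

#' @describeIn ProtofilamentSet-class the point table
#' @param x a `ProtofilamentSet`
#' @export
pfPoints <- function(x) x@points

#' @describeIn ProtofilamentSet-class nominal lattice radius (nm)
#' @export
pfLatticeRadius <- function(x) x@latticeRadius

#' @describeIn ProtofilamentSet-class provenance metadata list
#' @export
pfMetadata <- function(x) x@metadata

#' @describeIn ProtofilamentSet-class list of per-protofilament coordinate
#'   matrices (n x 3), named `mt.pf`, points ordered lattice to tip
#' @export
pfTraces <- function(x) {
  p <- x@points
  key <- paste(p$mt_id, p$pf_id, sep = ".")
  lapply(split(seq_len(nrow(p)), key), function(i) {
    i <- i[order(p$point_idx[i])]
    as.matrix(p[i, c("x", "y", "z")])
  })
}

setMethod("show", "ProtofilamentSet", function(object) {
  p <- object@points
  cat("ProtofilamentSet:", length(unique(p$mt_id)), "MT end(s),",
      length(unique(paste(p$mt_id, p$pf_id))), "protofilament trace(s),",
      nrow(p), "points\n")
  cat("  lattice radius:", object@latticeRadius, "nm\n")
})
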