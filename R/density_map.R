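#' Render a localization density map
#'
#' Bins localizations into voxel counts on a regular grid, the standard
#' rendering for MINFLUX data (1-nm voxels for 2D figures, 4 nm for 3D).
#' The voxel index convention is `floor((coord - origin) / voxelSize)`;
#' total counts are conserved (every rendered localization falls in
#' exactly one voxel).
#'
#' @param table a [LocalizationTable-class].
#' @param voxelSize voxel edge, nm (default 1 for 2D and 4 for 3D).
#' @param dims 2 or 3.
#' @param channel render only rows assigned to this channel (1 or 2);
#'   `NULL` renders all rows.
#' @param origin grid origin, nm (length `dims`); default: floor of the
#'   data minimum, padded by one voxel.
#' @param fieldDim number of voxels per dimension; default: tight fit plus
#'   one voxel of padding. Localizations outside an explicit field are
#'   dropped.
#' @return A [DensityMap-class].
#' @examples
#' tab <- simulateMinflux(filamentSpec(nLocalizations = 500), seed = 1)
#' renderDensity(tab, voxelSize = 1)
#' @export
renderDensity <- function(table, voxelSize = if (dims == 2) 1 else 4,
                          dims = 2, channel = NULL, origin = NULL,
                          fieldDim = NULL) {
  stopifnot(is(table, "LocalizationTable"))
  if (voxelSize <= 0) stop("voxelSize must be > 0")
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  d <- locData(table)
  if (!is.null(channel)) d <- d[!is.na(d$channel) & d$channel == channel, ]
  if (!nrow(d)) stop("no localizations selected for rendering")
  coords <- as.matrix(d[, c("x", "y", "z")[seq_len(dims)], drop = FALSE])
  if (is.null(origin))
    origin <- floor(apply(coords, 2, min) / voxelSize) * voxelSize -
      voxelSize
  idx <- floor(sweep(coords, 2, origin) / voxelSize) + 1L
  if (is.null(fieldDim)) {
    fieldDim <- apply(idx, 2, max) + 1L
  } else {
    keep <- rowSums(idx < 1L | sweep(idx, 2, fieldDim, `>`)) == 0L
    idx <- idx[keep, , drop = FALSE]
  }
  counts <- array(0, dim = fieldDim)
  lin <- idx[, 1]
  if (dims >= 2) lin <- lin + (idx[, 2] - 1L) * fieldDim[1]
  if (dims == 3) lin <- lin + (idx[, 3] - 1L) * fieldDim[1] * fieldDim[2]
  tb <- tabulate(lin, nbins = prod(fieldDim))
  counts[] <- tb
  new("DensityMap", counts = counts, voxelSize = voxelSize,
      origin = as.numeric(origin))
}

#' Maximum-intensity cross-section projection of a 3D density map
#'
#' Projects a 3D map along the filament axis over a window (default
#' 800 nm), giving the cross-section view used to inspect whether signal
#' lies inside or outside the microtubule outline.
#'
#' @param map a 3D [DensityMap-class].
#' @param axis dimension to project along (1 = x).
#' @param center window center in nm along that axis; default: field
#'   center.
#' @param window window length in nm.
#' @return 2D matrix of maximum counts.
#' @export
crossSectionProjection <- function(map, axis = 1L, center = NULL,
                                   window = 800) {
  stopifnot(is(map, "DensityMap"), length(dim(mapCounts(map))) == 3L)
  cnt <- mapCounts(map)
  vs <- mapVoxelSize(map)
  n <- dim(cnt)[axis]
  if (is.null(center)) center <- n * vs / 2
  lo <- max(1L, floor((center - window / 2) / vs) + 1L)
  hi <- min(n, ceiling((center + window / 2) / vs))
  apply(cnt, setdiff(1:3, axis), function(v) max(v[lo:hi]))
}
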