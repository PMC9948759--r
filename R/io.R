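# Plain-text and TIFF interchange for every pipeline stage.

#' Read/write tip trajectories as CSV
#'
#' CSV schema: `mt_id,time_s,position_um[,state]`. One file can hold many
#' microtubules; reading returns a named list of
#' [TipTrajectory-class] objects.
#'
#' @param path file path.
#' @return `readTipTrajectories`: named list of trajectories.
#' @export
readTipTrajectories <- function(path) {
  d <- utils::read.csv(path)
  need <- c("mt_id", "time_s", "position_um")
  if (!all(need %in% names(d)))
    stop("trace CSV must contain: ", paste(need, collapse = ", "))
  out <- lapply(split(d, d$mt_id), function(g) {
    g <- g[order(g$time_s), ]
    TipTrajectory(g$time_s, g$position_um,
                  if ("state" %in% names(g)) g$state else character(0))
  })
  out
}

#' @rdname readTipTrajectories
#' @param trajectories named list of [TipTrajectory-class] objects (or a
#'   single one).
#' @return `writeTipTrajectories`: the path, invisibly.
#' @export
writeTipTrajectories <- function(trajectories, path) {
  if (is(trajectories, "TipTrajectory"))
    trajectories <- list(`1` = trajectories)
  if (is.null(names(trajectories)))
    names(trajectories) <- seq_along(trajectories)
  rows <- lapply(names(trajectories), function(id) {
    tr <- trajectories[[id]]
    d <- data.frame(mt_id = id, time_s = trajTime(tr),
                    position_um = trajPosition(tr))
    if (length(trajState(tr))) d$state <- trajState(tr)
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read/write MINFLUX localization tables as CSV
#'
#' CSV schema: `tid,t_s,x_nm,y_nm,z_nm,dcr[,channel]`.
#'
#' @param path file path.
#' @return `readLocalizations`: a [LocalizationTable-class].
#' @export
readLocalizations <- function(path) {
  d <- utils::read.csv(path)
  need <- c("tid", "t_s", "x_nm", "y_nm", "dcr")
  if (!all(need %in% names(d)))
    stop("localization CSV must contain: ", paste(need, collapse = ", "))
  LocalizationTable(data.frame(
    tid = d$tid, t = d$t_s, x = d$x_nm, y = d$y_nm,
    z = if ("z_nm" %in% names(d)) d$z_nm else 0,
    dcr = d$dcr,
    channel = if ("channel" %in% names(d)) d$channel else NA_integer_))
}

#' @rdname readLocalizations
#' @param table a [LocalizationTable-class].
#' @return `writeLocalizations`: the path, invisibly.
#' @export
writeLocalizations <- function(table, path) {
  d <- locData(table)
  utils::write.csv(
    data.frame(tid = d$tid, t_s = d$t, x_nm = d$x, y_nm = d$y,
               z_nm = d$z, dcr = d$dcr, channel = d$channel),
    path, row.names = FALSE)
  invisible(path)
}

#' Read/write protofilament traces as CSV
#'
#' CSV schema: `mt_id,pf_id,point_idx,x_nm,y_nm,z_nm`.
#'
#' @param path file path.
#' @param latticeRadius lattice radius to attach, nm.
#' @return `readProtofilaments`: a [ProtofilamentSet-class].
#' @export
readProtofilaments <- function(path, latticeRadius = 12.5) {
  d <- utils::read.csv(path)
  need <- c("mt_id", "pf_id", "point_idx", "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(d)))
    stop("protofilament CSV must contain: ", paste(need, collapse = ", "))
  ProtofilamentSet(data.frame(mt_id = d$mt_id, pf_id = d$pf_id,
                              point_idx = d$point_idx,
                              x = d$x_nm, y = d$y_nm, z = d$z_nm),
                   latticeRadius = latticeRadius)
}

#' @rdname readProtofilaments
#' @param pfSet a [ProtofilamentSet-class].
#' @return `writeProtofilaments`: the path, invisibly.
#' @export
writeProtofilaments <- function(pfSet, path) {
  p <- pfPoints(pfSet)
  utils::write.csv(
    data.frame(mt_id = p$mt_id, pf_id = p$pf_id, point_idx = p$point_idx,
               x_nm = p$x, y_nm = p$y, z_nm = p$z),
    path, row.names = FALSE)
  invisible(path)
}

#' Read lattice annotations from CSV
#'
#' CSV schema: `tomogram_id,mt_id,length_um,n_defects,has_ilp` with
#' `has_ilp` as 0/1 or logical; suitable for [latticeSummaries()].
#'
#' @param path file path.
#' @return data.frame.
#' @export
readLatticeAnnotations <- function(path) {
  d <- utils::read.csv(path)
  d$has_ilp <- as.logical(d$has_ilp)
  d
}

#' Write an image or density map as 32-bit float TIFF
#'
#' TIFF storage covers \[0, 1\], so images with a larger dynamic range are
#' scaled by their maximum before writing (the scale factor is returned);
#' relative intensities, which all downstream analyses use, are preserved.
#'
#' @param x numeric matrix or a [DensityMap-class] (2D).
#' @param path output path.
#' @return invisibly, the scale factor by which stored values must be
#'   multiplied to recover the original intensities.
#' @export
writeImageTiff <- function(x, path) {
  if (is(x, "DensityMap")) x <- mapCounts(x)
  stopifnot(is.matrix(x))
  scale <- max(x, 1)
  tiff::writeTIFF(x / scale, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}

#' Read a grayscale TIFF image as a numeric matrix
#'
#' @param path file path.
#' @return numeric matrix (first channel if multi-channel).
#' @export
readImageTiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
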