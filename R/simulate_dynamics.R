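#' Configuration for the dynamic-instability simulator
#'
#' Parameterizes a three-state (growth / pause / shrinkage) continuous-time
#' Markov model of microtubule plus-end dynamics. Transition rates are per
#' second for the six ordered state pairs; velocities are in µm/min as
#' conventionally reported.
#'
#' @param vGrowth growth velocity, µm/min (> 0).
#' @param vShrink shrinkage velocity, µm/min (> 0; applied with negative
#'   sign).
#' @param rates named numeric vector of per-second transition rates for the
#'   six ordered pairs: `gs` (growth to shrinkage, catastrophe), `gp`
#'   (growth to pause), `pg` (pause to growth), `ps` (pause to shrinkage),
#'   `sg` (shrinkage to growth, rescue), `sp` (shrinkage to pause). Missing
#'   names default to 0.
#' @param duration total simulated time, s.
#' @param dt sampling interval of the output trajectory, s.
#' @param seedLength initial position, µm. Position is floored at 0 (the
#'   stabilized seed).
#' @param boundary what happens when a shrinking tip reaches position 0:
#'   `"reflect"` re-enters growth (non-depolymerizable seed), `"stop"`
#'   terminates the microtubule (it stays at 0, modelling a seed that
#'   disassembled).
#' @param initialState state at time 0.
#' @return A validated list of class `"DynamicsConfig"`.
#' @examples
#' cfg <- dynamicsConfig(vGrowth = 2, vShrink = 30,
#'                       rates = c(gs = 0.004, sg = 0.02, gp = 0.01,
#'                                 pg = 0.01),
#'                       duration = 600, dt = 0.5)
#' @export
dynamicsConfig <- function(vGrowth = 2, vShrink = 30,
                           rates = c(gs = 0.004, gp = 0.01, pg = 0.01,
                                     ps = 0, sg = 0.02, sp = 0),
                           duration = 600, dt = 0.5, seedLength = 0,
                           boundary = c("reflect", "stop"),
                           initialState = "growth") {
  boundary <- match.arg(boundary)
  full <- c(gs = 0, gp = 0, pg = 0, ps = 0, sg = 0, sp = 0)
  if (is.null(names(rates)) || !all(names(rates) %in% names(full)))
    stop("'rates' must be named with a subset of: ",
         paste(names(full), collapse = ", "))
  full[names(rates)] <- rates
  if (any(!is.finite(full)) || any(full < 0))
    stop("all transition rates must be finite and >= 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (duration < dt) stop("duration must be >= dt")
  if (vGrowth <= 0 || vShrink <= 0) stop("velocities must be > 0")
  if (seedLength < 0) stop("seedLength must be >= 0")
  if (!initialState %in% c("growth", "pause", "shrinkage"))
    stop("invalid initialState")
  structure(list(vGrowth = vGrowth, vShrink = vShrink, rates = full,
                 duration = duration, dt = dt, seedLength = seedLength,
                 boundary = boundary, initialState = initialState),
            class = "DynamicsConfig")
}

#' Simulate a microtubule tip trajectory
#'
#' Simulates dynamic instability as a memoryless three-state Markov chain
#' over growth, pause and shrinkage with exponential dwell times at the
#' configured rates. Position integrates `+vGrowth` during growth, 0 during
#' pause and `-vShrink` during shrinkage, and is floored at 0 (the
#' stabilized seed): a shrinking tip reaching 0 either re-enters growth
#' (`boundary = "reflect"`) or the microtubule is lost
#' (`boundary = "stop"`).
#'
#' The returned trajectory is sampled on the regular `dt` grid with the
#' ground-truth state of each sample. The exact continuous-time segment
#' record (piecewise-constant state, piecewise-linear position) is kept in
#' `trajMetadata(x)$segments`; forced boundary re-entries are marked there
#' (`forced`), which downstream frequency estimation uses to avoid counting
#' them as rescues.
#'
#' @param config a [dynamicsConfig()].
#' @param seed integer RNG seed; the same config and seed give identical
#'   trajectories. `NULL` uses the current RNG stream.
#' @return A [TipTrajectory-class] with states and metadata
#'   (`config`, `seed`, `segments`, `deathTime`).
#' @examples
#' traj <- simulateDynamics(dynamicsConfig(duration = 120), seed = 1)
#' traj
#' @export
simulateDynamics <- function(config, seed = NULL) {
  stopifnot(inherits(config, "DynamicsConfig"))
  withSeed(seed, {
    vel <- c(growth = config$vGrowth / 60, pause = 0,
             shrinkage = -config$vShrink / 60)  # um/s
    R <- matrix(0, 3, 3, dimnames = list(names(vel), names(vel)))
    r <- config$rates
    R["growth", "shrinkage"] <- r[["gs"]]
    R["growth", "pause"] <- r[["gp"]]
    R["pause", "growth"] <- r[["pg"]]
    R["pause", "shrinkage"] <- r[["ps"]]
    R["shrinkage", "growth"] <- r[["sg"]]
    R["shrinkage", "pause"] <- r[["sp"]]

    t <- 0; x <- config$seedLength; st <- config$initialState
    deathTime <- NA_real_
    t0 <- x0 <- t1 <- x1 <- numeric(0)
    states <- character(0); forced <- logical(0)
    addSeg <- function(a, b, xa, xb, s, f) {
      t0 <<- c(t0, a); t1 <<- c(t1, b); x0 <<- c(x0, xa); x1 <<- c(x1, xb)
      states <<- c(states, s); forced <<- c(forced, f)
    }
    while (t < config$duration) {
      rates <- R[st, ]
      total <- sum(rates)
      dwell <- if (total > 0) stats::rexp(1, total) else Inf
      tEnd <- min(t + dwell, config$duration)
      v <- vel[[st]]
      xEnd <- x + v * (tEnd - t)
      if (v < 0 && xEnd <= 0) {
        tHit <- t + (0 - x) / v
        addSeg(t, tHit, x, 0, st, FALSE)
        if (config$boundary == "stop") {
          deathTime <- tHit
          if (tHit < config$duration)
            addSeg(tHit, config$duration, 0, 0, "pause", FALSE)
          t <- config$duration
        } else {
          # non-depolymerizable seed: forced re-entry into growth
          t <- tHit; x <- 0; st <- "growth"
          forcedNext <- TRUE
          # mark the upcoming growth segment as boundary-forced
          rates <- R[st, ]; total <- sum(rates)
          dwell <- if (total > 0) stats::rexp(1, total) else Inf
          tEnd <- min(t + dwell, config$duration)
          xEnd <- x + vel[[st]] * (tEnd - t)
          addSeg(t, tEnd, x, xEnd, st, forcedNext)
          t <- tEnd; x <- xEnd
          if (t < config$duration)
            st <- sample(colnames(R), 1L, prob = rates / total)
        }
      } else {
        addSeg(t, tEnd, x, xEnd, st, FALSE)
        t <- tEnd; x <- xEnd
        if (t < config$duration && total > 0)
          st <- sample(colnames(R), 1L, prob = rates / total)
        else if (total == 0) t <- config$duration
      }
    }
    segs <- data.frame(t0 = t0, t1 = t1, x0 = x0, x1 = x1,
                       state = states, forced = forced)
    segs <- segs[segs$t1 > segs$t0, , drop = FALSE]

    grid <- seq(0, config$duration, by = config$dt)
    # sample position and state from the continuous record
    idx <- findInterval(grid, segs$t0, rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L
    frac <- (grid - segs$t0[idx]) /
      pmax(segs$t1[idx] - segs$t0[idx], .Machine$double.eps)
    pos <- segs$x0[idx] + frac * (segs$x1[idx] - segs$x0[idx])
    pos <- pmax(pos, 0)
    TipTrajectory(grid, pos, segs$state[idx],
                  metadata = list(config = config, seed = seed,
                                  segments = segs, deathTime = deathTime))
  })
}

#' Render a kymograph image from a tip trajectory
#'
#' Builds a space-time image the way kymographs are produced from a movie:
#' each row is one line-scan at successive times, each column one spatial
#' pixel. The tip appears as a Gaussian ridge of standard deviation
#' `psfSigma` pixels centred at the tip position; the ridge is evaluated
#' within 5 sigma and is exactly zero outside, so a noiseless,
#' background-free kymograph has zero pixels away from the trace.
#'
#' @param traj a [TipTrajectory-class].
#' @param pixelSize spatial pixel size, µm/px.
#' @param lineTime time per row, s.
#' @param psfSigma ridge standard deviation in pixels.
#' @param amplitude ridge peak intensity, a.u.
#' @param background constant background level, a.u.
#' @param noiseSd additive Gaussian noise SD, a.u.
#' @param nCols number of columns; defaults to the trajectory's maximum
#'   position plus a margin.
#' @param seed RNG seed for the noise.
#' @return numeric matrix, rows = time, columns = position.
#' @export
renderKymograph <- function(traj, pixelSize, lineTime, psfSigma = 1.5,
                            amplitude = 100, background = 0, noiseSd = 0,
                            nCols = NULL, seed = NULL) {
  stopifnot(is(traj, "TipTrajectory"))
  if (pixelSize <= 0 || lineTime <= 0)
    stop("pixelSize and lineTime must be > 0")
  tt <- trajTime(traj); px <- trajPosition(traj)
  if (length(tt) < 2L || (max(tt) - min(tt)) < lineTime)
    stop("trajectory shorter than one kymograph row")
  rowT <- seq(min(tt), max(tt), by = lineTime)
  xr <- stats::approx(tt, px, xout = rowT)$y / pixelSize  # in px units
  if (is.null(nCols)) nCols <- ceiling(max(xr) + 5 * psfSigma + 2)
  img <- matrix(background, nrow = length(rowT), ncol = nCols)
  centers <- seq_len(nCols) - 0.5
  win <- 5 * psfSigma
  for (i in seq_along(rowT)) {
    d <- centers - xr[i]
    inWin <- abs(d) <= win
    img[i, inWin] <- img[i, inWin] +
      amplitude * exp(-d[inWin]^2 / (2 * psfSigma^2))
  }
  if (noiseSd > 0)
    img <- withSeed(seed, img + matrix(stats::rnorm(length(img), 0, noiseSd),
                                       nrow = nrow(img)))
  pmax(img, 0)
}
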