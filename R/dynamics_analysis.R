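#' Event-classification thresholds for tip traces
#'
#' Thresholds used to classify traced tip-trajectory segments and to filter
#' sub-threshold events, following the conventions of in vitro MT dynamics
#' assays: segments with velocity faster than `vMin` (strictly) are growth,
#' faster shrinkage than `-vMin` are shrinkage, anything in between is a
#' pause. Only growth/shrinkage excursions longer than `minGrowthLength`
#' and pauses longer than `minPauseDuration` enter the statistics.
#'
#' @param vMin velocity cutoff, µm/min. Default 0.24.
#' @param minGrowthLength minimum growth/shrinkage excursion, µm.
#'   Default 0.40.
#' @param minPauseDuration minimum pause duration, s. Default 20.
#' @return A list of class `"DynamicsThresholds"`.
#' @export
dynamicsThresholds <- function(vMin = 0.24, minGrowthLength = 0.40,
                               minPauseDuration = 20) {
  if (vMin <= 0 || minGrowthLength < 0 || minPauseDuration < 0)
    stop("vMin must be > 0 and filter lengths >= 0")
  structure(list(vMin = vMin, minGrowthLength = minGrowthLength,
                 minPauseDuration = minPauseDuration),
            class = "DynamicsThresholds")
}

#' Classify a traced tip trajectory into growth/pause/shrinkage events
#'
#' Classifies each inter-vertex segment of a traced tip polyline by its
#' velocity (µm/min): strictly greater than `vMin` is growth, strictly less
#' than `-vMin` is shrinkage, otherwise pause. Consecutive segments of the
#' same class are merged into events. Events failing the length/duration
#' filters are kept in the table with `included = FALSE`; they are absorbed
#' into the preceding included event when building the contiguous timeline
#' (see [collapseEvents()]), so the timeline stays gap-free and
#' transition-frequency denominators remain well defined.
#'
#' @param time vertex times, s, strictly increasing; or a
#'   [TipTrajectory-class] (then `position` is ignored).
#' @param position vertex positions, µm.
#' @param thresholds a [dynamicsThresholds()].
#' @return data.frame (one row per event): `state`, `t_start`, `t_end`,
#'   `x_start`, `x_end`, `duration_s`, `length_um`, `velocity_um_min`,
#'   `included`.
#' @examples
#' ev <- classifyEvents(c(0, 60, 120, 180), c(0, 0.5, 0, 0.01))
#' ev$state
#' @export
classifyEvents <- function(time, position = NULL,
                           thresholds = dynamicsThresholds()) {
  if (is(time, "TipTrajectory")) {
    position <- trajPosition(time)
    time <- trajTime(time)
  }
  stopifnot(inherits(thresholds, "DynamicsThresholds"))
  if (length(time) < 2L) stop("need at least 2 vertices")
  dtv <- diff(time)
  if (any(dtv < 0)) stop("times must be monotone increasing")
  if (any(dtv == 0)) stop("duplicate timestamps in trace")
  v <- diff(position) / dtv * 60  # um/min
  cls <- ifelse(v > thresholds$vMin, "growth",
                ifelse(v < -thresholds$vMin, "shrinkage", "pause"))
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ev <- data.frame(
    state = r$values,
    t_start = time[starts], t_end = time[ends + 1L],
    x_start = position[starts], x_end = position[ends + 1L])
  ev$duration_s <- ev$t_end - ev$t_start
  ev$length_um <- abs(ev$x_end - ev$x_start)
  ev$velocity_um_min <- (ev$x_end - ev$x_start) / ev$duration_s * 60
  ev$included <- ifelse(
    ev$state == "pause",
    ev$duration_s > thresholds$minPauseDuration,
    ev$length_um > thresholds$minGrowthLength)
  ev
}

#' Collapse an event table into a contiguous included-event timeline
#'
#' Absorbs sub-threshold (`included = FALSE`) events into the preceding
#' included event; excluded events before the first included one are
#' absorbed into it. Adjacent events that end up in the same state are then
#' merged. The absorbed intervals keep contributing their time to the
#' absorbing event's state, so state-time denominators cover the full
#' record.
#'
#' @param events an event table from [classifyEvents()].
#' @return data.frame with `state`, `t_start`, `t_end`, `x_start`, `x_end`,
#'   `duration_s`.
#' @export
collapseEvents <- function(events) {
  stopifnot(nrow(events) >= 1L)
  if (!any(events$included)) {
    # degenerate record: no event passes the filters; report the whole
    # record as one event of the state holding the most time
    byState <- tapply(events$duration_s, events$state, sum)
    s <- names(byState)[which.max(byState)]
    return(data.frame(state = s, t_start = events$t_start[1],
                      t_end = events$t_end[nrow(events)],
                      x_start = events$x_start[1],
                      x_end = events$x_end[nrow(events)],
                      duration_s = events$t_end[nrow(events)] -
                        events$t_start[1]))
  }
  firstInc <- which(events$included)[1L]
  owner <- integer(nrow(events))
  cur <- firstInc
  for (i in seq_len(nrow(events))) {
    if (events$included[i]) cur <- i
    owner[i] <- if (i < firstInc) firstInc else cur
  }
  owners <- unique(owner)           # in time order: groups are contiguous
  grp <- match(owner, owners)
  iFirst <- as.integer(tapply(seq_along(owner), grp, min))
  iLast <- as.integer(tapply(seq_along(owner), grp, max))
  out <- data.frame(state = events$state[owners],
                    t_start = events$t_start[iFirst],
                    t_end = events$t_end[iLast],
                    x_start = events$x_start[iFirst],
                    x_end = events$x_end[iLast])
  # merge adjacent same-state stretches
  keep <- c(TRUE, out$state[-1] != head(out$state, -1))
  grp <- cumsum(keep)
  merged <- data.frame(
    state = tapply(out$state, grp, `[`, 1L),
    t_start = as.numeric(tapply(out$t_start, grp, min)),
    t_end = as.numeric(tapply(out$t_end, grp, max)),
    x_start = as.numeric(tapply(out$x_start, grp, `[`, 1L)),
    x_end = as.numeric(tapply(out$x_end, grp, function(z) z[length(z)])))
  merged$duration_s <- merged$t_end - merged$t_start
  rownames(merged) <- NULL
  merged
}

statePairs <- function() {
  s <- c("growth", "pause", "shrinkage")
  p <- expand.grid(from = s, to = s, stringsAsFactors = FALSE)
  p[p$from != p$to, ]
}

#' Transition counts and frequencies between dynamic states
#'
#' Counts transitions between consecutive events of the collapsed timeline
#' and converts them to frequencies by dividing by the total time the
#' source state was occupied (i.e. the time each transition "could have
#' occurred"), or optionally by the total observation time. States never
#' occupied yield `NA` frequencies (flagged as undefined rather than 0).
#'
#' For trajectories with a stabilized seed, a shrinkage-to-growth switch
#' occurring at the seed (position at `boundaryFloor`) is a forced
#' re-entry, not a rescue; with `boundaryFloor` set, such transitions are
#' censored: the shrinkage time still counts in the denominator but no
#' rescue event is scored, which keeps the estimator unbiased for the
#' underlying rescue rate.
#'
#' @param events an event table from [classifyEvents()], or a list of such
#'   tables (one per microtubule) to pool.
#' @param denominator `"state"` (time in the source state, default) or
#'   `"total"` (total observation time).
#' @param boundaryFloor position (µm) of the seed floor, or `NULL` to count
#'   every observed transition.
#' @param boundaryTol tolerance (µm) for identifying a transition as
#'   occurring at the floor.
#' @return list with `counts` (named 6-vector), `frequencies` (per-second,
#'   named, `NA` where undefined), `timeInState`, `totalTime`,
#'   `undefined` (names of flagged frequencies).
#' @examples
#' ev <- classifyEvents(c(0, 200, 202, 400, 402),
#'                      c(0, 4, 3, 7, 6))
#' transitionFrequencies(ev)$frequencies["growth_shrinkage"]
#' @export
transitionFrequencies <- function(events,
                                  denominator = c("state", "total"),
                                  boundaryFloor = NULL,
                                  boundaryTol = 1e-6) {
  denominator <- match.arg(denominator)
  if (is.data.frame(events)) events <- list(events)
  pairs <- statePairs()
  keys <- paste(pairs$from, pairs$to, sep = "_")
  counts <- stats::setNames(numeric(nrow(pairs)), keys)
  timeInState <- c(growth = 0, pause = 0, shrinkage = 0)
  totalTime <- 0
  for (ev in events) {
    cl <- collapseEvents(ev)
    tis <- tapply(cl$duration_s, cl$state, sum)
    timeInState[names(tis)] <- timeInState[names(tis)] + tis
    totalTime <- totalTime + sum(cl$duration_s)
    n <- nrow(cl)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        from <- cl$state[i]; to <- cl$state[i + 1L]
        if (!is.null(boundaryFloor) && from == "shrinkage" &&
            to == "growth" &&
            cl$x_end[i] <= boundaryFloor + boundaryTol) next
        key <- paste(from, to, sep = "_")
        counts[key] <- counts[key] + 1
      }
    }
  }
  denom <- if (denominator == "state")
    timeInState[pairs$from] else rep(totalTime, nrow(pairs))
  freq <- ifelse(denom > 0, counts / denom, NA_real_)
  names(freq) <- keys
  list(counts = counts, frequencies = freq, timeInState = timeInState,
       totalTime = totalTime, undefined = keys[is.na(freq)])
}

#' Summary statistics of microtubule plus-end dynamics
#'
#' Pools classified events from one or more microtubules into the summary
#' usually reported for dynamic-instability assays: mean growth rate and
#' pause duration with SEM over included events, the fraction of time spent
#' in each state over the contiguous timeline (sums to 1), transition
#' counts and frequencies, and the event/microtubule tallies.
#'
#' Event statistics (growth rate, pause duration) are computed from the
#' included events as classified, before sub-threshold neighbours are
#' absorbed, so absorbed intervals do not dilute event velocities; they do
#' contribute their time to the state fractions and frequency denominators.
#'
#' @param events an event table or a list of event tables (one per MT).
#' @param denominator,boundaryFloor passed to [transitionFrequencies()].
#' @return list with `growthRate` (mean, sem, n), `pauseDuration`
#'   (mean, sem, n), `stateFractions` (3-vector summing to 1),
#'   `transitions` (result of [transitionFrequencies()]), `nMTs`.
#' @export
summarizeDynamics <- function(events, denominator = "state",
                              boundaryFloor = NULL) {
  if (is.data.frame(events)) events <- list(events)
  all <- do.call(rbind, events)
  g <- all[all$state == "growth" & all$included, , drop = FALSE]
  p <- all[all$state == "pause" & all$included, , drop = FALSE]
  tr <- transitionFrequencies(events, denominator = denominator,
                              boundaryFloor = boundaryFloor)
  fr <- tr$timeInState / sum(tr$timeInState)
  list(
    growthRate = list(mean = if (nrow(g)) mean(g$velocity_um_min) else
                        NA_real_,
                      sem = semOf(g$velocity_um_min), n = nrow(g)),
    pauseDuration = list(mean = if (nrow(p)) mean(p$duration_s) else
                           NA_real_,
                         sem = semOf(p$duration_s), n = nrow(p)),
    stateFractions = fr,
    transitions = tr,
    nMTs = length(events))
}

#' Seed survival percentage
#'
#' Fraction (as a percentage) of microtubule seeds whose length never
#' reaches 0 before the horizon, the standard readout for seed
#' stabilization assays (horizon 300 s = 5 min).
#'
#' @param trajectories list of [TipTrajectory-class] objects (typically
#'   simulated with `boundary = "stop"` and a positive `seedLength`).
#' @param horizon observation horizon, s.
#' @return list with `percent`, `nSurvived`, `n`, and `partial` (TRUE when
#'   some record ends before the horizon, in which case survival is
#'   assessed over the available record and flagged).
#' @export
seedSurvival <- function(trajectories, horizon = 300) {
  stopifnot(length(trajectories) >= 1L)
  partial <- FALSE
  died <- vapply(trajectories, function(tr) {
    stopifnot(is(tr, "TipTrajectory"))
    tt <- trajTime(tr)
    if (max(tt) < horizon) partial <<- TRUE
    dt <- trajMetadata(tr)$deathTime
    if (!is.null(dt) && !is.na(dt)) return(dt <= horizon)
    any(trajPosition(tr)[tt <= horizon] <= 0)
  }, logical(1))
  list(percent = 100 * mean(!died), nSurvived = sum(!died),
       n = length(died), partial = partial)
}
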