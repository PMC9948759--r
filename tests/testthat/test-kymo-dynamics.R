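test_that("segment velocities classify with a strict 0.24 um/min cutoff", {
  # velocities +0.50, -0.50, +0.10 um/min -> growth, shrinkage, pause
  ev <- classifyEvents(c(0, 60, 120, 180),
                       c(0, 0.5, 0, 0.01))
  expect_identical(ev$state, c("growth", "shrinkage", "pause"))
  # exactly 0.24 um/min is a pause ("faster than" is strict);
  # over a 60-s segment the velocity in um/min equals the displacement
  evB <- classifyEvents(c(0, 60), c(0, 0.24))
  expect_identical(evB$state, "pause")
  evC <- classifyEvents(c(0, 60), c(0, 0.241))
  expect_identical(evC$state, "growth")
})

test_that("a 15-s pause flanked by growth is absorbed into one growth event", {
  # growth 0-100 s, pause 100-115 s, growth 115-215 s
  tt <- c(0, 100, 115, 215)
  xx <- c(0, 1.0, 1.0, 2.0)
  ev <- classifyEvents(tt, xx)
  expect_identical(ev$state, c("growth", "pause", "growth"))
  expect_false(ev$included[2])
  cl <- collapseEvents(ev)
  expect_identical(cl$state, "growth")
  expect_equal(cl$t_start, 0)
  expect_equal(cl$t_end, 215)
})

test_that("a 0.30-um growth excursion is excluded from statistics", {
  tt <- c(0, 100, 130, 230)
  xx <- c(0.5, 0.5, 0.8, 0.8)   # pause, +0.30 um growth, pause
  ev <- classifyEvents(tt, xx)
  g <- ev[ev$state == "growth", ]
  expect_equal(nrow(g), 1L)
  expect_false(g$included)
})

test_that("a single vertex pair at velocity zero is one pause event", {
  ev <- classifyEvents(c(0, 30), c(1, 1))
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$state, "pause")
})

test_that("non-monotone or duplicate timestamps are rejected", {
  expect_error(classifyEvents(c(0, 10, 5), c(0, 1, 2)), "monotone")
  expect_error(classifyEvents(c(0, 10, 10), c(0, 1, 2)), "duplicate")
})

test_that("transition frequencies divide counts by source-state time", {
  # 2 growth->shrinkage transitions over 400 s of growth: 0.005 per s
  tt <- c(0, 200, 202, 402, 404)
  xx <- c(0, 4, 3, 7, 6)
  ev <- classifyEvents(tt, xx)
  tf <- transitionFrequencies(ev)
  expect_equal(unname(tf$counts["growth_shrinkage"]), 2)
  expect_equal(unname(tf$timeInState["growth"]), 400)
  expect_equal(unname(tf$frequencies["growth_shrinkage"]), 0.005)
})

test_that("states with zero occupancy yield undefined frequencies", {
  ev <- classifyEvents(c(0, 100, 130), c(0, 1, 1))  # growth then pause
  ev$included <- TRUE
  tf <- transitionFrequencies(ev)
  expect_true(all(c("shrinkage_growth", "shrinkage_pause") %in%
                    tf$undefined))
  expect_true(is.na(tf$frequencies["shrinkage_growth"]))
  expect_false(is.na(tf$frequencies["growth_pause"]))
})

test_that("total-time denominator option divides by the whole record", {
  tt <- c(0, 200, 202, 402, 404)
  xx <- c(0, 4, 3, 7, 6)
  ev <- classifyEvents(tt, xx)
  tf <- transitionFrequencies(ev, denominator = "total")
  expect_equal(unname(tf$frequencies["growth_shrinkage"]), 2 / 404)
})

test_that("state fractions follow hand computation and sum to one", {
  # growth 60 s, pause 30 s, shrinkage 10 s -> fractions 0.6/0.3/0.1
  tt <- c(0, 60, 90, 100)
  xx <- c(0, 1, 1, 0.5)
  ev <- classifyEvents(tt, xx)
  ev$included <- TRUE   # keep the short shrinkage in the timeline
  sm <- summarizeDynamics(ev)
  expect_equal(unname(sm$stateFractions[c("growth", "pause",
                                          "shrinkage")]),
               c(0.6, 0.3, 0.1))
  expect_equal(sum(sm$stateFractions), 1, tolerance = 1e-9)
})

test_that("single growth event has defined mean but undefined SEM", {
  ev <- classifyEvents(c(0, 60), c(0, 1.2))
  sm <- summarizeDynamics(ev)
  expect_equal(sm$growthRate$mean, 1.2)
  expect_true(is.na(sm$growthRate$sem))
  expect_equal(sm$growthRate$n, 1L)
})

test_that("inserting collinear vertices does not change the event table", {
  tt <- c(0, 100, 115, 215)
  xx <- c(0, 1.0, 1.0, 2.0)
  ev1 <- classifyEvents(tt, xx)
  # refine each segment with interior collinear points
  tt2 <- sort(unique(c(tt, 50, 107.5, 160)))
  xx2 <- approx(tt, xx, xout = tt2)$y
  ev2 <- classifyEvents(tt2, xx2)
  expect_equal(ev1$state, ev2$state)
  expect_equal(ev1$t_start, ev2$t_start)
  expect_equal(ev1$x_end, ev2$x_end)
  expect_equal(ev1$included, ev2$included)
})

test_that("analyzer recovers simulated transition rates (round trip)", {
  cfg <- dynamicsConfig(vGrowth = 2, vShrink = 30,
                        rates = c(gs = 0.004, sg = 0.02, gp = 0.01,
                                  pg = 0.01),
                        duration = 2000, dt = 0.5)
  thr0 <- dynamicsThresholds(vMin = 0.24, minGrowthLength = 1e-9,
                             minPauseDuration = 1e-9)
  evs <- lapply(1:40, function(i)
    classifyEvents(simulateDynamics(cfg, seed = 400 + i),
                   thresholds = thr0))
  tol <- 30 / 60 * 0.5 + 0.05
  tf <- transitionFrequencies(evs, boundaryFloor = 0, boundaryTol = tol)
  truth <- c(growth_pause = 0.01, growth_shrinkage = 0.004,
             pause_growth = 0.01, shrinkage_growth = 0.02)
  for (k in names(truth)) {
    src <- sub("_.*", "", k)
    se <- sqrt(max(tf$counts[k], 1)) / tf$timeInState[src]
    expect_lt(abs(tf$frequencies[k] - truth[k]), 3 * se)
  }
})

test_that("doubling simulator rates doubles recovered frequencies", {
  run <- function(mult, seeds) {
    cfg <- dynamicsConfig(vGrowth = 2, vShrink = 30,
                          rates = c(gs = 0.004, sg = 0.02, gp = 0.01,
                                    pg = 0.01) * mult,
                          duration = 2000, dt = 0.5)
    thr0 <- dynamicsThresholds(minGrowthLength = 1e-9,
                               minPauseDuration = 1e-9)
    evs <- lapply(seeds, function(i)
      classifyEvents(simulateDynamics(cfg, seed = i), thresholds = thr0))
    transitionFrequencies(evs, boundaryFloor = 0,
                          boundaryTol = 0.3)$frequencies
  }
  f1 <- run(1, 600 + 1:40)
  f2 <- run(2, 700 + 1:40)
  r <- f2["growth_pause"] / f1["growth_pause"]
  expect_equal(unname(r), 2, tolerance = 0.35)
})

test_that("seed survival percentage counts seeds that never reach zero", {
  mk <- function(dies) {
    cfg <- dynamicsConfig(vGrowth = 2, vShrink = 30,
                          rates = if (dies) c(gs = 10) else c(gs = 0),
                          duration = 400, dt = 1, seedLength = 0.5,
                          boundary = "stop")
    simulateDynamics(cfg, seed = if (dies) 1 else 2)
  }
  all0 <- replicate(4, mk(TRUE), simplify = FALSE)
  expect_equal(seedSurvival(all0, horizon = 300)$percent, 0)
  all100 <- replicate(4, mk(FALSE), simplify = FALSE)
  expect_equal(seedSurvival(all100, horizon = 300)$percent, 100)
  half <- c(all0[1:2], all100[1:2])
  expect_equal(seedSurvival(half, horizon = 300)$percent, 50)
  # horizon beyond the record is flagged partial
  expect_true(seedSurvival(all100, horizon = 500)$partial)
})
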