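test_that("density rendering follows the floor convention and conserves counts", {
  tab <- LocalizationTable(data.frame(tid = 1, t = 1, x = 10.4, y = 20.7,
                                      z = 0, dcr = 0.5))
  m <- renderDensity(tab, voxelSize = 1, origin = c(0, 0))
  w <- which(mapCounts(m) == 1, arr.ind = TRUE)
  # voxel index floor(10.4), floor(20.7) -> matrix position [11, 21]
  expect_equal(unname(w[1, ]), c(11L, 21L))
  expect_equal(sum(mapCounts(m)), 1)
  # two localizations in one voxel accumulate
  tab2 <- LocalizationTable(data.frame(tid = 1, t = 1:2, x = c(5.1, 5.9),
                                       y = c(3.2, 3.8), z = 0, dcr = 0.5))
  m2 <- renderDensity(tab2, voxelSize = 1, origin = c(0, 0))
  expect_equal(max(mapCounts(m2)), 2)
  # conservation at scale
  tab3 <- simulateMinflux(filamentSpec(nLocalizations = 1234), seed = 9)
  expect_equal(sum(mapCounts(renderDensity(tab3, voxelSize = 1))), 1234)
})

test_that("channel selection filters rendering input", {
  d <- data.frame(tid = 1, t = 1:4, x = c(1, 2, 3, 4), y = 1, z = 0,
                  dcr = c(0.2, 0.2, 0.9, 0.9),
                  channel = c(1L, 1L, 2L, NA))
  tab <- LocalizationTable(d)
  expect_equal(sum(mapCounts(renderDensity(tab, channel = 1))), 2)
  expect_equal(sum(mapCounts(renderDensity(tab, channel = 2))), 1)
  expect_error(renderDensity(LocalizationTable(d[0, ])), "no localizations")
})

test_that("3D rendering uses 4-nm voxels and supports cross-sections", {
  tab <- simulateMinflux(filamentSpec(labelingMode = "surface", dims = 3,
                                      sigmaZ = 3.5,
                                      nLocalizations = 3000), seed = 10)
  m <- renderDensity(tab, dims = 3)
  expect_equal(mapVoxelSize(m), 4)
  expect_equal(length(dim(mapCounts(m))), 3L)
  expect_equal(sum(mapCounts(m)), 3000)
  cs <- crossSectionProjection(m, axis = 1, window = 800)
  expect_true(is.matrix(cs))
})

test_that("empty maps yield no centerlines", {
  m <- new("DensityMap", counts = array(0, c(50, 50)), voxelSize = 1,
           origin = c(0, 0))
  expect_length(extractCenterlines(m), 0)
})

test_that("a straight filament gives one centerline close to the true axis", {
  tab <- simulateMinflux(filamentSpec(polyline = cbind(c(0, 800),
                                                       c(0, 0)),
                                      nLocalizations = 2000), seed = 21)
  # sparse field: the filament occupies ~2% of the area, matching the
  # default threshold quantile
  map <- renderDensity(tab, voxelSize = 1, origin = c(-30, -500),
                       fieldDim = c(860, 1000))
  cls <- extractCenterlines(map, minLength = 300)
  expect_equal(length(cls), 1L)
  # maximum deviation from the true axis (y = 0) within one voxel... the
  # spline-refined line should track it closely
  expect_lt(max(abs(cls[[1]][, 2])), 1.5)
})

test_that("two parallel filaments yield two matched centerlines", {
  mk <- function(y0, seed) {
    simulateMinflux(filamentSpec(polyline = cbind(c(0, 800),
                                                  c(y0, y0)),
                                 nLocalizations = 2000), seed = seed)
  }
  d <- rbind(locData(mk(0, 31)), locData(mk(200, 32)))
  tab <- LocalizationTable(d)
  map <- renderDensity(tab, voxelSize = 1, origin = c(-30, -400),
                       fieldDim = c(860, 1000))
  # two filaments double the occupied fraction, so the threshold
  # quantile follows (see the methods vignette)
  cls <- extractCenterlines(map, minLength = 300,
                            thresholdQuantile = 0.96)
  expect_equal(length(cls), 2L)
  my <- sort(vapply(cls, function(m) mean(m[, 2]), numeric(1)))
  expect_lt(abs(my[1] - 0), 2)
  expect_lt(abs(my[2] - 200), 2)
})

test_that("profile FWHM matches the closed form for a Gaussian profile", {
  # construct a map holding an exact (discretized) Gaussian ridge
  x <- seq(-30.5, 30.5, 1)
  prof <- dnorm(x, 0, 3) * 1e4
  counts <- matrix(rep(prof, each = 200), nrow = 200, byrow = FALSE)
  m <- new("DensityMap", counts = counts, voxelSize = 1,
           origin = c(0, -31))
  wp <- filamentFWHM(m, cbind(c(0, 200), c(0, 0)), maxDist = 25,
                     smoothSigma = 0)
  expect_equal(wp$fwhm, 2 * sqrt(2 * log(2)) * 3, tolerance = 0.04)
})

test_that("profiles without a half-maximum crossing are flagged", {
  # intensity keeps rising to the window edge: the peak bin is the last
  # one, so the tip-side crossing does not exist
  y <- rep(seq(-9, 9, 1), times = 1:19)
  d <- data.frame(tid = 1, t = seq_along(y), x = seq_along(y) %% 50,
                  y = y, z = 0, dcr = 0.5)
  wp <- filamentFWHM(LocalizationTable(d), cbind(c(-1, 50), c(0, 0)),
                     maxDist = 9, smoothSigma = 0)
  expect_true(is.na(wp$fwhm))
})

test_that("FWHM is invariant under rigid rotation and translation", {
  base <- filamentSpec(polyline = cbind(c(0, 800), c(0, 0)),
                       nLocalizations = 2000)
  tab <- simulateMinflux(base, seed = 41)
  d <- locData(tab)
  ang <- 35 * pi / 180
  rot <- data.frame(tid = d$tid, t = d$t,
                    x = cos(ang) * d$x - sin(ang) * d$y + 300,
                    y = sin(ang) * d$x + cos(ang) * d$y - 150,
                    z = d$z, dcr = d$dcr)
  fw <- function(dd, cl) {
    tb <- LocalizationTable(dd)
    mp <- renderDensity(tb, voxelSize = 1)
    filamentFWHM(mp, cl)$fwhm
  }
  f0 <- fw(d, cbind(c(0, 800), c(0, 0)))
  p2 <- cbind(cos(ang) * c(0, 800) + 300, sin(ang) * c(0, 800) - 150)
  f1 <- fw(rot, p2)
  expect_lt(abs(f0 - f1), 1)
})

test_that("FWHM grows monotonically with localization error", {
  fwAt <- function(sigma, seed) {
    tab <- simulateMinflux(filamentSpec(polyline = cbind(c(0, 800),
                                                         c(0, 0)),
                                        sigmaXY = sigma,
                                        nLocalizations = 3000),
                           seed = seed)
    map <- renderDensity(tab, voxelSize = 1)
    filamentFWHM(map, cbind(c(0, 800), c(0, 0)))$fwhm
  }
  f <- c(fwAt(2, 51), fwAt(3.5, 52), fwAt(5, 53))
  expect_true(all(diff(f) > 0))
})

test_that("raw-localization profiles agree with map-based profiles", {
  tab <- simulateMinflux(filamentSpec(polyline = cbind(c(0, 800),
                                                       c(0, 0)),
                                      nLocalizations = 3000), seed = 61)
  cl <- cbind(c(0, 800), c(0, 0))
  fMap <- filamentFWHM(renderDensity(tab, voxelSize = 1), cl)$fwhm
  fRaw <- filamentFWHM(tab, cl)$fwhm
  expect_lt(abs(fMap - fRaw), 0.8)
})
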