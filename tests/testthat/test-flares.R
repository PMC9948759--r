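test_that("traces that never leave the cylinder are blunt", {
  tr <- cbind(12.5, 0, seq(0, 48, 4))
  dp <- findDeflectionPoint(tr)
  expect_equal(dp$index, nrow(tr))
  expect_true(dp$blunt)
  fm <- flareMetrics(tr, dp$index)
  expect_equal(fm$flareLength, 0)
})

test_that("a constructed departure at a known index is found", {
  # on-lattice for 7 points, then a sustained radial excess > tol
  r <- c(rep(12.5, 6), seq(15, 27, 3))
  tr <- cbind(r, 0, seq(0, by = 4, length.out = length(r)))
  dp <- findDeflectionPoint(tr, latticeRadius = 12.5, tol = 1.5)
  expect_equal(dp$index, 7L)
  expect_false(dp$blunt)
})

test_that("transient noise excursions do not trigger deflection", {
  # one spike above tol followed by a return to the lattice
  r <- c(12.5, 12.5, 14.5, 12.5, 12.5, seq(15, 24, 3))
  tr <- cbind(r, 0, seq(0, by = 4, length.out = length(r)))
  dp <- findDeflectionPoint(tr, tol = 1.5)
  expect_equal(dp$index, 6L)
})

test_that("false-deflection rate is below 1% for noisy straight traces", {
  set.seed(30)
  n <- 1000
  false_pos <- vapply(seq_len(n), function(i) {
    z <- seq(0, 60, 4)
    tr <- cbind(12.5, 0, z) +
      matrix(rnorm(3 * length(z), 0, 0.5), ncol = 3)  # noise = tol/3
    !findDeflectionPoint(tr, tol = 1.5)$blunt
  }, logical(1))
  expect_lt(mean(false_pos), 0.01)
})

test_that("flare metrics match circular-arc geometry", {
  # straight 24-nm flare: zero curvature over the flare itself
  tr <- rbind(cbind(12.5, 0, seq(-40, 0, 4)),
              cbind(12.5 + seq(4, 24, 4), 0, 0))
  fm <- flareMetrics(tr, 11)
  expect_equal(fm$flareLength, 24)
  expect_equal(fm$totalCurvature, 0, tolerance = 1e-9)
  expect_equal(fm$terminalCurvature, 0, tolerance = 1e-9)
  # the canonical check: a 90-degree arc of radius 100 nm
  th <- seq(0, pi / 2, length.out = 200)
  arc <- cbind(100 * (1 - cos(th)), 0, 100 * sin(th))
  fmA <- flareMetrics(arc, 1)
  expect_equal(fmA$totalCurvature, 90, tolerance = 0.01)
  expect_equal(fmA$flareLength, 100 * pi / 2, tolerance = 1e-3)
  # terminal curvature of constant-curvature arc: 8/100 rad = 4.58 deg/8nm
  # (vertex counting at the window edge is worth a few percent)
  expect_equal(fmA$terminalCurvature, 8 / 100 * 180 / pi,
               tolerance = 0.05)
})

test_that("flare metrics are invariant under rigid motion", {
  pf <- simulateFlares(flareSimSpec(nEnds = 1, noiseSd = 0), seed = 12)
  tr <- pfTraces(pf)[[3]]
  fm0 <- flareMetrics(tr, 10)
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0),
             c(sin(ang), cos(ang), 0),
             c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0),
              c(0, cos(0.3), -sin(0.3)),
              c(0, sin(0.3), cos(0.3)))
  trR <- tr %*% t(R) %*% t(R2) + matrix(rep(c(5, -3, 11), each = nrow(tr)),
                                        ncol = 3)
  fm1 <- flareMetrics(trR, 10)
  expect_equal(fm0$flareLength, fm1$flareLength, tolerance = 1e-9)
  expect_equal(fm0$totalCurvature, fm1$totalCurvature, tolerance = 1e-9)
  expect_equal(fm0$terminalCurvature, fm1$terminalCurvature,
               tolerance = 1e-9)
})

test_that("simulator round trip recovers flare length and curvature", {
  pf <- simulateFlares(flareSimSpec(nEnds = 5, curvatureMean = 4.58,
                                    curvatureSd = 0, flareLengthMean = 40,
                                    flareLengthSd = 0, raggednessSd = 0,
                                    noiseSd = 0), seed = 13)
  tru <- pfMetadata(pf)$truth
  traces <- pfTraces(pf)
  key <- paste(tru$mt_id, tru$pf_id, sep = ".")
  for (k in names(traces)[1:10]) {
    i <- match(k, key)
    fm <- flareMetrics(traces[[k]], tru$deflection_index[i])
    expect_equal(fm$flareLength, tru$flare_length[i], tolerance = 0.05)
    expect_equal(fm$terminalCurvature, tru$curvature_deg_per_8nm[i],
                 tolerance = 0.05)
  }
})

test_that("deflection detection matches generator truth without noise", {
  pf <- simulateFlares(flareSimSpec(nEnds = 3, noiseSd = 0), seed = 2)
  tru <- pfMetadata(pf)$truth
  traces <- pfTraces(pf)
  key <- paste(tru$mt_id, tru$pf_id, sep = ".")
  det <- vapply(names(traces), function(k)
    findDeflectionPoint(traces[[k]], 12.5, tol = 1e-9)$index, 0L)
  expect_equal(unname(det),
               tru$first_off_index[match(names(traces), key)])
})

test_that("raggedness follows the sample-SD definition", {
  tr <- lapply(c(0, 0, 0), makeKinkedTrace)
  er <- endRaggedness(tr, tol = 1e-9)
  expect_equal(er$ends$raggedness_nm, 0)
  tr2 <- lapply(c(0, 8, 16), makeKinkedTrace)
  er2 <- endRaggedness(tr2, tol = 1e-9)
  expect_equal(er2$ends$raggedness_nm, 8)
  # raggedness is undefined for a single protofilament
  er1 <- endRaggedness(tr2[1], tol = 1e-9)
  expect_true(is.na(er1$ends$raggedness_nm))
})

test_that("raggedness is translation invariant and scales linearly", {
  tr <- lapply(c(0, 8, 16), makeKinkedTrace)
  shifted <- lapply(tr, function(m) sweep(m, 2, c(0, 0, -100)))
  expect_equal(endRaggedness(shifted, tol = 1e-9)$ends$raggedness_nm, 8)
  scaled <- lapply(c(0, 16, 32), function(z)
    makeKinkedTrace(z, R = 25, kappa = 0.005, spacing = 8,
                    latticeLen = 80, arcLen = 80))
  expect_equal(endRaggedness(scaled, latticeRadius = 25,
                             tol = 1e-9)$ends$raggedness_nm, 16)
})

test_that("simulated raggedness is recovered across many ends", {
  pf <- simulateFlares(flareSimSpec(nEnds = 40, raggednessSd = 12),
                       seed = 31)
  er <- endRaggedness(pf)
  expect_equal(mean(er$ends$raggedness_nm), 12, tolerance = 0.10)
})

test_that("lattice summaries pool per tomogram with sample SD", {
  ann <- data.frame(tomogram_id = c(1, 1, 2, 2, 2),
                    mt_id = 1:5,
                    length_um = c(2, 2, 1, 1, 2),
                    n_defects = c(1, 1, 0, 2, 0),
                    has_ilp = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  ls <- latticeSummaries(ann)
  p <- ls$perTomogram
  expect_equal(p$defects_per_um[p$tomogram_id == 1], 0.5)
  expect_equal(p$pct_ilp[p$tomogram_id == 1], 50)
  # two tomograms at 20% and 40%: mean 30, SD 14.14
  ann2 <- data.frame(tomogram_id = rep(1:2, each = 5), mt_id = 1:10,
                     length_um = 1, n_defects = 0,
                     has_ilp = c(TRUE, rep(FALSE, 4),
                                 TRUE, TRUE, rep(FALSE, 3)))
  ls2 <- latticeSummaries(ann2)
  expect_equal(unname(ls2$pctIlp["mean"]), 30)
  expect_equal(unname(ls2$pctIlp["sd"]), sd(c(20, 40)), tolerance = 1e-9)
  expect_error(latticeSummaries(ann[, -3]), "must contain")
})
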