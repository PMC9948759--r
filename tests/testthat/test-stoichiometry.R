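test_that("lognormal MLE recovers the mode with its closed form", {
  set.seed(20)
  x <- exp(rnorm(1e4, log(100), 0.3))
  fit <- fitLognormalMode(x)
  expect_equal(fit$mode, 100 * exp(-0.09), tolerance = 0.03)
  expect_equal(fit$n, 1e4)
  # scale equivariance is exact
  fit2 <- fitLognormalMode(3 * x)
  expect_equal(fit2$mode, 3 * fit$mode, tolerance = 1e-12)
  # sigma -> 0 limit
  fit0 <- fitLognormalMode(rep(50, 30) * exp(rnorm(30, 0, 1e-8)))
  expect_equal(fit0$mode, 50, tolerance = 1e-6)
})

test_that("non-positive or undersized intensity samples are rejected", {
  expect_error(fitLognormalMode(c(rep(1, 40), -1)), "positive")
  expect_error(fitLognormalMode(rep(1, 10)), "at least 30")
})

test_that("molecules per 8 nm follows the normalization arithmetic", {
  expect_equal(moleculesPer8nm(1000, 80, 12.5), 8)
  expect_equal(moleculesPer8nm(0, 80, 12.5), 0)
  # doubling the length halves the result exactly
  expect_equal(moleculesPer8nm(1000, 160, 12.5),
               moleculesPer8nm(1000, 80, 12.5) / 2)
  expect_error(moleculesPer8nm(10, 0, 1), "lengthNm")
  expect_error(moleculesPer8nm(10, 8, 0), "singleMean")
})

test_that("initial binding ratio calls monomers and dimers correctly", {
  set.seed(21)
  single <- exp(rnorm(2000, log(80), 0.3))
  # identical distribution: ratio 1, monomer
  r1 <- initialBindingRatio(single, single)
  expect_equal(r1$ratio, 1)
  expect_true(r1$monomer)
  # dimer arrivals at 0.8 z-attenuation: ratio ~ 1.6, not a monomer
  dimer <- 2 * 0.8 * exp(rnorm(2000, log(80), 0.3))
  r2 <- initialBindingRatio(dimer, single)
  expect_equal(r2$ratio, 1.6, tolerance = 0.05)
  expect_false(r2$monomer)
  # attenuated monomer: ratio ~0.8 uncorrected, monomer after correction
  mono <- 0.8 * exp(rnorm(2000, log(80), 0.3))
  r3 <- initialBindingRatio(mono, single, zAttenuation = 0.8)
  expect_equal(r3$ratio, 0.8, tolerance = 0.05)
  expect_equal(r3$corrected, 1, tolerance = 0.05)
  expect_true(r3$monomer)
})

test_that("one-phase association is exact on noiseless model data", {
  t <- seq(0, 60, 2)
  y <- 1 + (2 - 1) * (1 - exp(-0.1 * t))
  fit <- fitOnePhaseAssociation(t, y)
  expect_equal(fit$I0, 1, tolerance = 1e-6)
  expect_equal(fit$plateau, 2, tolerance = 1e-6)
  expect_equal(fit$k, 0.1, tolerance = 1e-6)
  expect_lt(fit$residualRMS, 1e-8)
  # monotone increasing data implies plateau >= I0
  y2 <- cumsum(runif(20, 0, 0.1))
  fit2 <- fitOnePhaseAssociation(seq_along(y2), y2)
  expect_gte(fit2$plateau, fit2$I0)
  expect_error(fitOnePhaseAssociation(1:3, 1:3), "at least 5")
})

test_that("simulated traces round-trip through the association fit", {
  sim <- simulateIntensityTraces(
    intensitySimSpec(plateau = 2, kAssoc = 0.1, sigmaLog = 0.35,
                     nTraces = 300, traceLength = 60, noiseSd = 2),
    seed = 7)
  singleMean <- mean(sim$single)
  mt <- aggregate(intensity ~ t_s, sim$traces, mean)
  fit <- fitOnePhaseAssociation(mt$t_s, mt$intensity / singleMean)
  expect_lt(abs(fit$plateau - 2), 0.15)
  expect_lt(abs(fit$k - 0.1) / 0.1, 0.10)
  # molecule units are scale invariant: rescale all intensities by c
  fitScaled <- fitOnePhaseAssociation(
    mt$t_s, (mt$intensity * 7.3) / (singleMean * 7.3))
  expect_equal(fit$plateau, fitScaled$plateau, tolerance = 1e-9)
})

test_that("initial binding of simulated monomer traces is one molecule", {
  sim <- simulateIntensityTraces(
    intensitySimSpec(plateau = 2, kAssoc = 0.1, sigmaLog = 0.35,
                     nTraces = 80, traceLength = 30), seed = 8)
  first <- sim$traces$intensity[sim$traces$t_s == 0]
  r <- initialBindingRatio(first, sim$single)
  expect_true(r$monomer)
  expect_equal(r$ratio, 1, tolerance = 0.15)
})

test_that("Hill alignment uses K as the half-maximum reference", {
  t <- seq(0, 50, 0.5)
  hill <- function(t, K, n) t^n / (K^n + t^n)
  p1 <- data.frame(t = t, intensity = hill(t, 10, 2))
  p2 <- data.frame(t = t, intensity = hill(t, 15, 2))
  ap <- alignProfiles(list(p1, p2))
  expect_equal(ap$references, c(10, 15), tolerance = 1e-3)
  # identical profiles shifted by 5 s align pointwise with zero SEM;
  # the logistic family is shift equivariant, so the alignment is exact
  # even though the underlying shape is not a logistic
  p3 <- data.frame(t = t + 5, intensity = hill(t, 10, 2))
  ap2 <- alignProfiles(list(p1, p3), model = "sigmoid")
  expect_lt(max(ap2$sem, na.rm = TRUE), 1e-6)
})

test_that("alignment is idempotent within one sample interval", {
  t <- seq(0, 50, 0.5)
  hill <- function(t, K, n) t^n / (K^n + t^n)
  p1 <- data.frame(t = t, intensity = hill(t, 10, 2) +
                     0.01 * sin(t))
  p2 <- data.frame(t = t, intensity = hill(t, 16, 1.8) +
                     0.01 * cos(t))
  # the logistic family handles the negative times of aligned profiles
  # (the Hill form is only defined for t >= 0)
  ap <- alignProfiles(list(p1, p2), model = "sigmoid")
  aligned <- list(
    data.frame(t = p1$t - ap$references[1], intensity = p1$intensity),
    data.frame(t = p2$t - ap$references[2], intensity = p2$intensity))
  ap2 <- alignProfiles(aligned, model = "sigmoid")
  expect_lt(max(abs(ap2$references)), 0.5)
})

test_that("rectangle profiles integrate to their width", {
  expect_equal(profileAUC(c(0, 1), c(1, 1)), 1)
  expect_equal(profileAUC(c(0, 2), c(3, 3)), 2)  # normalized height 1
})

test_that("unfittable profiles are excluded and reported", {
  t <- seq(0, 50, 0.5)
  hill <- function(t, K, n) t^n / (K^n + t^n)
  good1 <- data.frame(t = t, intensity = hill(t, 10, 2))
  good2 <- data.frame(t = t, intensity = hill(t, 12, 2))
  bad <- data.frame(t = c(0, 1), intensity = c(1, 1))
  ap <- suppressWarnings(alignProfiles(list(good1, bad, good2)))
  expect_equal(ap$excluded, 2L)
  expect_equal(ap$n, 2L)
})
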