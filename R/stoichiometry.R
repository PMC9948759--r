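# Single-molecule intensity stoichiometry: lognormal calibration,
# molecule counting, association kinetics and profile alignment.

#' Lognormal fit of a single-fluorophore intensity sample
#'
#' Closed-form maximum-likelihood lognormal fit on the log-transformed
#' intensities. The modal value, `exp(mu - sigma^2)`, is the brightness
#' reference used for molecule counting; sample quartiles are reported as
#' plotted alongside intensity histograms.
#'
#' @param x positive intensity sample, n >= 30.
#' @return list of class `"LognormalFit"`: `muLog`, `sigmaLog` (MLE,
#'   denominator n), `mode`, `quartiles`, `n`.
#' @examples
#' set.seed(1)
#' f <- fitLognormalMode(exp(rnorm(1000, log(100), 0.3)))
#' f$mode          # close to exp(log(100) - 0.09)
#' @export
fitLognormalMode <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("intensities must be positive and finite")
  if (length(x) < 30L) stop("need at least 30 intensities")
  lx <- log(x)
  mu <- mean(lx)
  sig <- sqrt(mean((lx - mu)^2))
  structure(list(muLog = mu, sigmaLog = sig, mode = exp(mu - sig^2),
                 quartiles = stats::quantile(x, c(0.25, 0.5, 0.75)),
                 n = length(x)),
            class = "LognormalFit")
}

#' Molecules per 8 nm of accumulation length
#'
#' Converts an integrated accumulation intensity to a molecule count per
#' tubulin-dimer layer: the integrated intensity is divided by the average
#' single-fluorophore intensity and normalized to an 8-nm accumulation
#' length (one alpha/beta-tubulin layer).
#'
#' @param integrated integrated accumulation intensity, a.u. (>= 0).
#' @param lengthNm accumulation length, nm (> 0).
#' @param singleMean average single-fluorophore intensity, a.u. (> 0).
#' @return molecules per 8 nm.
#' @examples
#' moleculesPer8nm(1000, 80, 12.5)  # 8 molecules per 8 nm
#' @export
moleculesPer8nm <- function(integrated, lengthNm, singleMean) {
  if (lengthNm <= 0) stop("lengthNm must be > 0")
  if (singleMean <= 0) stop("singleMean must be > 0")
  if (any(integrated < 0)) stop("integrated intensity must be >= 0")
  (integrated / singleMean) * (8 / lengthNm)
}

# internal: lognormal mode of a sample without the calibration-size gate
lognormalModeOf <- function(x) {
  lx <- log(x)
  mu <- mean(lx); sig2 <- mean((lx - mu)^2)
  exp(mu - sig2)
}

#' Initial-binding intensity ratio and monomer call
#'
#' Compares the modal intensity of molecules upon initial binding to a
#' filament with the modal single-fluorophore intensity measured on the
#' coverslip. Filament-bound molecules sit higher in the evanescent field,
#' so their signal is attenuated; an optional multiplicative
#' `zAttenuation` correction (about 0.8 in typical TIRF geometries) can be
#' applied before calling the oligomeric state. The molecule is called a
#' monomer when the (corrected) ratio falls within `band`.
#'
#' @param onFilament intensities of initial binding events on the
#'   filament, a.u.
#' @param single single-fluorophore intensity sample, a.u.
#' @param zAttenuation attenuation factor to divide out (1 = no
#'   correction).
#' @param band inclusive ratio band for a monomer call.
#' @return list: `ratio` (uncorrected), `corrected`, `monomer` (logical),
#'   `modeOnFilament`, `modeSingle`.
#' @export
initialBindingRatio <- function(onFilament, single, zAttenuation = 1,
                                band = c(0.6, 1.3)) {
  if (!length(onFilament) || !length(single))
    stop("both samples must be non-empty")
  if (any(onFilament <= 0) || any(single <= 0))
    stop("intensities must be positive")
  mOn <- lognormalModeOf(onFilament)
  mSingle <- lognormalModeOf(single)
  ratio <- mOn / mSingle
  corrected <- ratio / zAttenuation
  list(ratio = ratio, corrected = corrected,
       monomer = corrected >= band[1] && corrected <= band[2],
       modeOnFilament = mOn, modeSingle = mSingle)
}

#' One-phase association fit
#'
#' Least-squares fit of the one-phase association model
#' `I(t) = I0 + (plateau - I0) * (1 - exp(-k t))` to a mean intensity time
#' course (conventionally in molecule units, i.e. intensity divided by the
#' single-fluorophore reference).
#'
#' @param t time, s (>= 5 points).
#' @param intensity observed intensities.
#' @return list of class `"AssociationFit"`: `I0`, `plateau`, `k`,
#'   `residualRMS`, `converged`, and `fitted` values.
#' @examples
#' t <- 0:30
#' y <- 1 + (2 - 1) * (1 - exp(-0.1 * t))
#' fitOnePhaseAssociation(t, y)$k
#' @export
fitOnePhaseAssociation <- function(t, intensity) {
  if (length(t) < 5L) stop("need at least 5 time points")
  if (length(t) != length(intensity)) stop("length mismatch")
  df <- data.frame(t = t, y = intensity)
  i0 <- intensity[which.min(t)]
  pl <- mean(intensity[t >= stats::quantile(t, 0.8)])
  k0 <- 1 / max(max(t) / 3, .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 + (P - I0) * (1 - exp(-k * t)), data = df,
                      start = list(I0 = i0, P = pl, k = k0),
                      lower = c(-Inf, -Inf, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(I0 = NA_real_, plateau = NA_real_, k = NA_real_,
                          residualRMS = NA_real_, converged = FALSE,
                          fitted = rep(NA_real_, length(t))),
                     class = "AssociationFit"))
  cf <- stats::coef(fit)
  structure(list(I0 = unname(cf["I0"]), plateau = unname(cf["P"]),
                 k = unname(cf["k"]),
                 residualRMS = sqrt(mean(stats::residuals(fit)^2)),
                 converged = TRUE, fitted = stats::fitted(fit)),
            class = "AssociationFit")
}

#' Normalized area under an intensity profile
#'
#' Trapezoidal integral of the max-normalized profile on its native time
#' grid, the summary used to compare accumulation time courses.
#'
#' @param t time, s.
#' @param intensity intensities (normalized to `max(intensity)` first).
#' @return the AUC.
#' @examples
#' profileAUC(c(0, 1), c(1, 1))   # unit rectangle: 1
#' @export
profileAUC <- function(t, intensity) {
  if (length(t) < 2L || length(t) != length(intensity))
    stop("need matching t/intensity vectors of length >= 2")
  trapezoid(t, intensity / max(intensity))
}

# fit one normalized profile with the chosen sigmoid family and return the
# half-maximum reference time
fitProfileReference <- function(t, yN, model) {
  if (model == "hill") {
    tPos <- pmax(t, .Machine$double.eps)
    k0 <- t[which.min(abs(yN - 0.5))]
    if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(tPos)
    fit <- minpack.lm::nlsLM(
      yN ~ Imax * tPos^n / (K^n + tPos^n),
      data = data.frame(tPos = tPos, yN = yN),
      start = list(Imax = 1, K = k0, n = 2),
      lower = c(0.2, 1e-6, 0.5), upper = c(2, Inf, 8),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    unname(stats::coef(fit)["K"])   # Hill half-maximum time is K
  } else {
    t0 <- t[which.min(abs(yN - 0.5))]
    fit <- minpack.lm::nlsLM(
      yN ~ Imax / (1 + exp(-(t - t0f) / s)),
      data = data.frame(t = t, yN = yN),
      start = list(Imax = 1, t0f = t0,
                   s = max(diff(range(t)) / 10, 1e-6)),
      lower = c(0.2, -Inf, 1e-6), upper = c(2, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    unname(stats::coef(fit)["t0f"])
  }
}

#' Align intensity profiles at their half-maximum reference and average
#'
#' Each profile is normalized to its maximum and fitted with a Hill curve
#' `I(t) = Imax t^n / (K^n + t^n)` (or a generic logistic sigmoid); the
#' time of half-maximal effective intensity (the Hill `K`, or the logistic
#' midpoint) serves as the alignment reference. Profiles are shifted so
#' the references coincide at 0, interpolated onto a common grid, and
#' averaged with SEM. The normalized area under the curve (AUC) of each
#' profile is computed by trapezoidal integration on its native grid.
#'
#' @param profiles list of data.frames with columns `t` and `intensity`
#'   (>= 2 profiles).
#' @param model `"hill"` or `"sigmoid"`.
#' @return list: `grid` (aligned time), `mean`, `sem`, `references`
#'   (per-profile half-maximum time, `NA` for excluded fits), `auc`
#'   (per-profile normalized AUC), `excluded` (indices of profiles whose
#'   fit failed), `n` used.
#' @export
alignProfiles <- function(profiles, model = c("hill", "sigmoid")) {
  model <- match.arg(model)
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  refs <- rep(NA_real_, length(profiles))
  auc <- rep(NA_real_, length(profiles))
  norm <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    yN <- p$intensity / max(p$intensity)
    norm[[i]] <- data.frame(t = p$t, y = yN)
    auc[i] <- trapezoid(p$t, yN)
    refs[i] <- tryCatch(fitProfileReference(p$t, yN, model),
                        error = function(e) NA_real_)
  }
  ok <- which(!is.na(refs))
  if (length(ok) < 2L) stop("fewer than 2 profiles could be fitted")
  shifted <- lapply(ok, function(i)
    data.frame(t = norm[[i]]$t - refs[i], y = norm[[i]]$y))
  lo <- max(vapply(shifted, function(d) min(d$t), numeric(1)))
  hi <- min(vapply(shifted, function(d) max(d$t), numeric(1)))
  if (hi <= lo) stop("aligned profiles do not overlap")
  step <- stats::median(unlist(lapply(shifted, function(d) diff(d$t))))
  grid <- seq(lo, hi, by = step)
  mat <- vapply(shifted, function(d)
    stats::approx(d$t, d$y, xout = grid)$y, numeric(length(grid)))
  list(grid = grid,
       mean = rowMeans(mat),
       sem = apply(mat, 1, semOf),
       references = refs, auc = auc,
       excluded = setdiff(seq_along(profiles), ok),
       n = length(ok))
}
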