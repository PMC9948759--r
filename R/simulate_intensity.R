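#' Specification for simulated single-molecule intensity traces
#'
#' Emulates the structure of fluorescence-intensity time courses of
#' molecules accumulating on a filament: each trace starts with one
#' molecule at t = 0 and additional molecules arrive so that the expected
#' molecule number follows the one-phase association law
#' `1 + (plateau - 1) * (1 - exp(-k t))`. Per-molecule brightness is drawn
#' from a lognormal single-fluorophore distribution; filament-bound signal
#' is attenuated by `zAttenuation` (evanescent-field drop-off in TIRF). A
#' separate sample of unattenuated single-fluorophore intensities (the
#' coverslip calibration chamber) is generated alongside.
#'
#' @param muLog,sigmaLog natural-log parameters of single-fluorophore
#'   brightness (a.u.).
#' @param plateau asymptotic expected molecule number (>= 1).
#' @param kAssoc association rate constant, 1/s.
#' @param zAttenuation multiplicative attenuation of filament-bound signal,
#'   in (0, 1].
#' @param frameInterval s between frames.
#' @param nTraces number of traces.
#' @param traceLength frames per trace.
#' @param noiseSd additive Gaussian noise SD (a.u.).
#' @param nSingle size of the single-fluorophore calibration sample.
#' @return list of class `"IntensitySimSpec"`.
#' @export
intensitySimSpec <- function(muLog = log(100), sigmaLog = 0.35,
                             plateau = 2, kAssoc = 0.1, zAttenuation = 1,
                             frameInterval = 1, nTraces = 54,
                             traceLength = 60, noiseSd = 0,
                             nSingle = 5000) {
  if (sigmaLog < 0) stop("sigmaLog must be >= 0")
  if (plateau < 1) stop("plateau must be >= 1")
  if (kAssoc < 0) stop("kAssoc must be >= 0")
  if (zAttenuation <= 0 || zAttenuation > 1)
    stop("zAttenuation must be in (0, 1]")
  if (frameInterval <= 0 || nTraces < 1 || traceLength < 2)
    stop("invalid trace geometry")
  structure(list(muLog = muLog, sigmaLog = sigmaLog, plateau = plateau,
                 kAssoc = kAssoc, zAttenuation = zAttenuation,
                 frameInterval = frameInterval, nTraces = nTraces,
                 traceLength = traceLength, noiseSd = noiseSd,
                 nSingle = nSingle),
            class = "IntensitySimSpec")
}

#' Simulate single-molecule intensity traces and a calibration sample
#'
#' See [intensitySimSpec()] for the model. The number of late-arriving
#' molecules per trace is `floor(plateau - 1)` plus a Bernoulli draw of the
#' fractional part (so the expectation is exact and integer plateaus give
#' deterministic molecule counts); each arrival is delayed by an
#' exponential time with rate `kAssoc`.
#'
#' @param spec an [intensitySimSpec()].
#' @param seed RNG seed.
#' @return list with `traces` (data.frame `trace_id`, `t_s`, `intensity`,
#'   `n_molecules` ground truth), `single` (numeric sample of unattenuated
#'   single-fluorophore intensities), and `spec`.
#' @examples
#' sim <- simulateIntensityTraces(intensitySimSpec(nTraces = 5), seed = 1)
#' head(sim$traces)
#' @export
simulateIntensityTraces <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "IntensitySimSpec"))
  withSeed(seed, {
    tGrid <- (seq_len(spec$traceLength) - 1L) * spec$frameInterval
    extraMean <- spec$plateau - 1
    out <- vector("list", spec$nTraces)
    for (i in seq_len(spec$nTraces)) {
      nExtra <- floor(extraMean) +
        stats::rbinom(1L, 1L, extraMean - floor(extraMean))
      arrivals <- if (nExtra > 0 && spec$kAssoc > 0)
        stats::rexp(nExtra, spec$kAssoc)
      else rep(Inf, nExtra)          # k = 0: extra molecules never arrive
      bright <- exp(stats::rnorm(nExtra + 1L, spec$muLog, spec$sigmaLog)) *
        spec$zAttenuation
      arrivalTimes <- c(0, arrivals)
      nMol <- vapply(tGrid, function(tt) sum(arrivalTimes <= tt), 0L)
      intensity <- vapply(tGrid, function(tt)
        sum(bright[arrivalTimes <= tt]), numeric(1))
      if (spec$noiseSd > 0)
        intensity <- intensity + stats::rnorm(length(tGrid), 0,
                                              spec$noiseSd)
      out[[i]] <- data.frame(trace_id = i, t_s = tGrid,
                             intensity = intensity, n_molecules = nMol)
    }
    single <- exp(stats::rnorm(spec$nSingle, spec$muLog, spec$sigmaLog))
    list(traces = do.call(rbind, out), single = single, spec = spec)
  })
}
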