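#' Fit a two-component Gaussian mixture to dcr values
#'
#' Fits a linear mixture of two Gaussians to detector-channel-ratio values
#' by expectation-maximization. Initialization is deterministic (no random
#' restarts): the sample is split at its median, each half providing the
#' initial mean and SD, with equal weights; EM then iterates until the
#' log-likelihood improves by less than `tol` or `maxIter` is reached.
#' Components are returned ordered by mean.
#'
#' @param dcr numeric vector of dcr values in \[0, 1\], length >= 50.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param maxIter maximum EM iterations.
#' @return A [DcrMixtureFit-class].
#' @examples
#' set.seed(1)
#' d <- c(rnorm(500, 0.3, 0.05), rnorm(500, 0.8, 0.05))
#' fitDcrMixture(pmin(pmax(d, 0), 1))
#' @export
fitDcrMixture <- function(dcr, tol = 1e-8, maxIter = 500L) {
  dcr <- as.numeric(dcr)
  if (length(dcr) < 50L) stop("need at least 50 dcr values")
  if (any(dcr < 0 | dcr > 1)) stop("dcr values must lie in [0, 1]")
  if (stats::sd(dcr) == 0) stop("degenerate dcr sample: all values identical")

  med <- stats::median(dcr)
  lo <- dcr[dcr <= med]; hi <- dcr[dcr > med]
  if (!length(hi)) { hi <- lo }     # heavy ties at the median
  sigFloor <- 1e-4
  mu <- c(mean(lo), mean(hi))
  sig <- pmax(c(stats::sd(lo), stats::sd(hi)), sigFloor)
  sig[is.na(sig)] <- sigFloor
  w <- c(0.5, 0.5)

  ll <- -Inf; converged <- FALSE; iter <- 0L
  for (iter in seq_len(maxIter)) {
    d1 <- w[1] * stats::dnorm(dcr, mu[1], sig[1])
    d2 <- w[2] * stats::dnorm(dcr, mu[2], sig[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    newLL <- sum(log(tot))
    if (is.finite(ll) && abs(newLL - ll) < tol) {
      ll <- newLL; converged <- TRUE; break
    }
    ll <- newLL
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- length(dcr) - n1
    mu <- c(sum(g1 * dcr) / n1, sum((1 - g1) * dcr) / n2)
    sig <- pmax(c(sqrt(sum(g1 * (dcr - mu[1])^2) / n1),
                  sqrt(sum((1 - g1) * (dcr - mu[2])^2) / n2)), sigFloor)
    w <- c(n1, n2) / length(dcr)
  }
  ord <- order(mu)
  new("DcrMixtureFit", mu = mu[ord], sigma = sig[ord], weight = w[ord],
      logLik = ll, nIter = iter, converged = converged)
}

#' Assign localizations to detector channels from a dcr mixture fit
#'
#' Applies the cut-off rule used for two-channel MINFLUX data: a
#' localization belongs to channel 1 when its dcr lies in
#' \[0, mu1 + 0.5 sigma1\] and to channel 2 when it lies in
#' \[mu2 - 0.5 sigma2, 1\]; both intervals are closed at their finite
#' endpoints. Everything in between stays unassigned (`NA`) and is excluded
#' from rendering.
#'
#' @param table a [LocalizationTable-class].
#' @param fit a [DcrMixtureFit-class].
#' @return the table with its `channel` column filled (1, 2 or `NA`).
#' @export
assignChannels <- function(table, fit) {
  stopifnot(is(table, "LocalizationTable"), is(fit, "DcrMixtureFit"))
  hi1 <- fit@mu[1] + 0.5 * fit@sigma[1]
  lo2 <- fit@mu[2] - 0.5 * fit@sigma[2]
  if (hi1 >= lo2)
    stop("channel cutoffs overlap (mu1 + 0.5*sigma1 >= mu2 - 0.5*sigma2): ",
         "mixture unusable for channel assignment")
  d <- locData(table)
  d$channel <- ifelse(d$dcr <= hi1, 1L, ifelse(d$dcr >= lo2, 2L,
                                               NA_integer_))
  initialize(table, data = d)
}

#' Per-axis localization precision from repeated localizations
#'
#' Estimates localization precision from fluorophore burst statistics:
#' each trace id with more than `minGroup - 1` successive localizations
#' (default: greater than four, i.e. at least five) contributes its
#' per-axis sample SD; the histogram of those SDs is summarized by its
#' modal value per axis.
#'
#' @param table a [LocalizationTable-class].
#' @param minGroup minimum localizations per group (default 5).
#' @param binWidth histogram bin width in nm for the modal estimate.
#' @return list with `groups` (data.frame `tid`, `n`, `sdX`, `sdY`, `sdZ`),
#'   `modal` (named vector of modal SDs per axis, nm), `empty` flag.
#' @export
localizationPrecision <- function(table, minGroup = 5L, binWidth = 0.25) {
  stopifnot(is(table, "LocalizationTable"))
  d <- locData(table)
  sp <- split(d, d$tid)
  sp <- sp[vapply(sp, nrow, 0L) >= minGroup]
  if (!length(sp))
    return(list(groups = data.frame(), modal = c(x = NA_real_,
                                                 y = NA_real_),
                empty = TRUE))
  groups <- data.frame(
    tid = vapply(sp, function(g) g$tid[1], numeric(1)),
    n = vapply(sp, nrow, 0L),
    sdX = vapply(sp, function(g) stats::sd(g$x), numeric(1)),
    sdY = vapply(sp, function(g) stats::sd(g$y), numeric(1)),
    sdZ = vapply(sp, function(g) stats::sd(g$z), numeric(1)))
  modalOf <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    br <- seq(0, max(v) + binWidth, by = binWidth)
    h <- hist(v, breaks = br, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
  list(groups = groups,
       modal = c(x = modalOf(groups$sdX), y = modalOf(groups$sdY),
                 z = modalOf(groups$sdZ)),
       empty = FALSE)
}
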