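# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# standard error of the mean with sample SD (ddof = 1); NA for n < 2
semOf <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# shift a matrix by (di, dj) with replicated borders
shiftMat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dj, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# shift with zero padding (for binary morphology)
shiftMat0 <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1L, 1L + di):min(nr, nr + di)
  cs <- max(1L, 1L + dj):min(nc, nc + dj)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - di, cs - dj, drop = FALSE]
  out
}

# trapezoidal area under y(x)
trapezoid <- function(x, y) pracma::trapz(x, y)

# linear interpolation of the x where y crosses `level` between two samples
crossingAt <- function(x1, x2, y1, y2, level) {
  if (y2 == y1) return((x1 + x2) / 2)
  x1 + (level - y1) / (y2 - y1) * (x2 - x1)
}

# 8-connected (or 4-connected) labeling of a logical matrix.
# Flood fill over foreground pixels; returns an integer matrix of labels
# (0 = background). Intended for sparse masks (comet images, skeletons).
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    off <- cbind(di = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                 dj = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    off <- cbind(di = c(-1L, 0L, 0L, 1L), dj = c(0L, -1L, 1L, 0L))
  }
  fg <- which(mask)
  current <- 0L
  for (p in fg) {
    if (lab[p] != 0L) next
    current <- current + 1L
    stack <- p
    lab[p] <- current
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      qi <- ((q - 1L) %% nr) + 1L
      qj <- ((q - 1L) %/% nr) + 1L
      ni <- qi + off[, "di"]
      nj <- qj + off[, "dj"]
      ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      idx <- (nj[ok] - 1L) * nr + ni[ok]
      idx <- idx[mask[idx] & lab[idx] == 0L]
      if (length(idx)) {
        lab[idx] <- current
        stack <- c(stack, idx)
      }
    }
  }
  lab
}

# Gaussian smoothing of a 1D profile with zero padding; sigma in samples.
smoothProfile <- function(p, sigma) {
  if (sigma <= 0) return(p)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  padded <- c(rep(0, half), p, rep(0, half))
  sm <- as.numeric(stats::filter(padded, k, sides = 2))
  sm[(half + 1L):(half + length(p))]
}
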