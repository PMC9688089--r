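# Internal numerical helpers shared across modules.

# Legendre polynomial basis P_0..P_degree evaluated on u in [-1, 1].
# Columns are orthogonal on the continuous interval; well conditioned for
# the baseline orders used here (<= ~8).
legendre_basis <- function(u, degree) {
  stopifnot(degree >= 0)
  B <- matrix(0, length(u), degree + 1L)
  B[, 1L] <- 1
  if (degree >= 1L) B[, 2L] <- u
  if (degree >= 2L)
    for (k in 2:degree)
      B[, k + 1L] <- ((2 * k - 1) * u * B[, k] - (k - 1) * B[, k - 1L]) / k
  colnames(B) <- paste0("P", 0:degree)
  B
}

# Map a wavenumber axis onto [-1, 1].
rescale_unit <- function(w) {
  r <- range(w)
  if (r[1] == r[2]) return(rep(0, length(w)))
  2 * (w - r[1]) / (r[2] - r[1]) - 1
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Run code with the global RNG state restored afterwards.
with_preserved_rng <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Otsu's threshold on a numeric image/vector (256-bin histogram): the cut
# maximizing between-class variance.  Used to segment band-intensity images.
#' Otsu threshold of an intensity image
#'
#' Computes the histogram threshold that maximizes between-class variance,
#' for segmenting band-intensity maps into signal and background.
#'
#' @param x numeric vector or matrix of intensities (NAs ignored).
#' @param n_bins number of histogram bins.
#' @return the threshold value (numeric scalar).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values")
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[n_bins]
  tot_mu <- mu[n_bins]
  # between-class variance at each candidate cut
  valid <- w > 0 & w < tot_w
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (tot_mu * w[valid] - tot_w * mu[valid])^2 /
    (w[valid] * (tot_w - w[valid]))
  breaks[which.max(bcv) + 1L]
}
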