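#' Iterative peak-excluding polynomial baseline removal
#'
#' Removes the broad fluorescence background by Vancouver-style modified
#' polynomial fitting: a polynomial of degree `order` is least-squares fitted
#' to the spectrum (on the wavenumber axis rescaled to \[-1, 1\]), the noise
#' level is estimated from the residuals lying below the fit, every intensity
#' exceeding `fit + noise` is clamped to that bound (peak removal), and the
#' fit is repeated until the baseline stabilizes.  The corrected spectrum is
#' the original minus the final baseline; small negative values are retained
#' (no clipping) so that downstream least squares stays unbiased.
#'
#' @param set a [spectrum_set] (or a single numeric vector together with
#'   `wavenumber`).
#' @param order polynomial degree (default 5).
#' @param max_iter maximum number of refit iterations (default 100).
#' @param tol convergence tolerance: relative change of the fitted baseline
#'   in max-norm (default 1e-4).
#' @param wavenumber wavenumber axis, only needed when `set` is a bare vector.
#' @return a list with `corrected` (same shape as the input) and `fits`, a
#'   per-spectrum list of baseline fit results (`order`, `coefficients` in the
#'   Legendre basis, `baseline`, `iterations`, `converged`, `noise_estimate`).
#' @export
vancouver_baseline <- function(set, order = 5L, max_iter = 100L, tol = 1e-4,
                               wavenumber = NULL) {
  if (is.numeric(set) && is.null(dim(set))) {
    if (is.null(wavenumber)) wavenumber <- seq_along(set)
    out <- vancouver_one(set, rescale_unit(wavenumber), order, max_iter, tol)
    return(list(corrected = out$corrected, fits = list(out$fit)))
  }
  stopifnot(inherits(set, "spectrum_set"))
  u <- rescale_unit(set$wavenumber)
  n <- n_spectra(set)
  X <- set$intensities
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    res <- vancouver_one(X[i, ], u, order, max_iter, tol)
    X[i, ] <- res$corrected
    fits[[i]] <- res$fit
  }
  names(fits) <- set$meta$spectrum_id
  list(corrected = spectrum_set(set$wavenumber, X, set$meta), fits = fits)
}

vancouver_one <- function(y, u, order, max_iter, tol) {
  p <- length(y)
  order <- as.integer(order)
  max_iter <- as.integer(max_iter)
  if (order < 1L) stop("polynomial order must be >= 1")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (p <= order + 1L)
    stop("spectrum has ", p, " channels; need more than order + 1 = ", order + 1L)
  B <- legendre_basis(u, order)
  qrB <- qr(B)
  yw <- y
  base_old <- NULL
  base <- numeric(p)
  noise <- 0
  converged <- FALSE
  it <- 0L
  beta <- numeric(order + 1L)
  for (it in seq_len(max_iter)) {
    beta <- qr.coef(qrB, yw)
    base <- drop(B %*% beta)
    r <- yw - base
    neg <- r[r < 0]
    noise <- if (length(neg) >= 2L) stats::sd(neg) else 0
    if (!is.null(base_old)) {
      denom <- max(abs(base))
      delta <- if (denom > 0) max(abs(base - base_old)) / denom else 0
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    base_old <- base
    yw <- pmin(yw, base + noise)
  }
  list(corrected = y - base,
       fit = list(order = order, coefficients = beta, baseline = base,
                  iterations = it, converged = converged,
                  noise_estimate = noise))
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial smoothing via [signal::sgolayfilt()].  Polynomials of
#' degree at most `polyorder` are reproduced exactly, including at the
#' endpoints (handled by asymmetric window fits).
#'
#' @param set a [spectrum_set] or a numeric vector.
#' @param window odd window length, at least `polyorder + 2` and at most the
#'   number of channels (default 7).
#' @param polyorder local polynomial degree (default 3).
#' @return smoothed object of the same shape as the input.
#' @export
smooth_spectra <- function(set, window = 7L, polyorder = 3L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  if (window < polyorder + 2L)
    stop("window must be at least polyorder + 2")
  if (is.numeric(set) && is.null(dim(set))) {
    if (window > length(set)) stop("window exceeds the number of channels")
    return(signal::sgolayfilt(set, p = polyorder, n = window))
  }
  stopifnot(inherits(set, "spectrum_set"))
  if (window > n_channels(set)) stop("window exceeds the number of channels")
  X <- t(apply(set$intensities, 1L, signal::sgolayfilt,
               p = polyorder, n = window))
  if (n_spectra(set) == 1L) X <- matrix(X, nrow = 1L)
  spectrum_set(set$wavenumber, X, set$meta)
}

#' Vector (unit Euclidean norm) normalization
#'
#' Divides each spectrum by its Euclidean norm, removing overall intensity
#' differences between cells.  Idempotent and invariant to positive scaling.
#'
#' @param set a [spectrum_set] or a numeric vector.
#' @return object of the same shape, each spectrum with L2 norm 1.
#' @export
vector_normalize <- function(set) {
  if (is.numeric(set) && is.null(dim(set))) {
    nrm <- sqrt(sum(set^2))
    if (nrm == 0) stop("cannot normalize an all-zero spectrum")
    return(set / nrm)
  }
  stopifnot(inherits(set, "spectrum_set"))
  nrm <- sqrt(rowSums(set$intensities^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stop("cannot normalize all-zero spectrum: ",
         paste(set$meta$spectrum_id[zero], collapse = ", "))
  spectrum_set(set$wavenumber, set$intensities / nrm, set$meta)
}
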