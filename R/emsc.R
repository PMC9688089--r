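#' Fit an extended multiplicative signal correction model
#'
#' Models a raw spectrum as a linear superposition of a reference spectrum
#' (the analyte profile measured free of interference), known interferent
#' spectra (glass, agarose, ...) and a smooth polynomial baseline:
#' \deqn{s(\nu) = b\,r(\nu) + \sum_i c_i g_i(\nu) + \sum_j p_j P_j(u) + e(\nu)}
#' where the \eqn{P_j} are Legendre polynomials on the wavenumber axis
#' rescaled to \[-1, 1\].  Coefficients are obtained by ordinary least
#' squares; the reported `p` are in the Legendre basis.
#'
#' The reference and interferent spectra are used exactly as given; in the
#' default pipeline they are themselves baseline-corrected and
#' vector-normalized before entering the design.
#'
#' @param spec numeric vector, or a single-spectrum [spectrum_set].
#' @param reference reference spectrum (numeric vector or 1-row
#'   `spectrum_set`) on the same grid.
#' @param interferents list of interferent spectra (same grid); names are
#'   used in the coefficient table (unnamed entries become `int1`, `int2`...).
#' @param poly_order baseline polynomial degree (default 4).
#' @param wavenumber wavenumber axis; required when `spec` is a bare vector
#'   (used to build the polynomial basis).
#' @return an object of class `emsc_model` with elements `b`, `c`, `p`,
#'   `residual_norm`, `fitted`, and the model ingredients.
#' @export
fit_emsc <- function(spec, reference, interferents = list(), poly_order = 4L,
                     wavenumber = NULL) {
  y <- spec_vector(spec)
  if (is.null(wavenumber)) {
    wavenumber <- if (inherits(spec, "spectrum_set")) spec$wavenumber
                  else if (inherits(reference, "spectrum_set")) reference$wavenumber
                  else seq_along(y)
  }
  ref <- spec_vector(reference)
  ints <- lapply(interferents, spec_vector)
  if (length(ints) && is.null(names(ints)))
    names(ints) <- paste0("int", seq_along(ints))
  if (length(ints) && any(names(ints) == ""))
    names(ints)[names(ints) == ""] <- paste0("int", which(names(ints) == ""))
  p <- length(y)
  if (any(!is.finite(y)))
    stop("spectrum contains non-finite intensities")
  if (length(ref) != p || any(lengths(ints) != p) || length(wavenumber) != p)
    stop("spectrum, reference and interferents must share one grid")
  B <- legendre_basis(rescale_unit(wavenumber), poly_order)
  D <- cbind(reference = ref,
             if (length(ints)) do.call(cbind, ints),
             B)
  colnames(D) <- c("reference", names(ints), colnames(B))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop("EMSC design matrix is rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrD, y)
  fitted <- drop(D %*% beta)
  k <- length(ints)
  structure(list(b = unname(beta[1L]),
                 c = if (k) stats::setNames(beta[1L + seq_len(k)], names(ints))
                     else numeric(0),
                 p = unname(beta[(k + 2L):length(beta)]),
                 residual_norm = sqrt(sum((y - fitted)^2)),
                 fitted = fitted,
                 poly_order = as.integer(poly_order),
                 wavenumber = wavenumber,
                 reference = ref,
                 interferents = ints),
            class = "emsc_model")
}

#' @export
print.emsc_model <- function(x, ...) {
  cat("<emsc_model> b =", format(x$b, digits = 4))
  if (length(x$c))
    cat(";", paste0("c_", names(x$c), " = ", format(x$c, digits = 4),
                    collapse = ", "))
  cat("; poly order", x$poly_order,
      "; residual norm", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

spec_vector <- function(x) {
  if (inherits(x, "spectrum_set")) {
    if (n_spectra(x) != 1L)
      stop("expected a single spectrum, got ", n_spectra(x))
    return(drop(x$intensities[1L, ]))
  }
  as.numeric(x)
}

#' Apply an EMSC correction
#'
#' `subtract` removes the fitted interferent and baseline contributions;
#' `normalize` additionally divides by the reference scale `b`, putting all
#' spectra on the reference's intensity scale.
#'
#' @param spec the spectrum the model was fitted on (vector or 1-row
#'   [spectrum_set]).
#' @param model an [fit_emsc()] result.
#' @param mode `"subtract"` (default) or `"normalize"`.
#' @return corrected spectrum (same shape as `spec`).
#' @export
emsc_correct <- function(spec, model, mode = c("subtract", "normalize")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "emsc_model"))
  y <- spec_vector(spec)
  if (length(y) != length(model$wavenumber))
    stop("spectrum is not on the model's grid")
  removed <- numeric(length(y))
  if (length(model$interferents))
    removed <- removed +
      drop(do.call(cbind, model$interferents) %*% model$c)
  B <- legendre_basis(rescale_unit(model$wavenumber), model$poly_order)
  removed <- removed + drop(B %*% model$p)
  out <- y - removed
  if (mode == "normalize") {
    if (abs(model$b) < 1e-8)
      stop("reference coefficient b is numerically zero; cannot normalize")
    out <- out / model$b
  }
  if (inherits(spec, "spectrum_set"))
    return(spectrum_set(spec$wavenumber, matrix(out, 1L), spec$meta))
  out
}

#' Batch EMSC over a spectrum set
#'
#' Fits and applies EMSC per spectrum, collecting a per-spectrum coefficient
#' table for quality control.  Per-row failures are collected and reported;
#' the batch aborts only if every row fails.
#'
#' @param set a [spectrum_set].
#' @param reference,interferents,poly_order as in [fit_emsc()].
#' @param mode as in [emsc_correct()].
#' @return a list with `corrected` (a `spectrum_set` of the successful rows),
#'   `coefficients` (data.frame: `spectrum_id`, `b`, one `c_*` column per
#'   interferent, `p_0`..`p_k`, `residual_norm`), and `failures`
#'   (data.frame: `spectrum_id`, `message`).
#' @export
batch_emsc <- function(set, reference, interferents = list(), poly_order = 4L,
                       mode = c("subtract", "normalize")) {
  stopifnot(inherits(set, "spectrum_set"))
  mode <- match.arg(mode)
  n <- n_spectra(set)
  ok <- logical(n)
  msgs <- character(n)
  rows <- vector("list", n)
  X <- set$intensities
  for (i in seq_len(n)) {
    res <- tryCatch({
      m <- fit_emsc(X[i, ], reference, interferents, poly_order,
                    wavenumber = set$wavenumber)
      corr <- emsc_correct(X[i, ], m, mode)
      list(model = m, corrected = corr)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      msgs[i] <- res
    } else {
      ok[i] <- TRUE
      X[i, ] <- res$corrected
      m <- res$model
      rows[[i]] <- c(b = m$b,
                     if (length(m$c)) stats::setNames(m$c, paste0("c_", names(m$c))),
                     stats::setNames(m$p, paste0("p_", seq_along(m$p) - 1L)),
                     residual_norm = m$residual_norm)
    }
  }
  if (n > 0L && !any(ok))
    stop("EMSC failed for every spectrum; first error: ", msgs[1L])
  coefs <- if (any(ok))
    data.frame(spectrum_id = set$meta$spectrum_id[ok],
               do.call(rbind, rows[ok]), check.names = FALSE,
               stringsAsFactors = FALSE)
  else
    data.frame(spectrum_id = character(0))
  list(corrected = spectrum_set(set$wavenumber, X[ok, , drop = FALSE],
                                set$meta[ok, , drop = FALSE]),
       coefficients = coefs,
       failures = data.frame(spectrum_id = set$meta$spectrum_id[!ok],
                             message = msgs[!ok],
                             stringsAsFactors = FALSE))
}
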